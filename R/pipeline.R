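#' Run the full reference-normalization build
#'
#' End-to-end pipeline: read the population VCF, select major alleles
#' (AF > threshold), resolve co-located conflicts, apply the edit set to the
#' genome, verify, build the coordinate map and chain file, and — when an
#' annotation is supplied — migrate the gene models and sanity-check them
#' against reference mRNA/protein sets. All artifacts are written under
#' `out_dir` together with a `config.json` recording the run parameters.
#'
#' @param vcf Path to the population VCF (or a population tibble).
#' @param fasta Path to the genome FASTA (or a named character vector).
#' @param out_dir Output directory (created if needed).
#' @param genepred Optional path to a genePred table (or a gene-model tibble).
#' @param mrna,protein Optional reference FASTA paths (or named vectors) for
#'   the sanity check.
#' @param threshold Selection threshold (strict). Default 0.5.
#' @param classes Variant classes eligible for replacement.
#' @param min_intron Intron-collapse threshold for annotation migration.
#' @param uppercase_all Uppercase the whole output genome.
#' @return Invisibly, a list with the in-memory artifacts: `genome`, `log`,
#'   `map`, `chain`, `summary`, `verification`, `models`, `sanity`.
#' @export
run_build <- function(vcf, fasta, out_dir,
                      genepred = NULL, mrna = NULL, protein = NULL,
                      threshold = 0.5,
                      classes = c("SNP", "INDEL", "SNP_INDEL", "MNP"),
                      min_intron = 0, uppercase_all = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta))
    read_genome(fasta) else fasta
  variants <- if (is.character(vcf)) read_population_vcf(vcf) else vcf

  edits_all <- select_major_alleles(variants, threshold = threshold)
  edits_all <- filter(edits_all, .data$class %in% classes)
  res <- resolve_colocated(edits_all)
  summary <- summarize_selection(variants, res$kept, res$dropped)

  applied <- apply_edits(genome, res$kept, uppercase_all = uppercase_all)
  verification <- verify_edits(applied$genome, applied$log, genome)
  if (!verification$pass) {
    stop_majorref("VERIFICATION_FAILED", "edited genome failed verification")
  }
  map <- build_map(applied$log)
  chain <- build_chain(applied$log)

  contigs <- vapply(genome, nchar, 0L)
  write_genome(applied$genome, file.path(out_dir, "normalized.fa"))
  if (requireNamespace("Rsamtools", quietly = TRUE)) {
    try(Rsamtools::indexFa(file.path(out_dir, "normalized.fa")), silent = TRUE)
  }
  write_edit_log(applied$log, file.path(out_dir, "edits.tsv"))
  jsonlite::write_json(applied$log$edits, file.path(out_dir, "edits.json"))
  write_chain(chain, file.path(out_dir, "new2old.over.chain"))
  write_vcf(res$kept, file.path(out_dir, "combined.vcf"), contigs = contigs)
  for (cl in intersect(classes, unique(res$kept$class))) {
    write_vcf(filter(res$kept, .data$class == cl),
              file.path(out_dir, paste0("selected_", cl, ".vcf")), contigs = contigs)
  }
  if (nrow(res$dropped) > 0) {
    readr::write_tsv(res$dropped, file.path(out_dir, "dropped_conflicts.tsv"))
  }
  readr::write_tsv(as_tibble(summary), file.path(out_dir, "selection_summary.tsv"))
  jsonlite::write_json(list(classes = as.data.frame(summary),
                            dropped_conflicts = attr(summary, "dropped_conflicts"),
                            no_frequency = attr(summary, "no_frequency")),
                       file.path(out_dir, "selection_summary.json"), auto_unbox = TRUE)

  models <- NULL; sanity <- NULL
  if (!is.null(genepred)) {
    gp <- if (is.character(genepred)) read_genepred(genepred) else genepred
    mrna_set <- if (is.character(mrna) && length(mrna) == 1 && file.exists(mrna))
      read_genome(mrna) else mrna
    protein_set <- if (is.character(protein) && length(protein) == 1 && file.exists(protein))
      read_genome(protein) else protein
    mig <- migrate_annotation(gp, map, applied$genome,
                              mrna_set = mrna_set, protein_set = protein_set,
                              min_intron = min_intron)
    models <- mig$models
    sanity <- mig$report
    write_genepred(select(models, -dplyr::any_of(c("snapped", "introns_merged", "status"))),
                   file.path(out_dir, "migrated.genePred"))
    if (!is.null(sanity)) {
      readr::write_tsv(sanity$per_transcript, file.path(out_dir, "sanity_per_transcript.tsv"))
      jsonlite::write_json(as.list(sanity$summary), file.path(out_dir, "sanity_summary.json"),
                           auto_unbox = TRUE)
    }
  }
  config <- list(threshold = threshold, classes = classes,
                 min_intron = min_intron, uppercase_all = uppercase_all)
  jsonlite::write_json(config, file.path(out_dir, "config.json"), auto_unbox = TRUE)
  invisible(list(genome = applied$genome, log = applied$log, map = map,
                 chain = chain, summary = summary, verification = verification,
                 models = models, sanity = sanity))
}
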