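test_that("quality filtering is strictly greater-than on both criteria", {
  calls <- tibble(chrom = "c1", pos = 1:5, ref = "A", alt = "G",
                  qual = c(11, 10, 30, 50, NA), dp = c(4, 9, 3, NA, 10))
  kept <- filter_calls(calls)
  expect_equal(kept$pos, 1L)
})

test_that("normalization yields minimal left-aligned records and is idempotent", {
  g <- c(c1 = "GGGTTTT")
  r <- normalize_variants(tibble(chrom = "c1", pos = 4L, ref = "TT", alt = "T"), g)
  expect_equal(r$pos, 3L)
  expect_equal(r$ref, "GT")
  expect_equal(r$alt, "G")

  g2 <- c(c1 = "AAAACATAA")
  r2 <- normalize_variants(tibble(chrom = "c1", pos = 5L, ref = "CAT", alt = "CGT"), g2)
  expect_equal(r2$pos, 6L)
  expect_equal(r2$ref, "A")
  expect_equal(r2$alt, "G")

  # an already-minimal SNP is untouched
  r3 <- normalize_variants(tibble(chrom = "c1", pos = 2L, ref = "G", alt = "C"), g)
  expect_equal(r3$ref, "G")
  expect_equal(r3$pos, 2L)

  # idempotence over generated indels
  sc <- sim_callsets(sim_genome(c(c1 = 5000L), seed = 81), seed = 81)
  n1 <- normalize_variants(sc$a, sim_genome(c(c1 = 5000L), seed = 81))
  n2 <- normalize_variants(n1, sim_genome(c(c1 = 5000L), seed = 81))
  expect_equal(as.data.frame(n1), as.data.frame(n2))

  expect_error(normalize_variants(tibble(chrom = "c1", pos = 1L, ref = "T", alt = "A"), g),
               class = "majorref_ref_mismatch")
})

test_that("decomposition emits per-base SNPs and alignment-derived indels", {
  d <- decompose_primitives(tibble(chrom = "c1", pos = 5L, ref = "AT", alt = "GC"))
  expect_equal(d$pos, c(5L, 6L))
  expect_equal(d$ref, c("A", "T"))
  expect_equal(d$alt, c("G", "C"))
  expect_equal(d$vclass, c("SNP", "SNP"))

  # a simple record passes through
  d2 <- decompose_primitives(tibble(chrom = "c1", pos = 5L, ref = "A", alt = "G"))
  expect_equal(nrow(d2), 1)
  expect_equal(d2$vclass, "SNP")

  # complex substitution: one SNP plus one deletion, per unit-cost alignment
  d3 <- decompose_primitives(tibble(chrom = "c1", pos = 5L, ref = "ACG", alt = "TG"))
  expect_equal(d3$vclass, c("SNP", "INDEL"))
  expect_equal(d3$ref, c("A", "TC"))
  expect_equal(d3$alt, c("T", "T"))
  expect_equal(d3$pos, c(5L, 5L))

  # extra columns (qual, dp) are carried onto every primitive
  d4 <- decompose_primitives(tibble(chrom = "c1", pos = 5L, ref = "AT", alt = "GC",
                                    qual = 33, dp = 12))
  expect_equal(d4$qual, c(33, 33))
})

test_that("decomposition conserves unit-cost edit distance on spans up to 20 bp", {
  set.seed(82)
  bases <- c("A", "C", "G", "T")
  for (i in 1:60) {
    # length-changing records follow the alignment; equal-length records are
    # defined as per-base SNPs, so only the former carry the optimality claim
    nr <- sample(2:20, 1)
    na <- sample(setdiff(2:20, nr), 1)
    ref <- paste(sample(bases, nr, TRUE), collapse = "")
    alt <- paste(sample(bases, na, TRUE), collapse = "")
    if (ref == alt) next
    prim <- decompose_primitives(tibble(chrom = "c1", pos = 100L, ref = ref, alt = alt))
    cost <- sum(ifelse(prim$vclass == "SNP", 1L,
                       abs(nchar(prim$ref) - nchar(prim$alt))))
    expect_equal(cost, as.integer(utils::adist(ref, alt)),
                 info = paste(ref, alt))
  }
})

test_that("set comparison counts common and unique calls as planted", {
  a <- tibble(chrom = c("1", "1", "2"), pos = c(5L, 10L, 7L),
              ref = c("A", "AT", "C"), alt = c("G", "A", "T"),
              vclass = c("SNP", "INDEL", "SNP"))
  b <- tibble(chrom = c("1", "2", "2"), pos = c(5L, 7L, 30L),
              ref = c("G", "C", "G"), alt = c("A", "T", "GTT"),
              vclass = c("SNP", "SNP", "INDEL"))
  rep <- compare_sets(a, b, mode = "position")
  g <- glance(rep)
  expect_equal(g$common, 2L)
  expect_equal(g$unique_a, 1L)
  expect_equal(g$unique_b, 1L)
  expect_equal(g$fp_pct, 33.33)
  expect_equal(g$fn_pct, 33.33)

  # identical sets: no uniques at all
  rep2 <- compare_sets(a, a)
  expect_true(all(tidy(rep2)$fp_pct[tidy(rep2)$total_a > 0] == 0))

  # allele mode reconciles REF/ALT swaps but rejects different alleles
  x <- tibble(chrom = "1", pos = 5L, ref = "A", alt = "G", vclass = "SNP")
  y <- tibble(chrom = "1", pos = 5L, ref = "G", alt = "A", vclass = "SNP")
  z <- tibble(chrom = "1", pos = 5L, ref = "A", alt = "T", vclass = "SNP")
  expect_equal(compare_sets(x, y, mode = "allele")$common[1], 1L)
  expect_equal(compare_sets(x, z, mode = "allele")$common[1], 0L)
  expect_equal(compare_sets(x, z, mode = "position")$common[1], 1L)

  # overlapping indels count as the same event; the window widens the net
  i1 <- tibble(chrom = "1", pos = 10L, ref = "TACGT", alt = "T", vclass = "INDEL")
  i2 <- tibble(chrom = "1", pos = 12L, ref = "CGTAA", alt = "C", vclass = "INDEL")
  i3 <- tibble(chrom = "1", pos = 18L, ref = "AAC", alt = "A", vclass = "INDEL")
  expect_equal(compare_sets(i1, i2)$common[2], 1L)
  expect_equal(compare_sets(i1, i3)$common[2], 0L)
  expect_equal(compare_sets(i1, i3, indel_window = 5)$common[2], 1L)

  expect_error(compare_sets(a[c(2, 1, 3), ], b), class = "majorref_sort_required")
})

test_that("swapping the sets swaps the unique counts and rates", {
  g <- sim_genome(c(c1 = 20000L), seed = 83)
  cs <- sim_callsets(g, seed = 83)
  ab <- tidy(compare_sets(cs$a, cs$b))
  ba <- tidy(compare_sets(cs$b, cs$a))
  expect_equal(ab$common, ba$common)
  expect_equal(ab$unique_a, ba$unique_b)
  expect_equal(ab$fp_pct, ba$fn_pct)
})

test_that("planted truth is recovered exactly in both comparison modes", {
  for (seed in c(84, 85)) {
    g <- sim_genome(c(c1 = 30000L, c2 = 20000L), seed = seed)
    cs <- sim_callsets(g, seed = seed, n_common = 60L, n_unique_a = 12L,
                       n_unique_b = 8L, n_swap = 6L, n_overlap_indel = 5L)
    for (mode in c("position", "allele")) {
      rep <- tidy(compare_sets(cs$a, cs$b, mode = mode))
      expect_equal(rep$common, cs$truth$common)
      expect_equal(rep$unique_a, cs$truth$unique_a)
      expect_equal(rep$unique_b, cs$truth$unique_b)
    }
  }
})

test_that("fp/fn percentages follow the unique/total ratios", {
  r <- compute_fp_fn(tibble(total_a = 200L, unique_a = 30L,
                            total_b = 100L, unique_b = 0L))
  expect_equal(r$fp_pct, 15)
  expect_equal(r$fn_pct, 0)
  r2 <- compute_fp_fn(tibble(total_a = 0L, unique_a = 0L, total_b = 0L, unique_b = 0L))
  expect_true(is.na(r2$fp_pct) && is.na(r2$fn_pct))
  r3 <- compute_fp_fn(tibble(total_a = 3L, unique_a = 1L, total_b = 3L, unique_b = 2L),
                      decimals = 3)
  expect_equal(r3$fp_pct, 33.333)
})
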