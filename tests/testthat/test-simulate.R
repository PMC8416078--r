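# Mock-formulation simulator: formula loading, read generation,
# determinism, proportions, chimera injection.

test_that("the bundled formulation table loads with the prescribed dosages", {
  f <- load_formula(fkdsw_formula_path())
  expect_equal(nrow(f), 6L)
  expect_equal(max(f$proportion), 59.26)
  expect_equal(min(f$proportion), 3.70)
})

test_that("formula validation enforces range and sum", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ingredient\ttaxid\tproportion", "only\t101\t100"), tf)
  expect_equal(nrow(load_formula(tf)), 1L) # degenerate single-ingredient
  writeLines(c("ingredient\ttaxid\tproportion",
               "a\t101\t60", "b\t102\t60"), tf)
  expect_error(load_formula(tf), "sum")
  writeLines(c("ingredient\ttaxid\tproportion",
               "a\t101\t0", "b\t102\t100"), tf)
  expect_error(load_formula(tf), "\\(0, 100\\]")
})

one_taxon_design <- function(n_pairs = 200L, error_rate = 0,
                             seed = 5L, ...) {
  f <- data.frame(ingredient = "only", taxid = 101L, proportion = 100)
  mock_design(f, contaminants = data.frame(taxid = integer(0),
                                           proportion = numeric(0)),
              chimera_fraction = 0, background_fraction = 0,
              error_rate = error_rate, n_pairs = n_pairs, seed = seed,
              ...)
}

test_that("at zero error every read is a substring of its locus", {
  set.seed(1)
  loci <- data.frame(taxid = 101L, marker = "ITS2",
                     locus = rand_dna(900), region = "",
                     stringsAsFactors = FALSE)
  sim <- simulate_shotgun(one_taxon_design(), loci)
  expect_true(all(vapply(sim$reads$seq1, grepl, TRUE, x = loci$locus,
                         fixed = TRUE)))
  # reverse mate is a reverse-complemented substring
  expect_true(all(vapply(revcomp(sim$reads$seq2), grepl, TRUE,
                         x = loci$locus, fixed = TRUE)))
})

test_that("identical design and seed give byte-identical FASTQ", {
  loci <- synthetic_loci(seed = 2)
  f <- load_formula(fkdsw_formula_path())
  d <- mock_design(f, n_pairs = 400L, seed = 99L)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  simulate_shotgun(d, loci, out_prefix = p1)
  simulate_shotgun(d, loci, out_prefix = p2)
  expect_identical(unname(tools::md5sum(paste0(p1, "_1.fastq"))),
                   unname(tools::md5sum(paste0(p2, "_1.fastq"))))
  expect_identical(unname(tools::md5sum(paste0(p1, "_2.fastq"))),
                   unname(tools::md5sum(paste0(p2, "_2.fastq"))))
})

test_that("read counts are conserved and recorded once per pair", {
  loci <- synthetic_loci(seed = 2)
  f <- load_formula(fkdsw_formula_path())
  d <- mock_design(f, n_pairs = 1000L, seed = 7L)
  sim <- simulate_shotgun(d, loci)
  expect_equal(nrow(sim$reads), 1000L)
  expect_equal(nrow(sim$truth), 1000L)
  expect_equal(anyDuplicated(sim$truth$pair_id), 0L)
})

test_that("dosage extremes reproduce the designed ~16x count ratio", {
  loci <- synthetic_loci(seed = 2)
  f <- load_formula(fkdsw_formula_path())
  d <- mock_design(f, contaminants = data.frame(taxid = integer(0),
                                                proportion = numeric(0)),
                   background_fraction = 0, chimera_fraction = 0,
                   n_pairs = 10000L, seed = 21L)
  sim <- simulate_shotgun(d, loci)
  n_hi <- sum(sim$truth$taxid == 105, na.rm = TRUE) # 59.26%
  n_lo <- sum(sim$truth$taxid == 103, na.rm = TRUE) # 3.70%
  ratio <- 59.26 / 3.70
  # 3-sigma band for the count ratio via the multinomial delta method
  N <- 10000
  p_hi <- 0.5926; p_lo <- 0.037
  sd_ratio <- ratio * sqrt((1 - p_hi) / (N * p_hi) +
                           (1 - p_lo) / (N * p_lo))
  expect_lt(abs(n_hi / n_lo - ratio), 3 * sd_ratio)
})

test_that("per-taxon fractions fit the design across 20 seeds", {
  loci <- synthetic_loci(seed = 2)
  f <- load_formula(fkdsw_formula_path())
  pvals <- vapply(1:20, function(s) {
    d <- mock_design(f, contaminants = data.frame(taxid = integer(0),
                                                  proportion = numeric(0)),
                     background_fraction = 0, chimera_fraction = 0,
                     n_pairs = 3000L, seed = s)
    sim <- simulate_shotgun(d, loci)
    counts <- table(factor(sim$truth$taxid, levels = f$taxid))
    suppressWarnings(
      stats::chisq.test(as.vector(counts), p = f$proportion / 100,
                        rescale.p = TRUE)$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.01))
})

test_that("chimera injection splices prefix of A onto suffix of B", {
  set.seed(8)
  pa <- rand_dna(300); pb <- rand_dna(300)
  frags <- data.frame(taxid = rep(c(1L, 2L), each = 5),
                      marker = "ITS2", seq = rep(c(pa, pb), each = 5),
                      stringsAsFactors = FALSE)
  # fraction 0 is a no-op
  out0 <- inject_chimeras(frags, 0)
  expect_identical(out0$seq, frags$seq)
  expect_false(any(out0$chimera))
  # fraction 1 on 10 fragments with 2 parent taxa: 10 flagged splices
  out1 <- inject_chimeras(frags, 1, seed = 9)
  expect_equal(sum(out1$chimera), 10L)
  for (i in which(out1$chimera)) {
    x <- out1$crossover[i]
    parent_a <- c(pa, pb)[match(out1$parent_a[i], c(1L, 2L))]
    parent_b <- c(pa, pb)[match(out1$parent_b[i], c(1L, 2L))]
    expect_identical(substr(out1$seq[i], 1, x), substr(parent_a, 1, x))
    expect_identical(substring(out1$seq[i], x + 1),
                     substring(parent_b, x + 1))
    # crossover confined to the middle 60%
    expect_gte(x, 0.2 * 300 - 1)
    expect_lte(x, 0.8 * 300 + 1)
  }
  # single parent taxon: error
  one <- frags[frags$taxid == 1L, ]
  expect_error(inject_chimeras(one, 0.5, seed = 1), "parent taxa")
})

test_that("locus shorter than the insert model is rejected by name", {
  loci <- data.frame(taxid = 101L, marker = "matK", locus = rand_dna(200),
                     region = "", stringsAsFactors = FALSE)
  expect_error(simulate_shotgun(one_taxon_design(), loci),
               "matK")
})
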