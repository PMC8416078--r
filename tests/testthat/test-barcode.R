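# Primer trimming, ITS2 flank annotation, chimera detection, OTU
# clustering.

test_that("exact primer flanks are trimmed to the insert", {
  set.seed(60)
  ps <- default_primer_sets()$matK
  insert <- rand_dna(700)
  contig <- paste0(rand_dna(40), ps$forward, insert,
                   revcomp(ps$reverse), rand_dna(40))
  r <- trim_primers(contig, ps)
  expect_identical(r$sequence, insert)
  expect_equal(r$trim_status, "both-ends")
  # a reverse-complemented contig gives the same forward-oriented insert
  r2 <- trim_primers(revcomp(contig), ps)
  expect_identical(r2$sequence, insert)
  # contig without primers passes through, flagged none
  plain <- rand_dna(500)
  r3 <- trim_primers(plain, ps)
  expect_equal(r3$trim_status, "none")
  expect_identical(r3$sequence, plain)
})

test_that("primer matching tolerates the per-length error allowance", {
  set.seed(61)
  # 20 nt primers: ceiling(0.1 * 20) = 2 errors allowed
  ps <- primer_set("rbcL", rand_dna(20), rand_dna(20),
                   max_error_rate = 0.1)
  insert <- rand_dna(400)
  fwd_mut <- ps$forward
  substr(fwd_mut, 7, 7) <- setdiff(c("A", "C", "G", "T"),
                                   substr(fwd_mut, 7, 7))[1]
  contig <- paste0(fwd_mut, insert, revcomp(ps$reverse))
  r <- trim_primers(contig, ps)
  expect_identical(r$sequence, insert)
  expect_equal(r$trim_status, "both-ends")
})

test_that("primer placement agrees with the exhaustive edit-distance oracle", {
  set.seed(62)
  for (i in 1:50) {
    primer <- rand_dna(20)
    pos <- sample(50:200, 1)
    implant <- primer
    n_err <- sample(0:2, 1)
    for (e in seq_len(n_err)) {
      p <- sample(20, 1)
      substr(implant, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    contig <- paste0(rand_dna(pos - 1), implant, rand_dna(80))
    got <- herbshot:::cpp_primer_find(contig, primer)
    want <- oracle_primer_best(contig, primer)
    expect_equal(got$dist, want$dist)
    expect_equal(got$end, want$end)
  }
})

test_that("ITS2 annotation recovers the region between the flank motifs", {
  set.seed(63)
  flanks <- default_flank_profiles()
  insert <- rand_dna(250, gc = 0.6)
  contig <- paste0(rand_dna(120), herbshot:::ITS2_FLANK_5_8S, insert,
                   herbshot:::ITS2_FLANK_28S, rand_dna(120))
  r <- annotate_its2(contig, flanks)
  expect_identical(r$sequence, insert)
  expect_equal(r$trim_status, "both-ends")
  # the reverse strand is found too
  r2 <- annotate_its2(revcomp(contig), flanks)
  expect_identical(r2$sequence, insert)
  # no flanks -> no candidate
  expect_null(annotate_its2(rand_dna(400), flanks))
})

test_that("a doubly substituted flank still scores above threshold", {
  set.seed(64)
  flanks <- default_flank_profiles()
  motif <- herbshot:::ITS2_FLANK_5_8S
  mut <- motif
  for (p in c(3L, 11L)) {
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, p, p))[1]
  }
  # hand-computed PWM score: 18 consensus + 2 off-consensus columns
  expected <- 18 * log2(0.91 / 0.25) + 2 * log2(0.03 / 0.25)
  got <- unname(herbshot:::pwm_scan(mut, flanks[["5.8S-end"]])[1])
  expect_equal(got, expected, tolerance = 1e-10)
  expect_gt(got, flanks[["5.8S-end"]]$threshold)
  # and the annotation cut is unchanged
  insert <- rand_dna(250, gc = 0.6)
  contig <- paste0(rand_dna(100), mut, insert,
                   herbshot:::ITS2_FLANK_28S, rand_dna(100))
  expect_identical(annotate_its2(contig, flanks)$sequence, insert)
})

test_that("chimera detection flags constructed splices and spares parents", {
  set.seed(65)
  pa <- rand_dna(300)
  pb <- rand_dna(300)
  splice_at <- 120L
  chim <- paste0(substr(pa, 1, splice_at), substring(pb, splice_at + 1))
  pool <- data.frame(candidate_id = c("A", "B"), sequence = c(pa, pb),
                     abundance = c(10, 10), stringsAsFactors = FALSE)
  q <- data.frame(candidate_id = "Q", sequence = chim, abundance = 1)
  v <- detect_chimera(q, pool)
  expect_true(v$chimeric)
  expect_setequal(c(v$parent_a, v$parent_b), c("A", "B"))
  expect_lte(abs(v$crossover - splice_at), 5)
  # identical to a pool member: full identity 100% > 97% -> non-chimeric
  dup <- data.frame(candidate_id = "D", sequence = pa, abundance = 1)
  expect_false(detect_chimera(dup, pool)$chimeric)
  # empty pool -> non-chimeric
  expect_false(detect_chimera(q, pool[0, ])$chimeric)
})

test_that("a point mutant of one parent is not a chimera (oracle-checked)", {
  set.seed(66)
  pa <- rand_dna(300)
  pb <- rand_dna(300)
  mut <- pa
  substr(mut, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                   substr(mut, 150, 150))[1]
  pool <- data.frame(candidate_id = c("A", "B"), sequence = c(pa, pb),
                     abundance = c(10, 10), stringsAsFactors = FALSE)
  q <- data.frame(candidate_id = "Q", sequence = mut, abundance = 1)
  expect_false(detect_chimera(q, pool)$chimeric)
  # the exhaustive split scan confirms no two-parent split reaches 99/99
  expect_false(oracle_split_scan(mut, c(pa, pb)))
  # and the genuine splice from the previous construction does
  chim <- paste0(substr(pa, 1, 120), substring(pb, 121))
  expect_true(oracle_split_scan(chim, c(pa, pb)))
})

test_that("OTU clustering groups exact haplotypes strand-insensitively", {
  set.seed(67)
  s <- rand_dna(220)
  s_mut <- s
  substr(s_mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                   substr(s_mut, 10, 10))[1]
  cands <- data.frame(
    candidate_id = paste0("c", 1:6),
    marker = "ITS2",
    sequence = c(rep(s, 4), revcomp(s), s_mut),
    stringsAsFactors = FALSE)
  otus <- cluster_otus(cands)
  expect_equal(nrow(otus), 2L)
  # 5 identical members (one as RC) dominate; the 1-mismatch variant is
  # its own OTU
  expect_equal(otus$n_members, c(5L, 1L))
  expect_equal(sort(unlist(strsplit(otus$members[1], ","))),
               paste0("c", 1:5))
  # empty input
  expect_equal(nrow(cluster_otus(cands[0, ])), 0L)
  # mixed markers are refused
  cands$marker[1] <- "matK"
  expect_error(cluster_otus(cands), "single marker")
})

test_that("simulated chimeric candidates are recovered with no false positives", {
  set.seed(68)
  loci <- synthetic_loci(seed = 2)
  f <- load_formula(fkdsw_formula_path())
  # parent haplotypes are the formulation species (mutually unrelated,
  # as in the mock sample); 10 candidate copies of each
  its2 <- loci[loci$marker == "ITS2" & loci$taxid %in% f$taxid, ]
  frags <- data.frame(taxid = rep(its2$taxid, each = 10), marker = "ITS2",
                      seq = rep(its2$region, each = 10),
                      stringsAsFactors = FALSE)
  out <- inject_chimeras(frags, 0.1, seed = 77)
  # build the candidate table: surviving parent copies collapse into
  # high-abundance candidates, each chimera is a singleton
  parents <- out[!out$chimera, ]
  ptab <- aggregate(list(abundance = parents$taxid),
                    by = list(sequence = parents$seq), FUN = length)
  cands <- rbind(
    data.frame(candidate_id = paste0("p", seq_len(nrow(ptab))),
               marker = "ITS2", sequence = ptab$sequence,
               abundance = ptab$abundance, truth = FALSE,
               stringsAsFactors = FALSE),
    data.frame(candidate_id = paste0("x", seq_len(sum(out$chimera))),
               marker = "ITS2", sequence = out$seq[out$chimera],
               abundance = 1, truth = TRUE, stringsAsFactors = FALSE))
  res <- filter_chimeras(cands[c("candidate_id", "marker", "sequence",
                                 "abundance")])
  flagged <- res$verdicts$candidate_id[res$verdicts$chimeric]
  truth_ids <- cands$candidate_id[cands$truth]
  recall <- length(intersect(flagged, truth_ids)) / length(truth_ids)
  expect_gte(recall, 0.9)
  expect_length(setdiff(flagged, truth_ids), 0L)
})
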