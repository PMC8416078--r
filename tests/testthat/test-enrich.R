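# Marker-labelled k-mer screening of read pairs.

tiny_db <- function(seqs, markers, tax = synthetic_taxonomy()) {
  reference_db(data.frame(ref_id = paste0("r", seq_along(seqs)),
                          marker = markers, taxid = 101L,
                          sequence = seqs, stringsAsFactors = FALSE),
               tax)
}

test_that("index size and shared-label lookups behave as specified", {
  set.seed(40)
  ref <- rand_dna(100)
  idx <- build_kmer_index(tiny_db(ref, "ITS2"), k = 31)
  # a 100 nt reference has L - k + 1 = 70 windows
  expect_equal(herbshot:::cpp_kmer_index_size(idx$ptr), 70L)
  # querying the reference itself hits every window under its own marker
  expect_equal(unname(herbshot:::kmer_hits(idx, ref)),
               c(70L, 0L, 0L))
  # a k-mer present in two markers carries both labels
  shared <- substr(ref, 10, 40)
  db2 <- tiny_db(c(ref, paste0(rand_dna(50), shared, rand_dna(50))),
                 c("ITS2", "rbcL"))
  idx2 <- build_kmer_index(db2, k = 31)
  h <- herbshot:::kmer_hits(idx2, shared)
  expect_equal(unname(h[c("ITS2", "rbcL")]), c(1L, 1L))
  # a reference and its reverse complement index identically
  idx_rc <- build_kmer_index(tiny_db(revcomp(ref), "ITS2"), k = 31)
  expect_equal(herbshot:::cpp_kmer_index_size(idx_rc$ptr), 70L)
  expect_equal(unname(herbshot:::kmer_hits(idx_rc, ref)), c(70L, 0L, 0L))
  # k validation
  expect_error(build_kmer_index(tiny_db(ref, "ITS2"), k = 22), "odd")
  expect_error(build_kmer_index(tiny_db(ref, "ITS2"), k = 131), "odd|31")
})

test_that("pair classification uses mate rescue, thresholds and ties", {
  set.seed(41)
  ref <- rand_dna(400)
  db <- tiny_db(ref, "ITS2")
  idx <- build_kmer_index(db, k = 21)
  bg <- rand_dna(150)
  # one informative mate suffices (130 hits >= 3)
  p <- data.frame(seq1 = substr(ref, 50, 199), seq2 = bg)
  expect_equal(classify_pair(p, idx), "ITS2")
  # seeded random background: zero index hits, unassigned
  expect_equal(unname(herbshot:::kmer_hits(idx, bg)), c(0L, 0L, 0L))
  expect_equal(classify_pair(data.frame(seq1 = bg, seq2 = rand_dna(150)),
                             idx), "unassigned")
  # a single shared k-mer stays below min_hits = 3
  one <- paste0(rand_dna(60), substr(ref, 100, 120), rand_dna(60))
  expect_equal(classify_pair(data.frame(seq1 = one, seq2 = bg), idx,
                             min_hits = 3), "unassigned")
  # tie at the top leaves the pair unassigned
  db_tie <- tiny_db(c(ref, ref), c("ITS2", "rbcL"))
  idx_tie <- build_kmer_index(db_tie, k = 21)
  expect_equal(classify_pair(data.frame(seq1 = substr(ref, 1, 150),
                                        seq2 = bg), idx_tie),
               "unassigned")
})

test_that("classification is invariant under reverse-complementing a pair", {
  set.seed(42)
  loci <- synthetic_loci(seed = 2)
  db <- synthetic_refdb(loci)
  idx <- build_kmer_index(db)
  for (i in 1:20) {
    row <- loci[sample(nrow(loci), 1), ]
    s <- sample(nchar(row$region) - 149, 1)
    p <- data.frame(seq1 = substr(row$region, s, s + 149),
                    seq2 = rand_dna(150))
    prc <- data.frame(seq1 = revcomp(p$seq1), seq2 = revcomp(p$seq2))
    expect_equal(classify_pair(p, idx), classify_pair(prc, idx))
    expect_equal(classify_pair(p, idx), row$marker)
  }
})

test_that("enrichment attains perfect recall at zero error and conserves counts", {
  loci <- synthetic_loci(seed = 2)
  db <- synthetic_refdb(loci)
  idx <- build_kmer_index(db)
  f <- load_formula(fkdsw_formula_path())
  d <- mock_design(f, chimera_fraction = 0, background_fraction = 0.4,
                   error_rate = 0, n_pairs = 2000L, seed = 17L)
  sim <- simulate_shotgun(d, loci)
  enr <- enrich_pairs(sim$reads, idx)
  # conservation: bins plus unassigned account for every pair
  expect_equal(sum(enr$counts) + enr$unassigned, nrow(sim$reads))
  # no background pair is ever assigned
  bg_ids <- sim$truth$pair_id[sim$truth$origin == "background"]
  assigned_ids <- unlist(lapply(enr$bins, `[[`, "pair_id"))
  expect_length(intersect(bg_ids, assigned_ids), 0L)
  # every assigned pair lands in its true marker bin
  for (m in c("ITS2", "matK", "rbcL")) {
    ids_m <- enr$bins[[m]]$pair_id
    truth_m <- sim$truth[match(ids_m, sim$truth$pair_id), ]
    expect_true(all(truth_m$marker == m))
  }
  # recall: on-target pairs whose mates overlap the indexed region by at
  # least k + min_hits - 1 nt are always assigned (pairs confined to the
  # unindexed flanks cannot be, by construction)
  tr <- sim$truth[sim$truth$origin == "taxon", ]
  key <- paste(tr$taxid, tr$marker)
  lkey <- paste(loci$taxid, loci$marker)
  rs <- vapply(seq_len(nrow(loci)), function(i) {
    regexpr(loci$region[i], loci$locus[i], fixed = TRUE)[1]
  }, 0L)
  i <- match(key, lkey)
  reg_lo <- rs[i]
  reg_hi <- rs[i] + nchar(loci$region[i]) - 1L
  need <- 21 + 3 - 1 # k + min_hits - 1
  ov <- function(lo, hi) pmax(0L, pmin(hi, reg_hi) - pmax(lo, reg_lo) + 1L)
  m1 <- ov(tr$start, tr$start + 149L)
  m2 <- ov(tr$start + tr$insert_len - 150L, tr$start + tr$insert_len - 1L)
  must <- tr$pair_id[pmax(m1, m2) >= need]
  expect_true(all(must %in% assigned_ids))
})
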