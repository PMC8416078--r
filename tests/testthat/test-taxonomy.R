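# Reference search, LCA placement, and the composition report.

test_that("reference search ranks exact and near-exact hits correctly", {
  set.seed(80)
  tax <- synthetic_taxonomy()
  ref200 <- rand_dna(200)
  db <- reference_db(data.frame(
    ref_id = c("exact", "other"), marker = "ITS2",
    taxid = c(101L, 102L), sequence = c(ref200, rand_dna(200)),
    stringsAsFactors = FALSE), tax)
  hits <- search_hits(ref200, db, "ITS2")
  expect_equal(hits$ref_id[1], "exact")
  expect_equal(hits$identity[1], 100)
  # one interior substitution on a 200 nt reference: identity 99.5
  mut <- ref200
  substr(mut, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                   substr(mut, 100, 100))[1]
  hits2 <- search_hits(mut, db, "ITS2")
  expect_equal(hits2$identity[1], 100 * 199 / 200)
  # a reverse-complement query scores identically
  hits3 <- search_hits(revcomp(ref200), db, "ITS2")
  expect_equal(hits3$score[1], hits$score[1])
  expect_error(search_hits(ref200, db, "matK"), "no records")
})

test_that("local alignment scores match the full Smith-Waterman oracle", {
  set.seed(81)
  for (i in 1:50) {
    q <- rand_dna(sample(80:200, 1))
    r <- if (i %% 2 == 0) {
      paste0(rand_dna(50), herbshot:::mutate_dna(q, runif(1, 0, 0.1)),
             rand_dna(50))
    } else rand_dna(sample(150:300, 1))
    got <- max(herbshot:::cpp_sw_affine(q, r)$score,
               herbshot:::cpp_sw_affine(revcomp(q), r)$score)
    expect_equal(got, oracle_local_score(q, r))
  }
})

test_that("LCA placement follows the top-percent band and identity gate", {
  tax <- synthetic_taxonomy()
  hit <- function(taxid, identity, score) {
    data.frame(ref_id = paste0("r", taxid), taxid = taxid,
               identity = identity, aligned_len = 200, score = score,
               strand = "+", stringsAsFactors = FALSE)
  }
  # single high-identity hit -> direct species call
  a <- assign_lca(hit(105, 100, 200), tax)
  expect_equal(a$taxid, 105L)
  expect_equal(a$method, "unique-best")
  # congeneric species inside the band -> genus
  h <- rbind(hit(106, 100, 200), hit(107, 97, 185))
  a2 <- assign_lca(h, tax)
  expect_equal(a2$name, "Bupleurum")
  expect_equal(a2$rank, "genus")
  expect_equal(a2$method, "lca")
  # hits spanning two families -> common ancestor per the path oracle
  h3 <- rbind(hit(101, 95, 200), hit(105, 94, 195))
  a3 <- assign_lca(h3, tax)
  expect_equal(a3$taxid, oracle_lca(c(101, 105), tax))
  # a lone low-identity hit cannot be called at species rank
  a4 <- assign_lca(hit(103, 92, 150), tax, species_min_identity = 97)
  expect_equal(a4$taxid, 103L)
  expect_equal(a4$method, "lca")
  # no hits -> unassigned
  expect_equal(assign_lca(hit(101, 100, 10)[0, ], tax)$rank,
               "unassigned")
  # a distant hit outside the band does not drag the call up the tree
  h5 <- rbind(hit(106, 100, 200), hit(108, 60, 100))
  expect_equal(assign_lca(h5, tax)$taxid, 106L)
})

test_that("the composition report aggregates, normalizes and categorizes", {
  tax <- synthetic_taxonomy()
  f <- load_formula(fkdsw_formula_path())
  asg <- data.frame(
    otu_id = paste0("ITS2_OTU_00", 1:5),
    marker = "ITS2",
    taxid = c(105L, 105L, 107L, 108L, 109L),
    rank = c("species", "species", "species", "species", "species"),
    name = c("Leonurus japonicus", "Leonurus japonicus",
             "Bupleurum falcatum", "Humulus scandens",
             "Alternaria alternata"),
    method = "unique-best", n_hits = 1L, stringsAsFactors = FALSE)
  ver <- data.frame(otu_id = asg$otu_id,
                    mapped_read_count = c(600L, 200L, 100L, 60L, 40L),
                    mean_depth = 50, coverage = 100, reliable = TRUE,
                    stringsAsFactors = FALSE)
  otus <- data.frame(otu_id = asg$otu_id, marker = "ITS2",
                     representative = replicate(5, rand_dna(220)),
                     stringsAsFactors = FALSE)
  rep <- build_report(asg, ver, f, tax, otus)
  comp <- rep$composition
  expect_equal(sum(comp$rel_abundance), 100, tolerance = 1e-8)
  # two Leonurus OTUs aggregate into one row with both read counts
  leo <- comp[comp$taxid == 105, ]
  expect_equal(leo$n_otus, 2L)
  expect_equal(leo$reads, 800L)
  expect_equal(leo$category, "prescribed")
  # a non-prescribed congener of a prescribed species is an
  # adulterant candidate
  expect_equal(comp$category[comp$taxid == 107], "adulterant-candidate")
  expect_equal(comp$category[comp$taxid == 108], "weed/other-plant")
  expect_equal(comp$category[comp$taxid == 109], "fungus")
  # detection matrix: only Leonurus is seen, and only in ITS2
  expect_true(rep$detection["Leonurus japonicus", "ITS2"])
  expect_false(any(rep$detection[rownames(rep$detection) !=
                                   "Leonurus japonicus", ]))
  # an unknown taxid in an assignment is an error
  bad <- asg
  bad$taxid[1] <- 31337L
  expect_error(build_report(bad, ver, f, tax, otus), "taxid")
})

test_that("a genus-level call over a prescribed species counts as prescribed", {
  tax <- synthetic_taxonomy()
  f <- load_formula(fkdsw_formula_path())
  expect_equal(herbshot:::taxon_category(20L, f, tax), "prescribed")
  expect_equal(herbshot:::taxon_category(21L, f, tax), "prescribed")
  expect_equal(herbshot:::taxon_category(107L, f, tax),
               "adulterant-candidate")
  expect_equal(herbshot:::taxon_category(27L, f, tax), "fungus")
  expect_equal(herbshot:::taxon_category(NA_integer_, f, tax),
               "unassigned")
})
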