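# Synthetic shotgun data of known composition.
#
# The simulator emulates a shotgun library of a dosage-weighted herbal
# formulation: barcode loci with flanking sequence are sampled per taxon
# in proportion to its mass fraction, diluted in an off-target random
# background, with i.i.d. substitution errors and optional two-parent
# chimeric splices.  A ground-truth table records the origin of every
# pair.

#' Load a formulation table
#'
#' @param file TSV with header row and columns `ingredient`, `taxid`,
#'   `proportion` (percent of mass).  Proportions must lie in (0, 100]
#'   and sum to 100 within 0.1.
#' @return data.frame with those columns.
#' @export
load_formula <- function(file) {
  f <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("ingredient", "taxid", "proportion")
  if (!all(need %in% names(f))) {
    stop("formula table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  f <- f[need]
  f$taxid <- as.integer(f$taxid)
  f$proportion <- as.numeric(f$proportion)
  if (any(f$proportion <= 0 | f$proportion > 100)) {
    stop("formula proportions must lie in (0, 100]", call. = FALSE)
  }
  if (abs(sum(f$proportion) - 100) > 0.1) {
    stop(sprintf("formula proportions sum to %.2f, not 100 (tolerance 0.1)",
                 sum(f$proportion)), call. = FALSE)
  }
  f
}

#' Path to the bundled FKDSW formulation table
#'
#' Six herbal ingredients at their prescribed mass proportions
#' (59.26% down to 3.70%), with taxids referring to the bundled
#' synthetic taxonomy.
#'
#' @return file path.
#' @export
fkdsw_formula_path <- function() {
  system.file("extdata", "fkdsw_formula.tsv", package = "herbshot",
              mustWork = TRUE)
}

#' Bundled synthetic taxonomy
#'
#' A small taxonomy covering the six prescribed FKDSW species, a
#' congeneric adulterant, a weed, a fungus, and their lineages.  Taxids
#' are synthetic (not NCBI).
#'
#' @return taxonomy data.frame (taxid, parent_taxid, rank, name).
#' @export
synthetic_taxonomy <- function() {
  n <- function(taxid, parent, rank, name) {
    data.frame(taxid = as.integer(taxid), parent_taxid = as.integer(parent),
               rank = rank, name = name, stringsAsFactors = FALSE)
  }
  rbind(
    n(1, 1, "no rank", "root"),
    n(2, 1, "kingdom", "Viridiplantae"),
    n(3, 1, "kingdom", "Fungi"),
    n(10, 2, "family", "Apiaceae"),
    n(11, 2, "family", "Lamiaceae"),
    n(12, 2, "family", "Asteraceae"),
    n(13, 2, "family", "Paeoniaceae"),
    n(14, 2, "family", "Cannabaceae"),
    n(15, 3, "family", "Pleosporaceae"),
    n(20, 10, "genus", "Angelica"),
    n(21, 10, "genus", "Bupleurum"),
    n(22, 10, "genus", "Hansenia"),
    n(23, 11, "genus", "Leonurus"),
    n(24, 12, "genus", "Saussurea"),
    n(25, 13, "genus", "Paeonia"),
    n(26, 14, "genus", "Humulus"),
    n(27, 15, "genus", "Alternaria"),
    n(101, 20, "species", "Angelica sinensis"),
    n(102, 25, "species", "Paeonia lactiflora"),
    n(103, 24, "species", "Saussurea costus"),
    n(104, 22, "species", "Hansenia weberbaueriana"),
    n(105, 23, "species", "Leonurus japonicus"),
    n(106, 21, "species", "Bupleurum chinense"),
    n(107, 21, "species", "Bupleurum falcatum"),
    n(108, 26, "species", "Humulus scandens"),
    n(109, 27, "species", "Alternaria alternata"),
    n(110, 20, "species", "Angelica acutiloba")
  )
}

# Barcode region length and GC targets per marker (means mirror typical
# plant barcode lengths and base composition), and the per-marker
# divergence between congeneric species: the nuclear ITS2 spacer evolves
# fast and resolves congeners at the species level, while the chloroplast
# coding markers are conserved and typically only resolve the genus.
LOCUS_SPEC <- list(
  ITS2 = list(len = c(190, 230), gc = 0.59, congener_div = 0.08),
  matK = list(len = c(810, 870), gc = 0.33, congener_div = 0.012),
  rbcL = list(len = c(680, 720), gc = 0.43, congener_div = 0.012)
)

#' Synthetic barcode loci for the bundled taxa
#'
#' For every species in the synthetic taxonomy, generates one locus per
#' marker it carries: the barcode region embedded in realistic context
#' (conserved 5.8S/28S flank motifs for ITS2; forward/reverse primer
#' sites for \emph{matK}/\emph{rbcL}) plus `flank` nt of random sequence
#' on each side.  Congeneric species are derived from each other by
#' point mutation so that genus-level ambiguity is representable; the
#' fungal taxon carries only ITS2.
#'
#' @param taxonomy taxonomy table (defaults to [synthetic_taxonomy()]).
#' @param seed integer seed controlling the generated sequences.
#' @param flank nt of random flanking sequence on each side of the
#'   structured locus (default 300).
#' @return data.frame with columns `taxid`, `marker`, `locus`, `region`
#'   (the barcode region proper).
#' @export
synthetic_loci <- function(taxonomy = synthetic_taxonomy(), seed = 1,
                           flank = 300) {
  set.seed(seed)
  primers <- default_primer_sets()
  species <- taxonomy$taxid[taxonomy$rank == "species"]
  plant <- vapply(species, function(t) {
    2 %in% ancestor_path(t, taxonomy)
  }, logical(1))
  derive <- c("107" = 106, "110" = 101) # congeners: child <- parent at 3%
  regions <- list()
  for (m in MARKERS) {
    spec <- LOCUS_SPEC[[m]]
    for (t in species) {
      if (m != "ITS2" && !plant[match(t, species)]) next # fungi: ITS2 only
      key <- paste(t, m)
      src <- derive[as.character(t)]
      if (!is.na(src) && !is.null(regions[[paste(src, m)]])) {
        regions[[key]] <- mutate_dna(regions[[paste(src, m)]],
                                     spec$congener_div)
      } else {
        len <- sample(spec$len[1]:spec$len[2], 1)
        regions[[key]] <- random_dna(len, spec$gc)
      }
    }
  }
  out <- list()
  for (key in names(regions)) {
    parts <- strsplit(key, " ")[[1]]
    t <- as.integer(parts[1]); m <- parts[2]
    region <- regions[[key]]
    core <- switch(m,
      ITS2 = paste0(ITS2_FLANK_5_8S, region, ITS2_FLANK_28S),
      paste0(primers[[m]]$forward, region, revcomp(primers[[m]]$reverse)))
    locus <- paste0(random_dna(flank, 0.45), core, random_dna(flank, 0.45))
    out[[key]] <- data.frame(taxid = t, marker = m, locus = locus,
                             region = region, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Synthetic barcode reference database
#'
#' Builds a [reference_db()] whose records are the barcode regions of
#' [synthetic_loci()] (one record per species and marker), the
#' search/enrichment substrate for the simulated pipeline.
#'
#' @param loci output of [synthetic_loci()].
#' @param taxonomy matching taxonomy table.
#' @return `reference_db` object.
#' @export
synthetic_refdb <- function(loci = synthetic_loci(),
                            taxonomy = synthetic_taxonomy()) {
  rec <- data.frame(
    ref_id = paste0("ref_", loci$marker, "_", loci$taxid),
    marker = loci$marker, taxid = loci$taxid, sequence = loci$region,
    stringsAsFactors = FALSE)
  reference_db(rec, taxonomy)
}

#' Design of a mock shotgun experiment
#'
#' @param formula formulation data.frame (see [load_formula()]).
#' @param contaminants data.frame with columns `taxid`, `proportion`
#'   (percent of on-target mass added on top of the formula).
#' @param chimera_fraction fraction of on-target fragments replaced by
#'   two-parent splices, in \[0, 0.2\].
#' @param background_fraction fraction of total pairs drawn from the
#'   off-target decoy.
#' @param read_length,insert_mean,insert_sd read and insert geometry (nt).
#' @param error_rate per-base substitution probability.
#' @param n_pairs number of read pairs.
#' @param seed integer seed; identical design + seed gives byte-identical
#'   output.
#' @param degrade_tail nt at each read 3' end degraded to Q2 with heavy
#'   substitution noise (0 disables; exercises the quality trimmer).
#' @return object of class `mock_design`.
#' @export
mock_design <- function(formula,
                        contaminants = data.frame(
                          taxid = c(107L, 108L, 109L),
                          proportion = c(2, 3, 3)),
                        chimera_fraction = 0.02,
                        background_fraction = 0.5,
                        read_length = 150, insert_mean = 350,
                        insert_sd = 50, error_rate = 0.01,
                        n_pairs = 50000L, seed = 1L,
                        degrade_tail = 0L) {
  stopifnot(read_length <= insert_mean,
            chimera_fraction >= 0, chimera_fraction <= 0.2,
            background_fraction >= 0, background_fraction <= 1,
            error_rate >= 0, error_rate <= 1,
            n_pairs >= 1)
  structure(list(formula = formula, contaminants = contaminants,
                 chimera_fraction = chimera_fraction,
                 background_fraction = background_fraction,
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, n_pairs = as.integer(n_pairs),
                 seed = as.integer(seed),
                 degrade_tail = as.integer(degrade_tail)),
            class = "mock_design")
}

#' @export
print.mock_design <- function(x, ...) {
  cat(sprintf("Mock shotgun design: %d pairs, %d x %d nt reads\n",
              x$n_pairs, 2L, x$read_length))
  cat(sprintf("  formula taxa: %d, contaminants: %d\n",
              nrow(x$formula), nrow(x$contaminants)))
  cat(sprintf("  background %.0f%%, chimeras %.1f%%, error %.2g/base, seed %d\n",
              100 * x$background_fraction, 100 * x$chimera_fraction,
              x$error_rate, x$seed))
  invisible(x)
}

#' Replace a fraction of fragments by two-parent chimeric splices
#'
#' Each selected fragment becomes parent A of a single-crossover splice:
#' a breakpoint is drawn uniformly from the middle 60% of the fragment,
#' the prefix is kept and the suffix is taken from a random co-occurring
#' fragment of the same marker but a different taxon (parent B).
#'
#' @param fragments data.frame with columns `seq`, `taxid`, `marker`.
#' @param chimera_fraction fraction of fragments to replace.
#' @param seed optional integer seed (default: continue the current RNG
#'   stream).
#' @return `fragments` with updated `seq` and added/updated columns
#'   `chimera`, `parent_a`, `parent_b`, `crossover`.
#' @export
inject_chimeras <- function(fragments, chimera_fraction, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(fragments)
  if (is.null(fragments$chimera)) {
    fragments$chimera <- FALSE
    fragments$parent_a <- NA_integer_
    fragments$parent_b <- NA_integer_
    fragments$crossover <- NA_integer_
  }
  if (chimera_fraction <= 0 || n == 0L) return(fragments)
  ok_marker <- names(which(
    tapply(fragments$taxid, fragments$marker,
           function(t) length(unique(t)) >= 2L)))
  if (length(ok_marker) == 0L) {
    stop("chimeras requested but no marker has >= 2 parent taxa",
         call. = FALSE)
  }
  eligible <- which(fragments$marker %in% ok_marker)
  n_chim <- round(chimera_fraction * n)
  n_chim <- min(n_chim, length(eligible))
  sel <- if (n_chim > 0) sample(eligible, n_chim) else integer(0)
  orig_seq <- fragments$seq # parents are always unspliced fragments
  for (i in sel) {
    mates <- which(fragments$marker == fragments$marker[i] &
                     fragments$taxid != fragments$taxid[i])
    j <- if (length(mates) == 1L) mates else sample(mates, 1L)
    la <- nchar(orig_seq[i]); lb <- nchar(orig_seq[j])
    lmin <- min(la, lb)
    lo <- max(2L, round(0.2 * lmin)); hi <- round(0.8 * lmin)
    x <- if (hi > lo) sample(lo:hi, 1L) else lo
    fragments$seq[i] <- paste0(substr(orig_seq[i], 1L, x),
                               substr(orig_seq[j], x + 1L, lb))
    fragments$chimera[i] <- TRUE
    fragments$parent_a[i] <- fragments$taxid[i]
    fragments$parent_b[i] <- fragments$taxid[j]
    fragments$crossover[i] <- x
  }
  fragments
}

#' Simulate a paired-end shotgun dataset from a mock design
#'
#' Pair counts per taxon are multinomial in proportion to mass fraction;
#' fragment starts are uniform over each locus; insert sizes follow a
#' truncated normal (minimum one read length); the reverse mate is
#' reverse-complemented; substitution errors are i.i.d. at the design
#' error rate; qualities are the constant Phred encoding of that rate.
#'
#' @param design a [mock_design()].
#' @param loci per-taxid locus table (see [synthetic_loci()]); every
#'   formula/contaminant taxid must carry at least one locus.
#' @param out_prefix if non-NULL, FASTQ pair and ground-truth TSV are
#'   written under this path prefix.
#' @return list of class `shotgun_sim` with elements `reads` (ReadPair
#'   data.frame) and `truth` (one row per pair: `pair_id`, `origin`,
#'   `taxid`, `marker`, `chimera`, `parent_a`, `parent_b`, `start`,
#'   `insert_len`).
#' @export
simulate_shotgun <- function(design, loci, out_prefix = NULL) {
  stopifnot(inherits(design, "mock_design"))
  set.seed(design$seed)
  taxa <- rbind(design$formula[c("taxid", "proportion")],
                design$contaminants[c("taxid", "proportion")])
  missing <- setdiff(taxa$taxid, loci$taxid)
  if (length(missing) > 0L) {
    stop("no locus for taxid(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  min_locus <- design$insert_mean + 2 * design$insert_sd
  short <- nchar(loci$locus) < min_locus
  if (any(short)) {
    stop(sprintf("locus too short for the insert model (< %d nt): taxid %d %s",
                 min_locus, loci$taxid[which(short)[1]],
                 loci$marker[which(short)[1]]), call. = FALSE)
  }

  n_bg <- round(design$n_pairs * design$background_fraction)
  n_on <- design$n_pairs - n_bg
  tax_counts <- as.vector(rmultinom(1, n_on, taxa$proportion))

  frags <- list()
  for (i in seq_len(nrow(taxa))) {
    t <- taxa$taxid[i]
    tloci <- loci[loci$taxid == t, , drop = FALSE]
    mk_counts <- as.vector(rmultinom(1, tax_counts[i],
                                     rep(1, nrow(tloci))))
    for (j in seq_len(nrow(tloci))) {
      c_ij <- mk_counts[j]
      if (c_ij == 0L) next
      locus <- tloci$locus[j]
      L <- nchar(locus)
      ins <- pmax(design$read_length,
                  pmin(L, round(rnorm(c_ij, design$insert_mean,
                                      design$insert_sd))))
      start <- 1L + floor(runif(c_ij) * (L - ins + 1))
      frags[[length(frags) + 1L]] <- data.frame(
        taxid = t, marker = tloci$marker[j],
        seq = substring(locus, start, start + ins - 1L),
        start = start, stringsAsFactors = FALSE)
    }
  }
  frags <- if (length(frags)) do.call(rbind, frags) else
    data.frame(taxid = integer(0), marker = character(0),
               seq = character(0), start = integer(0))
  frags <- inject_chimeras(frags, design$chimera_fraction)

  # off-target background: fragments sampled from one seeded decoy
  # sequence at GC 40%
  if (n_bg > 0L) {
    decoy_len <- max(100000L, 10L * design$insert_mean)
    decoy <- random_dna(decoy_len, 0.40)
    ins <- pmax(design$read_length,
                pmin(decoy_len, round(rnorm(n_bg, design$insert_mean,
                                            design$insert_sd))))
    start <- 1L + floor(runif(n_bg) * (decoy_len - ins + 1))
    bg <- data.frame(taxid = NA_integer_, marker = NA_character_,
                     seq = substring(decoy, start, start + ins - 1L),
                     start = start, chimera = FALSE,
                     parent_a = NA_integer_, parent_b = NA_integer_,
                     crossover = NA_integer_, stringsAsFactors = FALSE)
    frags <- rbind(frags, bg)
  }

  rl <- design$read_length
  flen <- nchar(frags$seq)
  seq1 <- substr(frags$seq, 1L, rl)
  seq2 <- revcomp(substring(frags$seq, flen - rl + 1L, flen))
  seq1 <- cpp_add_errors(seq1, design$error_rate)
  seq2 <- cpp_add_errors(seq2, design$error_rate)
  q <- if (design$error_rate > 0) {
    max(2L, min(40L, round(-10 * log10(design$error_rate))))
  } else 40L
  qual <- strrep(rawToChar(as.raw(q + 33L)), rl)
  qual1 <- qual2 <- rep(qual, nrow(frags))
  if (design$degrade_tail > 0L) {
    t <- design$degrade_tail
    head_q <- substr(qual, 1L, rl - t)
    tail_q <- strrep(rawToChar(as.raw(2L + 33L)), t)
    qual1 <- qual2 <- rep(paste0(head_q, tail_q), nrow(frags))
    noisy <- function(s) {
      paste0(substr(s, 1L, rl - t),
             cpp_add_errors(substring(s, rl - t + 1L, rl), 0.3))
    }
    seq1 <- noisy(seq1)
    seq2 <- noisy(seq2)
  }

  pair_id <- sprintf("sim_%06d", seq_len(nrow(frags)))
  reads <- data.frame(pair_id = pair_id, seq1 = seq1, qual1 = qual1,
                      seq2 = seq2, qual2 = qual2, stringsAsFactors = FALSE)
  truth <- data.frame(
    pair_id = pair_id,
    origin = ifelse(is.na(frags$taxid), "background", "taxon"),
    taxid = frags$taxid, marker = frags$marker,
    chimera = frags$chimera, parent_a = frags$parent_a,
    parent_b = frags$parent_b, start = frags$start,
    insert_len = flen, stringsAsFactors = FALSE)

  sim <- structure(list(reads = reads, truth = truth, design = design),
                   class = "shotgun_sim")
  if (!is.null(out_prefix)) {
    write_fastq_pairs(reads, out_prefix)
    write.table(truth, paste0(out_prefix, "_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  sim
}

#' @export
print.shotgun_sim <- function(x, ...) {
  cat(sprintf("Simulated shotgun dataset: %d pairs (%d on-target, %d background)\n",
              nrow(x$reads), sum(x$truth$origin == "taxon"),
              sum(x$truth$origin == "background")))
  cat(sprintf("  chimeric fragments: %d\n", sum(x$truth$chimera)))
  invisible(x)
}
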