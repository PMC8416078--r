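# Reduction of contigs to the barcode region proper, chimera removal,
# and exact-haplotype OTU clustering.

# Conserved flank motifs delimiting the ITS2 region: the 3' end of 5.8S
# and the 5' start of 28S (the annealing sites of the universal ITS3 /
# ITS4 primers).
ITS2_FLANK_5_8S <- "GCATCGATGAAGAACGCAGC"
ITS2_FLANK_28S  <- "GCATATCAATAAGCGGAGGA"

# Barcode length bounds per marker (nt).
BARCODE_BOUNDS <- list(ITS2 = c(100L, 500L), matK = c(300L, 1600L),
                       rbcL = c(300L, 1400L))

#' Primer set for one marker
#'
#' @param marker `"matK"` or `"rbcL"`.
#' @param forward,reverse IUPAC primer sequences (15-30 nt).
#' @param max_error_rate allowed error fraction (mismatches + indels)
#'   per primer, at most 0.2.
#' @return object of class `primer_set`.
#' @export
primer_set <- function(marker, forward, reverse, max_error_rate = 0.1) {
  stopifnot(nchar(forward) >= 15, nchar(forward) <= 30,
            nchar(reverse) >= 15, nchar(reverse) <= 30,
            max_error_rate <= 0.2)
  structure(list(marker = marker, forward = toupper(forward),
                 reverse = toupper(reverse),
                 max_error_rate = max_error_rate),
            class = "primer_set")
}

#' Default primer sets for matK and rbcL
#'
#' The widely used plant barcoding primers (matK KIM-3F/KIM-1R, rbcLa
#' forward/reverse).
#'
#' @return named list of [primer_set()] objects.
#' @export
default_primer_sets <- function() {
  list(
    matK = primer_set("matK", "CGTACAGTACTTTTGTGTTTACGAG",
                      "ACCCAGTCCATCTGGAAATCTTGGTTC"),
    rbcL = primer_set("rbcL", "ATGTCACCACAAACAGAGACTAAAGC",
                      "GTAAAATCAAGTCCACCRCG")
  )
}

#' Position-weight-matrix flank profile
#'
#' @param label boundary label (`"5.8S-end"` or `"28S-start"`).
#' @param pwm 4 x w probability matrix, rows A/C/G/T, columns
#'   normalized.
#' @param threshold score threshold in bits (log2-odds vs uniform
#'   background).
#' @return object of class `flank_profile`.
#' @export
flank_profile <- function(label, pwm, threshold) {
  stopifnot(nrow(pwm) == 4, ncol(pwm) >= 15, ncol(pwm) <= 40,
            all(abs(colSums(pwm) - 1) < 1e-6))
  rownames(pwm) <- c("A", "C", "G", "T")
  max_score <- sum(apply(log2(pwm / 0.25), 2, max))
  if (threshold > max_score) {
    stop("threshold unattainable by any sequence", call. = FALSE)
  }
  structure(list(label = label, pwm = pwm, threshold = threshold),
            class = "flank_profile")
}

pwm_from_consensus <- function(motif, p_consensus = 0.91) {
  bases <- strsplit(motif, "")[[1]]
  w <- length(bases)
  pwm <- matrix((1 - p_consensus) / 3, nrow = 4, ncol = w,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(w)) pwm[bases[i], i] <- p_consensus
  pwm
}

#' Default ITS2 flank profiles
#'
#' PWMs built around the conserved 5.8S-end and 28S-start motifs, with
#' a threshold permitting roughly two substitutions per flank.
#'
#' @return named list of two [flank_profile()] objects.
#' @export
default_flank_profiles <- function() {
  list(
    `5.8S-end` = flank_profile("5.8S-end",
                               pwm_from_consensus(ITS2_FLANK_5_8S), 25),
    `28S-start` = flank_profile("28S-start",
                                pwm_from_consensus(ITS2_FLANK_28S), 25)
  )
}

# Log2-odds PWM scores for every placement of the profile along seq.
pwm_scan <- function(seq, profile) {
  lpwm <- log2(profile$pwm / 0.25)
  w <- ncol(lpwm)
  n <- nchar(seq)
  if (n < w) return(numeric(0))
  codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  ns <- n - w + 1L
  s <- numeric(ns)
  floor_pen <- min(lpwm)
  for (o in seq_len(w)) {
    col <- lpwm[, o]
    v <- col[codes[o:(o + ns - 1L)]]
    v[is.na(v)] <- floor_pen # N never counts as a match
    s <- s + v
  }
  s
}

#' Trim matK/rbcL primers off a contig
#'
#' Each primer is searched semi-globally on both strands, allowing up to
#' `ceiling(max_error_rate * primer length)` mismatches plus indels; the
#' sequence strictly between the primer matches is returned, oriented to
#' the forward strand.  Absent primers are not an error: `trim_status`
#' records which ends matched and an untrimmable contig passes through.
#'
#' @param contig contig sequence (character scalar).
#' @param primers a [primer_set()].
#' @return list with elements `sequence` and `trim_status`
#'   (`"both-ends"`, `"one-end"` or `"none"`).
#' @export
trim_primers <- function(contig, primers) {
  fwd <- primers$forward
  rev_rc <- revcomp(primers$reverse) # reverse primer on the forward strand
  tol_f <- ceiling(primers$max_error_rate * nchar(fwd))
  tol_r <- ceiling(primers$max_error_rate * nchar(primers$reverse))
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else revcomp(contig)
    fh <- cpp_primer_find(s, fwd)
    rh <- cpp_primer_find(s, rev_rc)
    f_ok <- fh$dist <= tol_f
    r_ok <- rh$dist <= tol_r && (!f_ok || rh$start >= fh$end)
    n_ok <- f_ok + r_ok
    score <- n_ok * 1000 - (if (f_ok) fh$dist else 0) -
             (if (r_ok) rh$dist else 0)
    cand <- list(s = s, f_ok = f_ok, r_ok = r_ok, fh = fh, rh = rh,
                 score = score)
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  s <- best$s
  n <- nchar(s)
  from <- if (best$f_ok) best$fh$end + 1L else 1L
  to <- if (best$r_ok) best$rh$start else n
  status <- if (best$f_ok && best$r_ok) "both-ends"
            else if (best$f_ok || best$r_ok) "one-end" else "none"
  seq <- if (status == "none") contig else substr(s, from, to)
  list(sequence = seq, trim_status = status)
}

#' Annotate the ITS2 region of a contig by flank profiles
#'
#' The best-scoring placement of the 5.8S-end profile and of the
#' downstream 28S-start profile is sought on both strands; if both
#' exceed their thresholds and delimit a 100-500 nt region, that region
#' is returned.
#'
#' @param contig contig sequence.
#' @param flanks named list of two [flank_profile()]s (see
#'   [default_flank_profiles()]).
#' @return list with `sequence` and `trim_status = "both-ends"`, or
#'   `NULL` if no valid placement exists.
#' @export
annotate_its2 <- function(contig, flanks = default_flank_profiles()) {
  p1 <- flanks[["5.8S-end"]]
  p2 <- flanks[["28S-start"]]
  w1 <- ncol(p1$pwm)
  bounds <- BARCODE_BOUNDS$ITS2
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else revcomp(contig)
    s1 <- pwm_scan(s, p1)
    if (length(s1) == 0L) next
    i1 <- which.max(s1)
    if (s1[i1] < p1$threshold) next
    region_start <- i1 + w1 # first base after the 5.8S flank
    s2 <- pwm_scan(s, p2)
    valid2 <- seq_along(s2) >= region_start
    if (!any(valid2)) next
    s2[!valid2] <- -Inf
    i2 <- which.max(s2)
    if (s2[i2] < p2$threshold) next
    len <- i2 - region_start
    if (len < bounds[1] || len > bounds[2]) next
    score <- s1[i1] + s2[i2]
    if (is.null(best) || score > best$score) {
      best <- list(sequence = substr(s, region_start, i2 - 1L),
                   score = score)
    }
  }
  if (is.null(best)) return(NULL)
  list(sequence = best$sequence, trim_status = "both-ends")
}

#' Reduce contigs to barcode candidates
#'
#' Dispatches per marker: [annotate_its2()] for ITS2 (contigs without
#' valid flank placements are dropped), [trim_primers()] for matK/rbcL
#' (untrimmable contigs are retained, flagged `trim_status = "none"`).
#' Candidates outside the marker's length bounds are dropped.
#'
#' @param contigs contig data.frame (see [assemble_bin()]).
#' @param primers named list of [primer_set()]s.
#' @param flanks named list of [flank_profile()]s.
#' @return data.frame with columns `candidate_id`, `marker`, `sequence`,
#'   `source_contig_id`, `trim_status`, `abundance` (the source contig's
#'   mean k-mer coverage, used as the chimera-detection abundance
#'   proxy).
#' @export
extract_barcodes <- function(contigs, primers = default_primer_sets(),
                             flanks = default_flank_profiles()) {
  rows <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    m <- contigs$marker[i]
    res <- if (m == "ITS2") {
      annotate_its2(contigs$sequence[i], flanks)
    } else {
      trim_primers(contigs$sequence[i], primers[[m]])
    }
    if (is.null(res)) next
    b <- BARCODE_BOUNDS[[m]]
    if (nchar(res$sequence) < b[1] || nchar(res$sequence) > b[2]) next
    rows[[i]] <- data.frame(
      marker = m, sequence = res$sequence,
      source_contig_id = contigs$contig_id[i],
      trim_status = res$trim_status,
      abundance = contigs$mean_kmer_coverage[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    return(data.frame(candidate_id = character(0), marker = character(0),
                      sequence = character(0),
                      source_contig_id = character(0),
                      trim_status = character(0), abundance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out$candidate_id <- sprintf("%s_bc_%04d", out$marker,
                              ave(seq_len(nrow(out)), out$marker,
                                  FUN = seq_along))
  rownames(out) <- NULL
  out[c("candidate_id", "marker", "sequence", "source_contig_id",
        "trim_status", "abundance")]
}

# Per-query-position match profile against a parent, taking the better
# of the two parent orientations.
best_profile <- function(query, parent) {
  a <- cpp_match_profile(query, parent)
  b <- cpp_match_profile(query, revcomp(parent))
  if (a$nmatch >= b$nmatch) a else b
}

#' Two-parent chimera test for one barcode candidate
#'
#' The candidate is flagged chimeric iff some crossover position splits
#' it into a left segment >= 99% identical to one eligible parent and a
#' right segment >= 99% identical to another (both segments >= 30 nt),
#' while its full-length identity to every pool member is <= 97%.
#' Eligible parents must have abundance at least `parent_ratio` times
#' the query's (the de-novo convention: parents precede their chimeras).
#'
#' @param query one-row candidate data.frame (needs `candidate_id`,
#'   `sequence`, `abundance`).
#' @param pool candidate data.frame excluding the query.
#' @param segment_identity per-segment identity threshold (fraction).
#' @param max_full_identity full-length identity ceiling (fraction) for
#'   a chimera call.
#' @param min_segment minimum segment length (nt).
#' @param parent_ratio minimum parent/query abundance ratio.
#' @return one-row data.frame (a ChimeraVerdict): `candidate_id`,
#'   `chimeric`, `parent_a`, `parent_b`, `crossover`, `score`.
#' @export
detect_chimera <- function(query, pool, segment_identity = 0.99,
                           max_full_identity = 0.97, min_segment = 30L,
                           parent_ratio = 2) {
  verdict <- function(chim = FALSE, pa = NA_character_,
                      pb = NA_character_, x = NA_integer_,
                      score = NA_real_) {
    data.frame(candidate_id = query$candidate_id, chimeric = chim,
               parent_a = pa, parent_b = pb, crossover = x,
               score = score, stringsAsFactors = FALSE)
  }
  if (nrow(pool) == 0L) return(verdict())
  eligible <- pool[pool$abundance >= parent_ratio * query$abundance, ,
                   drop = FALSE]
  if (nrow(eligible) < 2L) return(verdict())
  q <- query$sequence
  L <- nchar(q)
  if (L < 2L * min_segment) return(verdict())
  # Per-query-position match profiles against every eligible parent,
  # both orientations, under four alignments: ungapped anchored at the
  # start, ungapped anchored at the end, and the two semi-global
  # (prefix- / suffix-anchored) gapped alignments.  A segment supports a
  # parent if any of that parent's profiles reaches the threshold, so
  # neither the non-parental half nor a length offset can mask a true
  # segment.  Every profile measures identity against genuine parent
  # bases, so the union inflates nothing.
  np <- nrow(eligible)
  qv <- strsplit(q, "")[[1]]
  prof <- list()
  owner <- integer(0)
  add <- function(v, p) {
    prof[[length(prof) + 1L]] <<- v
    owner[length(prof)] <<- p
  }
  for (p in seq_len(np)) {
    for (pseq in c(eligible$sequence[p], revcomp(eligible$sequence[p]))) {
      pv <- strsplit(pseq, "")[[1]]
      lp <- length(pv)
      n0 <- min(L, lp)
      u0 <- rep(FALSE, L) # ungapped, start-anchored
      u0[seq_len(n0)] <- qv[seq_len(n0)] == pv[seq_len(n0)]
      ue <- rep(FALSE, L) # ungapped, end-anchored
      ue[L - n0 + seq_len(n0)] <- qv[L - n0 + seq_len(n0)] ==
        pv[lp - n0 + seq_len(n0)]
      add(u0, p)
      add(ue, p)
      add(cpp_match_profile(q, pseq, 1L)$match, p)
      add(cpp_match_profile(q, pseq, 2L)$match, p)
    }
  }
  prefix <- vapply(prof, cumsum, numeric(L))
  xs <- seq(min_segment, L - min_segment)
  best <- NULL
  nc <- length(prof)
  for (ca in seq_len(nc)) {
    for (cb in seq_len(nc)) {
      a <- owner[ca]; b <- owner[cb]
      if (a == b) next
      left_id <- prefix[xs, ca] / xs
      right_id <- (prefix[L, cb] - prefix[xs, cb]) / (L - xs)
      ok <- left_id >= segment_identity & right_id >= segment_identity
      if (!any(ok)) next
      sc <- pmin(left_id, right_id)
      sc[!ok] <- -Inf
      i <- which.max(sc)
      if (is.null(best) || sc[i] > best$score) {
        best <- list(a = a, b = b, x = xs[i], score = sc[i])
      }
    }
  }
  if (is.null(best)) return(verdict())
  # full-length identity to every pool member must stay below the ceiling
  full_ids <- vapply(pool$sequence, function(p) {
    best_profile(q, p)$identity / 100
  }, numeric(1))
  if (any(full_ids > max_full_identity)) return(verdict())
  verdict(TRUE, eligible$candidate_id[best$a],
          eligible$candidate_id[best$b], best$x, best$score)
}

#' Remove chimeric candidates from a candidate set
#'
#' Applies [detect_chimera()] to every candidate against the remaining
#' pool of its marker.
#'
#' @param candidates candidate data.frame (see [extract_barcodes()]).
#' @param ... thresholds forwarded to [detect_chimera()].
#' @return list with elements `kept` (non-chimeric candidates) and
#'   `verdicts` (one ChimeraVerdict row per input candidate).
#' @export
filter_chimeras <- function(candidates, ...) {
  verdicts <- lapply(seq_len(nrow(candidates)), function(i) {
    pool <- candidates[candidates$marker == candidates$marker[i], ,
                       drop = FALSE]
    pool <- pool[pool$candidate_id != candidates$candidate_id[i], ,
                 drop = FALSE]
    detect_chimera(candidates[i, ], pool, ...)
  })
  verdicts <- if (length(verdicts)) do.call(rbind, verdicts) else
    data.frame(candidate_id = character(0), chimeric = logical(0),
               parent_a = character(0), parent_b = character(0),
               crossover = integer(0), score = numeric(0))
  kept <- candidates[!candidates$candidate_id %in%
                       verdicts$candidate_id[verdicts$chimeric], ,
                     drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, verdicts = verdicts)
}

#' Cluster candidates into exact-haplotype OTUs
#'
#' Strand-normalized exact-sequence grouping (100% identity over the
#' clustered region).  OTUs are ordered by member count descending, then
#' by representative sequence.
#'
#' @param candidates candidate data.frame, all of one marker.
#' @return data.frame with columns `otu_id`, `marker`, `representative`,
#'   `n_members`, `members` (comma-joined candidate ids).
#' @export
cluster_otus <- function(candidates) {
  empty <- data.frame(otu_id = character(0), marker = character(0),
                      representative = character(0),
                      n_members = integer(0), members = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) return(empty)
  marker <- unique(candidates$marker)
  if (length(marker) != 1L) {
    stop("cluster_otus expects candidates of a single marker",
         call. = FALSE)
  }
  can <- canonical_strand(candidates$sequence)
  groups <- split(candidates$candidate_id, can)
  otus <- data.frame(
    marker = marker, representative = names(groups),
    n_members = vapply(groups, length, 0L),
    members = vapply(groups, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  otus <- otus[order(-otus$n_members, otus$representative), ,
               drop = FALSE]
  otus$otu_id <- sprintf("%s_OTU_%03d", marker, seq_len(nrow(otus)))
  rownames(otus) <- NULL
  otus[c("otu_id", "marker", "representative", "n_members", "members")]
}
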