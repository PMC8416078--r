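# Adapter and quality trimming of paired reads.

#' Trimming policy
#'
#' @param adapter_seqs character vector of adapter sequences to clip
#'   (may be empty).
#' @param window_len sliding-window length (nt).
#' @param mean_q_threshold Phred threshold on the window mean quality.
#' @param min_len minimum surviving mate length; pairs where either
#'   trimmed mate is shorter are dropped.
#' @return object of class `trim_policy`.
#' @export
trim_policy <- function(adapter_seqs = character(0), window_len = 4L,
                        mean_q_threshold = 15, min_len = 36L) {
  stopifnot(window_len >= 1, min_len >= window_len)
  structure(list(adapter_seqs = toupper(adapter_seqs),
                 window_len = as.integer(window_len),
                 mean_q_threshold = mean_q_threshold,
                 min_len = as.integer(min_len)),
            class = "trim_policy")
}

phred_values <- function(qual) utf8ToInt(qual) - 33L

# Clip at the first exact 10-nt seed match of an adapter whose extension
# over the remaining adapter/read overlap has <= 10% mismatches.
clip_adapter <- function(seq, adapters) {
  for (ad in adapters) {
    seed <- substr(ad, 1L, 10L)
    if (nchar(seed) < 10L) next
    offset <- 0L
    rest <- seq
    repeat {
      hit <- regexpr(seed, rest, fixed = TRUE)[1]
      if (hit < 0L) break
      pos <- offset + hit # adapter start, 1-based in seq
      cmp_len <- min(nchar(ad), nchar(seq) - pos + 1L)
      a <- utf8ToInt(substr(ad, 1L, cmp_len))
      s <- utf8ToInt(substr(seq, pos, pos + cmp_len - 1L))
      if (sum(a != s) <= 0.1 * cmp_len) return(pos - 1L)
      offset <- pos
      rest <- substring(seq, offset + 1L)
    }
  }
  nchar(seq)
}

#' Trim one read by adapter clipping and sliding-window quality
#'
#' The adapter (if any) is clipped first; then windows of
#' `policy$window_len` are scanned 5' to 3' and the read is cut at the
#' first base of the first window whose mean quality falls below
#' `policy$mean_q_threshold`.  The result may be empty.
#'
#' @param seq,qual read sequence and Phred+33 quality string (equal
#'   lengths).
#' @param policy a [trim_policy()].
#' @return list with elements `seq` and `qual`.
#' @export
trim_read <- function(seq, qual, policy = trim_policy()) {
  if (nchar(seq) != nchar(qual)) {
    stop("sequence and quality lengths differ", call. = FALSE)
  }
  keep <- clip_adapter(seq, policy$adapter_seqs)
  seq <- substr(seq, 1L, keep)
  qual <- substr(qual, 1L, keep)
  n <- nchar(seq)
  w <- policy$window_len
  if (n >= w) {
    q <- phred_values(qual)
    means <- (cumsum(q)[w:n] - c(0, cumsum(q))[1:(n - w + 1L)]) / w
    bad <- which(means < policy$mean_q_threshold)
    if (length(bad) > 0L) {
      cut <- bad[1] - 1L # keep bases before the window's first base
      seq <- substr(seq, 1L, cut)
      qual <- substr(qual, 1L, cut)
    }
  }
  list(seq = seq, qual = qual)
}

#' Trim and filter read pairs
#'
#' Both mates of each pair are trimmed with [trim_read()]; a pair
#' survives iff both trimmed mates are at least `policy$min_len` long
#' (no orphan stream).
#'
#' @param pairs ReadPair data.frame (`pair_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`).
#' @param policy a [trim_policy()].
#' @return list with elements `pairs` (surviving, trimmed) and `stats`
#'   (input/output pair and base counts).
#' @export
filter_pairs <- function(pairs, policy = trim_policy()) {
  n <- nrow(pairs)
  bases_in <- sum(nchar(pairs$seq1)) + sum(nchar(pairs$seq2))
  for (mate in c(1L, 2L)) {
    sc <- paste0("seq", mate); qc <- paste0("qual", mate)
    trimmed <- mapply(function(s, q) trim_read(s, q, policy),
                      pairs[[sc]], pairs[[qc]], SIMPLIFY = FALSE,
                      USE.NAMES = FALSE)
    pairs[[sc]] <- vapply(trimmed, `[[`, "", "seq")
    pairs[[qc]] <- vapply(trimmed, `[[`, "", "qual")
  }
  ok <- nchar(pairs$seq1) >= policy$min_len &
        nchar(pairs$seq2) >= policy$min_len
  out <- pairs[ok, , drop = FALSE]
  rownames(out) <- NULL
  stats <- list(pairs_in = n, pairs_out = nrow(out),
                pairs_dropped = n - nrow(out),
                bases_in = bases_in,
                bases_out = sum(nchar(out$seq1)) + sum(nchar(out$seq2)))
  list(pairs = out, stats = stats)
}
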