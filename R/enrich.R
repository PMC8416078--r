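# Barcode-read enrichment: a marker-labelled canonical k-mer screen that
# pulls ITS2 / matK / rbcL read pairs out of the shotgun background.

#' Build a marker-labelled k-mer index over the reference database
#'
#' Every length-`k` window of every reference (skipping windows with N)
#' is indexed under its canonical form (the lexicographic minimum of the
#' k-mer and its reverse complement) together with the reference's
#' marker label.
#'
#' @param db a [reference_db()].
#' @param k odd k-mer size, 15-31.
#' @return object of class `kmer_index`.
#' @export
build_kmer_index <- function(db, k = 21L) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 15L || k > 31L) {
    stop("k must be odd and within 15..31", call. = FALSE)
  }
  if (nrow(db$records) == 0L) stop("empty reference database", call. = FALSE)
  if (k > min(nchar(db$records$sequence))) {
    stop("k exceeds the shortest reference length", call. = FALSE)
  }
  label <- match(db$records$marker, MARKERS) - 1L
  ptr <- cpp_kmer_index_build(db$records$sequence, label, k,
                              length(MARKERS))
  structure(list(ptr = ptr, k = k, markers = MARKERS),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("Canonical k-mer index: k = %d, %d distinct k-mer(s), markers %s\n",
              x$k, cpp_kmer_index_size(x$ptr),
              paste(x$markers, collapse = "/")))
  invisible(x)
}

# Per-marker counts of indexed canonical k-mer windows of one sequence.
kmer_hits <- function(index, seq) {
  setNames(cpp_kmer_hits(index$ptr, seq), index$markers)
}

#' Classify one read pair against the k-mer index
#'
#' Hits per marker are counted over the canonical k-mers of both mates
#' (mate rescue: one informative mate suffices).  The marker with the
#' most hits is assigned if its hit count reaches `min_hits`; a tie at
#' the top leaves the pair unassigned.
#'
#' @param pair one-row ReadPair data.frame (or list with `seq1`,
#'   `seq2`).
#' @param index a [build_kmer_index()] result.
#' @param min_hits minimum hit count for assignment.
#' @return marker name or `"unassigned"`.
#' @export
classify_pair <- function(pair, index, min_hits = 3L) {
  r <- cpp_classify_pairs(index$ptr, pair$seq1[1], pair$seq2[1],
                          as.integer(min_hits))
  if (r == 0L) "unassigned" else index$markers[r]
}

#' Enrich read pairs into per-marker bins
#'
#' @param pairs ReadPair data.frame.
#' @param index a [build_kmer_index()] result.
#' @param min_hits minimum hit count for assignment.
#' @return list of class `enrichment` with elements `bins` (named list
#'   of ReadPair data.frames, one per marker), `counts` (named integer
#'   vector per marker) and `unassigned` (count).  Bin counts plus
#'   unassigned always sum to the input pair count.
#' @export
enrich_pairs <- function(pairs, index, min_hits = 3L) {
  cls <- cpp_classify_pairs(index$ptr, pairs$seq1, pairs$seq2,
                            as.integer(min_hits))
  bins <- lapply(seq_along(index$markers), function(l) {
    b <- pairs[cls == l, , drop = FALSE]
    rownames(b) <- NULL
    b
  })
  names(bins) <- index$markers
  counts <- vapply(bins, nrow, 0L)
  structure(list(bins = bins, counts = counts,
                 unassigned = sum(cls == 0L)),
            class = "enrichment")
}

#' @export
print.enrichment <- function(x, ...) {
  cat("Read-pair enrichment\n")
  for (m in names(x$counts)) {
    cat(sprintf("  %-5s %d pair(s)\n", m, x$counts[[m]]))
  }
  cat(sprintf("  unassigned: %d\n", x$unassigned))
  invisible(x)
}
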