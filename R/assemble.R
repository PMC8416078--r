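# Targeted de Bruijn assembly of each marker bin over a ladder of k-mer
# sizes, followed by strand-aware dereplication at 100% identity.

#' Default assembly k-mer ladder
#'
#' Spans 31-127, capped below the read length.
#'
#' @param read_length read length in nt.
#' @return integer vector of odd k values.
#' @export
default_k_list <- function(read_length = 150L) {
  k <- c(31L, 55L, 77L, 99L, 127L)
  k[k < read_length]
}

#' Assemble a marker bin into contigs
#'
#' For each k in `k_list`, a de Bruijn graph is built from both strands
#' of both mates, edges below `min_edge_cov` are dropped, tips shorter
#' than 2k are removed, and maximal non-branching paths (unitigs) of at
#' least `min_contig_len` nt are emitted.  Unitigs are pooled across all
#' k, strand-normalized, and deduplicated exactly (containment
#' dereplication is a separate step, [dereplicate()]).
#'
#' @param reads ReadPair data.frame (a marker bin).
#' @param marker marker label recorded on the contigs.
#' @param k_list ascending odd k sizes, each below the read length.
#' @param min_edge_cov minimum k-mer coverage of a retained edge.
#' @param min_contig_len minimum emitted contig length (nt).
#' @param junction_alpha relative junction cleanup: at each branching
#'   node, edges with coverage below `junction_alpha` times the
#'   strongest competing edge are dropped (0 disables).  At high depth,
#'   error k-mers recur above any absolute cutoff; this removes those
#'   branches while preserving haplotype bubbles of comparable depth.
#' @return data.frame with columns `contig_id`, `marker`, `sequence`,
#'   `k_origin`, `mean_kmer_coverage`.
#' @export
assemble_bin <- function(reads, marker, k_list = default_k_list(),
                         min_edge_cov = 2L, min_contig_len = 100L,
                         junction_alpha = 0.05) {
  empty <- data.frame(contig_id = character(0), marker = character(0),
                      sequence = character(0), k_origin = integer(0),
                      mean_kmer_coverage = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  stopifnot(!is.unsorted(k_list), all(k_list %% 2L == 1L))
  seqs <- c(reads$seq1, reads$seq2)
  out <- list()
  for (k in k_list) {
    if (k >= max(nchar(seqs))) next
    res <- cpp_assemble(seqs, k, as.integer(min_edge_cov),
                        as.integer(min_contig_len), junction_alpha)
    if (length(res$sequence) == 0L) next
    can <- canonical_strand(res$sequence)
    keep <- !duplicated(can) # forward and RC unitigs collapse to one
    out[[as.character(k)]] <- data.frame(
      marker = marker, sequence = can[keep], k_origin = k,
      mean_kmer_coverage = res$coverage[keep], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  contigs <- do.call(rbind, out)
  contigs <- contigs[order(-nchar(contigs$sequence), contigs$sequence), ,
                     drop = FALSE]
  contigs$contig_id <- sprintf("%s_ctg_%04d", marker,
                               seq_len(nrow(contigs)))
  rownames(contigs) <- NULL
  contigs[c("contig_id", "marker", "sequence", "k_origin",
            "mean_kmer_coverage")]
}

#' Dereplicate contigs at 100% identity
#'
#' A contig is removed iff it is identical to, or an exact substring of,
#' another retained contig, considering both strands.  Among mutually
#' redundant contigs the longest is retained (ties: lexicographically
#' smallest sequence).  The retained set is independent of input order.
#'
#' @param contigs contig data.frame (see [assemble_bin()]).
#' @return the retained subset, same columns.
#' @export
dereplicate <- function(contigs) {
  if (nrow(contigs) == 0L) return(contigs)
  ord <- order(-nchar(contigs$sequence), contigs$sequence)
  contigs <- contigs[ord, , drop = FALSE]
  seqs <- contigs$sequence
  rcs <- revcomp(seqs)
  keep <- logical(length(seqs))
  kept_seqs <- character(0)
  for (i in seq_along(seqs)) {
    contained <- any(vapply(kept_seqs, function(K) {
      grepl(seqs[i], K, fixed = TRUE) || grepl(rcs[i], K, fixed = TRUE)
    }, logical(1)))
    if (!contained) {
      keep[i] <- TRUE
      kept_seqs <- c(kept_seqs, seqs[i])
    }
  }
  out <- contigs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
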