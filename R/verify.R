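# OTU verification: map the enriched read pairs back onto each OTU
# representative and apply the depth/coverage reliability filter.

#' Map a marker bin onto one OTU representative and profile it
#'
#' Each mate is aligned independently by exact 15-nt seed anchoring plus
#' a banded extension (band 8) and accepted iff its identity over the
#' aligned columns reaches `min_map_identity` across at least 80% of the
#' mate's length (soft-clipping is allowed only at representative
#' boundaries).  Accepted intervals accumulate a per-base depth array
#' from which mean depth and coverage are computed.
#'
#' @param reads ReadPair data.frame (the OTU's marker bin).
#' @param otu one-row OTU data.frame (needs `otu_id`,
#'   `representative`).
#' @param min_map_identity acceptance identity (fraction, default
#'   0.95).
#' @return list with elements `mappings` (data.frame: `otu_id`,
#'   `pair_id`, `mate`, `start`, `end`, `identity`, `strand`) and
#'   `verification` (one-row data.frame: `otu_id`,
#'   `mapped_read_count`, `mean_depth`, `coverage`, `reliable`).
#' @export
map_and_profile <- function(reads, otu, min_map_identity = 0.95) {
  rep_seq <- otu$representative[1]
  L <- nchar(rep_seq)
  if (L < 15L) stop("representative shorter than the 15 nt seed",
                    call. = FALSE)
  maps <- list()
  for (mate in c(1L, 2L)) {
    seqs <- reads[[paste0("seq", mate)]]
    hit <- cpp_map_reads(rep_seq, seqs, min_map_identity)
    if (nrow(hit) > 0L) {
      maps[[mate]] <- data.frame(
        otu_id = otu$otu_id[1], pair_id = reads$pair_id[hit$read],
        mate = mate, start = hit$start, end = hit$end,
        identity = hit$identity,
        strand = ifelse(hit$strand > 0, "+", "-"),
        stringsAsFactors = FALSE)
    }
  }
  mappings <- if (length(maps)) do.call(rbind, maps) else
    data.frame(otu_id = character(0), pair_id = character(0),
               mate = integer(0), start = integer(0), end = integer(0),
               identity = numeric(0), strand = character(0))
  depth <- depth_profile(mappings, L)
  verification <- data.frame(
    otu_id = otu$otu_id[1],
    mapped_read_count = nrow(mappings),
    mean_depth = mean(depth),
    coverage = 100 * mean(depth >= 1L),
    stringsAsFactors = FALSE)
  verification$reliable <- verification$mean_depth > 3 &
    verification$coverage > 95
  list(mappings = mappings, verification = verification)
}

# Per-base depth from half-open [start, end) intervals, via a
# difference array.
depth_profile <- function(mappings, L) {
  diffv <- integer(L + 1L)
  if (nrow(mappings) > 0L) {
    for (i in seq_len(nrow(mappings))) {
      s <- mappings$start[i] + 1L # to 1-based
      e <- mappings$end[i]
      diffv[s] <- diffv[s] + 1L
      diffv[e + 1L] <- diffv[e + 1L] - 1L
    }
  }
  cumsum(diffv)[seq_len(L)]
}

#' Verify every OTU of a marker against its read bin
#'
#' Reads may support multiple OTUs: each mate counts toward every
#' representative it maps to, so shared haplotypes do not lose support.
#'
#' @param reads ReadPair data.frame (the marker bin).
#' @param otus OTU data.frame (see [cluster_otus()]).
#' @param min_map_identity forwarded to [map_and_profile()].
#' @return data.frame of verifications, one row per OTU.
#' @export
verify_otus <- function(reads, otus, min_map_identity = 0.95) {
  rows <- lapply(seq_len(nrow(otus)), function(i) {
    map_and_profile(reads, otus[i, ], min_map_identity)$verification
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(otu_id = character(0), mapped_read_count = integer(0),
               mean_depth = numeric(0), coverage = numeric(0),
               reliable = logical(0))
  rownames(out) <- NULL
  out
}

#' Apply the depth/coverage reliability filter
#'
#' An OTU is removed iff its mean depth is <= `max_removed_depth` (3) or
#' its coverage is <= `max_removed_coverage` (95%); both retained and
#' removed sets are returned with reasons.
#'
#' @param verifications verification data.frame (see [verify_otus()]).
#' @param max_removed_depth depth at or below which an OTU is removed.
#' @param max_removed_coverage coverage (percent) at or below which an
#'   OTU is removed.
#' @return list with elements `reliable` and `removed` (the latter with
#'   a `reason` column).
#' @export
filter_reliable <- function(verifications, max_removed_depth = 3,
                            max_removed_coverage = 95) {
  low_depth <- verifications$mean_depth <= max_removed_depth
  low_cov <- verifications$coverage <= max_removed_coverage
  removed <- verifications[low_depth | low_cov, , drop = FALSE]
  if (nrow(removed) > 0L) {
    removed$reason <- paste0(
      ifelse(low_depth[low_depth | low_cov], "depth<=3", ""),
      ifelse(low_depth[low_depth | low_cov] & low_cov[low_depth | low_cov],
             ";", ""),
      ifelse(low_cov[low_depth | low_cov], "coverage<=95", ""))
  } else {
    removed$reason <- character(0)
  }
  reliable <- verifications[!(low_depth | low_cov), , drop = FALSE]
  rownames(reliable) <- rownames(removed) <- NULL
  list(reliable = reliable, removed = removed)
}
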