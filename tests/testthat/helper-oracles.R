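# Shared fixtures and independent brute-force oracles.  Oracles here are
# deliberately naive (exhaustive scans, path intersections, full DP via
# Biostrings) and never share code with the implementation they check.

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

rand_qual <- function(n, lo = 2, hi = 40) {
  intToUtf8(sample(lo:hi, n, replace = TRUE) + 33L)
}

# --- taxonomy ---------------------------------------------------------------

# Random rooted tree over n nodes (taxid i's parent is a smaller taxid).
random_taxonomy <- function(n) {
  parent <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  data.frame(taxid = seq_len(n), parent_taxid = parent,
             rank = c("no rank", rep("no rank", n - 1L)),
             name = paste0("node", seq_len(n)), stringsAsFactors = FALSE)
}

# Ancestor-or-self set of one node (independent of package internals).
oracle_ancestors <- function(taxid, tax) {
  parent <- setNames(tax$parent_taxid, tax$taxid)
  anc <- integer(0)
  cur <- taxid
  repeat {
    anc <- c(anc, cur)
    nxt <- parent[[as.character(cur)]]
    if (nxt == cur) break
    cur <- nxt
  }
  anc
}

# LCA by exhaustive ancestor-set intersection, deepest-by-path-length.
oracle_lca <- function(taxids, tax) {
  common <- Reduce(intersect, lapply(taxids, oracle_ancestors, tax = tax))
  depths <- vapply(common, function(t) length(oracle_ancestors(t, tax)), 0L)
  common[which.max(depths)]
}

# --- quality trimming -------------------------------------------------------

# Exhaustive scan over every window: first failing window's first base.
oracle_trim_cut <- function(qual, window, threshold) {
  q <- utf8ToInt(qual) - 33L
  n <- length(q)
  if (n < window) return(n)
  for (s in 1:(n - window + 1L)) {
    if (mean(q[s:(s + window - 1L)]) < threshold) return(s - 1L)
  }
  n
}

# --- alignment oracles (Biostrings full DP) ---------------------------------

oracle_local_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = 5, gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  max(Biostrings::score(Biostrings::pairwiseAlignment(
        a, b, type = "local", substitutionMatrix = mat,
        gapOpening = gap_open, gapExtension = gap_ext)),
      Biostrings::score(Biostrings::pairwiseAlignment(
        revcomp(a), b, type = "local", substitutionMatrix = mat,
        gapOpening = gap_open, gapExtension = gap_ext)))
}

# Accept/reject decision for one mate against a representative, by full
# (unbanded) global-local DP with the mapping scoring scheme.
oracle_map_accept <- function(read, rep_seq, min_identity) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                  mismatch = -1,
                                                  baseOnly = TRUE)
  best <- -Inf
  ident <- 0
  for (r in c(read, revcomp(read))) {
    aln <- Biostrings::pairwiseAlignment(r, rep_seq,
                                         type = "global-local",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    if (Biostrings::score(aln) > best) {
      best <- Biostrings::score(aln)
      cols <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
        Biostrings::nindel(aln)@insertion[2] +
        Biostrings::nindel(aln)@deletion[2]
      ident <- Biostrings::nmatch(aln) / cols
    }
  }
  ident >= min_identity
}

# Exhaustive primer placement by edit distance over all substrings.
oracle_primer_best <- function(seq, primer, slack = 5L) {
  plen <- nchar(primer)
  n <- nchar(seq)
  best <- list(dist = Inf, end = 0L)
  for (end in 1:n) {
    for (len in max(1L, plen - slack):min(end, plen + slack)) {
      d <- utils::adist(primer, substr(seq, end - len + 1L, end))[1, 1]
      if (d < best$dist) best <- list(dist = d, end = end)
    }
  }
  best
}

# Exhaustive two-parent split scan (gap-free; for same-length toys).
oracle_split_scan <- function(query, parents, min_segment = 30L,
                              thr = 0.99) {
  L <- nchar(query)
  q <- strsplit(query, "")[[1]]
  pm <- lapply(parents, function(p) strsplit(p, "")[[1]][1:L] == q)
  found <- FALSE
  for (a in seq_along(parents)) {
    for (b in seq_along(parents)) {
      if (a == b) next
      for (x in min_segment:(L - min_segment)) {
        if (mean(pm[[a]][1:x]) >= thr &&
            mean(pm[[b]][(x + 1):L]) >= thr) found <- TRUE
      }
    }
  }
  found
}

# --- small data builders ----------------------------------------------------

make_pairs <- function(seqs, qual_char = "I") {
  data.frame(pair_id = sprintf("p%04d", seq_along(seqs)),
             seq1 = seqs, qual1 = strrep(qual_char, nchar(seqs)),
             seq2 = revcomp(seqs), qual2 = strrep(qual_char, nchar(seqs)),
             stringsAsFactors = FALSE)
}

# Reads tiling a locus at step 1, duplicated so every k-mer (including
# terminal ones) reaches edge coverage >= 2.
tiling_pairs <- function(locus, read_len = 150L, step = 1L, copies = 2L) {
  starts <- seq(1L, nchar(locus) - read_len + 1L, by = step)
  reads <- substring(locus, starts, starts + read_len - 1L)
  make_pairs(rep(reads, copies))
}

# Minimal three-marker reference FASTA files + taxonomy for I/O tests.
write_tiny_refs <- function(dir, taxonomy, loci) {
  paths <- c()
  for (m in unique(loci$marker)) {
    lm <- loci[loci$marker == m, ]
    f <- file.path(dir, paste0(m, ".fasta"))
    writeLines(paste0(">ref_", m, "_", lm$taxid, "|", lm$taxid, "\n",
                      lm$region), f)
    paths[m] <- f
  }
  paths
}
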