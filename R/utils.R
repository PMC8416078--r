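#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, upper case).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) cpp_revcomp(as.character(x))

#' GC content of DNA strings
#'
#' N bases are excluded from the denominator.
#'
#' @param x character vector of DNA sequences.
#' @return numeric vector of GC fractions in \[0, 1\].
#' @export
gc_content <- function(x) cpp_gc_content(as.character(x))

# Strand-canonical form: the lexicographically smaller of a sequence and
# its reverse complement.  Used wherever strand must not matter
# (dereplication, OTU clustering).
canonical_strand <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains non-DNA characters (first offender: %s)",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

# Draw random DNA with a given GC fraction.
random_dna <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Point-mutate a sequence at a given per-base substitution rate (used to
# derive congeneric reference haplotypes in the synthetic database).
mutate_dna <- function(seq, rate) {
  bases <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  paste(bases, collapse = "")
}
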