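# FASTQ / FASTA I/O, via Biostrings (gzip transparent).
#
# In memory, paired reads travel as a plain data.frame with columns
# pair_id, seq1, qual1, seq2, qual2 -- the ReadPair table used by every
# downstream stage.

#' Read a pair of FASTQ files into a ReadPair table
#'
#' Mate ids may carry `/1` / `/2` suffixes; they are stripped and the two
#' files are matched positionally (an error is raised if the stripped ids
#' disagree).
#'
#' @param file1,file2 paths to the R1 and R2 FASTQ files (optionally
#'   gzipped).
#' @return data.frame with columns `pair_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @export
read_fastq_pairs <- function(file1, file2) {
  # Biostrings warns about dropping (empty) metadata columns; harmless
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(file1))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(file2))
  if (length(r1) == 0L) {
    stop("empty FASTQ input: ", file1, call. = FALSE)
  }
  if (length(r1) != length(r2)) {
    stop("FASTQ files have different numbers of records", call. = FALSE)
  }
  id1 <- sub("/[12]$", "", sub("\\s.*$", "", names(r1)))
  id2 <- sub("/[12]$", "", sub("\\s.*$", "", names(r2)))
  if (!identical(id1, id2)) {
    stop("read ids of the two FASTQ files do not match", call. = FALSE)
  }
  data.frame(pair_id = id1,
             seq1 = as.character(r1), qual1 = as.character(Biostrings::quality(r1)),
             seq2 = as.character(r2), qual2 = as.character(Biostrings::quality(r2)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a ReadPair table to a pair of FASTQ files
#'
#' @param pairs ReadPair data.frame (see [read_fastq_pairs()]).
#' @param prefix output path prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written (`.gz` appended if `gzip = TRUE`).
#' @param gzip compress the output files.
#' @return invisibly, the two file paths.
#' @export
write_fastq_pairs <- function(pairs, prefix, gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  f1 <- paste0(prefix, "_1", ext)
  f2 <- paste0(prefix, "_2", ext)
  s1 <- Biostrings::DNAStringSet(pairs$seq1)
  names(s1) <- paste0(pairs$pair_id, "/1")
  s2 <- Biostrings::DNAStringSet(pairs$seq2)
  names(s2) <- paste0(pairs$pair_id, "/2")
  Biostrings::writeXStringSet(s1, f1, format = "fastq",
                              qualities = Biostrings::BStringSet(pairs$qual1),
                              compress = gzip)
  Biostrings::writeXStringSet(s2, f2, format = "fastq",
                              qualities = Biostrings::BStringSet(pairs$qual2),
                              compress = gzip)
  invisible(c(f1, f2))
}

read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  setNames(as.character(x), names(x))
}

write_fasta <- function(seqs, names, file) {
  x <- Biostrings::DNAStringSet(setNames(seqs, names))
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}
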