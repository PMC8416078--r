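# Barcode reference database and taxonomy.
#
# The taxonomy is a plain table (taxid, parent_taxid, rank, name) whose
# parent chains terminate at a self-parented root; the reference records
# are taxon-annotated barcode sequences grouped by marker.  FASTA headers
# follow the dialect `>ref_id|taxid [free text]`.

#' Read a taxonomy table
#'
#' @param file TSV with header row and columns `taxid`, `parent_taxid`,
#'   `rank`, `name`.  Ranks outside the canonical set
#'   (kingdom...species) are collapsed to `"no rank"`.
#' @return data.frame with those four columns, taxids unique.
#' @export
read_taxonomy <- function(file) {
  tx <- read.delim(file, stringsAsFactors = FALSE)
  validate_taxonomy(tx)
}

validate_taxonomy <- function(tx) {
  need <- c("taxid", "parent_taxid", "rank", "name")
  if (!all(need %in% names(tx))) {
    stop("taxonomy must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tx <- tx[need]
  tx$taxid <- as.integer(tx$taxid)
  tx$parent_taxid <- as.integer(tx$parent_taxid)
  if (anyDuplicated(tx$taxid)) stop("duplicate taxids in taxonomy", call. = FALSE)
  tx$rank[!tx$rank %in% CANONICAL_RANKS] <- "no rank"
  if (!all(tx$parent_taxid %in% tx$taxid)) {
    stop("taxonomy contains parent_taxid values that are not taxids",
         call. = FALSE)
  }
  root <- tx$taxid[tx$taxid == tx$parent_taxid]
  if (length(root) != 1L) {
    stop("taxonomy must have exactly one self-parented root", call. = FALSE)
  }
  # every chain must reach the root in a bounded number of steps
  parent <- setNames(tx$parent_taxid, tx$taxid)
  cur <- tx$taxid
  for (i in seq_len(40)) cur <- unname(parent[as.character(cur)])
  if (!all(cur == root)) {
    stop("a parent chain does not terminate at the root within 40 steps",
         call. = FALSE)
  }
  tx
}

#' Parse a barcode reference FASTA for one marker
#'
#' Headers must follow `>ref_id|taxid` with optional trailing free text.
#' Records whose taxid is absent from the taxonomy are excluded; their
#' headers are returned in the `"rejected"` attribute and reported in a
#' warning.  Sequences shorter than 100 nt are likewise excluded (too
#' short to be a usable barcode reference).
#'
#' @param file path to a FASTA file.
#' @param marker one of `"ITS2"`, `"matK"`, `"rbcL"`.
#' @param taxonomy taxonomy table (see [read_taxonomy()]).
#' @return data.frame with columns `ref_id`, `marker`, `taxid`,
#'   `sequence`.
#' @export
parse_reference_fasta <- function(file, marker, taxonomy) {
  marker <- match.arg(marker, MARKERS)
  seqs <- read_fasta(file)
  if (length(seqs) == 0L) stop("empty reference FASTA: ", file, call. = FALSE)
  headers <- names(seqs)
  no_pipe <- !grepl("|", headers, fixed = TRUE)
  if (any(no_pipe)) {
    stop("malformed reference header (no '|taxid' field): ",
         headers[which(no_pipe)[1]], call. = FALSE)
  }
  parts <- strsplit(headers, "|", fixed = TRUE)
  ref_id <- vapply(parts, `[[`, "", 1L)
  taxid_field <- vapply(parts, `[[`, "", 2L)
  taxid <- suppressWarnings(as.integer(sub("\\s.*$", "", taxid_field)))
  if (anyNA(taxid)) {
    stop("malformed reference header (taxid not an integer): ",
         headers[which(is.na(taxid))[1]], call. = FALSE)
  }
  if (anyDuplicated(ref_id)) {
    stop("duplicate ref_id in reference FASTA: ",
         ref_id[which(duplicated(ref_id))[1]], call. = FALSE)
  }
  sequence <- toupper(unname(seqs))
  assert_dna(sequence, "reference sequence")
  rec <- data.frame(ref_id = ref_id, marker = marker, taxid = taxid,
                    sequence = sequence, stringsAsFactors = FALSE)
  bad_tax <- !rec$taxid %in% taxonomy$taxid
  bad_len <- nchar(rec$sequence) < 100L
  rejected <- headers[bad_tax | bad_len]
  if (length(rejected) > 0L) {
    warning(length(rejected), " reference record(s) rejected (",
            sum(bad_tax), " unresolvable taxid, ", sum(bad_len),
            " shorter than 100 nt)", call. = FALSE)
  }
  rec <- rec[!(bad_tax | bad_len), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "rejected") <- rejected
  rec
}

#' Write reference records to FASTA
#'
#' Inverse of [parse_reference_fasta()]: headers are `ref_id|taxid`.
#'
#' @param records reference record data.frame.
#' @param file output path.
#' @export
write_reference_fasta <- function(records, file) {
  write_fasta(records$sequence, paste0(records$ref_id, "|", records$taxid),
              file)
}

#' Assemble a reference database from per-marker records
#'
#' @param records data.frame of reference records (any mix of markers),
#'   e.g. rbind of [parse_reference_fasta()] results.
#' @param taxonomy taxonomy table.
#' @return object of class `reference_db`: list with elements `records`
#'   and `taxonomy`.
#' @export
reference_db <- function(records, taxonomy) {
  taxonomy <- validate_taxonomy(taxonomy)
  if (anyDuplicated(records$ref_id)) {
    stop("duplicate ref_ids across reference records", call. = FALSE)
  }
  if (!all(records$taxid %in% taxonomy$taxid)) {
    stop("reference record taxid not resolvable in taxonomy", call. = FALSE)
  }
  structure(list(records = records, taxonomy = taxonomy),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("Barcode reference database\n")
  tab <- table(factor(x$records$marker, levels = MARKERS))
  for (m in MARKERS) cat(sprintf("  %-5s %d record(s)\n", m, tab[[m]]))
  cat(sprintf("  taxonomy: %d node(s)\n", nrow(x$taxonomy)))
  invisible(x)
}

# Ancestor path of one taxid, ordered root -> node (self included).
ancestor_path <- function(taxid, taxonomy) {
  parent <- setNames(taxonomy$parent_taxid, taxonomy$taxid)
  path <- integer(0)
  cur <- taxid
  for (i in seq_len(41)) {
    path <- c(cur, path)
    nxt <- parent[[as.character(cur)]]
    if (nxt == cur) return(path)
    cur <- nxt
  }
  stop("parent chain does not terminate at root", call. = FALSE)
}

#' Lowest common ancestor of a set of taxids
#'
#' Returns the deepest taxonomy node that is an ancestor-or-self of every
#' input taxid.
#'
#' @param taxids nonempty vector of taxids, all present in the taxonomy.
#' @param taxonomy taxonomy table.
#' @return one-row data.frame (a TaxonNode): `taxid`, `parent_taxid`,
#'   `rank`, `name`.
#' @export
lca <- function(taxids, taxonomy) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0L) stop("empty taxid set", call. = FALSE)
  if (!all(taxids %in% taxonomy$taxid)) {
    stop("unknown taxid: ",
         paste(setdiff(taxids, taxonomy$taxid), collapse = ", "),
         call. = FALSE)
  }
  common <- ancestor_path(taxids[1], taxonomy)
  for (t in taxids[-1]) {
    p <- ancestor_path(t, taxonomy)
    n <- min(length(common), length(p))
    eq <- common[seq_len(n)] == p[seq_len(n)]
    common <- common[seq_len(if (all(eq)) n else which(!eq)[1] - 1L)]
  }
  taxonomy[taxonomy$taxid == common[length(common)], , drop = FALSE]
}
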