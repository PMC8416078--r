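# Taxonomic assignment of reliable OTUs (identity-ranked reference
# search + lowest common ancestor) and the composition report.

#' Search an OTU representative against the reference database
#'
#' Every reference of the OTU's marker is aligned locally (match +1,
#' mismatch -2, gap open -5, gap extend -2) on both strands; hits with
#' identity >= `min_identity` over an aligned region of at least 60% of
#' the query are kept, sorted by score then identity.
#'
#' @param query representative sequence (character scalar).
#' @param db a [reference_db()].
#' @param marker marker whose references to search.
#' @param min_identity percent identity cutoff (default 90).
#' @return data.frame of hits: `ref_id`, `taxid`, `identity`,
#'   `aligned_len`, `score`, `strand`.
#' @export
search_hits <- function(query, db, marker, min_identity = 90) {
  refs <- db$records[db$records$marker == marker, , drop = FALSE]
  if (nrow(refs) == 0L) {
    stop("reference database has no records for marker ", marker,
         call. = FALSE)
  }
  qf <- query
  qr <- revcomp(query)
  rows <- lapply(seq_len(nrow(refs)), function(i) {
    af <- cpp_sw_affine(qf, refs$sequence[i])
    ar <- cpp_sw_affine(qr, refs$sequence[i])
    a <- if (af$score >= ar$score) af else ar
    data.frame(ref_id = refs$ref_id[i], taxid = refs$taxid[i],
               identity = a$identity, aligned_len = a$align_len,
               score = a$score,
               strand = if (af$score >= ar$score) "+" else "-",
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[hits$identity >= min_identity &
                 hits$aligned_len >= 0.6 * nchar(query), , drop = FALSE]
  hits <- hits[order(-hits$score, -hits$identity), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Place an OTU by top-percent LCA of its hits
#'
#' Hits within `top_percent` of the best score are retained.  If they
#' name a single taxid and the best identity reaches
#' `species_min_identity`, the OTU is assigned to that taxon directly
#' (`unique-best`); otherwise it is assigned to the lowest common
#' ancestor of the retained taxids (`lca`).  No hits leave the OTU
#' unassigned.
#'
#' @param hits ranked hit data.frame (see [search_hits()]).
#' @param taxonomy taxonomy table.
#' @param top_percent score band below the best hit (percent).
#' @param species_min_identity identity required for a direct
#'   species-level call (percent).
#' @return one-row data.frame (an Assignment): `taxid`, `rank`, `name`,
#'   `method`, `n_hits`.
#' @export
assign_lca <- function(hits, taxonomy, top_percent = 10,
                       species_min_identity = 97) {
  if (nrow(hits) == 0L) {
    return(data.frame(taxid = NA_integer_, rank = "unassigned",
                      name = "unassigned", method = "none", n_hits = 0L,
                      stringsAsFactors = FALSE))
  }
  keep <- hits[hits$score >= (1 - top_percent / 100) * hits$score[1], ,
               drop = FALSE]
  taxids <- unique(keep$taxid)
  if (length(taxids) == 1L && keep$identity[1] >= species_min_identity) {
    node <- taxonomy[taxonomy$taxid == taxids, , drop = FALSE]
    method <- "unique-best"
  } else {
    node <- lca(taxids, taxonomy)
    method <- "lca"
  }
  data.frame(taxid = node$taxid, rank = node$rank, name = node$name,
             method = method, n_hits = nrow(keep),
             stringsAsFactors = FALSE)
}

#' Assign every OTU of a table
#'
#' @param otus OTU data.frame (see [cluster_otus()]).
#' @param db a [reference_db()].
#' @param min_identity,top_percent,species_min_identity see
#'   [search_hits()] and [assign_lca()].
#' @return data.frame: `otu_id`, `marker`, `taxid`, `rank`, `name`,
#'   `method`, `n_hits`.
#' @export
assign_otus <- function(otus, db, min_identity = 90, top_percent = 10,
                        species_min_identity = 97) {
  rows <- lapply(seq_len(nrow(otus)), function(i) {
    hits <- search_hits(otus$representative[i], db, otus$marker[i],
                        min_identity)
    a <- assign_lca(hits, db$taxonomy, top_percent,
                    species_min_identity)
    cbind(data.frame(otu_id = otus$otu_id[i], marker = otus$marker[i],
                     stringsAsFactors = FALSE), a)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(otu_id = character(0), marker = character(0),
               taxid = integer(0), rank = character(0),
               name = character(0), method = character(0),
               n_hits = integer(0))
  rownames(out) <- NULL
  out
}

# Category of an assigned taxon relative to the formulation:
# prescribed / adulterant-candidate / weed-other-plant / fungus /
# unassigned.
taxon_category <- function(taxid, formula, taxonomy) {
  if (is.na(taxid)) return("unassigned")
  if (taxid %in% formula$taxid) return("prescribed")
  # an ancestor of a prescribed species = prescribed ingredient resolved
  # at lower rank (e.g. a genus-level LCA call)
  ancestor_of_formula <- any(vapply(formula$taxid, function(t) {
    taxid %in% ancestor_path(t, taxonomy)
  }, logical(1)))
  if (ancestor_of_formula) return("prescribed")
  path <- ancestor_path(taxid, taxonomy)
  formula_genera <- unique(vapply(formula$taxid, function(t) {
    p <- ancestor_path(t, taxonomy)
    r <- taxonomy$rank[match(p, taxonomy$taxid)]
    g <- p[r == "genus"]
    if (length(g)) as.integer(g[length(g)]) else NA_integer_
  }, integer(1)))
  ranks <- taxonomy$rank[match(path, taxonomy$taxid)]
  genus <- path[ranks == "genus"]
  if (length(genus) && genus[length(genus)] %in% formula_genera) {
    return("adulterant-candidate")
  }
  kingdom <- taxonomy$name[match(path[ranks == "kingdom"],
                                 taxonomy$taxid)]
  if (any(kingdom == "Fungi")) return("fungus")
  if (any(kingdom == "Viridiplantae")) return("weed/other-plant")
  "unassigned"
}

#' Build the composition report
#'
#' Aggregates mapped reads of reliable OTUs per assigned taxon and
#' marker, computes relative abundances (per marker, summing to 100),
#' categorizes each taxon against the formulation, summarizes each
#' marker (OTU count, mean length, GC%), and emits the formula-species
#' x marker detection matrix.
#'
#' @param assignments OTU assignment data.frame (see [assign_otus()]).
#' @param verifications verification data.frame of the same OTUs.
#' @param formula formulation data.frame.
#' @param taxonomy taxonomy table.
#' @param otus OTU data.frame (for lengths and GC).
#' @return object of class `composition_report`: list with
#'   `composition`, `summary`, `detection`.
#' @export
build_report <- function(assignments, verifications, formula, taxonomy,
                         otus) {
  known <- assignments$taxid[!is.na(assignments$taxid)]
  if (!all(known %in% taxonomy$taxid)) {
    stop("assignment references a taxid absent from the taxonomy",
         call. = FALSE)
  }
  df <- merge(assignments, verifications[c("otu_id", "mapped_read_count")],
              by = "otu_id")
  comp <- NULL
  for (m in unique(df$marker)) {
    dm <- df[df$marker == m, , drop = FALSE]
    total <- sum(dm$mapped_read_count)
    key <- paste(dm$taxid, dm$name, dm$rank)
    agg <- aggregate(cbind(reads = dm$mapped_read_count,
                           n_otus = rep(1L, nrow(dm))),
                     by = list(key = key), FUN = sum)
    meta <- dm[!duplicated(key), c("taxid", "rank", "name")]
    meta <- meta[match(agg$key, paste(meta$taxid, meta$name, meta$rank)), ]
    rows <- data.frame(
      marker = m, taxid = meta$taxid, name = meta$name,
      rank = meta$rank, n_otus = agg$n_otus, reads = agg$reads,
      rel_abundance = if (total > 0) 100 * agg$reads / total else 0,
      stringsAsFactors = FALSE)
    rows$category <- vapply(rows$taxid, taxon_category, "",
                            formula = formula, taxonomy = taxonomy)
    rows <- rows[order(-rows$reads, rows$name), , drop = FALSE]
    comp <- rbind(comp, rows)
  }
  rownames(comp) <- NULL

  summ <- do.call(rbind, lapply(unique(otus$marker), function(m) {
    o <- otus[otus$marker == m, , drop = FALSE]
    data.frame(marker = m, n_otus = nrow(o),
               mean_length = mean(nchar(o$representative)),
               gc_percent = 100 * mean(gc_content(o$representative)),
               stringsAsFactors = FALSE)
  }))

  markers <- sort(unique(assignments$marker))
  det <- matrix(FALSE, nrow = nrow(formula), ncol = length(markers),
                dimnames = list(
                  taxonomy$name[match(formula$taxid, taxonomy$taxid)],
                  markers))
  for (i in seq_len(nrow(formula))) {
    for (m in markers) {
      det[i, m] <- any(assignments$marker == m &
                         !is.na(assignments$taxid) &
                         assignments$taxid == formula$taxid[i])
    }
  }
  structure(list(composition = comp, summary = summ, detection = det),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat("Composition report\n\nPer-marker summary:\n")
  print(x$summary, row.names = FALSE)
  cat("\nDetection of prescribed species (marker x species):\n")
  print(x$detection)
  cat("\nComposition (top rows):\n")
  print(head(x$composition, 15), row.names = FALSE)
  invisible(x)
}
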