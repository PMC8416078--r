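# Pipeline orchestration: refdb -> readqc -> enrich -> assemble ->
# barcode -> verify -> taxonomy, under one config, with a run manifest.

#' Load a multi-marker reference database from FASTA files
#'
#' @param fasta_paths named character vector of FASTA paths; names are
#'   marker labels (`ITS2`, `matK`, `rbcL`).
#' @param taxonomy taxonomy table or TSV path.
#' @return a [reference_db()].
#' @export
read_reference_db <- function(fasta_paths, taxonomy) {
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  if (is.null(names(fasta_paths)) ||
      !all(names(fasta_paths) %in% MARKERS)) {
    stop("fasta_paths must be named by marker (ITS2, matK, rbcL)",
         call. = FALSE)
  }
  recs <- do.call(rbind, lapply(names(fasta_paths), function(m) {
    parse_reference_fasta(fasta_paths[[m]], m, taxonomy)
  }))
  reference_db(recs, taxonomy)
}

#' Pipeline configuration
#'
#' Bundles input locations and every stage parameter.  `reads1`/`reads2`
#' may be FASTQ paths or `NULL` when `pairs` is given in memory;
#' `refdb` may be a [reference_db()] or a named vector of FASTA paths;
#' `taxonomy` and `formula` may be objects or TSV paths.
#'
#' @param reads1,reads2 FASTQ paths (optionally gzipped), or `NULL`.
#' @param pairs in-memory ReadPair data.frame (alternative to files).
#' @param refdb reference database or named FASTA paths.
#' @param taxonomy taxonomy table or path.
#' @param formula formulation table or path.
#' @param outdir output directory (created if missing).
#' @param trim a [trim_policy()].
#' @param enrich_k,enrich_min_hits k-mer screen parameters.
#' @param k_list,min_edge_cov,min_contig_len assembly parameters.
#' @param primers,flanks barcode-extraction definitions.
#' @param min_map_identity verification mapping identity (fraction).
#' @param min_identity,top_percent,species_min_identity taxonomy
#'   parameters (percent).
#' @param seed integer seed recorded in the manifest (the pipeline
#'   stages themselves are deterministic).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(reads1 = NULL, reads2 = NULL, pairs = NULL,
                            refdb, taxonomy, formula, outdir,
                            trim = trim_policy(),
                            enrich_k = 21L, enrich_min_hits = 3L,
                            k_list = default_k_list(),
                            min_edge_cov = 2L, min_contig_len = 100L,
                            primers = default_primer_sets(),
                            flanks = default_flank_profiles(),
                            min_map_identity = 0.95,
                            min_identity = 90, top_percent = 10,
                            species_min_identity = 97, seed = 1L) {
  stopifnot(min_map_identity > 0, min_map_identity <= 1,
            top_percent >= 0, top_percent <= 100,
            min_identity >= 0, min_identity <= 100)
  structure(list(reads1 = reads1, reads2 = reads2, pairs = pairs,
                 refdb = refdb, taxonomy = taxonomy, formula = formula,
                 outdir = outdir, trim = trim, enrich_k = enrich_k,
                 enrich_min_hits = enrich_min_hits, k_list = k_list,
                 min_edge_cov = min_edge_cov,
                 min_contig_len = min_contig_len, primers = primers,
                 flanks = flanks, min_map_identity = min_map_identity,
                 min_identity = min_identity, top_percent = top_percent,
                 species_min_identity = species_min_identity,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full shotgun metabarcoding pipeline
#'
#' Executes quality trimming, marker enrichment, multi-k assembly,
#' dereplication, barcode extraction, chimera removal, OTU clustering,
#' depth/coverage verification, taxonomic assignment and reporting, and
#' writes stage outputs plus a manifest into `config$outdir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, an object of class `herbshot_run`: list with
#'   `report`, `otus`, `verifications`, `assignments`, `chimera_verdicts`,
#'   `manifest`, `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(inputs = list(), config = list(
    enrich_k = config$enrich_k, enrich_min_hits = config$enrich_min_hits,
    k_list = config$k_list, min_edge_cov = config$min_edge_cov,
    min_contig_len = config$min_contig_len,
    min_map_identity = config$min_map_identity,
    min_identity = config$min_identity,
    top_percent = config$top_percent,
    species_min_identity = config$species_min_identity,
    seed = config$seed))

  db <- run_stage("refdb", {
    taxonomy <- config$taxonomy
    if (is.character(taxonomy)) {
      manifest$inputs$taxonomy <- unname(tools::md5sum(taxonomy))
      taxonomy <- read_taxonomy(taxonomy)
    }
    if (inherits(config$refdb, "reference_db")) config$refdb
    else {
      manifest$inputs$refdb <- unname(tools::md5sum(config$refdb))
      read_reference_db(config$refdb, taxonomy)
    }
  })
  formula <- run_stage("refdb", {
    if (is.character(config$formula)) {
      manifest$inputs$formula <- unname(tools::md5sum(config$formula))
      load_formula(config$formula)
    } else config$formula
  })

  qc <- run_stage("readqc", {
    pairs <- config$pairs
    if (is.null(pairs)) {
      manifest$inputs$reads1 <- unname(tools::md5sum(config$reads1))
      manifest$inputs$reads2 <- unname(tools::md5sum(config$reads2))
      pairs <- read_fastq_pairs(config$reads1, config$reads2)
    }
    if (nrow(pairs) == 0L) stop("no read pairs in input", call. = FALSE)
    filter_pairs(pairs, config$trim)
  })

  enr <- run_stage("enrich", {
    idx <- build_kmer_index(db, config$enrich_k)
    enrich_pairs(qc$pairs, idx, config$enrich_min_hits)
  })

  contigs <- run_stage("assemble", {
    do.call(rbind, lapply(MARKERS, function(m) {
      dereplicate(assemble_bin(enr$bins[[m]], m, config$k_list,
                               config$min_edge_cov,
                               config$min_contig_len))
    }))
  })

  bc <- run_stage("barcode", {
    cands <- extract_barcodes(contigs, config$primers, config$flanks)
    chim <- filter_chimeras(cands)
    otus <- do.call(rbind, lapply(MARKERS, function(m) {
      cluster_otus(chim$kept[chim$kept$marker == m, , drop = FALSE])
    }))
    list(candidates = cands, chim = chim, otus = otus)
  })

  ver <- run_stage("verify", {
    v <- do.call(rbind, lapply(MARKERS, function(m) {
      o <- bc$otus[bc$otus$marker == m, , drop = FALSE]
      verify_otus(enr$bins[[m]], o, config$min_map_identity)
    }))
    filter_reliable(v)
  })

  reliable_otus <- bc$otus[bc$otus$otu_id %in% ver$reliable$otu_id, ,
                           drop = FALSE]
  res <- run_stage("taxonomy", {
    asg <- assign_otus(reliable_otus, db, config$min_identity,
                       config$top_percent, config$species_min_identity)
    report <- build_report(asg, ver$reliable, formula, db$taxonomy,
                           reliable_otus)
    list(assignments = asg, report = report)
  })

  manifest$counts <- list(
    pairs_in = qc$stats$pairs_in, pairs_qc = qc$stats$pairs_out,
    enriched = as.list(enr$counts), unassigned = enr$unassigned,
    contigs = nrow(contigs), barcodes = nrow(bc$candidates),
    post_chimera = nrow(bc$chim$kept), otus = nrow(bc$otus),
    reliable_otus = nrow(ver$reliable))

  out <- config$outdir
  write_fasta(contigs$sequence, contigs$contig_id,
              file.path(out, "contigs.fasta"))
  write_fasta(bc$otus$representative,
              sprintf("%s|%s|members=%d", bc$otus$otu_id, bc$otus$marker,
                      bc$otus$n_members),
              file.path(out, "otus.fasta"))
  tsv <- function(x, f) write.table(x, file.path(out, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(data.frame(marker = names(enr$counts), pairs = unname(enr$counts)),
      "enrichment_summary.tsv")
  tsv(bc$chim$verdicts, "chimera_report.tsv")
  vtab <- rbind(cbind(ver$reliable, reason = ""), ver$removed)
  tsv(vtab, "verification.tsv")
  tsv(res$report$composition, "composition.tsv")
  tsv(res$report$summary, "marker_summary.tsv")
  write.table(res$report$detection, file.path(out, "detection_matrix.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(structure(list(report = res$report, otus = bc$otus,
                           verifications = vtab,
                           assignments = res$assignments,
                           chimera_verdicts = bc$chim$verdicts,
                           manifest = manifest, outdir = out),
                      class = "herbshot_run"))
}

#' @export
print.herbshot_run <- function(x, ...) {
  cat("herbshot pipeline run ->", x$outdir, "\n")
  c <- x$manifest$counts
  cat(sprintf("  pairs %d -> qc %d; enriched %s; contigs %d; barcodes %d; OTUs %d; reliable %d\n",
              c$pairs_in, c$pairs_qc,
              paste(sprintf("%s=%d", names(c$enriched),
                            unlist(c$enriched)), collapse = " "),
              c$contigs, c$barcodes, c$otus, c$reliable_otus))
  print(x$report)
  invisible(x)
}
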