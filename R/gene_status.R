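# Ortholog length-ratio classification: each panel gene in a genome is
# INTACT, PSEUDOGENE or MISSING. A gene is a pseudogene when its longest
# coding fragment is shorter than 80% of the reference ortholog, when it
# is split into two or more fragments, or (optionally) when the annotation
# already declares it disrupted.

#' Classification parameters
#'
#' @param length_threshold Ortholog length-ratio threshold in (0, 1]; a
#'   single-fragment gene is intact only when `query length >=
#'   length_threshold * reference length` (the rule is strictly "less
#'   than" on the pseudogene side). Default 0.8.
#' @param min_identity Identity floor for assigning a CDS to a panel gene
#'   (default 0.3).
#' @param min_fragment_coverage Per-fragment reference-coverage floor
#'   (default 0.1).
#' @param trust_declared_pseudo When `TRUE` (default) a CDS annotated as a
#'   pseudogene (e.g. an internal stop found by the annotation pipeline)
#'   is classified PSEUDOGENE even if it passes the length test.
#' @param alignment [alignment_params()].
#' @return A list of class `classify_params`.
#' @export
classify_params <- function(length_threshold = 0.8, min_identity = 0.3,
                            min_fragment_coverage = 0.1,
                            trust_declared_pseudo = TRUE,
                            alignment = alignment_params()) {
  if (!is.numeric(length_threshold) || length_threshold <= 0 ||
      length_threshold > 1)
    stop("length_threshold must be in (0, 1]")
  structure(list(length_threshold = length_threshold,
                 min_identity = min_identity,
                 min_fragment_coverage = min_fragment_coverage,
                 trust_declared_pseudo = trust_declared_pseudo,
                 alignment = alignment),
            class = "classify_params")
}

#' Classify one panel gene from its assigned hits
#'
#' @param hits Data frame of CDS hits assigned to this gene (possibly
#'   empty or `NULL`), with columns `cds_id`, `qlen` (translation length,
#'   aa), `declared_pseudo`, `identity`, `ref_start`, `ref_end`.
#' @param ref_length Reference protein length (aa).
#' @param gene_name Panel gene name.
#' @param genome Genome id for bookkeeping.
#' @param params [classify_params()].
#' @return A `gene_status` list: `status` (`"INTACT"`, `"PSEUDOGENE"` or
#'   `"MISSING"`), `length_ratio` (longest single fragment / reference
#'   length; `NA` when missing), `n_fragments` and the supporting `hits`.
#' @export
classify_gene <- function(hits, ref_length, gene_name = NA_character_,
                          genome = NA_character_, params = classify_params()) {
  n <- if (is.null(hits)) 0L else nrow(hits)
  if (n == 0L) {
    return(structure(list(gene_name = gene_name, genome = genome,
                          status = "MISSING", length_ratio = NA_real_,
                          n_fragments = 0L, hits = NULL),
                     class = "gene_status"))
  }
  ratio <- max(hits$qlen) / ref_length
  status <- if (n == 1L &&
                ratio >= params$length_threshold &&
                !(params$trust_declared_pseudo && any(hits$declared_pseudo))) {
    "INTACT"
  } else {
    # single short fragment, declared-pseudo hit, or a gene in >= 2 pieces
    "PSEUDOGENE"
  }
  structure(list(gene_name = gene_name, genome = genome, status = status,
                 length_ratio = ratio, n_fragments = n, hits = hits),
            class = "gene_status")
}

#' Build a status table from per-gene classifications
#'
#' @param genome Genome id.
#' @param records List of `gene_status` objects covering the panel.
#' @return A `status_table` data frame (one row per panel gene) with
#'   attribute `genome`.
#' @export
status_table <- function(genome, records) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(gene_name = r$gene_name, status = r$status,
               length_ratio = r$length_ratio, n_fragments = r$n_fragments,
               cds_ids = if (is.null(r$hits)) "" else
                 paste(r$hits$cds_id, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$gene_name), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, genome = genome, class = c("status_table", "data.frame"))
}

#' Hand-built status table
#'
#' Convenience constructor for a table of known statuses (e.g. transcribed
#' from published presence/absence figures) without alignment evidence.
#'
#' @param genome Genome id.
#' @param statuses Named character vector, gene name to status
#'   (`INTACT`/`PSEUDOGENE`/`MISSING`).
#' @return A `status_table`.
#' @export
manual_status_table <- function(genome, statuses) {
  bad <- setdiff(unique(statuses), c("INTACT", "PSEUDOGENE", "MISSING"))
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "))
  df <- data.frame(gene_name = names(statuses),
                   status = unname(as.character(statuses)),
                   length_ratio = NA_real_,
                   n_fragments = ifelse(statuses == "MISSING", 0L, 1L),
                   cds_ids = "", stringsAsFactors = FALSE)
  df <- df[order(df$gene_name), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, genome = genome, class = c("status_table", "data.frame"))
}

#' Classify every panel gene in a genome
#'
#' Screens all CDS translations against the reference panel (each CDS is
#' assigned to at most one panel gene, its best hit), pools fragments per
#' gene, and applies the ortholog length-ratio rule. The output covers the
#' full panel; genes with no assigned CDS are reported MISSING.
#'
#' @param genome An [annotated_genome].
#' @param panel A [reference_panel].
#' @param params [classify_params()].
#' @return A `status_table` with one row per panel gene. The screen is
#'   independent of CDS input order.
#' @export
classify_genome <- function(genome, panel, params = classify_params()) {
  if (!nrow(panel)) stop("panel is empty")
  hits <- .screen_cds(genome$cds, panel,
                      min_identity = params$min_identity,
                      min_ref_coverage = params$min_fragment_coverage,
                      params = params$alignment)
  recs <- lapply(seq_len(nrow(panel)), function(i) {
    g <- panel$gene_name[i]
    h <- hits[hits$gene_name == g, , drop = FALSE]
    classify_gene(if (nrow(h)) h else NULL, nchar(panel$protein[i]),
                  gene_name = g, genome = genome$strain_id, params = params)
  })
  status_table(genome$strain_id, recs)
}

#' @export
print.status_table <- function(x, ...) {
  cat("<status_table> genome ", attr(x, "genome"), ": ",
      sum(x$status == "INTACT"), " intact, ",
      sum(x$status == "PSEUDOGENE"), " pseudogene, ",
      sum(x$status == "MISSING"), " missing\n", sep = "")
  NextMethod()
}
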