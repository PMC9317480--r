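# Protein-level matching of query CDSs to reference panel entries:
# Smith-Waterman local alignment (BLOSUM62, affine gaps), best-hit
# assignment with content-based tie-breaks, and pooling of multiple
# fragments of a disrupted gene on the reference coordinate system.

#' Alignment scoring parameters
#'
#' @param matrix Substitution matrix name (a matrix shipped with Biostrings).
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_opening = 11,
                             gap_extension = 1) {
  structure(list(matrix = matrix, gap_opening = gap_opening,
                 gap_extension = gap_extension),
            class = "alignment_params")
}

.subst_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

.check_aa <- function(s, what = "sequence") {
  if (!nzchar(s)) stop(what, " is empty")
  if (!.aa_ok(s))
    stop(what, " contains non-amino-acid characters (other than X)")
  invisible(s)
}

# vectorized core: local-align many queries against one reference
.align_many <- function(queries, ref, params = alignment_params()) {
  qset <- Biostrings::AAStringSet(queries)
  aln <- Biostrings::pairwiseAlignment(
    pattern = qset, subject = Biostrings::AAString(ref), type = "local",
    substitutionMatrix = .subst_matrix(params$matrix),
    gapOpening = params$gap_opening, gapExtension = params$gap_extension)
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  ncols <- Biostrings::nchar(aln)       # alignment columns incl. gaps
  data.frame(
    score = Biostrings::score(aln),
    identity = ifelse(ncols > 0, Biostrings::nmatch(aln) / ncols, 0),
    query_coverage = (BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L) /
      nchar(queries),
    ref_coverage = (BiocGenerics::end(sub) - BiocGenerics::start(sub) + 1L) /
      nchar(ref),
    ref_start = BiocGenerics::start(sub) - 1L,   # 0-based half-open on ref
    ref_end = BiocGenerics::end(sub),
    stringsAsFactors = FALSE)
}

#' Optimal local protein alignment
#'
#' Smith-Waterman alignment of two amino-acid sequences under a
#' substitution matrix with affine gap penalties. Identity is the fraction
#' of identical positions over all alignment columns; coverages are the
#' aligned span over each sequence's full length.
#'
#' @param a Query amino-acid sequence.
#' @param b Reference amino-acid sequence.
#' @param params [alignment_params()].
#' @return An `alignment_result`: list with `score`, `identity`,
#'   `query_coverage`, `ref_coverage` and the 0-based half-open
#'   `ref_interval` covered on the reference.
#' @export
align_local <- function(a, b, params = alignment_params()) {
  .check_aa(a, "query"); .check_aa(b, "reference")
  r <- .align_many(a, b, params)
  structure(list(score = r$score, identity = r$identity,
                 query_coverage = r$query_coverage,
                 ref_coverage = r$ref_coverage,
                 ref_interval = c(r$ref_start, r$ref_end)),
            class = "alignment_result")
}

#' Best panel hit for one query
#'
#' Aligns the query against every panel entry and returns the entry with
#' the highest alignment score among those passing the identity and
#' per-fragment reference-coverage floors. Ties are broken by higher
#' identity, then by lexicographically smallest gene name, so the result
#' does not depend on panel order.
#'
#' @param query Amino-acid sequence (or a CDS record row with a
#'   `translation` column).
#' @param panel A [reference_panel].
#' @param min_identity Identity floor for a hit (default 0.3, permissive so
#'   pseudogene fragments remain assignable).
#' @param min_ref_coverage Reference-coverage floor per fragment
#'   (default 0.1).
#' @param params [alignment_params()].
#' @return `list(gene_name =, alignment =)` or `NULL` when nothing passes.
#' @export
best_hit <- function(query, panel, min_identity = 0.3,
                     min_ref_coverage = 0.1, params = alignment_params()) {
  if (is.list(query) && !is.null(query$translation)) query <- query$translation
  .check_aa(query, "query")
  if (!nrow(panel)) stop("panel is empty")
  res <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i)
    .align_many(query, panel$protein[i], params)))
  res$gene_name <- panel$gene_name
  pass <- res$identity >= min_identity & res$ref_coverage >= min_ref_coverage
  if (!any(pass)) return(NULL)
  res <- res[pass, , drop = FALSE]
  ord <- order(-res$score, -res$identity, res$gene_name)
  top <- res[ord[1], ]
  list(gene_name = top$gene_name,
       alignment = structure(list(score = top$score, identity = top$identity,
                                  query_coverage = top$query_coverage,
                                  ref_coverage = top$ref_coverage,
                                  ref_interval = c(top$ref_start, top$ref_end)),
                             class = "alignment_result"))
}

#' Pool fragments of a disrupted gene on the reference
#'
#' Takes the CDSs whose best hit is one reference protein and merges their
#' aligned reference intervals; overlapping positions are counted once.
#'
#' @param hits Data frame with one row per fragment, columns `cds_id`,
#'   `ref_start`, `ref_end` (0-based half-open intervals on the reference).
#' @param ref_length Reference protein length (aa).
#' @param ref_gene Reference gene name.
#' @return A `fragment_assignment`: fragments sorted by reference start and
#'   `merged_ref_coverage` = |union of intervals| / reference length; or
#'   `NULL` for an empty hit set.
#' @export
assign_fragments <- function(hits, ref_length, ref_gene = NA_character_) {
  if (is.null(hits) || !nrow(hits)) return(NULL)
  hits <- hits[order(hits$ref_start, hits$ref_end, hits$cds_id), , drop = FALSE]
  ir <- IRanges::IRanges(start = hits$ref_start + 1L, end = hits$ref_end)
  covered <- sum(IRanges::width(IRanges::reduce(ir)))
  structure(list(ref_gene = ref_gene, fragments = hits,
                 merged_ref_coverage = covered / ref_length),
            class = "fragment_assignment")
}

# screen every CDS of a genome against the panel; returns one row per
# (CDS, assigned gene) pair using best-hit assignment (one CDS, one gene)
.screen_cds <- function(cds, panel, min_identity = 0.3,
                        min_ref_coverage = 0.1, params = alignment_params()) {
  empty <- data.frame(cds_id = character(0), gene_name = character(0),
                      score = numeric(0), identity = numeric(0),
                      query_coverage = numeric(0), ref_coverage = numeric(0),
                      ref_start = integer(0), ref_end = integer(0),
                      qlen = integer(0), declared_pseudo = logical(0),
                      stringsAsFactors = FALSE)
  cds <- cds[nzchar(cds$translation), , drop = FALSE]
  if (!nrow(cds) || !nrow(panel)) return(empty)
  per_ref <- lapply(seq_len(nrow(panel)), function(i) {
    r <- .align_many(cds$translation, panel$protein[i], params)
    r$gene_name <- panel$gene_name[i]
    r
  })
  best <- lapply(seq_len(nrow(cds)), function(j) {
    rows <- do.call(rbind, lapply(per_ref, function(r) r[j, , drop = FALSE]))
    pass <- rows$identity >= min_identity &
      rows$ref_coverage >= min_ref_coverage
    if (!any(pass)) return(NULL)
    rows <- rows[pass, , drop = FALSE]
    ord <- order(-rows$score, -rows$identity, rows$gene_name)
    top <- rows[ord[1], , drop = FALSE]
    top$cds_id <- cds$id[j]
    top$qlen <- nchar(cds$translation[j])
    top$declared_pseudo <- cds$declared_pseudo[j]
    top
  })
  best <- best[!vapply(best, is.null, logical(1))]
  if (!length(best)) return(empty)
  out <- do.call(rbind, best)
  rownames(out) <- NULL
  out[order(out$gene_name, out$ref_start, out$cds_id), , drop = FALSE]
}
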