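# Biosynthetic-pathway completeness with alternative-enzyme logic, per
# genome and for the consortium (union of genomes). A step is SATISFIED
# when any of its alternative genes is intact in any considered genome;
# a pathway is complete only when every step is satisfied.

#' Construct a pathway catalog
#'
#' @param pathways List of pathways; each pathway a list with `name` and
#'   `steps`, each step a list with `step` (step name), `genes` (non-empty
#'   character vector of alternative gene names) and optional `enzyme`
#'   (free-text label).
#' @return An object of class `pathway_catalog`.
#' @export
pathway_catalog <- function(pathways) {
  for (p in pathways) {
    if (is.null(p$name) || !length(p$steps))
      stop("each pathway needs a name and at least one step")
    for (s in p$steps)
      if (is.null(s$step) || !length(s$genes))
        stop("pathway '", p$name, "': each step needs a name and >= 1 gene")
  }
  structure(list(pathways = pathways), class = "pathway_catalog")
}

#' Read a pathway catalog from YAML
#'
#' Schema: `pathways:` is a list of `{name, steps}`; each step is
#' `{step, enzyme, genes: [...]}` where `genes` lists alternative genes
#' able to perform the step.
#'
#' @param path YAML file.
#' @return A [pathway_catalog].
#' @export
read_pathway_catalog <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$pathways)) stop("catalog YAML must have a 'pathways' key")
  pathway_catalog(y$pathways)
}

#' Bundled default pathway catalog
#'
#' Covers riboflavin (with the phosphatase step's alternatives
#' yigB/ybjI/yigL), biotin, and the ten essential amino acids, populated
#' from the standard enterobacterial biosynthesis gene sets. Fully
#' user-overridable via [read_pathway_catalog()].
#'
#' @return A [pathway_catalog].
#' @export
default_pathway_catalog <- function() {
  read_pathway_catalog(system.file("extdata", "pathway_catalog.yaml",
                                   package = "symcomp", mustWork = TRUE))
}

#' Subset a catalog by pathway name
#'
#' @param catalog A [pathway_catalog].
#' @param names Pathway names to keep.
#' @return A [pathway_catalog].
#' @export
catalog_subset <- function(catalog, names) {
  keep <- Filter(function(p) p$name %in% names, catalog$pathways)
  if (!length(keep)) stop("no catalog pathway matches: ",
                          paste(names, collapse = ", "))
  pathway_catalog(keep)
}

.get_pathway <- function(catalog, name) {
  for (p in catalog$pathways) if (identical(p$name, name)) return(p)
  stop("pathway not in catalog: ", name)
}

.gene_status_in <- function(gene, table) {
  i <- match(gene, table$gene_name)
  if (is.na(i))
    stop("status table for genome '", attr(table, "genome"),
         "' does not cover gene '", gene, "'")
  table$status[i]
}

#' Status of one pathway step across genomes
#'
#' SATISFIED when any alternative gene is INTACT in any genome;
#' otherwise PSEUDOGENIZED when any alternative is a pseudogene anywhere
#' (a pseudogenized alternative dominates a missing one); otherwise
#' MISSING.
#'
#' @param step A catalog step (`list(step =, genes =, ...)`).
#' @param tables List of [status_table] objects (or a single one).
#' @return `list(value =, providers =)`; `providers` is the set of genome
#'   ids holding an intact alternative (non-empty iff SATISFIED).
#' @export
step_status <- function(step, tables) {
  if (inherits(tables, "status_table")) tables <- list(tables)
  providers <- character(0)
  any_pseudo <- FALSE
  for (t in tables) {
    st <- vapply(step$genes, .gene_status_in, character(1), table = t)
    if (any(st == "INTACT")) providers <- c(providers, attr(t, "genome"))
    if (any(st == "PSEUDOGENE")) any_pseudo <- TRUE
  }
  value <- if (length(providers)) "SATISFIED"
           else if (any_pseudo) "PSEUDOGENIZED" else "MISSING"
  list(value = value, providers = unique(providers))
}

#' Pathway completeness in a single genome
#'
#' @param pathway A catalog pathway (or its name, with `catalog` supplied).
#' @param table A [status_table].
#' @param catalog Optional [pathway_catalog] to resolve `pathway` by name.
#' @return `list(pathway =, steps =, complete =)`; `steps` is a named
#'   character vector of per-step statuses.
#' @export
pathway_completeness <- function(pathway, table, catalog = NULL) {
  if (is.character(pathway)) pathway <- .get_pathway(catalog, pathway)
  ss <- lapply(pathway$steps, step_status, tables = table)
  steps <- stats::setNames(vapply(ss, `[[`, character(1), "value"),
                           vapply(pathway$steps, `[[`, character(1), "step"))
  list(pathway = pathway$name, steps = steps,
       complete = all(steps == "SATISFIED"))
}

#' Pathway completeness in the union of genomes
#'
#' Evaluates each step over the pooled status tables of the consortium
#' members and attributes providers: a step covered by exactly one member
#' is a point of metabolic complementarity; a step covered by several is
#' redundant.
#'
#' @param pathway A catalog pathway (or its name, with `catalog`).
#' @param tables List of [status_table] objects, one per member.
#' @param catalog Optional [pathway_catalog].
#' @return A `consortium_verdict`: `per_step` (list of [step_status()]
#'   results), `complete`, `unique_providers` (named vector step ->
#'   genome) and `redundant_steps`.
#' @export
consortium_completeness <- function(pathway, tables, catalog = NULL) {
  if (is.character(pathway)) pathway <- .get_pathway(catalog, pathway)
  if (inherits(tables, "status_table")) tables <- list(tables)
  if (!length(tables)) stop("need at least one status table")
  ss <- lapply(pathway$steps, step_status, tables = tables)
  step_names <- vapply(pathway$steps, `[[`, character(1), "step")
  names(ss) <- step_names
  nprov <- vapply(ss, function(s) length(s$providers), integer(1))
  uniq <- vapply(ss[nprov == 1L], function(s) s$providers, character(1))
  structure(list(pathway = pathway$name, per_step = ss,
                 complete = all(vapply(ss, `[[`, character(1),
                                       "value") == "SATISFIED"),
                 unique_providers = uniq,
                 redundant_steps = step_names[nprov >= 2L]),
            class = "consortium_verdict")
}

#' @export
print.consortium_verdict <- function(x, ...) {
  cat("<consortium_verdict> ", x$pathway, ": ",
      if (x$complete) "COMPLETE" else "INCOMPLETE", "\n", sep = "")
  for (s in names(x$per_step)) {
    st <- x$per_step[[s]]
    cat("  ", format(s, width = 14), st$value,
        if (length(st$providers))
          paste0(" [", paste(st$providers, collapse = ","), "]") else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' Per-gene, per-genome complementarity matrix
#'
#' Assembles the tabular twin of a presence/absence pathway figure: one
#' row per (pathway, step, gene), one status column per genome, plus a
#' `consortium` column with the step status over the union of genomes.
#'
#' @param catalog A [pathway_catalog].
#' @param tables List of [status_table] objects.
#' @return A data frame suitable for [write_status_matrix()].
#' @export
complementarity_matrix <- function(catalog, tables) {
  if (inherits(tables, "status_table")) tables <- list(tables)
  mat <- status_matrix(tables, catalog)
  cons <- character(nrow(mat))
  for (p in catalog$pathways) {
    for (s in p$steps) {
      v <- step_status(s, tables)$value
      cons[mat$pathway == p$name & mat$step == s$step] <- v
    }
  }
  mat$consortium <- cons
  mat
}
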