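# Virulence-factor screening at identity/coverage thresholds and the
# higher-level verdicts drawn from it: flagellum completeness class and
# siderophore locus completeness.

#' Screen a genome against a virulence-factor panel
#'
#' Each panel gene is scored from the CDSs assigned to it (best hit,
#' fragments pooled): PRESENT when the gene is classified intact and the
#' evidence passes the identity and merged reference-coverage thresholds;
#' PSEUDOGENE when hits are detected (identity at or above the detection
#' floor) but the gene fails the length/fragment criteria or the
#' presence thresholds; ABSENT when no hit reaches the detection floor.
#'
#' @param genome An [annotated_genome].
#' @param vf_panel A [reference_panel] of virulence factors with category
#'   tags (e.g. `flagellum.hook`, `siderophore.ent`, `t5ss`, `toxin`).
#' @param min_identity Identity threshold for presence (default 0.5).
#' @param min_ref_coverage Merged reference-coverage threshold for
#'   presence (default 0.8).
#' @param detection_floor Identity floor below which hits are ignored
#'   entirely, i.e. the PSEUDOGENE/ABSENT boundary (default 0.3).
#' @param params [classify_params()] controlling the underlying
#'   classification; its `min_identity` is set to `detection_floor`.
#' @return A `virulence_map` data frame: columns `gene_name`, `category`,
#'   `status` (`PRESENT`/`PSEUDOGENE`/`ABSENT`), `identity`,
#'   `merged_ref_coverage`, `n_fragments`; attribute `genome`.
#' @export
screen_virulence <- function(genome, vf_panel, min_identity = 0.5,
                             min_ref_coverage = 0.8, detection_floor = 0.3,
                             params = classify_params()) {
  for (v in c(min_identity, min_ref_coverage, detection_floor))
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop("thresholds must be in (0, 1]")
  params$min_identity <- detection_floor
  hits <- .screen_cds(genome$cds, vf_panel,
                      min_identity = detection_floor,
                      min_ref_coverage = params$min_fragment_coverage,
                      params = params$alignment)
  rows <- lapply(seq_len(nrow(vf_panel)), function(i) {
    g <- vf_panel$gene_name[i]
    ref_len <- nchar(vf_panel$protein[i])
    h <- hits[hits$gene_name == g, , drop = FALSE]
    if (!nrow(h)) {
      return(data.frame(gene_name = g, category = vf_panel$category[i],
                        status = "ABSENT", identity = NA_real_,
                        merged_ref_coverage = 0, n_fragments = 0L,
                        stringsAsFactors = FALSE))
    }
    h$cds_id <- h$cds_id
    fa <- assign_fragments(h, ref_len, g)
    cls <- classify_gene(h, ref_len, gene_name = g,
                         genome = genome$strain_id, params = params)
    best_id <- max(h$identity)
    present <- cls$status == "INTACT" && best_id >= min_identity &&
      fa$merged_ref_coverage >= min_ref_coverage
    data.frame(gene_name = g, category = vf_panel$category[i],
               status = if (present) "PRESENT" else "PSEUDOGENE",
               identity = best_id,
               merged_ref_coverage = fa$merged_ref_coverage,
               n_fragments = nrow(h), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  structure(df, genome = genome$strain_id,
            class = c("virulence_map", "data.frame"))
}

#' Hand-built virulence map
#'
#' @param genome Genome id.
#' @param statuses Named character vector gene ->
#'   `PRESENT`/`PSEUDOGENE`/`ABSENT`.
#' @param categories Optional named character vector gene -> category tag.
#' @return A `virulence_map`.
#' @export
manual_virulence_map <- function(genome, statuses, categories = NULL) {
  bad <- setdiff(unique(statuses), c("PRESENT", "PSEUDOGENE", "ABSENT"))
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "))
  df <- data.frame(gene_name = names(statuses),
                   category = if (is.null(categories)) "" else
                     unname(categories[names(statuses)]),
                   status = unname(as.character(statuses)),
                   identity = NA_real_, merged_ref_coverage = NA_real_,
                   n_fragments = NA_integer_, stringsAsFactors = FALSE)
  structure(df, genome = genome, class = c("virulence_map", "data.frame"))
}

#' Default flagellar part map
#'
#' Assigns each gene of the standard enterobacterial flagellar regulon to
#' a structural/functional part: basal body, hook, filament, export
#' apparatus, or regulation. User-overridable.
#'
#' @return Named character vector, gene name -> part.
#' @export
default_flagellum_parts <- function() {
  c(flgB = "basal_body", flgC = "basal_body", flgF = "basal_body",
    flgG = "basal_body", flgH = "basal_body", flgI = "basal_body",
    fliE = "basal_body", fliF = "basal_body", fliG = "basal_body",
    fliM = "basal_body", fliN = "basal_body",
    flgD = "hook", flgE = "hook", flgK = "hook", fliK = "hook",
    fliC = "filament", flgL = "filament", fliD = "filament",
    flhA = "export", flhB = "export", fliH = "export", fliI = "export",
    fliP = "export", fliQ = "export", fliR = "export",
    flhC = "regulation", flhD = "regulation", fliA = "regulation")
}

.flag_parts <- c("basal_body", "hook", "filament", "export", "regulation")

#' Flagellum completeness class
#'
#' COMPLETE when every flagellar gene of every part is PRESENT; ABSENT
#' when none is; BASAL_BODY_ONLY when at least one basal-body gene is
#' PRESENT while the hook and the filament each retain no PRESENT gene
#' (the relic configuration of an eroding genome); PARTIAL otherwise.
#'
#' @param vmap A `virulence_map` covering the flagellar genes.
#' @param part_map Named character vector gene -> part; default
#'   [default_flagellum_parts()] restricted to the genes in `vmap`.
#' @return A `flagellum_verdict`: `value` and `intact_by_part` (PRESENT
#'   counts and totals per part).
#' @export
flagellum_assessment <- function(vmap, part_map = NULL) {
  if (is.null(part_map)) {
    part_map <- default_flagellum_parts()
    part_map <- part_map[names(part_map) %in% vmap$gene_name]
  }
  bad <- setdiff(unique(part_map), .flag_parts)
  if (length(bad))
    stop("unknown flagellar part tag(s): ", paste(bad, collapse = ", "))
  missing_genes <- setdiff(names(part_map), vmap$gene_name)
  if (length(missing_genes))
    stop("virulence map lacks flagellar gene(s): ",
         paste(missing_genes, collapse = ", "))
  st <- stats::setNames(vmap$status[match(names(part_map), vmap$gene_name)],
                        names(part_map))
  by_part <- lapply(.flag_parts, function(p) {
    genes <- names(part_map)[part_map == p]
    c(present = sum(st[genes] == "PRESENT"), total = length(genes))
  })
  names(by_part) <- .flag_parts
  n_present <- sum(st == "PRESENT")
  value <- if (n_present == 0L) {
    "ABSENT"
  } else if (all(st == "PRESENT")) {
    "COMPLETE"
  } else if (by_part$basal_body["present"] >= 1L &&
             by_part$hook["present"] == 0L &&
             by_part$filament["present"] == 0L) {
    "BASAL_BODY_ONLY"
  } else {
    "PARTIAL"
  }
  structure(list(value = value, intact_by_part = by_part),
            class = "flagellum_verdict")
}

#' @export
print.flagellum_verdict <- function(x, ...) {
  cat("<flagellum_verdict> ", x$value, "\n", sep = "")
  for (p in names(x$intact_by_part))
    cat("  ", format(p, width = 11), x$intact_by_part[[p]]["present"], "/",
        x$intact_by_part[[p]]["total"], " present\n", sep = "")
  invisible(x)
}

#' Locus completeness
#'
#' A locus (e.g. the enterobactin or yersiniabactin gene cluster) is
#' complete only when every one of its genes is PRESENT; otherwise the
#' failing (missing or pseudogenized) genes are listed.
#'
#' @param vmap A `virulence_map`.
#' @param locus_genes Character vector of locus gene names (must be
#'   covered by the map).
#' @return `list(complete =, failing =)`.
#' @export
locus_completeness <- function(vmap, locus_genes) {
  missing_genes <- setdiff(locus_genes, vmap$gene_name)
  if (length(missing_genes))
    stop("virulence map lacks locus gene(s): ",
         paste(missing_genes, collapse = ", "))
  st <- vmap$status[match(locus_genes, vmap$gene_name)]
  failing <- locus_genes[st != "PRESENT"]
  list(complete = length(failing) == 0L, failing = failing)
}
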