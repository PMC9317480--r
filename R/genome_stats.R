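# Genome-erosion and prevalence summary statistics.

#' Pseudogene percentage
#'
#' Percentage of pseudogenes among total CDSs, rounded to the nearest
#' integer (half away from zero).
#'
#' @param n_pseudogenes,n_cds_total Non-negative integer counts.
#' @return Integer percentage, or `NA` when there are no CDSs.
#' @export
pseudogene_pct <- function(n_pseudogenes, n_cds_total) {
  stopifnot(n_pseudogenes >= 0, n_cds_total >= 0,
            n_pseudogenes <= n_cds_total)
  if (n_cds_total == 0) return(NA_real_)
  round_half_up(100 * n_pseudogenes / n_cds_total)
}

#' Genome size in megabases
#'
#' Total base pairs over all replicons (plasmids included), reported in
#' Mb to two decimals (half away from zero), the convention used for
#' aggregate genome-size statements.
#'
#' @param total_bp Total length in base pairs.
#' @return Numeric Mb value.
#' @export
genome_mb <- function(total_bp) {
  round_half_up(total_bp / 1e6, 2)
}

#' Genome erosion summary
#'
#' Totals and pseudogene fraction for one strain. The pseudogene count
#' comes either from the annotation's declared flags or from a recomputed
#' [status_table]; with a table, panel genes classified PSEUDOGENE are
#' counted and `n_cds_total` is the number of panel genes detected
#' (intact + pseudogenized).
#'
#' @param genome An [annotated_genome].
#' @param table Optional `status_table`; when `NULL`, declared pseudo
#'   flags are used and all CDSs counted.
#' @return A `genome_summary` list: `strain_id`, `total_bp`,
#'   `n_replicons`, `n_cds_total`, `n_cds_intact`, `n_pseudogenes`,
#'   `pseudogene_pct`, `total_mb`.
#' @export
summarize_genome <- function(genome, table = NULL) {
  total_bp <- sum(genome$replicons$length)
  if (is.null(table)) {
    n_total <- nrow(genome$cds)
    n_pseudo <- sum(genome$cds$declared_pseudo)
  } else {
    n_pseudo <- sum(table$status == "PSEUDOGENE")
    n_total <- sum(table$status != "MISSING")
  }
  genome_summary(genome$strain_id, n_pseudogenes = n_pseudo,
                 n_cds_total = n_total, total_bp = total_bp,
                 n_replicons = nrow(genome$replicons))
}

#' Genome summary from printed counts
#'
#' Builds the same summary object directly from reported counts, e.g. to
#' recompute a published pseudogene fraction.
#'
#' @param strain_id Strain name.
#' @param n_pseudogenes,n_cds_total Counts.
#' @param total_bp Total genome length in bp (optional).
#' @param n_replicons Number of replicons (optional).
#' @return A `genome_summary`.
#' @export
genome_summary <- function(strain_id, n_pseudogenes, n_cds_total,
                           total_bp = NA_real_, n_replicons = NA_integer_) {
  structure(list(strain_id = strain_id,
                 total_bp = total_bp,
                 total_mb = if (is.na(total_bp)) NA_real_ else
                   genome_mb(total_bp),
                 n_replicons = n_replicons,
                 n_cds_total = n_cds_total,
                 n_cds_intact = n_cds_total - n_pseudogenes,
                 n_pseudogenes = n_pseudogenes,
                 pseudogene_pct = pseudogene_pct(n_pseudogenes, n_cds_total)),
            class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat("<genome_summary> ", x$strain_id, "\n", sep = "")
  if (!is.na(x$total_bp))
    cat("  size: ", x$total_bp, " bp (", sprintf("%.2f", x$total_mb),
        " Mb) over ", x$n_replicons, " replicon(s)\n", sep = "")
  cat("  CDS: ", x$n_cds_total, " total, ", x$n_pseudogenes,
      " pseudogenes (",
      if (is.na(x$pseudogene_pct)) "n/a" else paste0(x$pseudogene_pct, "%"),
      ")\n", sep = "")
  invisible(x)
}

#' Write a TSV of genome summaries
#'
#' @param summaries List of `genome_summary` objects.
#' @param path Output TSV.
#' @export
write_genome_summaries <- function(summaries, path) {
  df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(strain_id = s$strain_id, total_bp = s$total_bp,
               total_mb = s$total_mb, n_replicons = s$n_replicons,
               n_cds_total = s$n_cds_total, n_cds_intact = s$n_cds_intact,
               n_pseudogenes = s$n_pseudogenes,
               pseudogene_fraction = if (s$n_cds_total > 0)
                 s$n_pseudogenes / s$n_cds_total else NA_real_,
               pseudogene_pct = s$pseudogene_pct,
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Symbiont prevalence with exact binomial confidence interval
#'
#' Fraction of sampled colonies positive for the symbiont, with the
#' Clopper-Pearson 95% interval. Universal prevalence is the signature of
#' an obligate symbiont.
#'
#' @param n_positive Number of positive colonies.
#' @param n_sampled Number of colonies surveyed (> 0).
#' @return A `prevalence_result`: `n_positive`, `n_sampled`,
#'   `prevalence_pct` and `ci95` (percent scale).
#' @export
prevalence <- function(n_positive, n_sampled) {
  stopifnot(length(n_positive) == 1L, length(n_sampled) == 1L)
  if (n_sampled <= 0 || n_positive < 0 || n_positive != round(n_positive) ||
      n_sampled != round(n_sampled))
    stop("counts must be non-negative integers with n_sampled > 0")
  if (n_positive > n_sampled)
    stop("n_positive cannot exceed n_sampled")
  ci <- stats::binom.test(n_positive, n_sampled)$conf.int
  structure(list(n_positive = n_positive, n_sampled = n_sampled,
                 prevalence_pct = 100 * n_positive / n_sampled,
                 ci95 = 100 * as.numeric(ci)),
            class = "prevalence_result")
}

#' @export
print.prevalence_result <- function(x, ...) {
  cat(sprintf("<prevalence> %d/%d positive = %.1f%% (95%% CI %.1f-%.1f%%)\n",
              x$n_positive, x$n_sampled, x$prevalence_pct,
              x$ci95[1], x$ci95[2]))
  invisible(x)
}
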