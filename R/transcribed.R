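# Bundled qualitative fixtures: gene statuses reported for the
# B. aphidicola (Ba) + S. symbiotica (Ss) di-symbiotic consortia of the
# aphids Sipha maydis (Sm) and Periphyllus lyropictus (Pl), transcribed
# from the published presence/absence statements for those systems. They
# exercise the pathway engine and the virulome verdicts without any
# sequence data.

#' Transcribed vitamin-pathway status matrix
#'
#' Per-gene INTACT/PSEUDOGENE/MISSING statuses of the riboflavin and
#' biotin pathway genes in the four symbiont genomes BaSm, SsSm, BaPl and
#' SsPl (the two Buchnera/Serratia consortia). Rows not individually
#' reported are filled from the standard expectations for these systems.
#'
#' @return A status-matrix data frame (see [read_status_matrix()]).
#' @export
transcribed_vitamin_matrix <- function() {
  read_status_matrix(system.file("extdata", "vitamin_status_transcribed.tsv",
                                 package = "symcomp", mustWork = TRUE))
}

#' Transcribed virulence-factor maps
#'
#' PRESENT/PSEUDOGENE/ABSENT statuses of flagellar, siderophore (ent and
#' ybt loci), autotransporter and toxin genes in the SsSm and SsPl
#' genomes.
#'
#' @return Named list of two `virulence_map` objects (`SsSm`, `SsPl`).
#' @export
transcribed_virulome_maps <- function() {
  df <- read.delim(system.file("extdata", "virulome_transcribed.tsv",
                               package = "symcomp", mustWork = TRUE),
                   stringsAsFactors = FALSE)
  cats <- stats::setNames(df$category, df$gene)
  list(SsSm = manual_virulence_map("SsSm",
                                   stats::setNames(df$SsSm, df$gene), cats),
       SsPl = manual_virulence_map("SsPl",
                                   stats::setNames(df$SsPl, df$gene), cats))
}
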