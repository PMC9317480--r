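# Readers and writers for annotated genomes, reference panels and the
# tabular status matrices produced downstream. Internal coordinates are
# 0-based half-open; GFF3 (1-based inclusive) and GenBank locations are
# converted on read.

#' Construct an annotated genome
#'
#' Container for one symbiont strain: its replicons and its CDS records.
#' Coordinates are 0-based half-open on the forward strand of the replicon.
#'
#' @param strain_id Character scalar naming the strain.
#' @param replicons Data frame with columns `id`, `length` (bp),
#'   `topology` (`"circular"` or `"linear"`) and `kind` (`"chromosome"`,
#'   `"plasmid"` or `"contig"`).
#' @param cds Data frame with columns `id`, `replicon_id`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `translation` (amino acids, no terminal stop;
#'   may be `""` for declared pseudogenes), `declared_pseudo` (logical) and
#'   `product` (free text).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(strain_id, replicons, cds) {
  stopifnot(is.character(strain_id), length(strain_id) == 1L)
  replicons <- as.data.frame(replicons, stringsAsFactors = FALSE)
  cds <- as.data.frame(cds, stringsAsFactors = FALSE)
  need_rep <- c("id", "length", "topology", "kind")
  need_cds <- c("id", "replicon_id", "start", "end", "strand",
                "translation", "declared_pseudo", "product")
  if (!all(need_rep %in% names(replicons)))
    stop("replicons must have columns: ", paste(need_rep, collapse = ", "))
  if (!all(need_cds %in% names(cds)))
    stop("cds must have columns: ", paste(need_cds, collapse = ", "))
  if (nrow(cds)) {
    if (any(cds$end <= cds$start))
      stop("CDS intervals must satisfy end > start (0-based half-open)")
    bad_rep <- setdiff(cds$replicon_id, replicons$id)
    if (length(bad_rep))
      stop("CDS reference unknown replicon(s): ", paste(bad_rep, collapse = ", "))
    rlen <- replicons$length[match(cds$replicon_id, replicons$id)]
    if (any(cds$start < 0 | cds$end > rlen))
      stop("CDS coordinates outside replicon bounds")
    empty <- !nzchar(cds$translation)
    if (any(empty & !cds$declared_pseudo))
      stop("CDS without translation must be declared pseudo")
    ok <- vapply(cds$translation[!empty], .aa_ok, logical(1))
    if (!all(ok))
      stop("translation contains characters outside the 20 amino acids + X")
  }
  structure(list(strain_id = strain_id, replicons = replicons,
                 cds = cds[order(cds$replicon_id, cds$start, cds$id), ,
                           drop = FALSE]),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> ", x$strain_id, "\n", sep = "")
  cat("  replicons: ", nrow(x$replicons), " (",
      sum(x$replicons$length), " bp)\n", sep = "")
  cat("  CDS: ", nrow(x$cds), " (", sum(x$cds$declared_pseudo),
      " declared pseudo)\n", sep = "")
  invisible(x)
}

#' Read an annotated genome
#'
#' Parses either a GenBank flat file or a GFF3 annotation paired with the
#' genomic FASTA. Every CDS feature becomes one record; compound (joined)
#' locations are flattened to their outer bounds with the feature's strand.
#' Translations are taken from the `/translation` qualifier when embedded,
#' otherwise derived from the genome sequence under the bacterial genetic
#' code (table 11), trimming the terminal stop. CDSs flagged as pseudogenes
#' (`/pseudo` in GenBank, a `pseudo=true` attribute or `pseudogene` type in
#' GFF3) are recorded with `declared_pseudo = TRUE` and may lack a
#' translation.
#'
#' @param path Annotation file (GenBank flat file, or GFF3).
#' @param format `"genbank"` or `"gff3"`.
#' @param fasta Genomic FASTA path; required for `format = "gff3"`.
#' @param strain_id Strain name; defaults to the file base name.
#' @return An [annotated_genome]. CDSs that could not be completed (no
#'   translation and no sequence to translate from) are skipped and listed
#'   in `attr(, "skipped")`.
#' @export
read_genome_annotation <- function(path, format = c("gff3", "genbank"),
                                   fasta = NULL, strain_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  strain_id <- strain_id %||% sub("\\.[^.]+$", "", basename(path))
  if (format == "gff3") {
    if (is.null(fasta)) stop("format 'gff3' requires a genomic FASTA")
    .read_gff3_genome(path, fasta, strain_id)
  } else {
    .read_genbank_genome(path, strain_id)
  }
}

.translate_cds <- function(dnaset, replicon_id, start0, end, strand) {
  if (!replicon_id %in% names(dnaset)) return(NA_character_)
  seq <- Biostrings::subseq(dnaset[[replicon_id]], start0 + 1L, end)
  if (strand == "-") seq <- Biostrings::reverseComplement(seq)
  n <- (length(seq) %/% 3L) * 3L
  if (n < 3L) return("")
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::subseq(seq, 1L, n),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE, if.fuzzy.codon = "X")))
  aa <- sub("\\*$", "", aa)       # terminal stop
  gsub("\\*", "X", aa)            # internal stops (disrupted CDS)
}

.read_gff3_genome <- function(path, fasta, strain_id) {
  gff <- tryCatch(rtracklayer::readGFF(path),
                  error = function(e) stop("malformed GFF3 '", path, "': ",
                                           conditionMessage(e)))
  gff <- as.data.frame(gff)
  dnaset <- Biostrings::readDNAStringSet(fasta)
  names(dnaset) <- sub("\\s.*$", "", names(dnaset))
  pseudo_types <- unique(as.character(gff$ID[gff$type %in%
                                               c("pseudogene", "pseudogenic_CDS")]))
  cds_rows <- gff[gff$type %in% c("CDS", "pseudogenic_CDS"), , drop = FALSE]
  skipped <- character(0)
  recs <- list()
  if (nrow(cds_rows)) {
    ids <- as.character(cds_rows$ID)
    ids[is.na(ids) | !nzchar(ids)] <-
      paste0("cds_anon_", seq_len(sum(is.na(ids) | !nzchar(ids))))
    for (id in unique(ids)) {
      rows <- cds_rows[ids == id, , drop = FALSE]
      start0 <- min(rows$start) - 1L          # 1-based inclusive -> 0-based half-open
      end <- max(rows$end)
      strand <- as.character(rows$strand[1])
      if (!strand %in% c("+", "-")) strand <- "+"
      pseudo <- FALSE
      if ("pseudo" %in% names(rows))
        pseudo <- isTRUE(tolower(as.character(rows$pseudo[1])) %in%
                           c("true", "1", "yes"))
      pseudo <- pseudo || id %in% pseudo_types ||
        as.character(rows$type[1]) == "pseudogenic_CDS"
      replicon <- as.character(rows$seqid[1])
      tr <- .translate_cds(dnaset, replicon, start0, end, strand)
      if (is.na(tr)) {
        skipped <- c(skipped, id)
        next
      }
      product <- if ("product" %in% names(rows))
        as.character(rows$product[1]) else NA_character_
      recs[[id]] <- data.frame(
        id = id, replicon_id = replicon, start = start0, end = end,
        strand = strand, translation = if (pseudo && !nzchar(tr)) "" else tr,
        declared_pseudo = pseudo,
        product = product %||% "", stringsAsFactors = FALSE)
    }
  }
  cds <- if (length(recs)) do.call(rbind, recs) else
    data.frame(id = character(0), replicon_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               translation = character(0), declared_pseudo = logical(0),
               product = character(0), stringsAsFactors = FALSE)
  cds$product[is.na(cds$product)] <- ""
  replicons <- data.frame(id = names(dnaset),
                          length = Biostrings::width(dnaset),
                          topology = "linear", kind = "contig",
                          stringsAsFactors = FALSE)
  g <- annotated_genome(strain_id, replicons, cds)
  attr(g, "skipped") <- skipped
  g
}

# --- GenBank flat file (constrained subset: LOCUS / FEATURES / ORIGIN) ----

.parse_gb_location <- function(loc, line_no) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  loc <- gsub("[<>]", "", loc)
  parts <- strsplit(loc, ",")[[1]]
  m <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$", parts))
  if (any(vapply(m, length, integer(1)) != 3L))
    stop("cannot parse GenBank location near line ", line_no, ": ", loc)
  starts <- vapply(m, function(x) as.integer(x[2]), integer(1))
  ends <- vapply(m, function(x) as.integer(x[3]), integer(1))
  list(start = min(starts) - 1L, end = max(ends), strand = strand)
}

.read_genbank_genome <- function(path, strain_id) {
  lines <- readLines(path, warn = FALSE)
  rec_starts <- grep("^LOCUS", lines)
  if (!length(rec_starts)) stop("malformed GenBank file '", path,
                                "': no LOCUS line")
  rec_ends <- c(grep("^//", lines))
  if (length(rec_ends) < length(rec_starts))
    rec_ends <- c(rec_ends, length(lines))
  replicons <- list(); all_cds <- list(); skipped <- character(0)
  cds_n <- 0L
  for (ri in seq_along(rec_starts)) {
    span <- rec_starts[ri]:rec_ends[ri]
    rl <- lines[span]
    locus <- strsplit(trimws(rl[1]), "\\s+")[[1]]
    if (length(locus) < 3L) stop("malformed LOCUS line at line ", rec_starts[ri])
    rep_id <- locus[2]
    rep_len <- suppressWarnings(as.integer(locus[3]))
    if (is.na(rep_len)) stop("malformed LOCUS length at line ", rec_starts[ri])
    topology <- if (any(grepl("circular", rl[1]))) "circular" else "linear"
    kind <- "chromosome"
    feat_at <- grep("^FEATURES", rl)
    orig_at <- grep("^ORIGIN", rl)
    seq_str <- NULL
    if (length(orig_at)) {
      seq_lines <- rl[(orig_at[1] + 1L):length(rl)]
      seq_lines <- seq_lines[!grepl("^//", seq_lines)]
      seq_str <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    }
    if (length(feat_at)) {
      feat_end <- if (length(orig_at)) orig_at[1] - 1L else length(rl)
      fl <- rl[(feat_at[1] + 1L):feat_end]
      key_idx <- grep("^ {5}\\S", fl)
      for (ki in seq_along(key_idx)) {
        i0 <- key_idx[ki]
        i1 <- if (ki < length(key_idx)) key_idx[ki + 1L] - 1L else length(fl)
        block <- fl[i0:i1]
        key <- sub("^\\s+(\\S+).*$", "\\1", block[1])
        body <- trimws(block)
        # location may continue until the first qualifier line
        qual_at <- grep("^/", body)
        loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(body)
        loc_str <- paste(c(sub("^\\S+\\s*", "", body[1]),
                           body[seq_len(loc_end)[-1]]), collapse = "")
        if (key == "source") {
          if (any(grepl("^/plasmid", body))) kind <- "plasmid"
          next
        }
        if (key != "CDS") next
        cds_n <- cds_n + 1L
        loc <- .parse_gb_location(loc_str, rec_starts[ri] + feat_at[1] + i0 - 1L)
        quals <- paste(body[seq(loc_end + 1L, length.out = length(body) - loc_end)],
                       collapse = "\n")
        get_q <- function(name) {
          m <- regmatches(quals, regexec(
            paste0('/', name, '="([^"]*)"'), quals))[[1]]
          if (length(m) == 2L) gsub("\\s", "", m[2]) else NA_character_
        }
        get_q_text <- function(name) {
          m <- regmatches(quals, regexec(
            paste0('/', name, '="([^"]*)"'), quals))[[1]]
          if (length(m) == 2L) gsub("\\n\\s*", " ", m[2]) else NA_character_
        }
        id <- get_q("locus_tag") %||% NA_character_
        if (is.na(id)) id <- sprintf("cds%04d", cds_n)
        pseudo <- grepl("/pseudo(\\s|$|\\n)", paste0(quals, "\n"))
        tr <- get_q("translation")
        if (is.na(tr)) {
          if (!is.null(seq_str)) {
            dnaset <- Biostrings::DNAStringSet(seq_str)
            names(dnaset) <- rep_id
            tr <- .translate_cds(dnaset, rep_id, loc$start, loc$end, loc$strand)
          } else if (pseudo) {
            tr <- ""
          } else {
            skipped <- c(skipped, id)
            next
          }
        }
        all_cds[[length(all_cds) + 1L]] <- data.frame(
          id = id, replicon_id = rep_id, start = loc$start, end = loc$end,
          strand = loc$strand, translation = tr, declared_pseudo = pseudo,
          product = get_q_text("product") %||% "", stringsAsFactors = FALSE)
      }
    }
    replicons[[length(replicons) + 1L]] <- data.frame(
      id = rep_id, length = rep_len, topology = topology, kind = kind,
      stringsAsFactors = FALSE)
  }
  cds <- if (length(all_cds)) do.call(rbind, all_cds) else
    data.frame(id = character(0), replicon_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               translation = character(0), declared_pseudo = logical(0),
               product = character(0), stringsAsFactors = FALSE)
  cds$product[is.na(cds$product)] <- ""
  g <- annotated_genome(strain_id, do.call(rbind, replicons), cds)
  attr(g, "skipped") <- skipped
  g
}

# --- reference panels ------------------------------------------------------

#' Read a reference protein panel
#'
#' The panel is a protein FASTA whose headers are `gene_name|category`
#' (category free text, e.g. `riboflavin` or `flagellum.filament`). The
#' panel supplies both the ortholog length yardstick and the search targets
#' for the screens.
#'
#' @param path Protein FASTA file.
#' @return A `reference_panel` data frame with columns `gene_name`,
#'   `category`, `protein`.
#' @export
read_reference_panel <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("empty panel FASTA: ", path)
  hdr <- strsplit(names(aa), "|", fixed = TRUE)
  gene <- vapply(hdr, `[`, character(1), 1L)
  cat <- vapply(hdr, function(x)
    if (length(x) >= 2L) paste(x[-1], collapse = "|") else "", character(1))
  reference_panel(gene, as.character(aa), cat)
}

#' Construct a reference panel
#'
#' @param gene_name Unique gene names.
#' @param protein Amino-acid sequences (non-empty).
#' @param category Category tags (recycled if scalar).
#' @return A `reference_panel` data frame.
#' @export
reference_panel <- function(gene_name, protein, category = "") {
  if (anyDuplicated(gene_name))
    stop("duplicate gene_name in panel: ",
         paste(unique(gene_name[duplicated(gene_name)]), collapse = ", "))
  if (any(!nzchar(protein))) stop("empty protein sequence in panel")
  df <- data.frame(gene_name = as.character(gene_name),
                   category = rep_len(as.character(category), length(gene_name)),
                   protein = toupper(as.character(protein)),
                   stringsAsFactors = FALSE)
  ok <- vapply(df$protein, .aa_ok, logical(1))
  if (!all(ok))
    stop("panel protein(s) contain non-amino-acid characters: ",
         paste(df$gene_name[!ok], collapse = ", "))
  class(df) <- c("reference_panel", "data.frame")
  df
}

#' Write a reference panel as protein FASTA
#'
#' @param panel A [reference_panel].
#' @param path Output FASTA path.
#' @export
write_reference_panel <- function(panel, path) {
  aa <- Biostrings::AAStringSet(panel$protein)
  names(aa) <- ifelse(nzchar(panel$category),
                      paste(panel$gene_name, panel$category, sep = "|"),
                      panel$gene_name)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# --- status matrices -------------------------------------------------------

#' Write a gene-status matrix as TSV
#'
#' The textual twin of the presence/absence figures: one row per
#' (pathway, step, gene), one column per genome, each cell `INTACT`,
#' `PSEUDOGENE` or `MISSING`. Rows follow the catalog order (pathway, then
#' step index, then gene name); without a catalog, genes are listed
#' alphabetically under pathway `"-"`.
#'
#' @param tables A [status_table] or list of them (one per genome), or a
#'   pre-assembled matrix data frame as returned by
#'   [complementarity_matrix()] or [read_status_matrix()].
#' @param path Output TSV path.
#' @param catalog Optional [pathway_catalog] fixing the row order.
#' @return The written data frame, invisibly.
#' @export
write_status_matrix <- function(tables, path, catalog = NULL) {
  df <- if (is.data.frame(tables) && all(c("pathway", "step", "gene") %in%
                                           names(tables))) {
    tables
  } else {
    status_matrix(tables, catalog)
  }
  if (!nrow(df)) stop("status matrix is empty")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(df)
}

#' Assemble a status matrix data frame from per-genome tables
#'
#' @inheritParams write_status_matrix
#' @return Data frame with columns `pathway`, `step`, `gene` and one status
#'   column per genome.
#' @export
status_matrix <- function(tables, catalog = NULL) {
  if (inherits(tables, "status_table")) tables <- list(tables)
  genomes <- vapply(tables, function(t) attr(t, "genome"), character(1))
  if (anyDuplicated(genomes)) stop("duplicate genome ids in tables")
  if (is.null(catalog)) {
    genes <- sort(unique(unlist(lapply(tables, function(t) t$gene_name))))
    rows <- data.frame(pathway = "-", step = "-", gene = genes,
                       stringsAsFactors = FALSE)
  } else {
    rows <- do.call(rbind, lapply(catalog$pathways, function(p) {
      do.call(rbind, lapply(p$steps, function(s) {
        data.frame(pathway = p$name, step = s$step, gene = sort(s$genes),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    rows[[genomes[i]]] <- t$status[match(rows$gene, t$gene_name)]
    if (anyNA(rows[[genomes[i]]]))
      stop("genome '", genomes[i], "' lacks status for gene(s): ",
           paste(rows$gene[is.na(rows[[genomes[i]]])], collapse = ", "))
  }
  rows
}

#' Read a status matrix TSV
#'
#' @param path TSV written by [write_status_matrix()].
#' @return The matrix data frame.
#' @export
read_status_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- c("pathway", "step", "gene")
  if (!all(need %in% names(df)))
    stop("not a status matrix (missing pathway/step/gene columns): ", path)
  df
}

#' Extract per-genome status tables from a status matrix
#'
#' @param mat Matrix data frame from [read_status_matrix()] or
#'   [status_matrix()].
#' @param genomes Genome columns to extract; default all non-key columns.
#' @return Named list of [status_table] objects.
#' @export
status_tables_from_matrix <- function(mat, genomes = NULL) {
  keys <- c("pathway", "step", "gene")
  genomes <- genomes %||% setdiff(names(mat), keys)
  out <- lapply(genomes, function(g) {
    m <- mat[!duplicated(mat$gene), , drop = FALSE]
    manual_status_table(g, stats::setNames(m[[g]], m$gene))
  })
  stats::setNames(out, genomes)
}
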