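# Seeded generator of reference panels and degraded symbiont genomes with
# known ground truth. It emulates the erosion regime of a recently
# host-restricted symbiont: each panel gene is independently kept intact,
# deleted, truncated below the ortholog length threshold, or fragmented
# into several pieces, with point substitutions layered on top. Emitted
# genomes carry real nucleotide sequence (uniform-codon back-translation,
# bacterial code) so they round-trip through the annotation readers.

#' Generate a random reference panel
#'
#' Protein lengths are uniform over `length_range`; residues are i.i.d.
#' uniform over the 20 amino acids. Reproducible for a fixed seed.
#'
#' @param n_genes Number of panel genes (>= 1).
#' @param length_range Integer interval of protein lengths (aa).
#' @param seed RNG seed.
#' @param category Category tag(s) for the entries (recycled).
#' @param prefix Gene-name prefix.
#' @return A [reference_panel].
#' @export
generate_reference_panel <- function(n_genes, length_range = c(100, 300),
                                     seed = 1, category = "synthetic",
                                     prefix = "sg") {
  stopifnot(n_genes >= 1, length(length_range) == 2,
            length_range[1] >= 10, length_range[2] >= length_range[1])
  with_seed(seed, {
    # draw from the closed interval (sample() on a scalar means 1:x)
    lens <- length_range[1] +
      sample.int(length_range[2] - length_range[1] + 1L, n_genes,
                 replace = TRUE) - 1L
    prots <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
    reference_panel(sprintf("%s%03d", prefix, seq_len(n_genes)), prots,
                    category)
  })
}

#' Degradation regime specification
#'
#' Per-gene fate probabilities for the synthetic erosion process; the
#' residual probability keeps the gene intact. The truncation range must
#' stay below the classification threshold (0.8) by at least
#' `boundary_margin`, so ground-truth labels are unambiguous; set
#' `boundary_stress = TRUE` to instead truncate exactly at 0.8 and probe
#' the strict-inequality contract of the classifier.
#'
#' @param p_delete,p_truncate,p_fragment Fate probabilities (sum <= 1).
#' @param truncate_frac_range Interval of retained-length fractions for
#'   truncated genes, a subset of (0, 0.8 - boundary_margin].
#' @param n_fragments_range Integer interval (>= 2) of fragment counts.
#' @param mutation_rate Per-site amino-acid substitution probability.
#' @param boundary_margin Required gap between the truncation range and
#'   the 0.8 threshold (default 0.05).
#' @param boundary_stress Truncate exactly at 0.8 (overrides the range).
#' @param seed RNG seed.
#' @return A list of class `degradation_spec`.
#' @export
degradation_spec <- function(p_delete = 0.2, p_truncate = 0.3,
                             p_fragment = 0.1,
                             truncate_frac_range = c(0.2, 0.6),
                             n_fragments_range = c(2L, 4L),
                             mutation_rate = 0.05,
                             boundary_margin = 0.05,
                             boundary_stress = FALSE, seed = 1) {
  probs <- c(p_delete, p_truncate, p_fragment)
  if (any(probs < 0) || any(probs > 1) || sum(probs) > 1)
    stop("fate probabilities must lie in [0,1] and sum to at most 1")
  if (!boundary_stress) {
    if (truncate_frac_range[1] <= 0 ||
        truncate_frac_range[2] > 0.8 - boundary_margin)
      stop("truncate_frac_range must be within (0, ", 0.8 - boundary_margin,
           "] (0.8 threshold minus boundary_margin)")
  }
  if (n_fragments_range[1] < 2L)
    stop("fragment counts must be >= 2")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0,1]")
  structure(list(p_delete = p_delete, p_truncate = p_truncate,
                 p_fragment = p_fragment,
                 truncate_frac_range = truncate_frac_range,
                 n_fragments_range = as.integer(n_fragments_range),
                 mutation_rate = mutation_rate,
                 boundary_margin = boundary_margin,
                 boundary_stress = boundary_stress, seed = seed),
            class = "degradation_spec")
}

.mutate_protein <- function(p, rate) {
  if (rate <= 0) return(p)
  chars <- strsplit(p, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(AA20, a), 1L), character(1))
  }
  paste(chars, collapse = "")
}

# inverse genetic code (table 11), stop codons excluded
.codon_choices <- function() {
  gc <- Biostrings::getGeneticCode("11")
  gc <- gc[gc != "*"]
  split(names(gc), gc)
}

.back_translate <- function(protein, choices) {
  aas <- strsplit(protein, "")[[1]]
  codons <- vapply(aas, function(a) {
    cs <- choices[[a]]
    if (is.null(cs)) stop("cannot back-translate residue: ", a)
    cs[sample.int(length(cs), 1L)]
  }, character(1))
  paste(c(codons, "TAA"), collapse = "")
}

# lay out protein records on a single chromosome with random spacers and
# strands; returns the annotated genome plus its DNA
.emit_genome <- function(strain_id, records, spacer = 20L) {
  choices <- .codon_choices()
  chrom_id <- paste0(strain_id, "_chr")
  parts <- character(0)
  cursor <- 0L
  cds_rows <- list()
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  for (i in seq_len(nrow(records))) {
    sp <- rand_dna(spacer)
    dna <- .back_translate(records$protein[i], choices)
    strand <- sample(c("+", "-"), 1L)
    genomic <- if (strand == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
    else dna
    start0 <- cursor + spacer
    end <- start0 + nchar(dna)
    parts <- c(parts, sp, genomic)
    cursor <- end
    cds_rows[[i]] <- data.frame(
      id = records$id[i], replicon_id = chrom_id, start = start0, end = end,
      strand = strand, translation = records$protein[i],
      declared_pseudo = records$pseudo[i],
      product = "hypothetical protein", stringsAsFactors = FALSE)
  }
  parts <- c(parts, rand_dna(spacer))
  seq <- paste(parts, collapse = "")
  cds <- if (length(cds_rows)) do.call(rbind, cds_rows) else
    data.frame(id = character(0), replicon_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               translation = character(0), declared_pseudo = logical(0),
               product = character(0), stringsAsFactors = FALSE)
  replicons <- data.frame(id = chrom_id, length = nchar(seq),
                          topology = "linear", kind = "contig",
                          stringsAsFactors = FALSE)
  list(genome = annotated_genome(strain_id, replicons, cds),
       dna = stats::setNames(seq, chrom_id))
}

.fragment_intervals <- function(len, k, min_piece) {
  span_frac <- runif(1, 0.65, 0.95)
  span <- max(k * min_piece, floor(span_frac * len))
  span <- min(span, len)
  k <- max(2L, min(k, span %/% min_piece))
  start <- sample.int(len - span + 1L, 1L) - 1L
  sizes <- rep(span %/% k, k)
  extra <- span - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- start + cumsum(sizes)
  starts <- c(start, ends[-k])
  cbind(start = starts, end = ends)   # 0-based half-open on the protein
}

#' Degrade a panel into a synthetic symbiont genome with known truth
#'
#' Each panel gene independently receives a fate drawn from the
#' specification: kept intact (one full-length CDS), truncated (one CDS
#' retaining an N-terminal fraction below the pseudogene threshold),
#' fragmented (k CDSs partitioning a contiguous subset of the protein),
#' or deleted (no CDS). Point substitutions are applied to every emitted
#' translation at `mutation_rate`. Output files parse back through
#' [read_genome_annotation()].
#'
#' @param panel A [reference_panel].
#' @param spec A [degradation_spec()].
#' @param strain_id Strain name for the emitted genome.
#' @param dir Optional output directory; when given, the genome is
#'   written in `format` together with a `*_truth.tsv`.
#' @param format `"gff3"` (GFF3 + FASTA) or `"genbank"`.
#' @return `list(genome =, truth =, paths =)`; `truth` is a
#'   `ground_truth` data frame with per-gene fate and realized
#'   parameters.
#' @export
degrade_genome <- function(panel, spec = degradation_spec(),
                           strain_id = "synthetic_strain", dir = NULL,
                           format = c("gff3", "genbank")) {
  format <- match.arg(format)
  with_seed(spec$seed, {
    n <- nrow(panel)
    fates <- sample(c("DELETED", "TRUNCATED", "FRAGMENTED", "INTACT"), n,
                    replace = TRUE,
                    prob = c(spec$p_delete, spec$p_truncate, spec$p_fragment,
                             1 - spec$p_delete - spec$p_truncate -
                               spec$p_fragment))
    recs <- list()
    truth <- data.frame(gene_name = panel$gene_name, fate = fates,
                        trunc_frac = NA_real_, n_fragments = NA_integer_,
                        stringsAsFactors = FALSE)
    cds_n <- 0L
    for (i in seq_len(n)) {
      prot <- panel$protein[i]
      len <- nchar(prot)
      emit <- function(p) {
        cds_n <<- cds_n + 1L
        recs[[length(recs) + 1L]] <<- data.frame(
          id = sprintf("cds%04d", cds_n),
          protein = .mutate_protein(p, spec$mutation_rate),
          pseudo = FALSE, stringsAsFactors = FALSE)
      }
      switch(fates[i],
        INTACT = emit(prot),
        DELETED = NULL,
        TRUNCATED = {
          frac <- if (spec$boundary_stress) 0.8 else
            runif(1, spec$truncate_frac_range[1], spec$truncate_frac_range[2])
          keep <- max(10L, if (spec$boundary_stress)
            as.integer(round(frac * len)) else as.integer(floor(frac * len)))
          keep <- min(keep, len)
          truth$trunc_frac[i] <- keep / len
          emit(substr(prot, 1L, keep))
        },
        FRAGMENTED = {
          k <- spec$n_fragments_range[1] +
            sample.int(spec$n_fragments_range[2] -
                         spec$n_fragments_range[1] + 1L, 1L) - 1L
          min_piece <- max(12L, as.integer(ceiling(0.11 * len)))
          iv <- .fragment_intervals(len, k, min_piece)
          truth$n_fragments[i] <- nrow(iv)
          for (j in seq_len(nrow(iv)))
            emit(substr(prot, iv[j, "start"] + 1L, iv[j, "end"]))
        })
    }
    records <- if (length(recs)) do.call(rbind, recs) else
      data.frame(id = character(0), protein = character(0),
                 pseudo = logical(0), stringsAsFactors = FALSE)
    em <- .emit_genome(strain_id, records)
    class(truth) <- c("ground_truth", "data.frame")
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- write_synthetic_genome(em$genome, em$dna, dir, format)
      truth_path <- file.path(dir, paste0(strain_id, "_truth.tsv"))
      write.table(truth, truth_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      paths$truth <- truth_path
    }
    list(genome = em$genome, truth = truth, paths = paths)
  })
}

#' Write a synthetic genome to disk
#'
#' @param genome An [annotated_genome] produced by the generator.
#' @param dna Named character vector of replicon sequences.
#' @param dir Output directory.
#' @param format `"gff3"` (GFF3 + FASTA) or `"genbank"`.
#' @return Named list of written paths.
#' @export
write_synthetic_genome <- function(genome, dna, dir,
                                   format = c("gff3", "genbank")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "gff3") {
    gff <- file.path(dir, paste0(genome$strain_id, ".gff3"))
    fa <- file.path(dir, paste0(genome$strain_id, ".fna"))
    .write_gff3(genome, gff)
    set <- Biostrings::DNAStringSet(unname(dna))
    names(set) <- names(dna)
    Biostrings::writeXStringSet(set, fa)
    list(annotation = gff, fasta = fa)
  } else {
    gb <- file.path(dir, paste0(genome$strain_id, ".gbk"))
    .write_genbank(genome, dna, gb)
    list(annotation = gb)
  }
}

.write_gff3 <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genome$replicons)))
    writeLines(sprintf("##sequence-region %s 1 %d",
                       genome$replicons$id[i], genome$replicons$length[i]),
               con)
  for (i in seq_len(nrow(genome$cds))) {
    r <- genome$cds[i, ]
    attrs <- sprintf("ID=%s;product=%s", r$id, r$product)
    if (r$declared_pseudo) attrs <- paste0(attrs, ";pseudo=true")
    writeLines(paste(r$replicon_id, "symcomp", "CDS", r$start + 1L, r$end,
                     ".", r$strand, "0", attrs, sep = "\t"), con)
  }
  invisible(path)
}

.write_genbank <- function(genome, dna, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wrap_qual <- function(text, width = 58) {
    out <- character(0)
    while (nchar(text) > width) {
      out <- c(out, substr(text, 1, width))
      text <- substr(text, width + 1, nchar(text))
    }
    c(out, text)
  }
  for (ri in seq_len(nrow(genome$replicons))) {
    rep <- genome$replicons[ri, ]
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s   BCT 01-JAN-2026",
                       rep$id, rep$length,
                       if (rep$topology == "circular") "circular" else "linear"),
               con)
    writeLines(sprintf("DEFINITION  Synthetic degraded symbiont genome %s.",
                       rep$id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", rep$length), con)
    writeLines("                     /organism=\"synthetic construct\"", con)
    if (rep$kind == "plasmid")
      writeLines(sprintf("                     /plasmid=\"%s\"", rep$id), con)
    cds <- genome$cds[genome$cds$replicon_id == rep$id, , drop = FALSE]
    for (i in seq_len(nrow(cds))) {
      r <- cds[i, ]
      loc <- sprintf("%d..%d", r$start + 1L, r$end)
      if (r$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", r$id), con)
      writeLines(sprintf("                     /product=\"%s\"", r$product),
                 con)
      if (r$declared_pseudo)
        writeLines("                     /pseudo", con)
      if (nzchar(r$translation)) {
        tr <- wrap_qual(paste0("/translation=\"", r$translation, "\""))
        writeLines(paste0("                     ", tr), con)
      }
    }
    writeLines("ORIGIN", con)
    seq <- tolower(dna[[rep$id]])
    pos <- seq(1L, nchar(seq), by = 60L)
    for (p in pos) {
      chunk <- substr(seq, p, min(p + 59L, nchar(seq)))
      groups <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(groups, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Engineer a two-member consortium with known complementarity
#'
#' Builds two synthetic genomes from a panel and a pathway catalog such
#' that every scheduled pathway step is intact in exactly the assigned
#' member: the provider receives an intact copy of the step's first
#' alternative gene, the other member a deleted or truncated
#' (pseudogenized) copy. Pathways are then complete in the union but, for
#' scenarios that alternate providers, in neither member alone.
#'
#' @param panel A [reference_panel] containing the step genes.
#' @param catalog A [pathway_catalog].
#' @param scenario Named character vector `"pathway::step" -> member`,
#'   with members drawn from `members`.
#' @param members Length-2 character vector of genome ids.
#' @param mutation_rate Substitution rate applied to emitted proteins.
#' @param seed RNG seed.
#' @return `list(genomes = named list of two [annotated_genome]s,
#'   truth = data.frame(pathway, step, gene, provider, other_fate))`.
#' @export
simulate_consortium <- function(panel, catalog, scenario,
                                members = c("A", "B"), mutation_rate = 0.02,
                                seed = 1) {
  if (!length(scenario)) stop("scenario covers no steps")
  stopifnot(length(members) == 2L)
  if (!all(scenario %in% members))
    stop("scenario providers must be one of: ", paste(members, collapse = ", "))
  with_seed(seed, {
    recs <- stats::setNames(list(list(), list()), members)
    cds_n <- stats::setNames(c(0L, 0L), members)
    truth <- list()
    for (key in names(scenario)) {
      kv <- strsplit(key, "::", fixed = TRUE)[[1]]
      if (length(kv) != 2L)
        stop("scenario keys must be 'pathway::step': ", key)
      pw <- .get_pathway(catalog, kv[1])
      st <- NULL
      for (s in pw$steps) if (identical(s$step, kv[2])) st <- s
      if (is.null(st)) stop("no step '", kv[2], "' in pathway '", kv[1], "'")
      gene <- sort(st$genes)[1]
      i <- match(gene, panel$gene_name)
      if (is.na(i)) stop("panel lacks step gene: ", gene)
      prot <- panel$protein[i]
      provider <- scenario[[key]]
      other <- setdiff(members, provider)
      other_fate <- sample(c("DELETED", "TRUNCATED"), 1L)
      for (m in members) {
        p <- if (m == provider) prot else if (other_fate == "TRUNCATED")
          substr(prot, 1L, max(10L, floor(0.4 * nchar(prot)))) else NULL
        if (!is.null(p)) {
          cds_n[m] <- cds_n[m] + 1L
          recs[[m]][[length(recs[[m]]) + 1L]] <- data.frame(
            id = sprintf("%s_cds%03d", m, cds_n[m]),
            protein = .mutate_protein(p, mutation_rate), pseudo = FALSE,
            stringsAsFactors = FALSE)
        }
      }
      truth[[length(truth) + 1L]] <- data.frame(
        pathway = kv[1], step = kv[2], gene = gene, provider = provider,
        other_fate = other_fate, stringsAsFactors = FALSE)
    }
    genomes <- lapply(members, function(m) {
      df <- if (length(recs[[m]])) do.call(rbind, recs[[m]]) else
        data.frame(id = character(0), protein = character(0),
                   pseudo = logical(0), stringsAsFactors = FALSE)
      .emit_genome(m, df)$genome
    })
    names(genomes) <- members
    list(genomes = genomes, truth = do.call(rbind, truth))
  })
}

#' Compare a predicted status table with the generator's ground truth
#'
#' Fates map to expected statuses (DELETED to MISSING, TRUNCATED and
#' FRAGMENTED to PSEUDOGENE, INTACT to INTACT); the report is the 3x3
#' confusion matrix and the per-gene agreement fraction.
#'
#' @param predicted A [status_table].
#' @param truth A `ground_truth` data frame from [degrade_genome()].
#' @return A `recovery_report`: `confusion` (truth rows, prediction
#'   columns), `agreement`, `n`.
#' @export
recovery_report <- function(predicted, truth) {
  if (!setequal(predicted$gene_name, truth$gene_name))
    stop("predicted table and truth cover different gene sets")
  map <- c(DELETED = "MISSING", TRUNCATED = "PSEUDOGENE",
           FRAGMENTED = "PSEUDOGENE", INTACT = "INTACT")
  expected <- unname(map[truth$fate])
  got <- predicted$status[match(truth$gene_name, predicted$gene_name)]
  lev <- c("INTACT", "PSEUDOGENE", "MISSING")
  confusion <- table(truth = factor(expected, lev),
                     predicted = factor(got, lev))
  structure(list(confusion = confusion,
                 agreement = mean(expected == got),
                 n = length(expected)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> agreement %.4f over %d genes\n",
              x$agreement, x$n))
  print(x$confusion)
  invisible(x)
}
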