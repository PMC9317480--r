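# Independent oracles and small in-code fixture builders.

# quadratic Gotoh local-alignment oracle with affine gaps
# (gap of length L costs open + L * ext, matching the package convention);
# returns score, identity over alignment columns, and the 0-based
# half-open interval covered on b.
sw_oracle <- function(a, b, open = 11, ext = 1) {
  submat <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)   # gap consuming b (horizontal)
  F <- matrix(NEG, n + 1, m + 1)   # gap consuming a (vertical)
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - (open + ext), E[i + 1, j] - ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] - (open + ext), F[i, j + 1] - ext)
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + submat[av[i], bv[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  best <- which(H == max(H), arr.ind = TRUE)[1, ]
  i <- unname(best[1]) - 1L; j <- unname(best[2]) - 1L
  score <- max(H)
  # traceback
  state <- "H"; cols <- 0L; idn <- 0L
  i0 <- i; j0 <- j
  while (TRUE) {
    if (state == "H") {
      if (H[i0 + 1, j0 + 1] == 0) break
      if (i0 > 0 && j0 > 0 &&
          H[i0 + 1, j0 + 1] == H[i0, j0] + submat[av[i0], bv[j0]]) {
        cols <- cols + 1L
        if (av[i0] == bv[j0]) idn <- idn + 1L
        i0 <- i0 - 1L; j0 <- j0 - 1L
      } else if (H[i0 + 1, j0 + 1] == E[i0 + 1, j0 + 1]) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      cols <- cols + 1L
      if (E[i0 + 1, j0 + 1] == H[i0 + 1, j0] - (open + ext)) {
        j0 <- j0 - 1L; state <- "H"
      } else {
        j0 <- j0 - 1L
      }
    } else {
      cols <- cols + 1L
      if (F[i0 + 1, j0 + 1] == H[i0, j0 + 1] - (open + ext)) {
        i0 <- i0 - 1L; state <- "H"
      } else {
        i0 <- i0 - 1L
      }
    }
  }
  list(score = score,
       identity = if (cols > 0) idn / cols else 0,
       ref_interval = c(j0, j),
       ref_coverage = (j - j0) / m)
}

# brute-force boolean pathway evaluation: complete iff every step has some
# alternative INTACT in some table
bool_pathway_oracle <- function(pathway, tables) {
  if (inherits(tables, "status_table")) tables <- list(tables)
  all(vapply(pathway$steps, function(s) {
    any(vapply(tables, function(t) {
      any(t$status[match(s$genes, t$gene_name)] == "INTACT")
    }, logical(1)))
  }, logical(1)))
}

# positionwise interval-union oracle on 0-based half-open intervals
union_coverage_oracle <- function(starts, ends, len) {
  covered <- logical(len)
  for (k in seq_along(starts)) covered[(starts[k] + 1):ends[k]] <- TRUE
  mean(covered)
}

random_protein <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               len, replace = TRUE), collapse = "")
}

# mutate a protein at a fixed per-site substitution rate
mutate_protein <- function(p, rate) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  chars <- strsplit(p, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(aa, chars[i]), 1)
  paste(chars, collapse = "")
}

# tiny hand-written GFF3 + FASTA fixture on disk; returns the two paths
write_tiny_gff3 <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "tiny.fna")
  gff <- file.path(dir, "tiny.gff3")
  set.seed(99)
  seqchars <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  # CDS 1..300 on + strand: make it a clean ORF so translation is defined
  writeLines(c(">chrA", paste(seqchars, collapse = "")), fa)
  writeLines(c("##gff-version 3",
               "##sequence-region chrA 1 400",
               paste("chrA", "test", "CDS", "1", "300", ".", "+", "0",
                     "ID=cdsA;product=demo", sep = "\t"),
               paste("chrA", "test", "CDS", "310", "390", ".", "-", "0",
                     "ID=cdsB;product=demo2;pseudo=true", sep = "\t")),
             gff)
  list(gff = gff, fasta = fa)
}

# tiny hand-written GenBank record with 10 CDSs, 2 declared /pseudo
write_tiny_genbank <- function(path = tempfile(fileext = ".gbk")) {
  panel <- generate_reference_panel(10, c(30, 40), seed = 5)
  spec <- degradation_spec(p_delete = 0, p_truncate = 0, p_fragment = 0,
                           mutation_rate = 0, seed = 5)
  sim <- degrade_genome(panel, spec, strain_id = "tinygb")
  g <- sim$genome
  g$cds$declared_pseudo[1:2] <- TRUE
  # regenerate the DNA alongside the flags by writing through the emitter
  dirp <- tempfile(); dir.create(dirp)
  res <- degrade_genome(panel, spec, strain_id = "tinygb", dir = dirp,
                        format = "genbank")
  lines <- readLines(res$paths$annotation)
  # inject /pseudo into the first two CDS feature blocks
  cds_at <- grep("^     CDS ", lines)
  for (k in rev(cds_at[1:2]))
    lines <- append(lines, "                     /pseudo", after = k)
  writeLines(lines, path)
  path
}
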