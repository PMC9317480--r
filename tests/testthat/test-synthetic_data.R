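test_that("panel generation is reproducible and respects length bounds", {
  p1 <- generate_reference_panel(10, c(100, 400), seed = 1)
  p2 <- generate_reference_panel(10, c(100, 400), seed = 1)
  expect_identical(p1, p2)
  p3 <- generate_reference_panel(100, c(100, 400), seed = 2)
  lens <- nchar(p3$protein)
  expect_true(all(lens >= 100 & lens <= 400))
  expect_false(identical(p1$protein,
                         generate_reference_panel(10, c(100, 400),
                                                  seed = 3)$protein))
})

test_that("panel residue frequencies are uniform within 3 sigma", {
  p <- generate_reference_panel(500, c(190, 210), seed = 4)
  residues <- strsplit(paste(p$protein, collapse = ""), "")[[1]]
  n <- length(residues)
  expect_gte(n, 1e5)
  counts <- table(factor(residues, levels = c("A","C","D","E","F","G","H",
                                              "I","K","L","M","N","P","Q",
                                              "R","S","T","V","W","Y")))
  expected <- n / 20
  sigma <- sqrt(n * (1 / 20) * (19 / 20))
  expect_true(all(abs(counts - expected) <= 3 * sigma))
})

test_that("degradation output is byte-identical for a fixed seed and spec", {
  panel <- generate_reference_panel(12, c(80, 140), seed = 5)
  spec <- degradation_spec(seed = 5)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- degrade_genome(panel, spec, strain_id = "det", dir = d1)
  s2 <- degrade_genome(panel, spec, strain_id = "det", dir = d2)
  expect_identical(s1$truth, s2$truth)
  expect_identical(readLines(s1$paths$annotation),
                   readLines(s2$paths$annotation))
  expect_identical(readLines(s1$paths$fasta), readLines(s2$paths$fasta))
})

test_that("fate frequencies converge to the spec probabilities", {
  panel <- generate_reference_panel(10000, c(50, 60), seed = 6)
  spec <- degradation_spec(p_delete = 0.2, p_truncate = 0.3,
                           p_fragment = 0.1, mutation_rate = 0, seed = 6)
  sim <- degrade_genome(panel, spec)
  n <- nrow(panel)
  probs <- c(DELETED = 0.2, TRUNCATED = 0.3, FRAGMENTED = 0.1, INTACT = 0.4)
  for (f in names(probs)) {
    got <- sum(sim$truth$fate == f)
    sigma <- sqrt(n * probs[f] * (1 - probs[f]))
    expect_lte(abs(got - n * probs[f]), 3 * sigma)
  }
  # fates consistent with emitted content
  expect_true(all(is.na(sim$truth$trunc_frac[sim$truth$fate != "TRUNCATED"])))
  expect_true(all(sim$truth$trunc_frac[sim$truth$fate == "TRUNCATED"] < 0.8,
                  na.rm = TRUE))
  expect_true(all(sim$truth$n_fragments[sim$truth$fate == "FRAGMENTED"] >= 2,
                  na.rm = TRUE))
})

test_that("degradation spec validates its probability vector and ranges", {
  expect_error(degradation_spec(p_delete = 0.7, p_truncate = 0.5),
               "sum to at most 1")
  expect_error(degradation_spec(truncate_frac_range = c(0.2, 0.79)),
               "boundary_margin")
  expect_error(degradation_spec(n_fragments_range = c(1, 3)), ">= 2")
  expect_no_error(degradation_spec(truncate_frac_range = c(0.2, 0.75)))
})

test_that("boundary-stress truncation pins the strict-inequality contract", {
  panel <- generate_reference_panel(10, c(100, 100), seed = 12)
  spec <- degradation_spec(p_delete = 0, p_truncate = 1, p_fragment = 0,
                           mutation_rate = 0, boundary_stress = TRUE,
                           seed = 12)
  sim <- degrade_genome(panel, spec)
  tab <- classify_genome(sim$genome, panel)
  # retained length is exactly 80% of a 100-aa reference: not a pseudogene
  expect_true(all(tab$length_ratio == 0.8))
  expect_true(all(tab$status == "INTACT"))
})

test_that("engineered consortia are complete only in union", {
  panel <- generate_reference_panel(30, c(90, 150), seed = 13)
  # rename panel genes to match a small two-step catalog
  cat <- pathway_catalog(list(list(name = "pw", steps = list(
    list(step = "s1", genes = panel$gene_name[1]),
    list(step = "s2", genes = panel$gene_name[2]),
    list(step = "s3", genes = panel$gene_name[3]),
    list(step = "s4", genes = panel$gene_name[4])))))
  scenario <- c("pw::s1" = "A", "pw::s2" = "B", "pw::s3" = "A",
                "pw::s4" = "B")
  sim <- simulate_consortium(panel, cat, scenario, seed = 13)
  tabs <- lapply(sim$genomes, classify_genome, panel = panel)
  pw <- cat$pathways[[1]]
  expect_false(pathway_completeness(pw, tabs$A)$complete)
  expect_false(pathway_completeness(pw, tabs$B)$complete)
  v <- consortium_completeness(pw, tabs)
  expect_true(v$complete)
  expect_equal(v$unique_providers[names(scenario) |>
                                    sub(pattern = "pw::", replacement = "")],
               scenario |> stats::setNames(sub("pw::", "", names(scenario))))
  # one-sided scenario: provider A alone completes the pathway
  one <- stats::setNames(rep("A", 4), names(scenario))
  sim2 <- simulate_consortium(panel, cat, one, seed = 14)
  tabs2 <- lapply(sim2$genomes, classify_genome, panel = panel)
  expect_true(pathway_completeness(pw, tabs2$A)$complete)
  expect_true(consortium_completeness(pw, tabs2)$complete)
  expect_error(simulate_consortium(panel, cat, character(0)), "no steps")
})

test_that("recovery report counts confusion and agreement correctly", {
  truth <- data.frame(gene_name = paste0("g", 1:10),
                      fate = c(rep("INTACT", 4), rep("TRUNCATED", 3),
                               rep("DELETED", 3)))
  perfect <- manual_status_table("g", stats::setNames(
    c(rep("INTACT", 4), rep("PSEUDOGENE", 3), rep("MISSING", 3)),
    truth$gene_name))
  r <- recovery_report(perfect, truth)
  expect_equal(r$agreement, 1)
  expect_equal(unname(diag(r$confusion)), c(4, 3, 3))
  # two planted mismatches -> agreement 0.8
  flipped <- perfect
  flipped$status[flipped$gene_name == "g1"] <- "MISSING"
  flipped$status[flipped$gene_name == "g5"] <- "INTACT"
  r2 <- recovery_report(flipped, truth)
  expect_equal(r2$agreement, 0.8)
  expect_error(recovery_report(perfect[-1, ], truth), "different gene sets")
})
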