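rib_step <- list(step = "phosphatase", genes = c("yigB", "ybjI", "yigL"))

test_that("step status applies alternative-gene logic with Ψ dominance", {
  # reported SsSm configuration: both named genes absent, alternative split
  ssm <- manual_status_table("SsSm", c(yigB = "MISSING", ybjI = "MISSING",
                                       yigL = "PSEUDOGENE"))
  s <- step_status(rib_step, ssm)
  expect_equal(s$value, "PSEUDOGENIZED")
  expect_length(s$providers, 0)
  # reported SsPl configuration: the alternative is intact
  spl <- manual_status_table("SsPl", c(yigB = "MISSING", ybjI = "MISSING",
                                       yigL = "INTACT"))
  s2 <- step_status(rib_step, spl)
  expect_equal(s2$value, "SATISFIED")
  expect_equal(s2$providers, "SsPl")
  # everything missing everywhere
  non <- manual_status_table("g", c(yigB = "MISSING", ybjI = "MISSING",
                                    yigL = "MISSING"))
  expect_equal(step_status(rib_step, non)$value, "MISSING")
  # a table that does not cover an alternative is a config error
  expect_error(step_status(rib_step,
                           manual_status_table("g", c(yigB = "MISSING"))),
               "does not cover")
})

test_that("per-genome pathway completeness matches the transcribed vitamin fixtures", {
  tabs <- status_tables_from_matrix(transcribed_vitamin_matrix())
  cat <- default_pathway_catalog()
  rib <- pathway_completeness("riboflavin", tabs$BaSm, cat)
  expect_false(rib$complete)
  expect_true(all(rib$steps == "MISSING"))
  ribp <- pathway_completeness("riboflavin", tabs$SsPl, cat)
  expect_true(ribp$complete)
  ribs <- pathway_completeness("riboflavin", tabs$SsSm, cat)
  expect_false(ribs$complete)
  expect_equal(unname(ribs$steps["phosphatase"]), "PSEUDOGENIZED")
})

test_that("consortium completeness attributes unique providers", {
  tabs <- status_tables_from_matrix(transcribed_vitamin_matrix())
  cat <- default_pathway_catalog()
  # biotin completed jointly, the downstream steps uniquely by SsSm
  v_sm <- consortium_completeness("biotin", tabs[c("BaSm", "SsSm")], cat)
  expect_true(v_sm$complete)
  expect_equal(unname(v_sm$unique_providers[c("bioA", "bioD", "bioB")]),
               rep("SsSm", 3))
  # the second consortium fails on the pseudogenized transaminase/synthetase
  v_pl <- consortium_completeness("biotin", tabs[c("BaPl", "SsPl")], cat)
  expect_false(v_pl$complete)
  expect_equal(v_pl$per_step$bioA$value, "PSEUDOGENIZED")
  expect_equal(v_pl$per_step$bioD$value, "PSEUDOGENIZED")
})

random_tables <- function(genes, genomes, p_intact = 0.3) {
  lapply(genomes, function(g) {
    st <- sample(c("INTACT", "PSEUDOGENE", "MISSING"), length(genes),
                 replace = TRUE, prob = c(p_intact, 0.3, 1 - p_intact - 0.3))
    manual_status_table(g, stats::setNames(st, genes))
  })
}

random_pathway <- function(genes, n_steps, max_alts) {
  steps <- lapply(seq_len(n_steps), function(i) {
    list(step = paste0("s", i),
         genes = sample(genes, sample(1:max_alts, 1)))
  })
  list(name = "rand", steps = steps)
}

test_that("verdicts equal exhaustive boolean evaluation on random instances", {
  set.seed(123)
  genes <- paste0("g", 1:12)
  for (rep in 1:60) {
    n_genomes <- sample(1:4, 1)
    pw <- random_pathway(genes, sample(1:10, 1), 3)
    tabs <- random_tables(genes, paste0("G", seq_len(n_genomes)))
    v <- consortium_completeness(pw, tabs)
    expect_equal(v$complete, bool_pathway_oracle(pw, tabs))
    for (t in tabs)
      expect_equal(pathway_completeness(pw, t)$complete,
                   bool_pathway_oracle(pw, t))
  }
})

test_that("union monotonicity: a pathway complete in one member stays complete", {
  set.seed(321)
  genes <- paste0("g", 1:8)
  for (rep in 1:25) {
    pw <- random_pathway(genes, sample(2:6, 1), 3)
    tabs <- random_tables(genes, c("G1", "G2", "G3"), p_intact = 0.5)
    sat1 <- vapply(seq_along(pw$steps), function(i)
      step_status(pw$steps[[i]], tabs[1])$value == "SATISFIED", logical(1))
    satU <- vapply(seq_along(pw$steps), function(i)
      step_status(pw$steps[[i]], tabs)$value == "SATISFIED", logical(1))
    expect_true(all(satU[sat1]))  # union satisfied set is a superset
    if (pathway_completeness(pw, tabs[[1]])$complete)
      expect_true(consortium_completeness(pw, tabs)$complete)
  }
})

test_that("duplicating a member table changes no verdict", {
  tabs <- status_tables_from_matrix(transcribed_vitamin_matrix())
  cat <- default_pathway_catalog()
  v1 <- consortium_completeness("riboflavin", tabs[c("BaSm", "SsSm")], cat)
  v2 <- consortium_completeness("riboflavin",
                                c(tabs[c("BaSm", "SsSm")], tabs["SsSm"]),
                                cat)
  expect_equal(v1$complete, v2$complete)
  expect_equal(vapply(v1$per_step, `[[`, character(1), "value"),
               vapply(v2$per_step, `[[`, character(1), "value"))
})

test_that("the complementarity matrix is deterministic and round-trips", {
  tabs <- status_tables_from_matrix(transcribed_vitamin_matrix())
  cat <- catalog_subset(default_pathway_catalog(), c("riboflavin", "biotin"))
  m1 <- complementarity_matrix(cat, tabs)
  m2 <- complementarity_matrix(cat, tabs)
  expect_equal(m1, m2)
  path <- tempfile(fileext = ".tsv")
  write_status_matrix(m1, path)
  expect_equal(read_status_matrix(path), m1)
  # row order: catalog pathway order, then step, then gene
  expect_equal(m1$pathway[1], "riboflavin")
  ph <- m1[m1$step == "phosphatase", "gene"]
  expect_equal(ph, sort(ph))
})
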