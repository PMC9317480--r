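make_vf_panel <- function() {
  generate_reference_panel(8, c(120, 200), seed = 55, category = "vf",
                           prefix = "vf")
}

test_that("virulence screen separates present, pseudogenized and absent genes", {
  panel <- make_vf_panel()
  # genome carries: exact copy of vf001, vf002 truncated to 50%, vf003 absent
  half <- substr(panel$protein[2], 1, floor(0.5 * nchar(panel$protein[2])))
  recs <- data.frame(id = c("c1", "c2"),
                     protein = c(panel$protein[1], half),
                     pseudo = FALSE)
  g <- symcomp:::.emit_genome("vtest", recs)$genome
  vmap <- screen_virulence(g, panel)
  expect_equal(vmap$status[vmap$gene_name == "vf001"], "PRESENT")
  expect_equal(vmap$status[vmap$gene_name == "vf002"], "PSEUDOGENE")
  expect_equal(vmap$status[vmap$gene_name == "vf003"], "ABSENT")
  expect_true(all(vmap$status[4:8] == "ABSENT"))
})

test_that("raising thresholds never converts ABSENT to PRESENT", {
  panel <- make_vf_panel()
  sim <- degrade_genome(panel, degradation_spec(seed = 6), strain_id = "v2")
  v_low <- screen_virulence(sim$genome, panel, min_identity = 0.4,
                            min_ref_coverage = 0.5)
  v_high <- screen_virulence(sim$genome, panel, min_identity = 0.7,
                             min_ref_coverage = 0.9)
  absent_low <- v_low$gene_name[v_low$status == "ABSENT"]
  expect_true(all(v_high$status[v_high$gene_name %in% absent_low] != "PRESENT"))
  # and PRESENT can only shrink
  present_high <- v_high$gene_name[v_high$status == "PRESENT"]
  expect_true(all(present_high %in%
                    v_low$gene_name[v_low$status == "PRESENT"]))
})

test_that("screen rejects out-of-range thresholds", {
  panel <- make_vf_panel()
  sim <- degrade_genome(panel[1, ], degradation_spec(seed = 1))
  expect_error(screen_virulence(sim$genome, panel, min_identity = 0),
               "thresholds")
  expect_error(screen_virulence(sim$genome, panel, min_ref_coverage = 1.5),
               "thresholds")
})

test_that("flagellum classes reproduce the reported strain contrast", {
  vm <- transcribed_virulome_maps()
  expect_equal(flagellum_assessment(vm$SsPl)$value, "COMPLETE")
  v <- flagellum_assessment(vm$SsSm)
  expect_equal(v$value, "BASAL_BODY_ONLY")
  expect_gte(v$intact_by_part$basal_body["present"], 1)
  expect_equal(unname(v$intact_by_part$hook["present"]), 0)
  expect_equal(unname(v$intact_by_part$filament["present"]), 0)
})

test_that("flagellum edge classes and config errors", {
  genes <- c(flgB = "basal_body", flgE = "hook", fliC = "filament")
  all_absent <- manual_virulence_map("g", c(flgB = "ABSENT", flgE = "ABSENT",
                                            fliC = "ABSENT"))
  expect_equal(flagellum_assessment(all_absent, genes)$value, "ABSENT")
  all_present <- manual_virulence_map("g", c(flgB = "PRESENT",
                                             flgE = "PRESENT",
                                             fliC = "PRESENT"))
  expect_equal(flagellum_assessment(all_present, genes)$value, "COMPLETE")
  mixed <- manual_virulence_map("g", c(flgB = "PRESENT", flgE = "PRESENT",
                                       fliC = "ABSENT"))
  expect_equal(flagellum_assessment(mixed, genes)$value, "PARTIAL")
  expect_error(flagellum_assessment(all_present,
                                    c(flgB = "propeller")),
               "unknown flagellar part")
  expect_error(flagellum_assessment(all_present,
                                    c(flgZ = "hook")),
               "lacks flagellar gene")
})

test_that("siderophore locus completeness lists failing genes", {
  vm <- transcribed_virulome_maps()
  ent <- c("entA", "entB", "entC", "entE", "entF")
  for (m in vm) {
    r <- locus_completeness(m, ent)
    expect_false(r$complete)
    expect_setequal(r$failing, ent)  # all five missing or pseudogenized
  }
  ybt <- c("irp1", "irp2", "fyuA", "ybtA", "ybtS", "ybtU", "ybtT",
           "ybtD", "psn")
  r2 <- locus_completeness(vm$SsPl, ybt)
  expect_false(r2$complete)
  expect_setequal(r2$failing, c("ybtS", "ybtU", "ybtT", "ybtD", "psn"))
  # a trivially complete one-gene locus
  expect_true(locus_completeness(vm$SsPl, "irp1")$complete)
  expect_error(locus_completeness(vm$SsPl, "nosuch"), "lacks locus gene")
})

test_that("a complete flagellum implies locus completeness of its gene set", {
  vm <- transcribed_virulome_maps()
  parts <- default_flagellum_parts()
  flag_genes <- intersect(names(parts), vm$SsPl$gene_name)
  if (flagellum_assessment(vm$SsPl)$value == "COMPLETE")
    expect_true(locus_completeness(vm$SsPl, flag_genes)$complete)
})
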