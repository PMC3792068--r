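test_that("edges are single-residue additions only", {
  g <- build_network(parse_glycan_code(c("5200", "5300")))
  e <- igraph::as_data_frame(g)
  expect_equal(nrow(e), 1L)
  expect_equal(e$from, "5200")
  expect_equal(e$to, "5300")
  expect_equal(e$residue, "hexnac")

  g2 <- build_network(parse_glycan_code(c("5401", "5402")))
  expect_equal(igraph::as_data_frame(g2)$residue, "neuac")

  # differ by more than one residue: no edge
  g3 <- build_network(parse_glycan_code(c("5200", "5402")))
  expect_equal(igraph::ecount(g3), 0L)
  expect_equal(igraph::gorder(g3), 2L)

  expect_error(build_network(parse_glycan_code(c("5200", "5200"))), "unique")
})

test_that("the panel network is an acyclic graph with residue-mass edge deltas", {
  g <- build_network(reference_panel())
  expect_equal(igraph::gorder(g), 61L)
  expect_true(igraph::is_dag(g))
  deltas <- igraph::E(g)$delta_mz
  allowed <- c(162.052824, 203.079373, 146.057909, 291.095417 + 14.015650)
  expect_true(all(vapply(deltas,
                         function(d) any(abs(d - allowed) < 1e-6),
                         logical(1))))
})

test_that("fold-change annotation is log2 of arithmetic group means", {
  panel <- reference_panel()
  g <- build_network(panel)
  ab <- tibble::as_tibble(c(
    list(sample_id = c("a", "b", "c", "d")),
    setNames(as.list(as.data.frame(matrix(10, 4, 61))), panel$code)
  ))
  ab[["5402"]] <- c(20, 20, 10, 10) # case mean 20, control mean 10
  ab[["5410"]] <- c(5, 5, 10, 10)   # case mean 5, control mean 10
  groups <- c("UC", "UC", "HLT", "HLT")
  ga <- annotate_fold_change(g, ab, groups, panel = panel)
  fc <- setNames(igraph::V(ga)$log2fc, igraph::V(ga)$name)
  expect_equal(unname(fc["5402"]), 1)
  expect_equal(unname(fc["5410"]), -1)
  expect_equal(unname(fc["5200"]), 0)

  ab_bad <- ab
  ab_bad[["5200"]][1] <- 0
  expect_error(annotate_fold_change(g, ab_bad, groups, panel = panel),
               "positive")
})

test_that("graphml and sif exports round-trip nodes, edges and attributes", {
  panel <- reference_panel()
  cohort <- simulate_cohort(cohort_config(n_uc = 5, n_hlt = 5, seed = 2))
  g <- annotate_fold_change(build_network(panel), cohort$abundance,
                            cohort$metadata$group, panel = panel)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gml, format = "graphml")
  g_back <- import_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g_back)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(g_back), igraph::ecount(g))
  ord <- match(igraph::V(g)$name, igraph::V(g_back)$name)
  expect_equal(igraph::V(g_back)$log2fc[ord], igraph::V(g)$log2fc,
               tolerance = 1e-9)

  sif <- withr::local_tempfile(fileext = ".sif")
  paths <- export_graph(g, sif, format = "sif")
  expect_length(paths, 2L)
  s_back <- import_graph(sif, format = "sif")
  expect_setequal(igraph::V(s_back)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(s_back), igraph::ecount(g))
  ord <- match(igraph::V(g)$name, igraph::V(s_back)$name)
  expect_equal(igraph::V(s_back)$log2fc[ord], igraph::V(g)$log2fc,
               tolerance = 1e-9)
})

test_that("sif export writes `source addition target` lines", {
  g <- build_network(parse_glycan_code(c("5200", "5300")))
  sif <- withr::local_tempfile(fileext = ".sif")
  export_graph(g, sif, format = "sif")
  expect_equal(readLines(sif), "5200 addition 5300")

  # empty graph exports valid (empty) documents
  g0 <- build_network(parse_glycan_code("5200"))
  export_graph(g0, sif, format = "sif")
  expect_equal(readLines(sif), "5200")
})

test_that("class summary reports mean fold change per class", {
  panel <- reference_panel()
  g <- build_network(panel)
  expect_error(class_summary(g), "annotate")

  ab <- tibble::as_tibble(c(
    list(sample_id = c("a", "b")),
    setNames(as.list(as.data.frame(matrix(7, 2, 61))), panel$code)
  ))
  ga <- annotate_fold_change(g, ab, c("UC", "HLT"), panel = panel)
  cs <- class_summary(ga)
  expect_true(all(cs$mean_log2fc == 0))
  expect_equal(cs$n[cs$class == "highly_sialylated_multibranched"], 13L)

  # default synthetic cohort: disease-elevated classes show positive means
  cohort <- default_cohort()
  ga2 <- annotate_fold_change(g, cohort$abundance, cohort$metadata$group,
                              panel = panel)
  cs2 <- class_summary(ga2)
  expect_gt(cs2$mean_log2fc[cs2$class == "highly_sialylated_multibranched"], 0)
  expect_gt(cs2$mean_log2fc[cs2$class == "complex"], 0)
  expect_gt(cs2$mean_log2fc[cs2$class == "agalactosyl_bi"], 0)
})
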