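make_run_config <- function(out, seed = 5, regions = 8, n_perm = 150,
                            ...) {
  atlas <- tiny_atlas(regions)
  list(out = out, seed = seed, atlas = atlas,
       simulate = list(group_sizes = c(KO = 7, WT = 7),
                       base_correlation =
                         exchangeable_correlation(regions, 0.3),
                       seed = seed),
       group_a = "KO", group_b = "WT", n_permutations = n_perm, ...)
}

test_that("run_pipeline emits the complete artifact set, byte-stable", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  res <- run_pipeline(make_run_config(out1))
  expect_s3_class(res, "edge_results")
  expected <- c("uptake.csv", "ground_truth.json", "suvr.csv",
                "r_KO.csv", "z_KO.csv", "r_WT.csv", "z_WT.csv",
                "edges.csv", "significant_edges.csv", "run_metadata.json")
  expect_setequal(list.files(out1), expected)
  edges <- utils::read.csv(file.path(out1, "edges.csv"))
  expect_identical(nrow(edges), 28L)
  run_pipeline(make_run_config(out2))
  for (f in expected) {
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6),
                     label = paste("bytes of", f))
  }
})

test_that("pipeline errors name the failing stage and leave no artifacts", {
  out <- withr::local_tempdir()
  cfg <- list(out = out, seed = 1, atlas = tiny_atlas(4),
              uptake = file.path(out, "does_not_exist.csv"))
  expect_error(run_pipeline(cfg), "stage 'input'")
  expect_identical(list.files(out), character(0))
  expect_error(run_pipeline(list(out = out, seed = 1)), "uptake")
  expect_error(run_pipeline(list(seed = 1)), "out")
})

test_that("config files round-trip through JSON and drive the pipeline", {
  out <- withr::local_tempdir()
  cfg_path <- withr::local_tempfile(fileext = ".json")
  cfg <- list(out = out, seed = 7,
              simulate = list(group_sizes = list(KO = 7, WT = 7)),
              n_permutations = 60)
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  back <- read_run_config(cfg_path)
  expect_identical(back$seed, 7L)
  expect_identical(back$n_permutations, 60L)
  res <- run_pipeline(cfg_path)  # default 53-region atlas
  expect_identical(nrow(res), 1378L)
})

test_that("rendered edge table mirrors the tiered two-column layout", {
  df <- data.frame(
    region_i = c("olfactory_bulb_R", "globus_pallidus_L", "amygdala_R",
                 "optic_nerve_R"),
    region_j = c("amygdala_L", "optic_nerve_L", "corpus_callosum_L",
                 "frontal_lobe_R"),
    delta_z = c(2.1, -1.8, -1.2, 0.9),
    p_value = c(0.002, 0.004, 0.03, 0.2))
  df <- classify_edges(df)
  lines <- render_edge_table(df, quiet = TRUE)
  expect_match(lines[1], "Increased Correlation between Two Nodes")
  expect_match(lines[1], "Decreased Correlation between Two Nodes")
  # p<0.05 block first, then p<0.005; the ns edge never appears
  expect_match(lines[2], "amygdala_R -- corpus_callosum_L")
  expect_match(lines[2], "p<0.05$")
  expect_match(lines[3], "olfactory_bulb_R -- amygdala_L")
  expect_match(lines[3], "globus_pallidus_L -- optic_nerve_L")
  expect_match(lines[3], "p<0.005$")
  expect_false(any(grepl("optic_nerve_R -- frontal_lobe_R", lines)))

  all_ns <- classify_edges(data.frame(region_i = "a", region_j = "b",
                                      delta_z = 1, p_value = 0.9))
  expect_length(render_edge_table(all_ns, quiet = TRUE), 1L)  # header only
})

test_that("stable tie-break ordering within tiers of significant_edges", {
  df <- data.frame(region_i = c("b", "a", "a"),
                   region_j = c("c", "c", "b"),
                   delta_z = c(1, 1, -1),
                   p_value = c(0.02, 0.02, 0.001))
  df <- classify_edges(df)
  sig <- significant_edges(df)
  expect_identical(paste(sig$region_i, sig$region_j),
                   c("a b", "a c", "b c"))
  expect_identical(sig$tier, c("p<0.005", "p<0.05", "p<0.05"))
})

test_that("GraphML export carries nodes and edge attributes", {
  skip_if_not_installed("igraph")
  suvr <- compute_suvr(sim_cohort(n = 5, regions = 5, rho = 0, seed = 33))
  res <- permutation_edge_test(suvr, "KO", "WT", n_permutations = 50,
                               seed = 3)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_edges_graphml(res, suvr$atlas, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 10)
  expect_true(all(c("delta_z", "p", "tier") %in%
                    igraph::edge_attr_names(g)))
})
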