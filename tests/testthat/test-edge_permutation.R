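test_that("duplicating one group as the other yields p = 1 everywhere", {
  atlas <- tiny_atlas(5)
  half <- sim_cohort(n = 5, regions = 5, rho = 0.3, seed = 2,
                     groups = c(KO = 5))
  vals <- rbind(half$values, half$values)
  tbl <- uptake_table(vals, c(paste0("k", 1:5), paste0("w", 1:5)),
                      rep(c("KO", "WT"), each = 5), atlas)
  res <- permutation_edge_test(compute_suvr(tbl), "KO", "WT",
                               n_permutations = 200, seed = 9)
  expect_true(all(res$delta_z == 0))
  expect_true(all(res$p_value == 1))
  expect_true(all(res$tier == "ns"))
  expect_true(all(res$direction == "none"))
})

test_that("edge tests are deterministic given a seed and require one", {
  suvr <- compute_suvr(sim_cohort(n = 5, regions = 5, rho = 0.2, seed = 4))
  a <- permutation_edge_test(suvr, "KO", "WT", n_permutations = 300,
                             seed = 11)
  b <- permutation_edge_test(suvr, "KO", "WT", n_permutations = 300,
                             seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- permutation_edge_test(suvr, "KO", "WT", n_permutations = 300,
                             seed = 12)
  expect_false(identical(a$p_value, c$p_value))
  expect_error(permutation_edge_test(suvr, "KO", "WT"), "seed")
})

test_that("edge list covers each unordered pair once, in atlas order", {
  suvr <- compute_suvr(sim_cohort(n = 4, regions = 6, rho = 0, seed = 6))
  res <- permutation_edge_test(suvr, "KO", "WT", n_permutations = 50,
                               seed = 1)
  expect_identical(nrow(res), 15L)
  key <- paste(res$region_i, res$region_j)
  expect_false(any(duplicated(key)))
  idx_i <- match(res$region_i, suvr$atlas$name)
  idx_j <- match(res$region_j, suvr$atlas$name)
  expect_true(all(idx_i < idx_j))
  expect_true(all(res$p_value >= 1 / 51 & res$p_value <= 1))
})

test_that("swapping the group pair flips directions and preserves p-values", {
  suvr <- compute_suvr(sim_cohort(n = 7, regions = 6, rho = 0.2, seed = 8,
                                  effects = data.frame(
                                    region_i = "region_a_R",
                                    region_j = "region_c_R",
                                    group = "KO", target_r = 0.95)))
  ab <- permutation_edge_test(suvr, "KO", "WT", n_permutations = 400,
                              seed = 14)
  ba <- permutation_edge_test(suvr, "WT", "KO", n_permutations = 400,
                              seed = 14)
  expect_identical(ba$p_value, ab$p_value)
  expect_identical(ba$delta_z, -ab$delta_z)
  swap <- c(increased = "decreased", decreased = "increased", none = "none")
  expect_identical(ba$direction, unname(swap[ab$direction]))
  expect_identical(ba$tier, ab$tier)
})

test_that("tier classification uses the smallest passed threshold, strictly", {
  df <- data.frame(delta_z = c(1, -1, -0.5, 0.2, -0.1),
                   p_value = c(0.003, 0.03, 0.05, 0.009, 0.5))
  out <- classify_edges(df)
  expect_identical(out$tier,
                   c("p<0.005", "p<0.05", "ns", "p<0.01", "ns"))
  expect_identical(out$direction,
                   c("increased", "decreased", "none", "increased", "none"))
  # exact-boundary p values never pass (strict <)
  edge_cases <- classify_edges(data.frame(delta_z = c(1, 1, 1),
                                          p_value = c(0.05, 0.01, 0.005)))
  expect_identical(edge_cases$tier, c("ns", "p<0.05", "p<0.01"))
  expect_error(classify_edges(df[0, ]), "non-empty")
  expect_error(classify_edges(df, thresholds = c(0.01, 0.05)),
               "decreasing")
})

test_that("an injected strong effect is flagged with the right direction", {
  eff <- data.frame(region_i = "region_a_R", region_j = "region_b_R",
                    group = "KO", target_r = 0.95)
  suvr <- compute_suvr(sim_cohort(n = 12, regions = 6, rho = 0, seed = 19,
                                  effects = eff,
                                  groups = c(KO = 12, WT = 12)))
  res <- permutation_edge_test(suvr, "KO", "WT", n_permutations = 999,
                               seed = 21)
  hit <- res[res$region_i == "region_a_R" & res$region_j == "region_b_R", ]
  expect_lt(hit$p_value, 0.05)
  expect_identical(hit$direction, "increased")
  expect_gt(hit$delta_z, 0)
})

test_that("BH annotation adds adjusted p-values without filtering rows", {
  suvr <- compute_suvr(sim_cohort(n = 5, regions = 5, rho = 0, seed = 25))
  res <- permutation_edge_test(suvr, "KO", "WT", n_permutations = 100,
                               seed = 2, bh_annotate = TRUE)
  expect_true("p_bh" %in% names(res))
  expect_identical(nrow(res), 10L)
  expect_equal(res$p_bh, stats::p.adjust(res$p_value, "BH"),
               tolerance = 1e-15)
  expect_true(all(res$p_bh >= res$p_value))
})
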