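# Shared fixtures: tiny atlases and cohorts built in code.

# n-region atlas; last two regions form the reference pool (medulla_L/R
# style) unless n < 3, in which case only the last region is reference.
tiny_atlas <- function(n = 6L) {
  nm <- c(paste0("region_", letters[seq_len(n - 2L)], "_R"),
          "medulla_L", "medulla_R")[seq_len(max(n, 1L))]
  if (n < 3L) nm <- c("region_a_R", "medulla_R")[seq_len(n)]
  voi_atlas(nm,
            hemisphere = ifelse(grepl("_L$", nm), "L",
                                ifelse(grepl("_R$", nm), "R", "NA")),
            is_reference = grepl("^medulla", nm))
}

# Deterministic hand-built uptake table (no RNG): values are offset sums
# so every region varies across subjects.
tiny_uptake <- function(atlas = tiny_atlas(), n_per_group = 4L,
                        groups = c("KO", "WT")) {
  p <- n_regions(atlas)
  n <- n_per_group * length(groups)
  vals <- outer(seq_len(n), seq_len(p), function(i, j) 1 + 0.1 * i + 0.01 * i * j)
  colnames(vals) <- atlas$name
  uptake_table(vals, sprintf("m%02d", seq_len(n)),
               rep(groups, each = n_per_group), atlas)
}

# Simulated two-group cohort over a small atlas.
sim_cohort <- function(n = 7L, regions = 6L, rho = 0, seed = 1L,
                       effects = NULL, cv = 0.1,
                       groups = c(KO = n, WT = n)) {
  atlas <- tiny_atlas(regions)
  base <- if (rho == 0) "identity"
          else exchangeable_correlation(regions, rho)
  simulate_cohort(cohort_spec(atlas, groups, base,
                              edge_effects = effects, cv = cv, seed = seed))
}

# Textbook Pearson correlation, written out long-hand: the independent
# oracle for stats::cor-based implementation code.
pearson_by_hand <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
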