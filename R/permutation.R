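#' Permutation test for between-group connectivity differences at every edge
#'
#' For each unordered region pair (edge), the observed statistic is the
#' difference in Fisher z between the two group networks,
#' \code{delta_z = z_a - z_b} (by convention \code{group_a} is the mutant
#' or treatment group, so "increased" means stronger correlation in
#' \code{group_a}). The null distribution is built by repeatedly permuting
#' the group labels over the pooled subjects — preserving the original
#' group sizes — and recomputing both correlation matrices, their Fisher
#' transforms, and the per-edge difference. One shared permutation stream
#' serves all edges.
#'
#' The two-sided p-value uses add-one smoothing:
#' \code{p = (1 + #permutations with |delta_z_perm| >= |delta_z_obs|) /
#' (n_permutations + 1)}, so p is never exactly zero and ties count
#' against significance. Edges are then classified by [classify_edges()].
#'
#' No multiple-comparison correction is applied by default; the tiered
#' thresholds are per-edge. With \code{bh_annotate = TRUE} a
#' Benjamini-Hochberg adjusted p-value column (\code{p_bh}) is added for
#' honesty about the 1378-edge search space; it annotates, never filters.
#'
#' @param suvr an \code{suvr_table} containing both groups.
#' @param group_a,group_b group labels; \code{group_a} minus
#'   \code{group_b} defines the sign of \code{delta_z}.
#' @param n_permutations number of label permutations (default 5000).
#' @param seed integer seed for the permutation stream (required: results
#'   are only reproducible given a seed).
#' @param thresholds strictly decreasing significance levels in
#'   \code{(0, 1)}; default \code{c(0.05, 0.01, 0.005)}.
#' @param clamp_epsilon clamp for [fisher_z()]; applied identically to the
#'   observed and every permuted network.
#' @param bh_annotate add a \code{p_bh} column of Benjamini-Hochberg
#'   adjusted p-values (default \code{FALSE}).
#' @return A data frame of class \code{edge_results}, one row per
#'   unordered region pair in atlas order (\code{n * (n - 1) / 2} rows),
#'   with columns \code{region_i}, \code{region_j}, \code{r_a},
#'   \code{r_b}, \code{z_a}, \code{z_b}, \code{delta_z}, \code{p_value},
#'   \code{direction} (\code{increased}/\code{decreased}/\code{none}) and
#'   \code{tier} (\code{"p<0.005"}, \code{"p<0.01"}, \code{"p<0.05"} or
#'   \code{"ns"}). Test metadata is attached as attributes.
#' @export
permutation_edge_test <- function(suvr, group_a, group_b,
                                  n_permutations = 5000L, seed,
                                  thresholds = c(0.05, 0.01, 0.005),
                                  clamp_epsilon = 1e-6,
                                  bh_annotate = FALSE) {
  validate_uptake(suvr)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (identical(group_a, group_b)) {
    stop("group_a and group_b must differ", call. = FALSE)
  }
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  check_thresholds(thresholds)
  check_two_groups(suvr, group_a, group_b)

  labels <- suvr$subjects$group
  pooled <- which(labels %in% c(group_a, group_b))
  x <- suvr$values[pooled, , drop = FALSE]
  labs <- labels[pooled]
  n <- length(labs)
  p <- ncol(x)

  net_a <- group_network(suvr, group_a, clamp_epsilon)
  net_b <- group_network(suvr, group_b, clamp_epsilon)
  dz_obs <- net_a$z_matrix - net_b$z_matrix
  abs_obs <- abs(dz_obs)

  count <- matrix(0, p, p)
  set.seed(as.integer(seed))
  for (k in seq_len(n_permutations)) {
    pl <- labs[sample.int(n)]
    za <- fisher_z(stats::cor(x[which(pl == group_a), , drop = FALSE]),
                   clamp_epsilon)
    zb <- fisher_z(stats::cor(x[which(pl == group_b), , drop = FALSE]),
                   clamp_epsilon)
    dz <- za - zb
    if (anyNA(dz)) {
      stop("zero-variance region in a permuted pseudo-group; ",
           "input data are degenerate", call. = FALSE)
    }
    diag(dz) <- 0
    count <- count + (abs(dz) >= abs_obs)
  }
  pmat <- (1 + count) / (n_permutations + 1)

  ut <- which(upper.tri(pmat), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  nm <- suvr$atlas$name
  res <- data.frame(
    region_i = nm[ut[, 1L]],
    region_j = nm[ut[, 2L]],
    r_a = net_a$r_matrix[ut],
    r_b = net_b$r_matrix[ut],
    z_a = net_a$z_matrix[ut],
    z_b = net_b$z_matrix[ut],
    delta_z = dz_obs[ut],
    p_value = pmat[ut],
    stringsAsFactors = FALSE
  )
  res <- classify_edges(res, thresholds)
  if (bh_annotate) res$p_bh <- stats::p.adjust(res$p_value, method = "BH")
  attr(res, "group_a") <- group_a
  attr(res, "group_b") <- group_b
  attr(res, "n_subjects") <- c(a = net_a$n_subjects, b = net_b$n_subjects)
  attr(res, "n_permutations") <- n_permutations
  attr(res, "seed") <- as.integer(seed)
  attr(res, "clamp_epsilon") <- clamp_epsilon
  attr(res, "thresholds") <- thresholds
  class(res) <- c("edge_results", "data.frame")
  res
}

check_thresholds <- function(thresholds) {
  if (!length(thresholds) || any(thresholds <= 0) || any(thresholds >= 1) ||
      any(diff(thresholds) >= 0)) {
    stop("thresholds must be strictly decreasing values in (0, 1)",
         call. = FALSE)
  }
  invisible(thresholds)
}

tier_label <- function(threshold) sprintf("p<%g", threshold)

#' Classify edges into significance tiers and directions
#'
#' Each edge gets the tier of the smallest threshold its p-value passes
#' (strict inequality, so p equal to a threshold does not pass it), and a
#' direction from the sign of \code{delta_z}: \code{increased} if the
#' first group's Fisher z is larger, \code{decreased} if smaller,
#' \code{none} for non-significant edges.
#'
#' @param results data frame with columns \code{delta_z} and
#'   \code{p_value} (as produced by [permutation_edge_test()]).
#' @param thresholds strictly decreasing significance levels in
#'   \code{(0, 1)}.
#' @return \code{results} with \code{tier} and \code{direction} columns
#'   (re)filled.
#' @export
classify_edges <- function(results, thresholds = c(0.05, 0.01, 0.005)) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("results must be a non-empty data frame", call. = FALSE)
  }
  if (!all(c("delta_z", "p_value") %in% names(results))) {
    stop("results must have delta_z and p_value columns", call. = FALSE)
  }
  check_thresholds(thresholds)
  tier <- rep("ns", nrow(results))
  for (th in thresholds) {           # descending: smallest passed wins
    tier[results$p_value < th] <- tier_label(th)
  }
  direction <- ifelse(tier == "ns", "none",
                      ifelse(results$delta_z > 0, "increased", "decreased"))
  results$direction <- direction
  results$tier <- tier
  results
}

#' Significant edges of an edge-results table
#' @param results an \code{edge_results} data frame.
#' @return the rows with \code{tier != "ns"}, ordered by tier (most
#'   significant first), then region pair.
#' @export
significant_edges <- function(results) {
  sig <- results[results$tier != "ns", , drop = FALSE]
  lev <- c(vapply(sort(attr(results, "thresholds") %||%
                         c(0.05, 0.01, 0.005)), tier_label, character(1L)),
           "ns")
  sig[order(match(sig$tier, lev), sig$region_i, sig$region_j), ,
      drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.edge_results <- function(x, ...) {
  cat("edge results: ", nrow(x), " region pairs, ",
      attr(x, "group_a"), " vs ", attr(x, "group_b"), ", ",
      attr(x, "n_permutations"), " permutations\n", sep = "")
  tab <- base::table(x$tier)
  cat("tiers:", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}
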