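#' Exchangeable (compound-symmetric) correlation matrix
#'
#' @param n dimension.
#' @param rho common off-diagonal correlation, in \code{(-1/(n-1), 1)} for
#'   positive semidefiniteness.
#' @return an \code{n x n} correlation matrix.
#' @export
exchangeable_correlation <- function(n, rho) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (rho <= -1 || rho >= 1) stop("rho must be in (-1, 1)", call. = FALSE)
  m <- matrix(rho, n, n)
  diag(m) <- 1
  m
}

#' Project a symmetric matrix to the nearest valid correlation matrix
#'
#' Alternates eigenvalue clipping at zero with diagonal renormalization
#' until the iterates stabilize. Injecting edge-level correlation targets
#' into a base structure can break positive semidefiniteness; this
#' projection restores it while perturbing the remaining entries as little
#' as the scheme allows. A matrix that is already positive semidefinite is
#' returned unchanged. Only the post-conditions (symmetry, unit diagonal,
#' eigenvalues >= -1e-10) are contractual; the projection path is internal.
#'
#' @param m square symmetric matrix with unit diagonal and entries in
#'   \code{[-1, 1]}.
#' @param tol convergence tolerance on the max absolute change between
#'   iterates (default \code{1e-10}).
#' @param max_iter iteration cap (default 100).
#' @return a positive semidefinite correlation matrix of the same dimension.
#' @export
nearest_correlation <- function(m, tol = 1e-10, max_iter = 100L) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) {
    stop("matrix must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(m) - 1)) > 1e-8) {
    stop("matrix must have unit diagonal", call. = FALSE)
  }
  if (any(m < -1 - 1e-8) || any(m > 1 + 1e-8)) {
    stop("entries must lie in [-1, 1]", call. = FALSE)
  }
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) >= 0) {
    return(m)   # already a valid correlation matrix: fixed point
  }
  a <- (m + t(m)) / 2
  for (it in seq_len(max_iter)) {
    prev <- a
    e <- eigen(a, symmetric = TRUE)
    a <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    d <- sqrt(pmax(diag(a), .Machine$double.eps))
    a <- a / tcrossprod(d)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    a[a > 1] <- 1
    a[a < -1] <- -1
    if (max(abs(a - prev)) < tol) break
  }
  a
}

# Deterministic 31-base polynomial hash of a group label, mod 2^31 - 1.
# Mixing the label into the per-group seed keeps each group's stream
# independent of which other groups exist in the spec.
.label_hash <- function(label) {
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2147483647
  h
}

.group_seed <- function(seed, label) {
  as.integer((as.numeric(seed) + .label_hash(label)) %% 2147483647)
}

#' Specify a two-group (or multi-group) synthetic cohort
#'
#' Describes a cohort of subjects whose regional uptake is drawn from a
#' group-specific multivariate Gaussian: mean \code{mean_uptake}, per-region
#' SD \code{cv * mean_uptake}, and correlation equal to the base structure
#' with that group's edge effects injected, projected to the nearest valid
#' correlation matrix. Gaussian marginals with a small coefficient of
#' variation (and rejection of non-positive draws) keep the Pearson
#' correlation targets exact while mimicking the positive, low-variance
#' scale of SUVR-like uptake data.
#'
#' @param atlas a \code{voi_atlas}.
#' @param group_sizes named integer vector, group label -> subject count
#'   (each at least 3).
#' @param base_correlation \code{"identity"} or a square correlation matrix
#'   of dimension \code{n_regions(atlas)} (see
#'   [exchangeable_correlation()]).
#' @param edge_effects \code{NULL} or a data frame with columns
#'   \code{region_i}, \code{region_j}, \code{group}, \code{target_r}
#'   (\code{target_r} in \code{(-1, 1)}): the correlation of that region
#'   pair is set to \code{target_r} for that group before projection.
#' @param mean_uptake per-region positive means; a scalar is recycled. The
#'   default is 1.0 everywhere and 1.2 for reference regions, an SUVR-like
#'   scale with a slightly hotter reference pool.
#' @param cv coefficient of variation per region (scalar recycled),
#'   dimensionless, > 0; default 0.1.
#' @param seed integer root seed; per-group streams are derived from it.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(atlas, group_sizes,
                        base_correlation = "identity",
                        edge_effects = NULL,
                        mean_uptake = NULL, cv = 0.1, seed = 1L) {
  validate_atlas(atlas)
  p <- n_regions(atlas)
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop("group_sizes must be a named vector", call. = FALSE)
  }
  if (any(group_sizes < 3L)) {
    stop("every group must have at least 3 subjects", call. = FALSE)
  }
  if (is.character(base_correlation)) {
    base_correlation <- match.arg(base_correlation, "identity")
    base_correlation <- diag(p)
  }
  base_correlation <- as.matrix(base_correlation)
  if (!all(dim(base_correlation) == p)) {
    stop("base_correlation must be ", p, " x ", p, call. = FALSE)
  }
  if (max(abs(base_correlation - t(base_correlation))) > 1e-8 ||
      max(abs(diag(base_correlation) - 1)) > 1e-8 ||
      any(abs(base_correlation) > 1 + 1e-8)) {
    stop("base_correlation must be symmetric with unit diagonal and ",
         "entries in [-1, 1]", call. = FALSE)
  }
  if (!is.null(edge_effects)) {
    edge_effects <- as.data.frame(edge_effects)
    need <- c("region_i", "region_j", "group", "target_r")
    if (!all(need %in% names(edge_effects))) {
      stop("edge_effects needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    bad <- setdiff(unique(c(edge_effects$region_i, edge_effects$region_j)),
                   atlas$name)
    if (length(bad)) {
      stop("edge_effects name unknown region(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(abs(edge_effects$target_r) >= 1)) {
      stop("target_r must lie in (-1, 1)", call. = FALSE)
    }
    if (!all(edge_effects$group %in% names(group_sizes))) {
      stop("edge_effects reference unknown group(s)", call. = FALSE)
    }
  }
  if (is.null(mean_uptake)) {
    mean_uptake <- ifelse(atlas$is_reference, 1.2, 1.0)
  }
  mean_uptake <- rep_len(as.numeric(mean_uptake), p)
  if (any(mean_uptake <= 0)) stop("mean_uptake must be > 0", call. = FALSE)
  cv <- rep_len(as.numeric(cv), p)
  if (any(cv <= 0)) stop("cv must be > 0", call. = FALSE)
  structure(
    list(atlas = atlas,
         group_sizes = stats::setNames(as.integer(group_sizes),
                                       names(group_sizes)),
         base_correlation = base_correlation,
         edge_effects = edge_effects,
         mean_uptake = mean_uptake, cv = cv, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Target correlation matrix for one group: base structure with that
# group's edge effects written in, projected back to a valid correlation
# matrix.
group_target_correlation <- function(spec, group) {
  m <- spec$base_correlation
  ee <- spec$edge_effects
  if (!is.null(ee)) {
    ee <- ee[ee$group == group, , drop = FALSE]
    for (k in seq_len(nrow(ee))) {
      i <- match(ee$region_i[k], spec$atlas$name)
      j <- match(ee$region_j[k], spec$atlas$name)
      m[i, j] <- m[j, i] <- ee$target_r[k]
    }
  }
  nearest_correlation(m)
}

#' Simulate a cohort from a specification
#'
#' Draws each group's subjects from its multivariate Gaussian; any draw
#' containing a non-positive value is rejected and redrawn, so all emitted
#' uptake is strictly positive. The same spec and seed always reproduce the
#' identical table. Ground truth — the exact post-projection correlation
#' matrix used per group — is attached as attribute
#' \code{"ground_truth"} (a named list of matrices).
#'
#' @param spec a \code{cohort_spec}.
#' @return An \code{uptake_table} with one row per simulated subject,
#'   groups in the order of \code{spec$group_sizes}.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- n_regions(spec$atlas)
  sds <- spec$cv * spec$mean_uptake
  groups <- names(spec$group_sizes)
  truth <- list()
  blocks <- list()
  ids <- character(0)
  labels <- character(0)
  for (g in groups) {
    n <- spec$group_sizes[[g]]
    corr <- group_target_correlation(spec, g)
    truth[[g]] <- corr
    sigma <- corr * tcrossprod(sds)
    set.seed(.group_seed(spec$seed, g))
    accepted <- matrix(NA_real_, n, p)
    got <- 0L
    attempts <- 0L
    while (got < n) {
      draw <- MASS::mvrnorm(n - got, mu = spec$mean_uptake, Sigma = sigma)
      draw <- matrix(draw, ncol = p)
      attempts <- attempts + nrow(draw)
      ok <- apply(draw > 0, 1L, all)
      keep <- draw[ok, , drop = FALSE]
      if (nrow(keep)) {
        accepted[(got + 1L):(got + nrow(keep)), ] <- keep
        got <- got + nrow(keep)
      }
      if (attempts >= 1000L && got / attempts < 0.5) {
        stop("rejection rate above 50% after ", attempts,
             " draws; cv too large for strictly positive uptake",
             call. = FALSE)
      }
    }
    # Small cohorts can finish before the guard sees enough draws; if the
    # acceptance rate looks poor, probe up to 1000 attempts to confirm
    # before trusting the configuration.
    if (got / attempts < 0.5) {
      probe_ok <- got
      while (attempts < 1000L) {
        draw <- matrix(MASS::mvrnorm(100L, mu = spec$mean_uptake,
                                     Sigma = sigma), ncol = p)
        attempts <- attempts + nrow(draw)
        probe_ok <- probe_ok + sum(apply(draw > 0, 1L, all))
      }
      if (probe_ok / attempts < 0.5) {
        stop("rejection rate above 50% after ", attempts,
             " draws; cv too large for strictly positive uptake",
             call. = FALSE)
      }
    }
    colnames(accepted) <- spec$atlas$name
    blocks[[g]] <- accepted
    ids <- c(ids, sprintf("%s_%02d", g, seq_len(n)))
    labels <- c(labels, rep(g, n))
  }
  tbl <- uptake_table(do.call(rbind, blocks), ids, labels, spec$atlas)
  attr(tbl, "ground_truth") <- truth
  tbl
}

#' Ground-truth correlation matrices of a simulated cohort
#' @param table an \code{uptake_table} produced by [simulate_cohort()].
#' @return named list of per-group target correlation matrices
#'   (post-projection), or \code{NULL} for non-simulated tables.
#' @export
cohort_ground_truth <- function(table) attr(table, "ground_truth")
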