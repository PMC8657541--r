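#' Fisher r-to-z transformation with clamping
#'
#' \code{z = atanh(r) = 0.5 * log((1 + r) / (1 - r))}, the
#' variance-stabilizing transform of a Pearson correlation. Values are
#' clamped into \code{[-1 + clamp_epsilon, 1 - clamp_epsilon]} first: with
#' small groups, sample correlations of exactly +/-1 occur and would map
#' to infinite z, making their edges untestable.
#'
#' @param r numeric vector or matrix of correlations.
#' @param clamp_epsilon clamp margin in \code{(0, 1)}; default \code{1e-6}.
#' @return z values, same shape as \code{r}.
#' @export
fisher_z <- function(r, clamp_epsilon = 1e-6) {
  if (!is.numeric(clamp_epsilon) || length(clamp_epsilon) != 1L ||
      clamp_epsilon <= 0 || clamp_epsilon >= 1) {
    stop("clamp_epsilon must be a single number in (0, 1)", call. = FALSE)
  }
  atanh(pmin(pmax(r, -1 + clamp_epsilon), 1 - clamp_epsilon))
}

#' Inter-subject correlation network of one group
#'
#' Computes the Pearson correlation across the group's subjects for every
#' pair of regions: each subject contributes one SUVR value per region, so
#' with \code{n} subjects every correlation is estimated from \code{n}
#' paired observations. The resulting region-by-region matrix is the
#' group's metabolic connectivity network.
#'
#' @param suvr an \code{suvr_table} (any \code{uptake_table} works; SUVR
#'   is the intended input).
#' @param group group label to select subjects.
#' @return An object of class \code{group_network}: list with
#'   \code{group}, \code{n_subjects}, \code{r_matrix} (symmetric, unit
#'   diagonal) and \code{z_matrix} (\code{NULL} until
#'   [fisher_transform()]).
#' @export
correlation_matrix <- function(suvr, group) {
  validate_uptake(suvr)
  rows <- which(suvr$subjects$group == group)
  if (length(rows) < 3L) {
    stop("group '", group, "' has ", length(rows),
         " subjects; at least 3 required for correlation", call. = FALSE)
  }
  x <- suvr$values[rows, , drop = FALSE]
  sds <- apply(x, 2L, stats::sd)
  flat <- which(sds == 0)
  if (length(flat)) {
    stop("zero variance across subjects of group '", group,
         "' in region(s): ", paste(colnames(x)[flat], collapse = ", "),
         " (a sole reference region is SUVR-constant; pool the reference ",
         "bilaterally or drop the region)", call. = FALSE)
  }
  r <- stats::cor(x)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(
    list(group = group, n_subjects = length(rows), r_matrix = r,
         z_matrix = NULL, clamp_epsilon = NA_real_),
    class = "group_network"
  )
}

#' Fisher-transform a group network
#'
#' Fills the network's z matrix: off-diagonal \code{z = atanh(clamped r)};
#' the diagonal is set to 0 by convention (self-edges are meaningless and
#' never tested).
#'
#' @param network a \code{group_network} from [correlation_matrix()].
#' @param clamp_epsilon clamp margin passed to [fisher_z()].
#' @return the network with \code{z_matrix} and \code{clamp_epsilon} set.
#' @export
fisher_transform <- function(network, clamp_epsilon = 1e-6) {
  stopifnot(inherits(network, "group_network"))
  z <- fisher_z(network$r_matrix, clamp_epsilon)
  diag(z) <- 0
  network$z_matrix <- z
  network$clamp_epsilon <- clamp_epsilon
  network
}

#' Correlation network with Fisher z in one step
#' @inheritParams correlation_matrix
#' @inheritParams fisher_transform
#' @return a \code{group_network} with both matrices filled.
#' @export
group_network <- function(suvr, group, clamp_epsilon = 1e-6) {
  fisher_transform(correlation_matrix(suvr, group), clamp_epsilon)
}

#' @export
print.group_network <- function(x, ...) {
  cat("group network '", x$group, "': ", nrow(x$r_matrix), " regions, n = ",
      x$n_subjects, " subjects", sep = "")
  cat(if (is.null(x$z_matrix)) " (r only)\n" else
    sprintf(" (Fisher z, clamp %g)\n", x$clamp_epsilon))
  invisible(x)
}
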