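#' Normalize uptake to standard uptake value ratios (SUVR)
#'
#' Divides each subject's regional uptake by that subject's reference
#' value: the unweighted mean of their uptake over the reference pool.
#' This removes global per-subject scaling (injected dose, body weight,
#' scanner sensitivity), leaving dimensionless ratios comparable across
#' subjects. By default the pool is every atlas region flagged
#' \code{is_reference} — for the shipped atlas, the bilateral medulla.
#' Pooling both medullae rather than normalizing to a single side keeps
#' each individual medulla region usable as a network node: a sole
#' reference region would have zero variance (SUVR identically 1) and an
#' undefined correlation with everything.
#'
#' @param table an \code{uptake_table} of raw uptake.
#' @param reference \code{"atlas-default"} to use the atlas reference
#'   flags, or a character vector of region names to pool.
#' @return An object of class \code{suvr_table} (same structure as
#'   \code{uptake_table}; values are dimensionless), with attribute
#'   \code{reference_definition} recording the pooled regions and method.
#' @export
compute_suvr <- function(table, reference = "atlas-default") {
  validate_uptake(table)
  atlas <- table$atlas
  if (identical(reference, "atlas-default")) {
    ref_names <- reference_regions(atlas)
  } else {
    ref_names <- as.character(reference)
    missing_ref <- setdiff(ref_names, atlas$name)
    if (length(missing_ref)) {
      stop("reference region(s) not in atlas: ",
           paste(missing_ref, collapse = ", "), call. = FALSE)
    }
  }
  if (!length(ref_names)) stop("empty reference pool", call. = FALSE)
  v <- table$values
  ref <- rowMeans(v[, ref_names, drop = FALSE])
  bad <- which(!(ref > 0))
  if (length(bad)) {
    stop("non-positive reference uptake for subject '",
         table$subjects$subject_id[bad[1L]], "'", call. = FALSE)
  }
  suvr <- v / ref
  out <- uptake_table(suvr, table$subjects$subject_id,
                      table$subjects$group, atlas)
  class(out) <- c("suvr_table", class(out))
  attr(out, "reference_definition") <- list(
    regions = ref_names,
    method = "unweighted mean of reference-region uptake per subject"
  )
  out
}

#' Reference definition of an SUVR table
#' @param suvr a \code{suvr_table}.
#' @return list with elements \code{regions} and \code{method}.
#' @export
reference_definition <- function(suvr) attr(suvr, "reference_definition")
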