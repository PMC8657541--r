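#' Construct a VOI atlas
#'
#' A VOI (volume-of-interest) atlas is the ordered set of named brain regions
#' over which per-subject uptake is tabulated. Atlas order is canonical: it
#' fixes the row/column order of every correlation matrix and the pair order
#' of every edge list produced downstream, regardless of the column order of
#' input files.
#'
#' @param name character vector of unique, non-empty region names.
#' @param hemisphere character vector, one of \code{"L"}, \code{"R"},
#'   \code{"NA"} per region (midline or unlateralized regions use
#'   \code{"NA"}).
#' @param is_reference logical vector flagging the regions whose pooled mean
#'   uptake defines the SUVR denominator. At least one region must be
#'   flagged.
#'
#' @return An object of class \code{voi_atlas}: a data frame with columns
#'   \code{name}, \code{hemisphere}, \code{is_reference}.
#' @seealso [read_atlas()], [default_atlas()], [compute_suvr()]
#' @export
voi_atlas <- function(name, hemisphere = "NA", is_reference = FALSE) {
  name <- as.character(name)
  atlas <- data.frame(
    name = name,
    hemisphere = rep_len(as.character(hemisphere), length(name)),
    is_reference = rep_len(as.logical(is_reference), length(name)),
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("voi_atlas", "data.frame")
  validate_atlas(atlas)
  atlas
}

validate_atlas <- function(atlas) {
  if (!is.data.frame(atlas) ||
      !all(c("name", "hemisphere", "is_reference") %in% names(atlas))) {
    stop("atlas must have columns name, hemisphere, is_reference",
         call. = FALSE)
  }
  if (nrow(atlas) < 1L) stop("atlas has no regions", call. = FALSE)
  if (any(is.na(atlas$name)) || any(!nzchar(atlas$name))) {
    stop("atlas region names must be non-empty", call. = FALSE)
  }
  dup <- unique(atlas$name[duplicated(atlas$name)])
  if (length(dup)) {
    stop("duplicate region name(s) in atlas: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(atlas$hemisphere), c("L", "R", "NA"))
  if (length(bad)) {
    stop("hemisphere must be one of 'L', 'R', 'NA'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(atlas$is_reference))) {
    stop("is_reference must be TRUE or FALSE for every region", call. = FALSE)
  }
  if (!any(atlas$is_reference)) {
    stop("atlas must flag at least one reference region (is_reference)",
         call. = FALSE)
  }
  invisible(atlas)
}

#' Number of regions in an atlas
#' @param atlas a \code{voi_atlas}.
#' @return integer count of regions.
#' @export
n_regions <- function(atlas) nrow(atlas)

#' Names of the reference regions of an atlas
#' @param atlas a \code{voi_atlas}.
#' @return character vector of the regions flagged \code{is_reference}.
#' @export
reference_regions <- function(atlas) atlas$name[atlas$is_reference]

#' Read a VOI atlas from JSON
#'
#' The file must contain a JSON array of objects with fields \code{name},
#' \code{hemisphere} (\code{"L"}, \code{"R"} or \code{"NA"}) and
#' \code{is_reference}. Region order in the file is preserved and becomes
#' the canonical matrix order.
#'
#' @param path path to a JSON atlas file.
#' @return A \code{voi_atlas}.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.data.frame(raw)) stop("atlas JSON must be an array of objects",
                                call. = FALSE)
  missing_fields <- setdiff(c("name", "hemisphere", "is_reference"),
                            names(raw))
  if (length(missing_fields)) {
    stop("atlas JSON records lack field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  voi_atlas(raw$name, raw$hemisphere, raw$is_reference)
}

#' Write a VOI atlas to JSON
#' @param atlas a \code{voi_atlas}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  df <- as.data.frame(atlas)[, c("name", "hemisphere", "is_reference")]
  jsonlite::write_json(df, path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Default 53-region mouse VOI atlas
#'
#' A 53-node mouse brain atlas of lateralized volumes of interest with
#' the bilateral medulla flagged as the SUVR reference pool. The full
#' published node set for this kind of mouse FDG-PET connectivity analysis
#' is not publicly enumerated, so this atlas is an illustrative
#' reconstruction: the lateralized region names reported in edge tables of
#' that literature (retained verbatim, including inconsistent spellings
#' such as \code{mamilothalamic_tract_L} next to \code{mammilothalamic_R})
#' padded with mirrored-hemisphere counterparts of one-sided names to reach
#' 53 nodes. Treat it as a template: any user-supplied atlas of the same
#' JSON shape works everywhere.
#'
#' @return A \code{voi_atlas} with 53 regions; \code{medulla_L} and
#'   \code{medulla_R} have \code{is_reference = TRUE}.
#' @export
default_atlas <- function() {
  nm <- c(
    # right-hemisphere names observed in published edge tables
    "olfactory_bulb_R", "optic_nerve_R", "frontal_lobe_R", "midbrain_R",
    "anterior_commissure_R", "parietal_temporal_cortex_R",
    "stria_medullaris_thalami_R", "subcortical_region_parieto_temopal_R",
    "internal_capsule_R", "fasciculus_retroflexus_R", "fornix_R",
    "globus_pallidus_R", "amygdala_R", "medulla_R", "ventricle_sum_sup_R",
    "occipital_cortex_R", "thalamus_R", "ventricle_sum_lat_R",
    "subcortical_region_frontal_R", "striatum_R", "mammilothalamic_R",
    "pons_R", "cerebellum_R",
    # left-hemisphere names observed in published edge tables
    "olfactory_bulb_L", "optic_nerve_L", "frontal_lobe_L", "midbrain_L",
    "anterior_commissure_L", "stria_medullaris_thalami_L",
    "subcortical_region_parieto_temopal_L", "internal_capsule_L",
    "globus_pallidus_L", "left_amygdala_L", "medulla_L",
    "ventricle_sum_sup_L", "ventricle_sum_lat_L",
    "subcortical_region_frontal_L", "striatum_L", "left_pons_L",
    "cerebellum_L", "corpus_callosum_L", "mamilothalamic_tract_L",
    "hippocampus_L", "hypothalamus_L",
    # mirrored counterparts of one-sided names, padding the set to 53
    "parietal_temporal_cortex_L", "fasciculus_retroflexus_L", "fornix_L",
    "occipital_cortex_L", "thalamus_L", "hippocampus_R", "hypothalamus_R",
    "amygdala_L", "pons_L"
  )
  hemi <- ifelse(grepl("_R$", nm), "R", ifelse(grepl("_L$", nm), "L", "NA"))
  voi_atlas(nm, hemi, is_reference = nm %in% c("medulla_L", "medulla_R"))
}

#' @export
print.voi_atlas <- function(x, ...) {
  cat("VOI atlas:", nrow(x), "regions (",
      sum(x$hemisphere == "L"), "L /", sum(x$hemisphere == "R"), "R )\n")
  cat("reference pool:", paste(reference_regions(x), collapse = ", "), "\n")
  invisible(x)
}
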