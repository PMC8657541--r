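#' Construct a subject-by-region uptake table
#'
#' Holds strictly positive regional uptake values (arbitrary activity
#' units) for a cohort of subjects, each carrying a group label, with
#' columns in atlas order.
#'
#' @param values numeric matrix, subjects x regions, strictly positive and
#'   finite. Columns must be named; they are re-ordered to atlas order.
#' @param subject_id character vector of unique subject identifiers.
#' @param group character vector of group labels, one per subject.
#' @param atlas a \code{voi_atlas}; its region order is canonical.
#'
#' @return An object of class \code{uptake_table}: a list with elements
#'   \code{values} (matrix with subject row names and region column names),
#'   \code{subjects} (data frame \code{subject_id}, \code{group}) and
#'   \code{atlas}.
#' @export
uptake_table <- function(values, subject_id, group, atlas) {
  validate_atlas(atlas)
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop("uptake values must have region column names", call. = FALSE)
  }
  missing_cols <- setdiff(atlas$name, colnames(values))
  if (length(missing_cols)) {
    stop("uptake table lacks atlas region column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(colnames(values), atlas$name)
  if (length(extra)) {
    stop("uptake table has column(s) not in the atlas: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  values <- values[, atlas$name, drop = FALSE]   # atlas order wins
  subject_id <- as.character(subject_id)
  group <- as.character(group)
  if (length(subject_id) != nrow(values) || length(group) != nrow(values)) {
    stop("subject_id/group length must equal the number of value rows",
         call. = FALSE)
  }
  if (any(duplicated(subject_id))) {
    stop("subject ids must be unique", call. = FALSE)
  }
  rownames(values) <- subject_id
  tbl <- structure(
    list(values = values,
         subjects = data.frame(subject_id = subject_id, group = group,
                               stringsAsFactors = FALSE),
         atlas = atlas),
    class = "uptake_table"
  )
  validate_uptake(tbl)
  tbl
}

validate_uptake <- function(tbl) {
  v <- tbl$values
  if (!all(is.finite(v))) {
    idx <- which(!is.finite(v), arr.ind = TRUE)[1L, ]
    stop("non-finite uptake for subject '", rownames(v)[idx[1L]],
         "', region '", colnames(v)[idx[2L]], "'", call. = FALSE)
  }
  if (any(v <= 0)) {
    idx <- which(v <= 0, arr.ind = TRUE)[1L, ]
    stop("non-positive uptake for subject '", rownames(v)[idx[1L]],
         "', region '", colnames(v)[idx[2L]], "'", call. = FALSE)
  }
  if (!identical(colnames(v), tbl$atlas$name)) {
    stop("uptake columns out of atlas order", call. = FALSE)
  }
  invisible(tbl)
}

#' Subject counts per group
#' @param table an \code{uptake_table}.
#' @return named integer vector of group sizes.
#' @export
group_sizes <- function(table) {
  tab <- base::table(table$subjects$group)
  stats::setNames(as.integer(tab), names(tab))
}

# Comparison workflows need exactly two groups, each with >= 3 subjects
# (Pearson r across subjects is undefined below n = 3).
check_two_groups <- function(table, group_a, group_b, min_n = 3L) {
  sizes <- group_sizes(table)
  for (g in c(group_a, group_b)) {
    if (!g %in% names(sizes)) {
      stop("group '", g, "' not present in table (groups: ",
           paste(names(sizes), collapse = ", "), ")", call. = FALSE)
    }
    if (sizes[[g]] < min_n) {
      stop("group '", g, "' has ", sizes[[g]],
           " subjects; at least ", min_n, " required", call. = FALSE)
    }
  }
  invisible(sizes[c(group_a, group_b)])
}

#' Read an uptake table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row and columns
#' \code{subject_id}, \code{group}, then one column per atlas region.
#' Region columns may appear in any order; they are matched to the atlas
#' by exact, case-sensitive name and re-ordered to atlas order, so file
#' column order never influences downstream matrices.
#'
#' @param path path to a CSV file.
#' @param atlas a \code{voi_atlas} the table must conform to.
#' @return An \code{uptake_table}.
#' @export
read_uptake <- function(path, atlas) {
  if (!file.exists(path)) stop("uptake file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  for (col in c("subject_id", "group")) {
    if (!col %in% names(df)) {
      stop("uptake CSV lacks required column '", col, "'", call. = FALSE)
    }
  }
  missing_cols <- setdiff(atlas$name, names(df))
  if (length(missing_cols)) {
    stop("uptake CSV lacks region column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(df[, atlas$name, drop = FALSE])
  if (!is.numeric(vals)) {
    stop("region columns must be numeric", call. = FALSE)
  }
  uptake_table(vals, df$subject_id, df$group, atlas)
}

#' Write an uptake table to CSV
#'
#' Values are written with 17 significant digits so that
#' \code{read_uptake(write_uptake(t))} reproduces \code{t} bit for bit.
#'
#' @param table an \code{uptake_table} (or \code{suvr_table}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_uptake <- function(table, path) {
  validate_uptake(table)
  v <- table$values
  header <- paste(c("subject_id", "group", colnames(v)), collapse = ",")
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(table$subjects$subject_id[i], table$subjects$group[i],
            sprintf("%.17g", v[i, ])), collapse = ",")
  }, character(1L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' @export
print.uptake_table <- function(x, ...) {
  sizes <- group_sizes(x)
  cat(class(x)[1L], ":", nrow(x$values), "subjects x",
      ncol(x$values), "regions\n")
  cat("groups:", paste(sprintf("%s (n=%d)", names(sizes), sizes),
                       collapse = ", "), "\n")
  invisible(x)
}
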