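#' Render significant edges as a two-column text table
#'
#' Lays out the significant edges the way edge tables are reported in the
#' FDG-PET connectivity literature: blocked by significance tier (least
#' stringent first), with increased-correlation pairs in the left column
#' and decreased-correlation pairs in the right, region names printed
#' verbatim from the atlas. Within a block, edges are ordered by
#' (region_i, region_j); an empty significant set renders headers only.
#'
#' @param results an \code{edge_results} data frame.
#' @return character vector of lines, invisibly; also printed unless
#'   \code{quiet}.
#' @param quiet suppress printing and just return the lines.
#' @export
render_edge_table <- function(results, quiet = FALSE) {
  thresholds <- attr(results, "thresholds") %||% c(0.05, 0.01, 0.005)
  check_thresholds(thresholds)
  pair <- function(df) {
    if (!nrow(df)) return(character(0))
    df <- df[order(df$region_i, df$region_j), , drop = FALSE]
    paste(df$region_i, df$region_j, sep = " -- ")
  }
  width <- max(45L, nchar(c(results$region_i, results$region_j)) * 2L + 6L)
  fmt <- sprintf("%%-%ds  %%-%ds  %%s", width, width)
  lines <- sprintf(fmt, "Increased Correlation between Two Nodes",
                   "Decreased Correlation between Two Nodes", "p-Value")
  # blocks from least to most stringent; each edge appears in its own tier
  for (th in sort(thresholds, decreasing = TRUE)) {
    blk <- results[results$tier == tier_label(th), , drop = FALSE]
    up <- pair(blk[blk$direction == "increased", , drop = FALSE])
    dn <- pair(blk[blk$direction == "decreased", , drop = FALSE])
    nrow_blk <- max(length(up), length(dn))
    if (nrow_blk == 0L) next
    length(up) <- nrow_blk
    length(dn) <- nrow_blk
    up[is.na(up)] <- ""
    dn[is.na(dn)] <- ""
    tag <- c(tier_label(th), rep("", nrow_blk - 1L))
    lines <- c(lines, sprintf(fmt, up, dn, tag))
  }
  if (!quiet) cat(lines, sep = "\n")
  invisible(lines)
}

# Square matrix -> CSV with a leading region column and region headers.
write_square_csv <- function(m, path) {
  stopifnot(nrow(m) == ncol(m))
  header <- paste(c("region", colnames(m)), collapse = ",")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = ",")
  }, character(1L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

# Data frame -> CSV with doubles at full precision (deterministic bytes).
write_full_csv <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  rows <- do.call(paste, c(cols, sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = ","), rows), con)
  invisible(path)
}

#' Export an edge-results table as GraphML
#'
#' Nodes are the atlas regions (with hemisphere and reference-flag
#' attributes); every tested edge carries \code{delta_z}, \code{p} and
#' \code{tier} attributes, ready for downstream graph tooling.
#'
#' @param results an \code{edge_results} data frame.
#' @param atlas the \code{voi_atlas} the results were computed on.
#' @param path output path (conventionally \code{.graphml}).
#' @return \code{path}, invisibly.
#' @export
write_edges_graphml <- function(results, atlas, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("GraphML export needs the igraph package", call. = FALSE)
  }
  vertices <- data.frame(name = atlas$name, hemisphere = atlas$hemisphere,
                         is_reference = atlas$is_reference,
                         stringsAsFactors = FALSE)
  edges <- data.frame(from = results$region_i, to = results$region_j,
                      delta_z = results$delta_z, p = results$p_value,
                      tier = results$tier, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Run the full connectivity comparison pipeline
#'
#' Orchestrates simulate (optional) -> SUVR -> per-group networks ->
#' permutation edge test, writing a complete artifact set under
#' \code{config$out}: \code{suvr.csv}, \code{r_<group>.csv} and
#' \code{z_<group>.csv} per group, \code{edges.csv},
#' \code{significant_edges.csv} and \code{run_metadata.json} (plus
#' \code{uptake.csv} and \code{ground_truth.json} when simulating, and
#' \code{edges.graphml} when \code{graphml = TRUE}). All output is
#' deterministic text: the same config and seed reproduce byte-identical
#' files. On any stage failure the partial artifacts are removed and an
#' error naming the stage is raised.
#'
#' @param config a named list (or path to a JSON/YAML file holding one)
#'   with elements:
#'   \describe{
#'     \item{out}{output directory (created if absent) — required.}
#'     \item{seed}{integer seed for simulation and permutation — required.}
#'     \item{atlas}{path to an atlas JSON, a \code{voi_atlas}, or omitted
#'       for [default_atlas()].}
#'     \item{uptake}{path to an uptake CSV, or omitted when
#'       \code{simulate} is given.}
#'     \item{simulate}{a \code{cohort_spec}, or a list of arguments for
#'       [cohort_spec()] (minus \code{atlas}), to generate the cohort.}
#'     \item{group_a, group_b}{the ordered comparison pair
#'       (\code{group_a} = mutant by convention); default "KO", "WT".}
#'     \item{reference}{SUVR reference: \code{"atlas-default"} or region
#'       names.}
#'     \item{n_permutations}{default 5000.}
#'     \item{thresholds}{default \code{c(0.05, 0.01, 0.005)}.}
#'     \item{clamp_epsilon}{default \code{1e-6}.}
#'     \item{graphml}{logical, also write \code{edges.graphml}.}
#'   }
#' @return the \code{edge_results} data frame, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$out)) stop("config$out is required", call. = FALSE)
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  group_a <- config$group_a %||% "KO"
  group_b <- config$group_b %||% "WT"
  n_perm <- as.integer(config$n_permutations %||% 5000L)
  thresholds <- as.numeric(config$thresholds %||% c(0.05, 0.01, 0.005))
  clamp <- as.numeric(config$clamp_epsilon %||% 1e-6)
  reference <- config$reference %||% "atlas-default"
  seed <- as.integer(config$seed)

  out_dir <- config$out
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(writer, ..., file) {
    path <- file.path(out_dir, file)
    writer(..., path)
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  result <- tryCatch({
    stage <- "atlas"
    atlas <- if (is.null(config$atlas)) default_atlas()
             else if (inherits(config$atlas, "voi_atlas")) config$atlas
             else read_atlas(config$atlas)

    stage <- "input"
    if (!is.null(config$simulate)) {
      spec <- config$simulate
      if (!inherits(spec, "cohort_spec")) {
        spec$atlas <- atlas
        if (is.null(spec$seed)) spec$seed <- seed
        spec <- do.call(cohort_spec, spec)
      }
      uptake <- simulate_cohort(spec)
      emit(write_uptake, uptake, file = "uptake.csv")
      emit(function(x, path) jsonlite::write_json(
             lapply(x, function(m) round(unname(m), 12)), path,
             auto_unbox = TRUE, digits = NA),
           cohort_ground_truth(uptake), file = "ground_truth.json")
    } else if (!is.null(config$uptake)) {
      uptake <- read_uptake(config$uptake, atlas)
    } else {
      stop("config needs either 'uptake' or 'simulate'", call. = FALSE)
    }

    stage <- "suvr"
    suvr <- compute_suvr(uptake, reference)
    emit(write_uptake, suvr, file = "suvr.csv")

    stage <- "network"
    for (g in c(group_a, group_b)) {
      net <- group_network(suvr, g, clamp)
      emit(write_square_csv, net$r_matrix, file = sprintf("r_%s.csv", g))
      emit(write_square_csv, net$z_matrix, file = sprintf("z_%s.csv", g))
    }

    stage <- "compare"
    res <- permutation_edge_test(suvr, group_a, group_b,
                                 n_permutations = n_perm, seed = seed,
                                 thresholds = thresholds,
                                 clamp_epsilon = clamp,
                                 bh_annotate = isTRUE(config$bh_annotate))
    emit(write_full_csv, as.data.frame(res), file = "edges.csv")
    sig <- significant_edges(res)
    emit(write_full_csv,
         sig[, c("direction", "region_i", "region_j", "tier", "p_value")],
         file = "significant_edges.csv")
    if (isTRUE(config$graphml)) {
      stage <- "graphml"
      emit(write_edges_graphml, res, atlas, file = "edges.graphml")
    }

    stage <- "metadata"
    meta <- list(
      package_version = as.character(utils::packageVersion("metabconn")),
      seed = seed, n_permutations = n_perm,
      group_a = group_a, group_b = group_b,
      thresholds = thresholds, clamp_epsilon = clamp,
      reference_definition = reference_definition(suvr),
      n_regions = n_regions(atlas),
      n_edges = nrow(res),
      group_sizes = as.list(group_sizes(uptake))
    )
    emit(function(x, path) jsonlite::write_json(x, path, auto_unbox = TRUE,
                                                pretty = TRUE, digits = NA),
         meta, file = "run_metadata.json")
    res
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Read a pipeline configuration from JSON or YAML
#' @param path config file; \code{.yml}/\code{.yaml} are parsed with the
#'   yaml package, anything else as JSON.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}
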