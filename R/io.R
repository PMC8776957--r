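# Survey table I/O: six UTF-8 CSV tables per survey (design, taxa,
# cover, trees, litter, soil), missing values as empty fields.

survey_files <- c(design = "design.csv", taxa = "taxa.csv",
                  cover = "cover.csv", trees = "trees.csv",
                  litter = "litter.csv", soil = "soil.csv")

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
}

read_csv_plain <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write a survey dataset to a directory
#'
#' Emits `design.csv`, `taxa.csv`, `cover.csv` (long format:
#' subplot_id, taxon_id, cover), `trees.csv` (branch diameters as a
#' `";"`-delimited column), `litter.csv` and `soil.csv`.
#'
#' @param dataset a `survey_dataset`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_survey <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, survey_files)
  names(paths) <- names(survey_files)
  write_csv_plain(dataset$design, paths["design"])
  write_csv_plain(dataset$taxa, paths["taxa"])
  v <- dataset$cover$values
  nz <- which(v > 0, arr.ind = TRUE)
  cov <- data.frame(
    subplot_id = rownames(v)[nz[, 1]],
    taxon_id = colnames(v)[nz[, 2]],
    cover = v[nz],
    stringsAsFactors = FALSE
  )
  cov <- cov[order(match(cov$subplot_id, rownames(v)),
                   match(cov$taxon_id, colnames(v))), ]
  write_csv_plain(cov, paths["cover"])
  write_csv_plain(dataset$trees, paths["trees"])
  write_csv_plain(dataset$litter, paths["litter"])
  write_csv_plain(dataset$soil, paths["soil"])
  invisible(paths)
}

require_columns <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    data_error("file '%s' is missing column(s): %s", file,
               paste(miss, collapse = ", "))
  }
}

#' Read a survey dataset from a directory
#'
#' Loads and validates the six survey tables written by
#' [write_survey()]: schema (required columns), referential integrity
#' (every record's unit and taxon must exist) and type invariants.
#' A missing or empty trees table loads as zero trees with a warning.
#'
#' @param dir directory holding the survey CSVs.
#' @param config optional [survey_config()] attached to the result (the
#'   plot area defaults to 4 x 25 m^2 when absent).
#' @return A `survey_dataset`.
#' @export
read_survey <- function(dir, config = NULL) {
  paths <- file.path(dir, survey_files)
  names(paths) <- names(survey_files)
  for (f in c("design", "taxa", "cover")) {
    if (!file.exists(paths[f])) {
      data_error("required file missing: %s", paths[f])
    }
  }
  design <- read_csv_plain(paths["design"])
  require_columns(design, c("subplot_id", "plot_id", "cell_id",
                            "forest_type", "island"), "design.csv")
  plot_map <- unique(design[, c("plot_id", "forest_type", "island")])
  dup <- plot_map$plot_id[duplicated(plot_map$plot_id)]
  if (length(dup)) {
    data_error("plot(s) mapped to several island/type cells: %s",
               paste(unique(dup), collapse = ", "))
  }
  taxa <- read_csv_plain(paths["taxa"])
  require_columns(taxa, c("taxon_id", "status", "growth_form", "leaf_type"),
                  "taxa.csv")
  bad_status <- setdiff(unique(taxa$status), c("endemic", "native", "exotic"))
  if (length(bad_status)) {
    data_error("unknown taxon status value(s): %s",
               paste(bad_status, collapse = ", "))
  }
  cov_long <- read_csv_plain(paths["cover"])
  require_columns(cov_long, c("subplot_id", "taxon_id", "cover"),
                  "cover.csv")
  orphan_u <- setdiff(unique(cov_long$subplot_id), design$subplot_id)
  if (length(orphan_u)) {
    data_error("cover.csv references unknown subplot(s): %s",
               paste(orphan_u, collapse = ", "))
  }
  orphan_t <- setdiff(unique(cov_long$taxon_id), taxa$taxon_id)
  if (length(orphan_t)) {
    data_error("cover.csv references unknown taxon id(s): %s",
               paste(orphan_t, collapse = ", "))
  }
  vals <- matrix(0, nrow(design), nrow(taxa),
                 dimnames = list(design$subplot_id, taxa$taxon_id))
  vals[cbind(match(cov_long$subplot_id, design$subplot_id),
             match(cov_long$taxon_id, taxa$taxon_id))] <- cov_long$cover

  trees <- if (file.exists(paths["trees"])) {
    read_csv_plain(paths["trees"])
  } else {
    data.frame()
  }
  if (nrow(trees) == 0) {
    warnf("trees table empty or missing; dataset loads with zero trees")
    trees <- data.frame(tree_id = character(), plot_id = character(),
                        taxon_id = character(), branch_dbh_cm = character(),
                        height_m = numeric(), stringsAsFactors = FALSE)
  } else {
    require_columns(trees, c("tree_id", "plot_id", "taxon_id",
                             "branch_dbh_cm", "height_m"), "trees.csv")
    orphan <- setdiff(unique(trees$plot_id), design$plot_id)
    if (length(orphan)) {
      data_error("trees.csv references unknown plot(s): %s",
                 paste(orphan, collapse = ", "))
    }
    orphan <- setdiff(unique(trees$taxon_id), taxa$taxon_id)
    if (length(orphan)) {
      data_error("trees.csv references unknown taxon id(s): %s",
                 paste(orphan, collapse = ", "))
    }
    if (any(trees$height_m <= 0)) data_error("tree heights must be > 0")
    if (any(vapply(parse_branches(trees$branch_dbh_cm),
                   function(d) any(!is.finite(d)) || any(d <= 0),
                   logical(1)))) {
      data_error("branch diameters must be positive numbers")
    }
  }
  read_plot_table <- function(key, cols) {
    if (!file.exists(paths[key])) return(NULL)
    df <- read_csv_plain(paths[key])
    if (nrow(df) == 0) return(df)
    require_columns(df, cols, survey_files[key])
    orphan <- setdiff(unique(df$plot_id), design$plot_id)
    if (length(orphan)) {
      data_error("%s references unknown plot(s): %s", survey_files[key],
                 paste(orphan, collapse = ", "))
    }
    df
  }
  litter <- read_plot_table("litter", c("plot_id", "dry_mass_g_per_m2",
                                        "carbon_conc_gC_per_kg"))
  soil <- read_plot_table("soil", c("plot_id", "bulk_density_kg_per_m3",
                                    "organic_matter_g_per_kg", "depth_m"))
  structure(
    list(
      taxa = taxa,
      cover = abundance_matrix(vals, "subplot"),
      trees = trees,
      litter = litter %||% data.frame(),
      soil = soil %||% data.frame(),
      design = design,
      config = config %||% list(plot_area_m2 = 100)
    ),
    class = "survey_dataset"
  )
}

#' Write / read a labelled square distance matrix as CSV
#'
#' @param dist a [distance_matrix()].
#' @param path CSV path.
#' @return `write_distance_csv` the path invisibly; `read_distance_csv`
#'   a [distance_matrix()].
#' @export
write_distance_csv <- function(dist, path) {
  m <- as.matrix(dist)
  df <- data.frame(unit = rownames(m), m, check.names = FALSE)
  write_csv_plain(df, path)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$unit
  colnames(m) <- names(df)[-1]
  distance_matrix(m)
}
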