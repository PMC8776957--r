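# Dendrometric structural diversity: density, branch-wise basal area,
# basal-area Shannon indices and height summaries per plot.

#' Basal area of one tree from its branch diameters
#'
#' `BA = sum over branches of (d/100)^2 * pi / 4` in m^2 (diameters in
#' cm). Every branch of a retained tree counts.
#'
#' @param branch_dbh_cm numeric vector of branch diameters (cm), all > 0.
#' @return Basal area in m^2.
#' @export
#' @examples
#' tree_basal_area(10)        # 0.007854 m^2
#' tree_basal_area(c(10, 10)) # doubled
tree_basal_area <- function(branch_dbh_cm) {
  if (length(branch_dbh_cm) == 0) data_error("a tree needs >= 1 branch")
  assert_numeric_vector(branch_dbh_cm, "branch_dbh_cm")
  if (any(branch_dbh_cm <= 0)) data_error("branch diameters must be > 0")
  sum((branch_dbh_cm / 100)^2 * pi / 4)
}

#' Stand density
#'
#' Trees per hectare from a plot count: `n * 10000 / plot_area_m2`.
#'
#' @param n_trees number of retained trees.
#' @param plot_area_m2 sampled plot area in m^2.
#' @return Trees per hectare.
#' @export
stand_density <- function(n_trees, plot_area_m2) {
  if (plot_area_m2 <= 0) data_error("plot area must be positive")
  n_trees * 10000 / plot_area_m2
}

# DBH >= 2.5 cm retention rule: a tree is kept iff its largest branch
# reaches the measurement threshold; applied before every statistic.
retain_trees <- function(trees, threshold_cm = 2.5) {
  if (nrow(trees) == 0) return(trees)
  keep <- vapply(parse_branches(trees$branch_dbh_cm), function(d) {
    max(d) >= threshold_cm
  }, logical(1))
  trees[keep, , drop = FALSE]
}

# branch diameters are stored as a ";"-delimited list column
parse_branches <- function(x) {
  if (is.list(x)) return(lapply(x, as.numeric))
  lapply(strsplit(as.character(x), ";", fixed = TRUE), as.numeric)
}

#' Structural summary of one plot
#'
#' Applies the DBH >= 2.5 cm retention filter, sums branch-wise basal
#' area per taxon, and computes density, basal-area Shannon diversity and
#' evenness (via the package's diversity indices on BA shares) and height
#' summaries.
#'
#' @param trees data frame of tree records for a single plot: `tree_id`,
#'   `plot_id`, `taxon_id`, `branch_dbh_cm` (numeric list column or
#'   `";"`-delimited string), `height_m`.
#' @param plot_area_m2 plot area in m^2.
#' @param dbh_threshold_cm retention threshold, cm.
#' @return One-row data frame: `plot_id`, `n_trees`, `density_per_ha`,
#'   `ba_m2` (per plot), `ba_m2_ha` (scaled per hectare), `ba_gamma`,
#'   `ba_shannon`, `ba_evenness`, `height_mean_m`, `height_sd_m`,
#'   `height_max_m`; attribute `ba_per_taxon` (named vector, m^2 per
#'   plot).
#' @export
stand_structure <- function(trees, plot_area_m2 = 100,
                            dbh_threshold_cm = 2.5) {
  plot_id <- if (nrow(trees)) unique(trees$plot_id) else NA_character_
  if (length(plot_id) > 1) {
    data_error("stand_structure expects trees from a single plot, got: %s",
               paste(plot_id, collapse = ", "))
  }
  kept <- retain_trees(trees, dbh_threshold_cm)
  if (nrow(kept) == 0) {
    if (nrow(trees)) {
      warnf("plot '%s': no trees reach DBH %.1f cm", plot_id,
            dbh_threshold_cm)
    }
    out <- data.frame(
      plot_id = plot_id, n_trees = 0L, density_per_ha = 0, ba_m2 = 0,
      ba_m2_ha = 0, ba_gamma = 0L, ba_shannon = 0, ba_evenness = 0,
      height_mean_m = NA_real_, height_sd_m = NA_real_,
      height_max_m = NA_real_, stringsAsFactors = FALSE
    )
    attr(out, "ba_per_taxon") <- numeric(0)
    return(out)
  }
  ba_tree <- vapply(parse_branches(kept$branch_dbh_cm), tree_basal_area,
                    numeric(1))
  ba_taxon <- tapply(ba_tree, kept$taxon_id, sum)
  ba_taxon <- ba_taxon[ba_taxon > 0]
  H <- shannon(as.numeric(ba_taxon))
  S <- richness(as.numeric(ba_taxon))
  out <- data.frame(
    plot_id = plot_id,
    n_trees = nrow(kept),
    density_per_ha = stand_density(nrow(kept), plot_area_m2),
    ba_m2 = sum(ba_tree),
    ba_m2_ha = sum(ba_tree) * 10000 / plot_area_m2,
    ba_gamma = S,
    ba_shannon = H,
    ba_evenness = evenness(H, S),
    height_mean_m = mean(kept$height_m),
    height_sd_m = if (nrow(kept) > 1) stats::sd(kept$height_m) else NA_real_,
    height_max_m = max(kept$height_m),
    stringsAsFactors = FALSE
  )
  attr(out, "ba_per_taxon") <- as.numeric(ba_taxon)
  names(attr(out, "ba_per_taxon")) <- names(ba_taxon)
  out
}

#' Structural summaries for every plot of a survey
#'
#' @param dataset a `survey_dataset` (or list with `trees`, `design`,
#'   `config`).
#' @return Data frame with one [stand_structure()] row per plot, joined
#'   to the design's grouping columns; plots without trees get zero
#'   density and basal area.
#' @export
survey_structure <- function(dataset) {
  key <- dataset$design[!duplicated(dataset$design$plot_id),
                        c("plot_id", "cell_id", "forest_type", "island")]
  area <- dataset$config$plot_area_m2 %||% 100
  rows <- lapply(key$plot_id, function(p) {
    tr <- dataset$trees[dataset$trees$plot_id == p, , drop = FALSE]
    st <- suppressWarnings(stand_structure(tr, area))
    st$plot_id <- p
    st
  })
  out <- do.call(rbind, rows)
  merge(key, out, by = "plot_id", sort = FALSE)
}
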