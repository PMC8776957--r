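# Sampling-unit x taxon abundance container used throughout the package.

#' Abundance matrix
#'
#' A sampling-unit x taxon table of non-negative cover or count values
#' with a declared unit level (`"subplot"` or `"plot"`).
#'
#' @param values numeric matrix, units in rows (rownames = unit ids),
#'   taxa in columns (colnames = taxon ids); all entries finite and >= 0.
#' @param level `"subplot"` or `"plot"`.
#' @return An object of class `abundance_matrix` with elements `values`,
#'   `units`, `taxa` and `level`.
#' @export
#' @examples
#' m <- matrix(c(1, 0, 2, 3), 2, 2,
#'             dimnames = list(c("u1", "u2"), c("t1", "t2")))
#' abundance_matrix(m, "plot")
abundance_matrix <- function(values, level = c("subplot", "plot")) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values)) {
    data_error("abundance values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    data_error("abundance matrix needs unit rownames and taxon colnames")
  }
  if (anyDuplicated(rownames(values))) {
    data_error("duplicate unit ids in abundance matrix")
  }
  if (anyDuplicated(colnames(values))) {
    data_error("duplicate taxon ids in abundance matrix")
  }
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0)) {
    data_error("abundance values must be finite and non-negative")
  }
  structure(
    list(values = values, units = rownames(values),
         taxa = colnames(values), level = level),
    class = "abundance_matrix"
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("Abundance matrix: %d %ss x %d taxa (%.1f%% non-zero)\n",
              length(x$units), x$level, length(x$taxa),
              100 * mean(x$values > 0)))
  invisible(x)
}

#' Aggregate subplot cover to the plot level
#'
#' Plot-level composition is the sum of the plot's subplot covers; this is
#' the unit used for clustering, ordination, PERMANOVA and IndVal.
#'
#' @param cover an [abundance_matrix()] at subplot level.
#' @param design design table with `subplot_id` and `plot_id` columns.
#' @return An [abundance_matrix()] at plot level, rows in the design's
#'   plot order.
#' @export
aggregate_to_plots <- function(cover, design) {
  if (!inherits(cover, "abundance_matrix")) {
    data_error("'cover' must be an abundance_matrix")
  }
  if (cover$level != "subplot") {
    data_error("'cover' is already at the %s level", cover$level)
  }
  idx <- match(cover$units, design$subplot_id)
  if (anyNA(idx)) {
    data_error("units missing from design: %s",
               paste(cover$units[is.na(idx)], collapse = ", "))
  }
  plot_of <- design$plot_id[idx]
  plots <- unique(design$plot_id)
  vals <- rowsum(cover$values, group = plot_of, reorder = FALSE)
  vals <- vals[match(plots, rownames(vals)), , drop = FALSE]
  rownames(vals) <- plots
  abundance_matrix(vals, level = "plot")
}
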