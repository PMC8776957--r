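# Taxonomic diversity indices and additive hierarchical partitioning of
# gamma diversity.

#' Species richness
#'
#' Number of taxa with strictly positive abundance.
#'
#' @param abundances numeric vector of non-negative abundances.
#' @return Integer count of positive entries.
#' @export
#' @examples
#' richness(c(1.0, 0, 2.5))  # 2
richness <- function(abundances) {
  assert_numeric_vector(abundances, "abundances")
  if (any(abundances < 0)) data_error("abundances must be non-negative")
  sum(abundances > 0)
}

#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive abundance, with
#' `p_i` the relative abundances. Reported in nats.
#'
#' @param abundances numeric vector of non-negative abundances with at
#'   least one positive entry.
#' @return Shannon H in `[0, log(S)]`.
#' @export
#' @examples
#' shannon(c(1, 1, 1, 1))  # log(4)
shannon <- function(abundances) {
  assert_numeric_vector(abundances, "abundances")
  if (any(abundances < 0)) data_error("abundances must be non-negative")
  x <- abundances[abundances > 0]
  if (length(x) == 0) data_error("shannon undefined for an all-zero vector")
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Pielou evenness
#'
#' `E = H / log(S)` for `S >= 2`; defined as 0 for a single-species
#' community so the value always exists.
#'
#' @param H Shannon diversity in nats.
#' @param S species richness (>= 1).
#' @return Evenness in `[0, 1]`.
#' @export
evenness <- function(H, S) {
  if (S < 1) data_error("richness must be >= 1")
  if (H < 0) data_error("Shannon H must be non-negative")
  if (S == 1) {
    if (H > 1e-9) data_error("H > 0 is inconsistent with S = 1")
    return(0)
  }
  if (H > log(S) + 1e-9) {
    data_error("H = %g exceeds log(S) = %g: inconsistent inputs", H, log(S))
  }
  min(H / log(S), 1)
}

#' Per-plot diversity from subplot cover
#'
#' For each plot: alpha = mean subplot richness, gamma = richness of the
#' pooled (summed) subplot abundances, beta = gamma - alpha, and Shannon
#' H / Pielou evenness on the pooled plot abundances.
#'
#' @param cover an [abundance_matrix()] at subplot level.
#' @param design design table mapping `subplot_id` to `plot_id` (and
#'   carrying `forest_type` / `island` when present, which are joined to
#'   the output).
#' @return Data frame with one row per plot: `plot_id`, `alpha`, `gamma`,
#'   `beta`, `shannon`, `evenness` (plus design grouping columns).
#' @export
plot_diversity <- function(cover, design) {
  if (!inherits(cover, "abundance_matrix") || cover$level != "subplot") {
    data_error("'cover' must be a subplot-level abundance_matrix")
  }
  idx <- match(cover$units, design$subplot_id)
  if (anyNA(idx)) {
    data_error("subplots missing from design: %s",
               paste(cover$units[is.na(idx)], collapse = ", "))
  }
  plot_of <- design$plot_id[idx]
  plots <- unique(design$plot_id)
  res <- lapply(plots, function(p) {
    rows <- cover$values[plot_of == p, , drop = FALSE]
    a <- mean(apply(rows, 1, richness))
    pooled <- colSums(rows)
    g <- richness(pooled)
    if (g == 0) {
      warnf("plot '%s' has no recorded taxa; diversity set to zero", p)
      return(data.frame(plot_id = p, alpha = 0, gamma = 0, beta = 0,
                        shannon = 0, evenness = 0,
                        stringsAsFactors = FALSE))
    }
    H <- shannon(pooled)
    data.frame(plot_id = p, alpha = a, gamma = g, beta = g - a,
               shannon = H, evenness = evenness(H, g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  extra <- intersect(c("cell_id", "forest_type", "island"), names(design))
  if (length(extra)) {
    key <- design[!duplicated(design$plot_id), c("plot_id", extra)]
    out <- merge(out, key, by = "plot_id", sort = FALSE)
  }
  out
}

#' Additive partition of gamma diversity over a nested hierarchy
#'
#' Decomposes total (gamma) richness into the mean richness at each
#' hierarchy level plus the successive between-level differences:
#' `alpha_k` is the unweighted mean richness of the level-k groups (each
#' group's richness computed from its pooled abundances),
#' `beta_k = alpha_{k+1} - alpha_k` and `beta_L = gamma - alpha_L`, so
#' that `gamma = alpha_1 + sum(beta)` exactly.
#'
#' @param cover an [abundance_matrix()].
#' @param hierarchy data frame of grouping columns for the matrix's
#'   units, ordered from the finest level (first column; one row per
#'   unit, typically the unit id itself) upward. Columns must be nested:
#'   every group at level k lies inside exactly one group at level k+1.
#' @param weighted if `TRUE`, level means weight each group by its number
#'   of base units instead of equally.
#' @return An object of class `diversity_partition`: list with `levels`,
#'   `alpha`, `beta`, `gamma`, and `percent` (each alpha_1/beta component
#'   as a share of gamma).
#' @export
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 0, 1), 2, 3,
#'             dimnames = list(c("u1", "u2"), c("a", "b", "c")))
#' h <- data.frame(unit = c("u1", "u2"), all = "tot")
#' additive_partition(abundance_matrix(m, "plot"), h)
additive_partition <- function(cover, hierarchy, weighted = FALSE) {
  if (!inherits(cover, "abundance_matrix")) {
    data_error("'cover' must be an abundance_matrix")
  }
  if (nrow(hierarchy) != length(cover$units)) {
    data_error("hierarchy must have one row per sampling unit")
  }
  L <- ncol(hierarchy)
  if (L < 1) data_error("hierarchy needs at least one level")
  # nestedness: each level-k group maps to exactly one level-(k+1) group
  if (L > 1) {
    for (k in seq_len(L - 1)) {
      tab <- unique(hierarchy[, c(k, k + 1)])
      dup <- tab[[1]][duplicated(tab[[1]])]
      if (length(dup)) {
        data_error(
          "hierarchy not nested: level-%d group(s) %s belong to several level-%d groups",
          k, paste(unique(dup), collapse = ", "), k + 1
        )
      }
    }
  }
  vals <- cover$values
  alpha <- numeric(L)
  for (k in seq_len(L)) {
    g <- as.character(hierarchy[[k]])
    pooled <- rowsum(vals, group = g, reorder = FALSE)
    rich <- apply(pooled, 1, richness)
    if (weighted) {
      w <- as.vector(table(g)[rownames(pooled)])
      alpha[k] <- sum(rich * w) / sum(w)
    } else {
      alpha[k] <- mean(rich)
    }
  }
  gamma <- richness(colSums(vals))
  beta <- c(diff(alpha), gamma - alpha[L])
  comp <- c(alpha[1], beta)
  names(comp) <- c("alpha_1", paste0("beta_", seq_len(L)))
  structure(
    list(
      levels = names(hierarchy),
      alpha = stats::setNames(alpha, paste0("alpha_", seq_len(L))),
      beta = stats::setNames(beta, paste0("beta_", seq_len(L))),
      gamma = gamma,
      percent = 100 * comp / gamma,
      weighted = weighted,
      log_base = "natural (nats)"
    ),
    class = "diversity_partition"
  )
}

#' Partition components from stated level means
#'
#' Applies the additive-partition identities to externally supplied level
#' means: `beta_k = alpha_{k+1} - alpha_k`, `beta_L = gamma - alpha_L`,
#' reconstructed `gamma = alpha_1 + sum(beta)`, and percentage shares of
#' gamma. Useful for checking published partition tables.
#'
#' @param alpha numeric vector of level means `alpha_1..alpha_L`.
#' @param gamma total richness.
#' @return A `diversity_partition` object.
#' @export
#' @examples
#' partition_from_means(c(10.2, 13.9, 59.0), 108.0)
partition_from_means <- function(alpha, gamma) {
  assert_numeric_vector(alpha, "alpha")
  if (any(diff(alpha) < 0)) data_error("alpha means must be non-decreasing")
  if (gamma < alpha[length(alpha)]) {
    data_error("gamma must be at least the top-level alpha")
  }
  L <- length(alpha)
  beta <- c(diff(alpha), gamma - alpha[L])
  comp <- c(alpha[1], beta)
  names(comp) <- c("alpha_1", paste0("beta_", seq_len(L)))
  structure(
    list(
      levels = paste0("level_", seq_len(L)),
      alpha = stats::setNames(alpha, paste0("alpha_", seq_len(L))),
      beta = stats::setNames(beta, paste0("beta_", seq_len(L))),
      gamma = gamma,
      percent = 100 * comp / gamma,
      weighted = FALSE,
      log_base = "natural (nats)"
    ),
    class = "diversity_partition"
  )
}

#' @export
print.diversity_partition <- function(x, digits = 3, ...) {
  cat("Additive diversity partition (", length(x$alpha), " levels)\n",
      sep = "")
  cat("  alpha:", paste(sprintf("%s=%.*f", names(x$alpha), digits, x$alpha),
                        collapse = "  "), "\n")
  cat("  beta: ", paste(sprintf("%s=%.*f", names(x$beta), digits, x$beta),
                        collapse = "  "), "\n")
  cat(sprintf("  gamma: %.*f\n", digits, x$gamma))
  cat("  percent of gamma:",
      paste(sprintf("%s=%.1f%%", names(x$percent), x$percent),
            collapse = "  "), "\n")
  invisible(x)
}

#' Default partition hierarchy for a survey
#'
#' Builds the hierarchy table plot < island x type cell < forest type for
#' a plot-level abundance matrix, the package's default reading of the
#' three spatial scales.
#'
#' @param cover plot-level [abundance_matrix()].
#' @param design survey design table.
#' @return Data frame with columns `plot`, `cell`, `type`, one row per
#'   matrix unit.
#' @export
default_hierarchy <- function(cover, design) {
  key <- design[!duplicated(design$plot_id),
                c("plot_id", "cell_id", "forest_type")]
  idx <- match(cover$units, key$plot_id)
  if (anyNA(idx)) data_error("units missing from design")
  data.frame(
    plot = key$plot_id[idx],
    cell = key$cell_id[idx],
    type = key$forest_type[idx],
    stringsAsFactors = FALSE
  )
}
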