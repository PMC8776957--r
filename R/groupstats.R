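# Group-comparison machinery behind the summary tables: two-way ANOVA,
# Tukey HSD post-hoc, compact letter displays and cell summaries.

#' Two-way crossed ANOVA with interaction
#'
#' Fixed-effects ANOVA `y ~ A * B`. Balanced designs use the classical
#' (sequential) decomposition; unbalanced data fall back to Type-II sums
#' of squares, which coincide with the classical ones when balanced.
#' Shapiro-Wilk (residual normality) and Levene (homogeneity across
#' cells) diagnostics are attached but never gate the computation.
#'
#' @param values numeric response.
#' @param factor_a,factor_b crossed factors, >= 2 levels each.
#' @return Object of class `anova_result`: data frame with term, df, SS,
#'   MS, F and p rows for A, B, A:B and residuals; attributes
#'   `shapiro_p` and `levene_p`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  assert_numeric_vector(values, "values")
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    data_error("both factors need >= 2 levels")
  }
  cells <- table(a, b)
  if (any(cells == 0)) {
    data_error("empty design cell(s): %s",
               paste(which(cells == 0, arr.ind = TRUE)[, 1], collapse = ", "))
  }
  df <- data.frame(y = values, a = a, b = b)
  fit <- stats::lm(y ~ a * b, data = df)
  balanced <- length(unique(as.vector(cells))) == 1
  if (balanced) {
    tab <- stats::anova(fit)
  } else {
    tab <- car::Anova(fit, type = 2)
  }
  rows <- match(c("a", "b", "a:b", "Residuals"), rownames(tab))
  out <- data.frame(
    term = c("A", "B", "A:B", "Residuals"),
    df = tab$Df[rows],
    SS = tab[["Sum Sq"]][rows],
    MS = tab[["Sum Sq"]][rows] / tab$Df[rows],
    F = c(tab[["F value"]][rows[1:3]], NA_real_),
    p = c(tab[["Pr(>F)"]][rows[1:3]], NA_real_),
    stringsAsFactors = FALSE
  )
  res <- stats::residuals(fit)
  attr(out, "shapiro_p") <- tryCatch(
    stats::shapiro.test(res)$p.value, error = function(e) NA_real_)
  attr(out, "levene_p") <- levene_p(values, interaction(a, b))
  attr(out, "fit") <- fit
  class(out) <- c("anova_result", "data.frame")
  out
}

# Brown-Forsythe variant: one-way ANOVA on absolute deviations from the
# cell medians.
levene_p <- function(values, groups) {
  g <- factor(groups)
  med <- tapply(values, g, stats::median)
  z <- abs(values - med[g])
  if (stats::sd(z) == 0) return(NA_real_)
  stats::anova(stats::lm(z ~ g))[["Pr(>F)"]][1]
}

#' Tukey HSD all-pairs comparison
#'
#' Studentized-range comparison of group means with pooled residual
#' variance: for groups i, j the statistic is
#' `q = |m_i - m_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))` and the adjusted p
#' comes from the studentized-range distribution with the pooled residual
#' degrees of freedom. Groups with a single observation are excluded with
#' a warning.
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups with n >= 2 after exclusion).
#' @param alpha significance level for the `significant` flag.
#' @return Object of class `tukey_result`: data frame with `group_i`,
#'   `group_j`, `diff` (mean_j - mean_i), `se`, `q`, `p_adj`,
#'   `significant`; attribute `means` (named group means).
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  assert_numeric_vector(values, "values")
  n_by <- table(g)
  if (any(n_by < 2)) {
    drop <- names(n_by)[n_by < 2]
    warnf("excluding single-observation group(s): %s",
          paste(drop, collapse = ", "))
    keep <- !(g %in% drop)
    values <- values[keep]
    g <- droplevels(g[keep])
    n_by <- table(g)
  }
  k <- nlevels(g)
  if (k < 2) data_error("Tukey needs >= 2 groups with n >= 2")
  means <- tapply(values, g, mean)
  n <- length(values)
  mse <- sum(tapply(values, g, function(x) sum((x - mean(x))^2))) / (n - k)
  df_res <- n - k
  pairs <- utils::combn(levels(g), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(m) {
    i <- pairs[1, m]; j <- pairs[2, m]
    se <- sqrt(mse / 2 * (1 / n_by[[i]] + 1 / n_by[[j]]))
    diffij <- means[[j]] - means[[i]]
    q <- if (se > 0) abs(diffij) / se else if (diffij == 0) 0 else Inf
    p <- if (is.finite(q)) {
      stats::ptukey(q, nmeans = k, df = df_res, lower.tail = FALSE)
    } else 0
    if (se == 0 && diffij == 0) p <- 1
    data.frame(group_i = i, group_j = j, diff = diffij, se = se, q = q,
               p_adj = p, stringsAsFactors = FALSE)
  }))
  out$significant <- out$p_adj < alpha
  attr(out, "means") <- means
  attr(out, "alpha") <- alpha
  class(out) <- c("tukey_result", "data.frame")
  out
}

#' Compact letter display
#'
#' Insertion-algorithm letter assignment from a pairwise significance
#' table: two groups share a letter if and only if their comparison is
#' non-significant. Letters are ordered by ascending group mean; the
#' letter count is not guaranteed minimal, but the sharing invariant
#' always holds (non-transitive patterns are handled by letter
#' multiplicity).
#'
#' @param pairwise a [tukey_hsd()] result, or any data frame with
#'   `group_i`, `group_j` and `significant` columns.
#' @param means optional named group means used to order letters
#'   (defaults to the `means` attribute of `pairwise`).
#' @return Named character vector: group id -> letter string.
#' @export
#' @examples
#' pw <- data.frame(group_i = c("g1", "g1", "g2"),
#'                  group_j = c("g2", "g3", "g3"),
#'                  significant = c(FALSE, TRUE, FALSE))
#' letter_display(pw, means = c(g1 = 1, g2 = 2, g3 = 3))
letter_display <- function(pairwise, means = attr(pairwise, "means")) {
  need <- c("group_i", "group_j", "significant")
  if (!all(need %in% names(pairwise))) {
    data_error("pairwise table needs columns %s", paste(need, collapse = ", "))
  }
  groups <- unique(c(pairwise$group_i, pairwise$group_j))
  if (!is.null(means)) {
    groups <- groups[order(means[groups])]
  }
  sets <- list(groups)
  for (m in seq_len(nrow(pairwise))) {
    if (!isTRUE(pairwise$significant[m])) next
    i <- pairwise$group_i[m]
    j <- pairwise$group_j[m]
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    sets <- absorb_subsets(new_sets)
  }
  sets <- sets[lengths(sets) > 0]
  # order letters by the first (lowest-mean) group they contain
  first_pos <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first_pos)]
  letters_of <- stats::setNames(rep("", length(groups)), groups)
  for (li in seq_along(sets)) {
    lab <- compact_letter(li)
    for (gname in sets[[li]]) {
      letters_of[gname] <- paste0(letters_of[gname], lab)
    }
  }
  letters_of
}

# drop duplicate sets and sets properly contained in another
absorb_subsets <- function(sets) {
  sets <- unique(lapply(sets, sort))
  keep <- rep(TRUE, length(sets))
  for (u in seq_along(sets)) {
    for (v in seq_along(sets)) {
      if (u != v && keep[v] &&
          length(sets[[u]]) < length(sets[[v]]) &&
          all(sets[[u]] %in% sets[[v]])) {
        keep[u] <- FALSE
      }
    }
  }
  sets[keep]
}

# a..z then A..Z; beyond 52 letter sets fall back to digit markers
compact_letter <- function(i) {
  c(letters, LETTERS, as.character(0:9))[i]
}

#' Cell means and standard errors
#'
#' @param values numeric response.
#' @param factor_a,factor_b crossed factors.
#' @return Data frame with one row per A x B cell: `a`, `b`, `n`, `mean`,
#'   `se` (`NA` for n < 2, `NA` mean for empty cells).
#' @export
cell_summary <- function(values, factor_a, factor_b) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  grid <- expand.grid(a = levels(a), b = levels(b),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- a == grid$a[i] & b == grid$b[i]
    x <- values[sel]
    data.frame(
      a = grid$a[i], b = grid$b[i], n = sum(sel),
      mean = if (length(x)) mean(x) else NA_real_,
      se = std_error(x),
      stringsAsFactors = FALSE
    )
  }))
  out
}

#' Full group comparison for one metric
#'
#' Convenience wrapper reproducing the summary-table workflow: two-way
#' ANOVA (island x forest type), Tukey HSD over the 9 island x type cells
#' treated as groups, a compact letter display, and cell means/standard
#' errors with letters attached.
#'
#' @param values numeric response (one per plot).
#' @param factor_a,factor_b crossed factors (e.g. forest type and
#'   island).
#' @param alpha significance level.
#' @return List with `anova`, `tukey`, `letters` and `cells` (cell
#'   summary with a `letters` column).
#' @export
compare_groups <- function(values, factor_a, factor_b, alpha = 0.05) {
  # degenerate single-level second factor: one-way comparison on A
  if (length(unique(factor_b)) < 2) {
    g <- factor(factor_a)
    fit <- stats::lm(values ~ g)
    ref <- stats::anova(fit)
    an <- data.frame(
      term = c("A", "Residuals"),
      df = ref$Df, SS = ref[["Sum Sq"]],
      MS = ref[["Sum Sq"]] / ref$Df,
      F = c(ref[["F value"]][1], NA_real_),
      p = c(ref[["Pr(>F)"]][1], NA_real_),
      stringsAsFactors = FALSE
    )
    class(an) <- c("anova_result", "data.frame")
    tk <- tukey_hsd(values, interaction(g, factor(factor_b), sep = ":"),
                    alpha = alpha)
    lt <- letter_display(tk)
    cells <- cell_summary(values, factor_a, factor_b)
    cells$letters <- lt[paste(cells$a, cells$b, sep = ":")]
    return(list(anova = an, tukey = tk, letters = lt, cells = cells))
  }
  an <- two_way_anova(values, factor_a, factor_b)
  cell <- interaction(factor(factor_a), factor(factor_b), sep = ":")
  tk <- tukey_hsd(values, cell, alpha = alpha)
  lt <- letter_display(tk)
  cells <- cell_summary(values, factor_a, factor_b)
  cells$letters <- lt[paste(cells$a, cells$b, sep = ":")]
  list(anova = an, tukey = tk, letters = lt, cells = cells)
}
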