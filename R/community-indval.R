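# Indicator species analysis (Dufrene-Legendre IndVal, single groups).

# taxon-wise mean abundance per group (rows = groups in gl order)
group_means <- function(x, groups, gl) {
  m <- matrix(0, length(gl), ncol(x), dimnames = list(gl, colnames(x)))
  for (g in gl) m[g, ] <- colMeans(x[groups == g, , drop = FALSE])
  m
}

# fraction of each group's units where the taxon is present
group_occupancy <- function(x, groups, gl) {
  m <- matrix(0, length(gl), ncol(x), dimnames = list(gl, colnames(x)))
  for (g in gl) m[g, ] <- colMeans((x[groups == g, , drop = FALSE] > 0) * 1)
  m
}

indval_components <- function(x, groups, gl) {
  means <- group_means(x, groups, gl)
  A <- sweep(means, 2, colSums(means), "/")
  B <- group_occupancy(x, groups, gl)
  list(A = A, B = B, indval = 100 * A * B)
}

#' Indicator value (IndVal) analysis
#'
#' For each taxon t and group g: specificity
#' `A_tg = mean abundance of t in g / sum over groups of mean abundances`
#' and fidelity `B_tg = fraction of group-g units where t is present`;
#' `IndVal_tg = 100 * A_tg * B_tg`. Each taxon is reported for its best
#' (argmax) group; significance comes from permuting group labels, the
#' permutation statistic being the taxon's maximum-group IndVal, with
#' the add-one p estimator. Taxa at or above `threshold` percent with
#' `p < alpha` are flagged as characteristic indicator species.
#'
#' @param cover plot-level [abundance_matrix()] (or matrix).
#' @param groups group label per unit (>= 2 groups, each non-empty).
#' @param n_perm number of permutations (default 999; 0 skips the test).
#' @param seed integer seed.
#' @param threshold characteristic-species IndVal threshold, percent.
#' @param alpha significance level for the characteristic flag.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return Object of class `indval_result`: data frame with one row per
#'   taxon (`taxon_id`, `group`, `A`, `B`, `indval`, `p`,
#'   `characteristic`) sorted by decreasing IndVal; attribute
#'   `indval_matrix` holds the full group x taxon IndVal table.
#' @export
#' @examples
#' m <- rbind(p1 = c(a = 5, b = 0), p2 = c(a = 4, b = 0),
#'            p3 = c(a = 0, b = 2), p4 = c(a = 0, b = 3))
#' indval(m, c("g1", "g1", "g2", "g2"), n_perm = 0)
indval <- function(cover, groups, n_perm = 999, seed = 1L,
                   threshold = 70, alpha = 0.05,
                   p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  x <- cover_values(cover)
  groups <- as.character(groups)
  if (length(groups) != nrow(x)) data_error("one group label per unit required")
  gl <- unique(groups)
  if (length(gl) < 2) data_error("IndVal needs at least 2 groups")

  absent <- colSums(x) == 0
  if (any(absent)) {
    warnf("excluding %d taxa absent everywhere: %s", sum(absent),
          paste(utils::head(colnames(x)[absent], 5), collapse = ", "))
    x <- x[, !absent, drop = FALSE]
  }
  if (ncol(x) == 0) data_error("no taxa with positive abundance")

  obs <- indval_components(x, groups, gl)
  best_idx <- apply(obs$indval, 2, which.max)
  sel <- cbind(best_idx, seq_len(ncol(x)))
  best_iv <- obs$indval[sel]

  p <- rep(NA_real_, ncol(x))
  if (n_perm > 0) {
    exceed <- integer(ncol(x))
    with_seed(derive_seed(seed, "indval"), {
      for (b in seq_len(n_perm)) {
        gp <- groups[sample.int(length(groups))]
        ivp <- indval_components(x, gp, gl)$indval
        exceed <- exceed + (apply(ivp, 2, max) >= best_iv - 1e-9)
      }
    })
    p <- (1 + exceed) / (1 + n_perm)
    if (p_adjust == "holm") p <- stats::p.adjust(p, "holm")
  }

  out <- data.frame(
    taxon_id = colnames(x),
    group = gl[best_idx],
    A = obs$A[sel],
    B = obs$B[sel],
    indval = best_iv,
    p = p,
    stringsAsFactors = FALSE
  )
  out$characteristic <- !is.na(out$p) & out$indval >= threshold & out$p < alpha
  out <- out[order(-out$indval), ]
  rownames(out) <- NULL
  attr(out, "indval_matrix") <- obs$indval
  attr(out, "n_perm") <- n_perm
  attr(out, "threshold") <- threshold
  class(out) <- c("indval_result", "data.frame")
  out
}

#' @export
print.indval_result <- function(x, n = 10, ...) {
  cat(sprintf(
    "IndVal indicator species analysis (%d permutations, threshold %g%%)\n",
    attr(x, "n_perm"), attr(x, "threshold")))
  print.data.frame(utils::head(format(as.data.frame(x), digits = 3), n),
                   row.names = FALSE)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more taxa\n")
  invisible(x)
}
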