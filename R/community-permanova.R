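# Permutational multivariate analysis of variance on a distance matrix
# (Gower-centred inner-product partition, sequential sums of squares).

#' PERMANOVA
#'
#' Partitions the total sum of squared distances among the supplied
#' factors. The squared distance matrix is Gower-centred
#' (`G = -1/2 C D2 C` with `C` the centring matrix); each term's sum of
#' squares is the sequential (entry-order) increment `tr(H_k G) -
#' tr(H_{k-1} G)` of the nested hat matrices, the residual is
#' `tr(G) - tr(H_full G)`, and the pseudo-F of a term is its mean square
#' over the residual mean square. Significance comes from free
#' permutation of unit labels with the add-one estimator
#' `p = (1 + #(F* >= F)) / (1 + n_perm)`.
#'
#' @param dist a [distance_matrix()].
#' @param factors data frame of factors (one row per unit, tested in
#'   column order).
#' @param n_perm number of permutations (default 999; 0 skips the test).
#' @param seed integer seed for the permutations.
#' @return Object of class `permanova_table`: data frame with df, SS,
#'   MS, pseudo-F, R2 and p per term plus residual and total rows;
#'   attributes `n_perm` and `seed`.
#' @export
permanova <- function(dist, factors, n_perm = 999, seed = 1L) {
  d <- as.matrix(dist)
  n <- nrow(d)
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  if (nrow(factors) != n) data_error("factors must have one row per unit")
  for (nm in names(factors)) {
    factors[[nm]] <- factor(factors[[nm]])
    if (nlevels(factors[[nm]]) < 2) {
      data_error("factor '%s' has a single level", nm)
    }
  }
  if (n_perm < 0) config_error("'n_perm' must be >= 0")

  ones <- matrix(1 / n, n, n)
  G <- -0.5 * (diag(n) - ones) %*% (d^2) %*% (diag(n) - ones)
  ss_total <- sum(diag(G))

  terms <- names(factors)
  hats <- vector("list", length(terms))
  dfs <- integer(length(terms))
  prev_rank <- 1L
  mm <- matrix(1, n, 1)
  for (k in seq_along(terms)) {
    mm <- cbind(mm, stats::model.matrix(
      ~ x - 1, data.frame(x = factors[[terms[k]]]))[, -1, drop = FALSE])
    qrm <- qr(mm)
    hats[[k]] <- tcrossprod(qr.Q(qrm)[, seq_len(qrm$rank), drop = FALSE])
    dfs[k] <- qrm$rank - prev_rank
    prev_rank <- qrm$rank
  }
  df_res <- n - prev_rank

  ss_terms_of <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    c(tr[1], diff(tr))
  }
  ss <- ss_terms_of(G)
  ss_res <- ss_total - sum(ss)
  ms <- ss / dfs
  ms_res <- ss_res / df_res
  f_obs <- ms / ms_res

  p <- rep(NA_real_, length(terms))
  if (n_perm > 0) {
    exceed <- integer(length(terms))
    with_seed(derive_seed(seed, "permanova"), {
      for (b in seq_len(n_perm)) {
        perm <- sample.int(n)
        ssb <- ss_terms_of(G[perm, perm])
        fb <- (ssb / dfs) / ((ss_total - sum(ssb)) / df_res)
        exceed <- exceed + (fb >= f_obs - 1e-12)
      }
    })
    p <- (1 + exceed) / (1 + n_perm)
  }

  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    SS = c(ss, ss_res, ss_total),
    MS = c(ms, ms_res, NA_real_),
    pseudo_F = c(f_obs, NA_real_, NA_real_),
    R2 = c(ss, ss_res, ss_total) / ss_total,
    p = c(p, NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
  attr(tab, "n_perm") <- n_perm
  attr(tab, "seed") <- seed
  class(tab) <- c("permanova_table", "data.frame")
  tab
}

#' @export
print.permanova_table <- function(x, ...) {
  cat(sprintf("PERMANOVA (%d free permutations)\n", attr(x, "n_perm")))
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}
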