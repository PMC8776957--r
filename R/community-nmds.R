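# Non-metric multidimensional scaling by direct Kruskal stress-1
# minimisation with monotone (isotonic) regression.

#' Non-metric multidimensional scaling
#'
#' Embeds the units of a distance matrix in `n_dim` dimensions by
#' minimising Kruskal's stress-1,
#' `sqrt(sum((d_conf - d_hat)^2) / sum(d_conf^2))`, where `d_hat` is the
#' monotone (least-squares isotonic) regression of the configuration
#' distances on the input dissimilarity order (primary, weak-tie
#' treatment). Each of `n_starts` seeded random initial configurations is
#' optimised by quasi-Newton descent with an analytic gradient (the
#' isotonic fit is a projection, so its contribution vanishes almost
#' everywhere); the lowest-stress solution is returned. The returned
#' stress never exceeds the stress of its own initial configuration.
#'
#' @param dist a [distance_matrix()].
#' @param n_dim embedding dimension (default 2).
#' @param n_starts number of random starts (default 20).
#' @param max_iter optimiser iteration cap per start.
#' @param seed integer seed for the random starts.
#' @param tol convergence tolerance on the relative stress change.
#' @return Object of class `forest_ordination`: `points` (units x n_dim),
#'   `stress`, `converged`, `n_dim`, `seed`.
#' @export
nmds <- function(dist, n_dim = 2, n_starts = 20, max_iter = 200,
                 seed = 1L, tol = 1e-6) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 3) data_error("NMDS needs at least 3 units")
  if (n_dim < 1 || n_dim >= n) data_error("n_dim must lie in [1, n - 1]")
  dvec <- dist_vector(d)
  ord <- order(dvec)
  sum_obs <- sum(dvec^2)
  if (sum_obs == 0) data_error("all distances are zero")

  lower <- which(lower.tri(d))
  ri <- row(d)[lower]
  ci <- col(d)[lower]

  stress_of <- function(y) {
    conf <- matrix(y, n, n_dim)
    dc <- dist_vector(as.matrix(stats::dist(conf)))
    dhat <- numeric(length(dc))
    dhat[ord] <- stats::isoreg(seq_along(ord), dc[ord])$yf
    sqrt(sum((dc - dhat)^2) / sum(dc^2))
  }
  grad_of <- function(y) {
    conf <- matrix(y, n, n_dim)
    dm <- as.matrix(stats::dist(conf))
    dc <- dm[lower]
    dhat <- numeric(length(dc))
    dhat[ord] <- stats::isoreg(seq_along(ord), dc[ord])$yf
    sstar <- sum((dc - dhat)^2)
    tstar <- sum(dc^2)
    s1 <- sqrt(sstar / tstar)
    if (s1 == 0) return(rep(0, length(y)))
    # dS1/d dc_p, treating the isotonic fit as locally constant
    dS_ddc <- ((dc - dhat) * tstar - sstar * dc) / (s1 * tstar^2)
    g <- matrix(0, n, n_dim)
    safe <- pmax(dc, 1e-12)
    for (p in seq_along(dc)) {
      i <- ri[p]; j <- ci[p]
      u <- (conf[i, ] - conf[j, ]) / safe[p]
      g[i, ] <- g[i, ] + dS_ddc[p] * u
      g[j, ] <- g[j, ] - dS_ddc[p] * u
    }
    as.vector(g)
  }

  best <- NULL
  with_seed(derive_seed(seed, "nmds"), {
    for (s in seq_len(n_starts)) {
      init <- stats::rnorm(n * n_dim) * mean(dvec)
      init_stress <- stress_of(init)
      fit <- stats::optim(init, stress_of, grad_of, method = "BFGS",
                          control = list(maxit = max_iter, reltol = tol))
      val <- min(fit$value, init_stress)
      par <- if (fit$value <= init_stress) fit$par else init
      if (is.null(best) || val < best$stress) {
        best <- list(stress = val, par = par,
                     converged = fit$convergence == 0)
      }
    }
  })
  points <- matrix(best$par, n, n_dim,
                   dimnames = list(rownames(d),
                                   paste0("NMDS", seq_len(n_dim))))
  points <- scale(points, center = TRUE, scale = FALSE)
  structure(
    list(points = points, stress = best$stress,
         converged = best$converged, n_dim = n_dim, seed = seed),
    class = "forest_ordination"
  )
}

#' @export
print.forest_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d units in %d dimensions, stress = %.4f%s\n",
              nrow(x$points), x$n_dim, x$stress,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
plot.forest_ordination <- function(x, groups = NULL, ...) {
  if (x$n_dim < 2) {
    graphics::plot(x$points[, 1], rep(0, nrow(x$points)),
                   xlab = "NMDS1", ylab = "", ...)
    return(invisible(x))
  }
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(x$points[, 1], x$points[, 2], col = col, pch = 19,
                 xlab = "NMDS1", ylab = "NMDS2", ...)
  invisible(x)
}
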