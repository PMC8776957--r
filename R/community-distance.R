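# Compositional distances. The Hellinger transform/distance pair is the
# package's primary metric; Bray-Curtis and Euclidean exist for the
# clustering model-selection table.

#' Hellinger transformation
#'
#' Each row is replaced by the square root of its relative abundances:
#' `y_ij = sqrt(x_ij / sum_j x_ij)`, so every transformed row has unit
#' sum of squares.
#'
#' @param cover an [abundance_matrix()] or a plain non-negative matrix;
#'   every row must have a positive total.
#' @return Numeric matrix of the same dimensions.
#' @export
#' @examples
#' hellinger_transform(rbind(u1 = c(a = 1, b = 1)))
hellinger_transform <- function(cover) {
  x <- cover_values(cover)
  tot <- rowSums(x)
  if (any(tot <= 0)) {
    data_error("all-zero row(s): %s",
               paste(rownames(x)[tot <= 0], collapse = ", "))
  }
  sqrt(x / tot)
}

cover_values <- function(cover) {
  if (inherits(cover, "abundance_matrix")) return(cover$values)
  if (!is.matrix(cover) || !is.numeric(cover)) {
    data_error("expected an abundance_matrix or numeric matrix")
  }
  if (any(cover < 0)) data_error("abundances must be non-negative")
  if (is.null(rownames(cover))) {
    rownames(cover) <- paste0("u", seq_len(nrow(cover)))
  }
  cover
}

#' Hellinger distance matrix
#'
#' Euclidean distance between Hellinger-transformed rows; bounded by
#' `sqrt(2)`.
#'
#' @inheritParams hellinger_transform
#' @return A symmetric `dist`-convertible matrix of class
#'   `distance_matrix` (square labelled matrix, zero diagonal).
#' @export
hellinger_distance <- function(cover) {
  y <- hellinger_transform(cover)
  distance_matrix(as.matrix(stats::dist(y)))
}

#' Bray-Curtis dissimilarity matrix
#' @inheritParams hellinger_transform
#' @return A `distance_matrix`.
#' @export
bray_curtis_distance <- function(cover) {
  x <- cover_values(cover)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(abs(x[i, ] - x[j, ]))
      den <- sum(x[i, ] + x[j, ])
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    }
  }
  distance_matrix(d)
}

#' Euclidean distance matrix on raw abundances
#' @inheritParams hellinger_transform
#' @return A `distance_matrix`.
#' @export
euclidean_distance <- function(cover) {
  distance_matrix(as.matrix(stats::dist(cover_values(cover))))
}

#' Distance matrix container
#'
#' Validates a symmetric non-negative matrix with zero diagonal.
#'
#' @param m square numeric matrix with unit-id dimnames.
#' @return The matrix with class `distance_matrix`.
#' @export
distance_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    data_error("distance matrix must be square")
  }
  if (anyNA(m) || any(!is.finite(m))) {
    data_error("distance matrix entries must be finite")
  }
  if (any(abs(m - t(m)) > 1e-10)) data_error("distance matrix must be symmetric")
  if (any(diag(m) != 0)) data_error("distance matrix diagonal must be zero")
  if (any(m < 0)) data_error("distances must be non-negative")
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("u", seq_len(nrow(m)))
  }
  m <- (m + t(m)) / 2
  class(m) <- c("distance_matrix", "matrix", "array")
  m
}

dist_vector <- function(d) d[lower.tri(d)]

registered_distances <- function() {
  list(
    hellinger = hellinger_distance,
    bray_curtis = bray_curtis_distance,
    euclidean = euclidean_distance
  )
}
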