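# Agglomerative clustering from definitions: UPGMA (and single/complete
# linkage for the model-selection table), cophenetic correlation,
# silhouette widths, the Mantel cluster statistic and cluster-number
# selection.

#' Agglomerative hierarchical clustering
#'
#' Implements the agglomeration schedule directly: at each step the two
#' closest clusters merge at the height of their current distance, and
#' inter-cluster distances are updated by the linkage rule. UPGMA uses
#' the unweighted mean of all between-leaf distances
#' (`d(k, i+j) = (n_i d(k,i) + n_j d(k,j)) / (n_i + n_j)`).
#' Ties break towards the earliest cluster pair in current index order.
#'
#' @param dist a [distance_matrix()] (or square symmetric matrix), n >= 2.
#' @param linkage `"upgma"`, `"single"` or `"complete"`.
#' @return An `hclust`-compatible object (classes `forest_dendrogram`,
#'   `hclust`) with `merge`, `height`, `order` and `labels`, usable with
#'   [stats::cutree()] and [as_newick()].
#' @export
#' @examples
#' d <- distance_matrix(matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3, 3,
#'                      dimnames = list(letters[1:3], letters[1:3])))
#' agglomerate(d)$height  # both merges at 2
agglomerate <- function(dist, linkage = c("upgma", "single", "complete")) {
  linkage <- match.arg(linkage)
  d <- unclass(as.matrix(dist))
  n <- nrow(d)
  if (n < 2) data_error("clustering needs at least 2 units")
  labels <- rownames(d)
  # active[k]: hclust code of the cluster currently in slot k
  # (negative = singleton leaf index, positive = merge step)
  active <- -seq_len(n)
  sizes <- rep(1L, n)
  alive <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  work <- d
  diag(work) <- Inf
  for (step in seq_len(n - 1)) {
    idx <- which(alive)
    sub <- work[idx, idx, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- idx[best[1]]
    j <- idx[best[2]]
    height[step] <- work[i, j]
    merge[step, ] <- sort(c(active[i], active[j]))
    for (k in idx) {
      if (k == i || k == j) next
      work[i, k] <- work[k, i] <- switch(
        linkage,
        upgma = (sizes[i] * work[i, k] + sizes[j] * work[j, k]) /
          (sizes[i] + sizes[j]),
        single = min(work[i, k], work[j, k]),
        complete = max(work[i, k], work[j, k])
      )
    }
    sizes[i] <- sizes[i] + sizes[j]
    alive[j] <- FALSE
    active[i] <- step
  }
  out <- structure(
    list(merge = merge, height = height, order = integer(n),
         labels = labels, method = linkage,
         dist.method = attr(dist, "metric") %||% "unknown",
         call = match.call()),
    class = c("forest_dendrogram", "hclust")
  )
  out$order <- dendrogram_leaf_order(merge, n)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dendrogram_leaf_order <- function(merge, n) {
  walk <- function(code) {
    if (code < 0) return(-code)
    c(walk(merge[code, 1]), walk(merge[code, 2]))
  }
  walk(n - 1)
}

#' UPGMA clustering
#'
#' Convenience wrapper for [agglomerate()] with average linkage, the
#' scheme used for community classification throughout the package.
#'
#' @inheritParams agglomerate
#' @return See [agglomerate()].
#' @export
upgma <- function(dist) agglomerate(dist, "upgma")

#' Cophenetic distances of a dendrogram
#'
#' The cophenetic distance of two leaves is the merge height at which
#' they first join the same cluster; computed directly from the merge
#' schedule.
#'
#' @param tree an [agglomerate()] result.
#' @return Square labelled matrix of cophenetic distances.
#' @export
cophenetic_distances <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", n - 1)
  cd <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  for (step in seq_len(n - 1)) {
    grab <- function(code) {
      if (code < 0) -code else members[[code]]
    }
    a <- grab(tree$merge[step, 1])
    b <- grab(tree$merge[step, 2])
    cd[a, b] <- tree$height[step]
    cd[b, a] <- tree$height[step]
    members[[step]] <- c(a, b)
  }
  cd
}

#' Cophenetic correlation
#'
#' Pearson correlation between the `n(n-1)/2` original distances and the
#' dendrogram's cophenetic distances; the package's model-selection score
#' for distance/linkage combinations.
#'
#' @param tree an [agglomerate()] result.
#' @param dist the distance matrix the tree was built from (same units).
#' @return Correlation in `[-1, 1]`, or `NA` when either distance vector
#'   is constant (zero variance).
#' @export
cophenetic_correlation <- function(tree, dist) {
  d <- as.matrix(dist)
  if (!setequal(rownames(d), tree$labels)) {
    data_error("tree leaves and distance units differ")
  }
  d <- d[tree$labels, tree$labels]
  x <- dist_vector(d)
  y <- dist_vector(cophenetic_distances(tree))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Select the best distance/linkage combination
#'
#' Evaluates every candidate pair and returns the one with the highest
#' cophenetic correlation (ties break to the earliest candidate in list
#' order), together with the full score table.
#'
#' @param cover plot-level abundance matrix.
#' @param distances character vector of registered distances
#'   (`"hellinger"`, `"bray_curtis"`, `"euclidean"`).
#' @param linkages character vector of linkages for [agglomerate()].
#' @return List with `distance`, `linkage`, `tree`, `dist`,
#'   `cophenetic_r` and `scores` (data frame of all combinations).
#' @export
select_clustering <- function(cover,
                              distances = c("hellinger", "bray_curtis",
                                            "euclidean"),
                              linkages = c("upgma", "single", "complete")) {
  reg <- registered_distances()
  unknown <- setdiff(distances, names(reg))
  if (length(unknown)) {
    config_error("unknown distance(s): %s", paste(unknown, collapse = ", "))
  }
  rows <- list()
  best <- NULL
  for (dn in distances) {
    dmat <- reg[[dn]](cover)
    for (ln in linkages) {
      tree <- agglomerate(dmat, ln)
      r <- cophenetic_correlation(tree, dmat)
      rows[[length(rows) + 1L]] <- data.frame(
        distance = dn, linkage = ln, cophenetic_r = r,
        stringsAsFactors = FALSE
      )
      if (!is.na(r) && (is.null(best) || r > best$cophenetic_r)) {
        best <- list(distance = dn, linkage = ln, tree = tree,
                     dist = dmat, cophenetic_r = r)
      }
    }
  }
  if (is.null(best)) data_error("no candidate produced a defined score")
  best$scores <- do.call(rbind, rows)
  best
}

#' Silhouette widths of a partition
#'
#' Rousseeuw's quality index: `s(i) = (b_i - a_i) / max(a_i, b_i)` with
#' `a_i` the mean distance to the other members of i's cluster and `b_i`
#' the smallest mean distance to any other cluster; members of singleton
#' clusters get `s(i) = 0`.
#'
#' @param dist a [distance_matrix()].
#' @param labels cluster assignment, one per unit (>= 2 clusters).
#' @return List with `widths` (per-unit, named) and `mean`.
#' @export
silhouette_widths <- function(dist, labels) {
  d <- as.matrix(dist)
  labels <- as.character(labels)
  if (length(labels) != nrow(d)) data_error("one label per unit required")
  cl <- unique(labels)
  if (length(cl) < 2) data_error("silhouette needs at least 2 clusters")
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) {
      s[i] <- 0
      next
    }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cl, labels[i]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(widths = stats::setNames(s, rownames(d)), mean = mean(s))
}

#' Mantel statistic for a cluster partition
#'
#' Pearson correlation between the pairwise distance vector and the
#' binary model vector (0 = same cluster, 1 = different clusters); higher
#' values mean between-cluster distances exceed within-cluster ones.
#'
#' @inheritParams silhouette_widths
#' @return Correlation in `[-1, 1]`, `NA` when either vector is constant.
#' @export
mantel_cluster_statistic <- function(dist, labels) {
  d <- as.matrix(dist)
  labels <- as.character(labels)
  if (length(labels) != nrow(d)) data_error("one label per unit required")
  if (length(unique(labels)) < 2) {
    data_error("Mantel cluster statistic needs at least 2 clusters")
  }
  x <- dist_vector(d)
  model <- outer(labels, labels, FUN = `!=`) * 1
  y <- dist_vector(model)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Choose the number of community groups
#'
#' Cuts the dendrogram at each k in `2..k_max` and scores the partitions
#' by mean silhouette width (selection criterion; ties break to the
#' smaller k) with the Mantel statistic attached as a diagnostic.
#'
#' @param tree an [agglomerate()] result.
#' @param dist the distance matrix the tree was built from.
#' @param k_max largest number of clusters to consider
#'   (`2 <= k_max <= n - 1`).
#' @return List with `k` (selected), `diagnostics` (data frame of k,
#'   mean silhouette, Mantel r) and `labels` (assignment at the chosen k).
#' @export
choose_k <- function(tree, dist, k_max = 10) {
  n <- length(tree$labels)
  if (k_max < 2 || k_max > n - 1) {
    data_error("k_max must lie in [2, n - 1]")
  }
  d <- as.matrix(dist)[tree$labels, tree$labels]
  ks <- 2:k_max
  sil <- numeric(length(ks))
  man <- numeric(length(ks))
  cuts <- vector("list", length(ks))
  for (m in seq_along(ks)) {
    labels <- stats::cutree(tree, k = ks[m])
    cuts[[m]] <- labels
    sil[m] <- silhouette_widths(distance_matrix(d), labels)$mean
    man[m] <- mantel_cluster_statistic(distance_matrix(d), labels)
  }
  pick <- which(sil >= max(sil) - 1e-12)[1]
  list(
    k = ks[pick],
    diagnostics = data.frame(k = ks, mean_silhouette = sil, mantel_r = man),
    labels = cuts[[pick]]
  )
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths place each leaf at depth equal to its cluster's merge
#' height over two (ultrametric tree).
#'
#' @param tree an [agglomerate()] result.
#' @return Newick string (terminated by `;`).
#' @export
as_newick <- function(tree) {
  phy <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(phy)
}
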