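# Community classification and inference: distances, UPGMA, cophenetic
# correlation, cluster diagnostics, NMDS, PERMANOVA and IndVal.

test_that("Hellinger transform and distance match their definitions", {
  expect_equal(as.numeric(hellinger_transform(rbind(u = c(1, 0, 0)))),
               c(1, 0, 0))
  expect_equal(as.numeric(hellinger_transform(rbind(u = c(1, 1)))),
               c(sqrt(0.5), sqrt(0.5)))
  m <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(hellinger_distance(m)["a", "b"], sqrt(2))
  m2 <- rbind(a = c(1, 1), b = c(1, 0))
  expect_equal(hellinger_distance(m2)["a", "b"],
               sqrt((sqrt(0.5) - 1)^2 + 0.5), tolerance = 1e-9)
  expect_equal(hellinger_distance(m2)["a", "b"], 0.7654, tolerance = 1e-4)
  # definition oracle on random rows + unit row sums of squares
  x <- rand_cover(6, 10, seed = 7)
  tr <- hellinger_transform(x)
  expect_equal(rowSums(tr^2), setNames(rep(1, 6), rownames(x)))
  d <- hellinger_distance(x)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      direct <- sqrt(sum((sqrt(x[i, ] / sum(x[i, ])) -
                            sqrt(x[j, ] / sum(x[j, ])))^2))
      expect_equal(d[i, j], direct, tolerance = 1e-12)
    }
  }
  expect_true(all(d <= sqrt(2) + 1e-12))
  expect_error(hellinger_transform(rbind(z = c(0, 0))), "all-zero")
})

test_that("Hellinger distance agrees with vegan and satisfies the triangle inequality", {
  skip_if_not_installed("vegan")
  x <- rand_cover(8, 12, seed = 13)
  mine <- hellinger_distance(x)
  ref <- as.matrix(stats::dist(vegan::decostand(x, "hellinger")))
  expect_equal(unclass(mine), ref, tolerance = 1e-12,
               ignore_attr = TRUE)
  set.seed(14)
  for (rep in 1:50) {
    ijk <- sample(8, 3)
    expect_lte(mine[ijk[1], ijk[3]],
               mine[ijk[1], ijk[2]] + mine[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("UPGMA reproduces the average-linkage agglomeration schedule", {
  d3 <- const_dist(3, 2)
  tr <- upgma(d3)
  expect_equal(tr$height, c(2, 2))
  # two tight pairs far apart merge first
  d4 <- dist_from_points(c(0, 0.1, 10, 10.1), letters[1:4])
  tr4 <- upgma(d4)
  expect_equal(sort(tr4$height[1:2]), c(0.1, 0.1), tolerance = 1e-12)
  # brute-force cross-check against stats::hclust average linkage, n <= 6
  for (s in 1:8) {
    n <- sample(3:6, 1)
    dm <- rand_distance(n, seed = 100 + s)
    mine <- upgma(dm)
    ref <- stats::hclust(stats::as.dist(unclass(dm)), method = "average")
    expect_equal(mine$height, ref$height, tolerance = 1e-12)
    expect_equal(cophenetic_distances(mine)[ref$labels, ref$labels],
                 as.matrix(stats::cophenetic(ref)), tolerance = 1e-12)
  }
  expect_error(upgma(distance_matrix(matrix(0, 1, 1))), "at least 2")
})

test_that("UPGMA heights are monotone and cophenetic distances ultrametric", {
  for (s in 1:5) {
    dm <- rand_distance(7, seed = 200 + s)
    tr <- upgma(dm)
    expect_true(all(diff(tr$height) >= -1e-12))
    cd <- cophenetic_distances(tr)
    n <- nrow(cd)
    for (rep in 1:30) {
      ijk <- sample(n, 3)
      expect_lte(cd[ijk[1], ijk[2]],
                 max(cd[ijk[1], ijk[3]], cd[ijk[2], ijk[3]]) + 1e-9)
    }
  }
})

test_that("cophenetic correlation behaves at its edge cases and oracle", {
  dm <- rand_distance(6, seed = 301)
  tr <- upgma(dm)
  # ultrametric input: tree reproduces its own cophenetic matrix, r = 1
  ultra <- distance_matrix(cophenetic_distances(tr))
  expect_equal(cophenetic_correlation(upgma(ultra), ultra), 1,
               tolerance = 1e-9)
  # three equidistant points: zero variance, flagged missing
  d3 <- const_dist(3, 2)
  expect_true(is.na(cophenetic_correlation(upgma(d3), d3)))
  # oracle: correlate with stats::cophenetic on the same tree
  ref <- stats::hclust(stats::as.dist(unclass(dm)), method = "average")
  r_ref <- stats::cor(stats::as.dist(unclass(dm)), stats::cophenetic(ref))
  expect_equal(cophenetic_correlation(tr, dm), r_ref, tolerance = 1e-12)
})

test_that("clustering model selection returns the argmax with list-order ties", {
  x <- rand_cover(8, 10, seed = 17)
  single <- select_clustering(x, distances = "hellinger",
                              linkages = "upgma")
  expect_equal(single$distance, "hellinger")
  expect_equal(nrow(single$scores), 1)
  full <- select_clustering(x)
  best_row <- full$scores[which.max(full$scores$cophenetic_r), ]
  expect_equal(full$distance, best_row$distance)
  expect_equal(full$linkage, best_row$linkage)
  expect_equal(full$cophenetic_r, max(full$scores$cophenetic_r))
  # duplicated candidate: tie resolves to the first occurrence
  tie <- select_clustering(x, distances = c("hellinger", "hellinger"),
                           linkages = "upgma")
  expect_equal(tie$distance, "hellinger")
  expect_equal(nrow(tie$scores), 2)
})

test_that("silhouette widths follow Rousseeuw's formula", {
  d <- dist_from_points(c(0, 0.1, 0.2, 10, 10.1, 10.2))
  lab <- rep(c("A", "B"), each = 3)
  sw <- silhouette_widths(d, lab)
  expect_gt(sw$mean, 0.9)
  skip_if_not_installed("cluster")
  ref <- cluster::silhouette(as.integer(factor(lab)),
                             stats::as.dist(unclass(d)))
  expect_equal(unname(sw$widths), unname(ref[, "sil_width"]),
               tolerance = 1e-12)
  # equal within- and between-distances give s = 0
  deq <- const_dist(4, 1, paste0("u", 1:4))
  expect_equal(silhouette_widths(deq, c("A", "A", "B", "B"))$mean, 0)
  # random labels on structureless distances: mean near zero
  set.seed(33)
  vals <- replicate(20, {
    dm <- rand_distance(10, seed = sample.int(1e6, 1))
    silhouette_widths(dm, sample(c("A", "B"), 10, replace = TRUE))$mean
  })
  expect_lt(abs(mean(vals)), 0.15)
  expect_error(silhouette_widths(d, rep("A", 6)), "2 clusters")
})

test_that("Mantel cluster statistic correlates distance with the model matrix", {
  blocks <- matrix(1, 4, 4) - diag(1, 4)
  blocks[1:2, 1:2] <- 0.1
  blocks[3:4, 3:4] <- 0.1
  diag(blocks) <- 0
  dimnames(blocks) <- list(paste0("u", 1:4), paste0("u", 1:4))
  d <- distance_matrix(blocks)
  expect_equal(mantel_cluster_statistic(d, c("A", "A", "B", "B")), 1)
  # anti-structure: between-cluster distances smaller than within
  expect_lt(mantel_cluster_statistic(d, c("A", "B", "A", "B")), 0)
  set.seed(44)
  vals <- replicate(20, {
    dm <- rand_distance(10, seed = sample.int(1e6, 1))
    mantel_cluster_statistic(dm, sample(c("A", "B"), 10, replace = TRUE))
  })
  expect_lt(abs(mean(vals)), 0.15)
  expect_error(mantel_cluster_statistic(d, rep("A", 4)), "2 clusters")
})

test_that("choose_k recovers planted cluster counts and breaks ties downward", {
  # two clusters
  d2 <- dist_from_points(c(0, 0.2, 0.4, 8, 8.2, 8.4))
  ck2 <- choose_k(upgma(d2), d2, k_max = 4)
  expect_equal(ck2$k, 2)
  # three clusters
  d3 <- dist_from_points(c(0, 0.2, 5, 5.2, 11, 11.2))
  ck3 <- choose_k(upgma(d3), d3, k_max = 5)
  expect_equal(ck3$k, 3)
  expect_equal(nrow(ck3$diagnostics), 4)
  expect_error(choose_k(upgma(d3), d3, k_max = 1), "k_max")
})

test_that("NMDS embeds exact configurations at near-zero stress deterministically", {
  # collinear points, 1-D target
  dl <- dist_from_points(c(0, 1, 2.5, 4, 7))
  ol <- nmds(dl, n_dim = 1, n_starts = 5, seed = 2)
  expect_lt(ol$stress, 1e-3)
  # distances from exact 2-D coordinates
  set.seed(8)
  xy <- matrix(stats::rnorm(20), 10, 2)
  d2 <- dist_from_points(xy)
  o2 <- nmds(d2, n_dim = 2, n_starts = 5, seed = 2)
  expect_lt(o2$stress, 0.01)
  o2b <- nmds(d2, n_dim = 2, n_starts = 5, seed = 2)
  expect_identical(o2$points, o2b$points)
})

test_that("PERMANOVA partitions variance and matches adonis2", {
  skip_if_not_installed("vegan")
  x <- rand_cover(12, 10, seed = 19)
  f <- data.frame(ty = rep(c("A", "B", "C"), each = 4),
                  isl = rep(c("x", "y"), 6))
  d <- hellinger_distance(x)
  mine <- permanova(d, f, n_perm = 199, seed = 5)
  ref <- vegan::adonis2(stats::as.dist(unclass(d)) ~ ty + isl, data = f,
                        permutations = 199, by = "terms")
  expect_equal(mine$SS[1:2], ref$SumOfSqs[1:2], tolerance = 1e-9)
  expect_equal(mine$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-9)
  expect_equal(mine$R2[1:2], ref$R2[1:2], tolerance = 1e-9)
  expect_equal(sum(mine$R2[1:3]), 1, tolerance = 1e-9)
  expect_true(all(mine$p[1:2] >= 1 / 200))
})

test_that("PERMANOVA drives R2 to 1 for duplicated separated compositions", {
  base <- rbind(c(10, 0, 0, 1), c(0, 10, 1, 0))
  x <- base[rep(1:2, each = 5), ] + matrix(stats::runif(40, 0, 1e-3), 10, 4)
  dimnames(x) <- list(paste0("u", 1:10), paste0("t", 1:4))
  f <- data.frame(g = rep(c("A", "B"), each = 5))
  res <- permanova(hellinger_distance(x), f, n_perm = 999, seed = 1)
  expect_gt(res$R2[1], 0.99)
  # minimum attainable p: only partition-preserving permutations
  # (5!5!2! / 10! = 1/126) can reach the observed F
  expect_lte(res$p[1], 1 / 126 + 3 * sqrt((1 / 126) * (125 / 126) / 999))
  expect_error(permanova(hellinger_distance(x),
                         data.frame(g = rep("A", 10)), 99), "single level")
})

test_that("Monte-Carlo PERMANOVA p agrees with exhaustive enumeration at n = 4", {
  x <- rand_cover(4, 6, seed = 23)
  d <- hellinger_distance(x)
  f <- data.frame(g = c("A", "A", "B", "B"))
  # exhaustive: all 24 orderings of the labels
  perms <- rbind(
    c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 3, 2, 4), c(1, 3, 4, 2),
    c(1, 4, 2, 3), c(1, 4, 3, 2), c(2, 1, 3, 4), c(2, 1, 4, 3),
    c(2, 3, 1, 4), c(2, 3, 4, 1), c(2, 4, 1, 3), c(2, 4, 3, 1),
    c(3, 1, 2, 4), c(3, 1, 4, 2), c(3, 2, 1, 4), c(3, 2, 4, 1),
    c(3, 4, 1, 2), c(3, 4, 2, 1), c(4, 1, 2, 3), c(4, 1, 3, 2),
    c(4, 2, 1, 3), c(4, 2, 3, 1), c(4, 3, 1, 2), c(4, 3, 2, 1)
  )
  f_of <- function(ord) {
    permanova(distance_matrix(unclass(d)[ord, ord]), f, n_perm = 0)$pseudo_F[1]
  }
  f_obs <- f_of(1:4)
  exact <- mean(vapply(seq_len(24), function(i) {
    f_of(perms[i, ]) >= f_obs - 1e-12
  }, logical(1)))
  mc <- permanova(d, f, n_perm = 4999, seed = 9)$p[1]
  # agreement within Monte-Carlo error (3 binomial sd)
  expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / 4999) + 1e-3)
})

test_that("IndVal matches hand computation, edge cases and exhaustive p", {
  # perfect indicator: present in every plot of one group only
  m <- rbind(p1 = c(a = 3, b = 1), p2 = c(a = 5, b = 0),
             p3 = c(a = 0, b = 2), p4 = c(a = 0, b = 1))
  res <- suppressWarnings(indval(m, c("G1", "G1", "G2", "G2"), n_perm = 0))
  expect_equal(res$indval[res$taxon_id == "a"], 100)
  # symmetric case: equal means and full occupancy in k groups -> 100/k
  ms <- matrix(2, 4, 1, dimnames = list(paste0("p", 1:4), "t"))
  rs <- indval(ms, c("G1", "G1", "G2", "G2"), n_perm = 0)
  expect_equal(rs$indval, 50)
  # hand-built 6-plot, 2-group, 3-taxon table
  mh <- rbind(
    p1 = c(x = 4, y = 0, z = 1), p2 = c(x = 2, y = 0, z = 0),
    p3 = c(x = 3, y = 1, z = 2), p4 = c(x = 0, y = 5, z = 1),
    p5 = c(x = 0, y = 3, z = 3), p6 = c(x = 1, y = 4, z = 0)
  )
  g <- c("G1", "G1", "G1", "G2", "G2", "G2")
  res_h <- indval(mh, g, n_perm = 1999, seed = 3)
  # hand computation for taxon x in G1:
  # mean(G1) = 3, mean(G2) = 1/3; A = 3 / (3 + 1/3) = 0.9; B = 1
  x_row <- res_h[res_h$taxon_id == "x", ]
  expect_equal(x_row$group, "G1")
  expect_equal(x_row$A, 0.9, tolerance = 1e-12)
  expect_equal(x_row$B, 1, tolerance = 1e-12)
  expect_equal(x_row$indval, 90, tolerance = 1e-12)
  # exhaustive p over the 20 distinct 3|3 label splits
  splits <- utils::combn(6, 3)
  exact_p <- function(taxon) {
    obs <- res_h$indval[res_h$taxon_id == taxon]
    stat <- vapply(seq_len(ncol(splits)), function(i) {
      gi <- rep("G2", 6)
      gi[splits[, i]] <- "G1"
      comp <- indval(mh, gi, n_perm = 0)
      comp$indval[comp$taxon_id == taxon]
    }, numeric(1))
    mean(stat >= obs - 1e-9)
  }
  for (taxon in c("x", "y")) {
    pe <- exact_p(taxon)
    pm <- res_h$p[res_h$taxon_id == taxon]
    expect_lt(abs(pm - pe), 3 * sqrt(pe * (1 - pe) / 1999) + 2e-3)
  }
})

test_that("IndVal is invariant to rescaling a taxon and flags absences", {
  m <- rand_cover(8, 5, seed = 29)
  g <- rep(c("A", "B"), each = 4)
  r1 <- indval(m, g, n_perm = 0)
  m2 <- m
  m2[, 3] <- m2[, 3] * 17.3
  r2 <- indval(m2, g, n_perm = 0)
  expect_equal(r1$A, r2$A, tolerance = 1e-12)
  expect_equal(r1$B, r2$B, tolerance = 1e-12)
  expect_equal(r1$indval, r2$indval, tolerance = 1e-12)
  m3 <- cbind(m, dead = 0)
  expect_warning(r3 <- indval(m3, g, n_perm = 0), "absent")
  expect_false("dead" %in% r3$taxon_id)
})
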