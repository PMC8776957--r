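# Diversity indices and the additive hierarchical partition.

test_that("richness counts strictly positive entries", {
  expect_equal(richness(c(0, 0, 0)), 0)
  expect_equal(richness(c(1.0, 0, 2.5)), 2)
  expect_error(richness(c(1, -1)), "non-negative")
  set.seed(21)
  for (rep in 1:20) {
    x <- stats::rexp(30) * stats::rbinom(30, 1, 0.5)
    brute <- length(which(x > 0))
    expect_equal(richness(x), brute)
  }
})

test_that("shannon matches direct evaluation and its bounds", {
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon(7), 0)
  # direct -sum(p log p) for (1, 2, 3)
  p <- c(1, 2, 3) / 6
  expect_equal(shannon(c(1, 2, 3)), -sum(p * log(p)))
  expect_equal(shannon(c(1, 2, 3)), 1.0114, tolerance = 1e-4)
  expect_error(shannon(c(0, 0)), "all-zero")
  set.seed(22)
  for (rep in 1:20) {
    x <- stats::rexp(10)
    H <- shannon(x)
    expect_gte(H, 0)
    expect_lte(H, log(10) + 1e-12)
  }
})

test_that("evenness is Pielou's J with the S = 1 convention", {
  expect_equal(evenness(log(4), 4), 1)
  expect_equal(evenness(0, 1), 0)
  expect_equal(evenness(1.0114, 3), 0.9206, tolerance = 1e-4)
  expect_error(evenness(2, 2), "exceeds")
})

test_that("plot diversity pools subplots correctly", {
  taxa <- paste0("t", 1:5)
  units <- paste0("P1.s", 1:4)
  identical_rows <- matrix(1, 4, 5, dimnames = list(units, taxa))
  design <- data.frame(subplot_id = units, plot_id = "P1")
  pd <- plot_diversity(abundance_matrix(identical_rows, "subplot"), design)
  expect_equal(pd$alpha, 5)
  expect_equal(pd$gamma, 5)
  expect_equal(pd$beta, 0)

  disjoint <- diag(4)
  dimnames(disjoint) <- list(units, paste0("t", 1:4))
  pd2 <- plot_diversity(abundance_matrix(disjoint, "subplot"), design)
  expect_equal(pd2$alpha, 1)
  expect_equal(pd2$gamma, 4)
  expect_equal(pd2$beta, 3)

  # random matrix vs brute-force set-union oracle
  m <- rand_cover(8, 12, seed = 31)
  des <- data.frame(subplot_id = rownames(m),
                    plot_id = rep(c("A", "B"), each = 4))
  pd3 <- plot_diversity(abundance_matrix(m, "subplot"), des)
  for (p in c("A", "B")) {
    rows <- m[des$plot_id == p, ]
    union_taxa <- unique(unlist(apply(rows, 1, function(r) {
      colnames(m)[r > 0]
    })))
    expect_equal(pd3$gamma[pd3$plot_id == p], length(union_taxa))
    expect_equal(pd3$alpha[pd3$plot_id == p],
                 mean(rowSums(rows > 0)))
  }
})

test_that("empty plots are emitted with zero diversity and a warning", {
  m <- matrix(c(1, 0, 0, 0), 2, 2,
              dimnames = list(c("a.s1", "b.s1"), c("t1", "t2")))
  des <- data.frame(subplot_id = c("a.s1", "b.s1"), plot_id = c("a", "b"))
  expect_warning(
    pd <- plot_diversity(abundance_matrix(m, "subplot"), des),
    "no recorded taxa"
  )
  expect_equal(pd$gamma[pd$plot_id == "b"], 0)
})

test_that("additive partition matches exhaustive hand computation", {
  # all units identical: alpha_k = S at every level, all beta zero
  m <- matrix(1, 4, 6, dimnames = list(paste0("u", 1:4), paste0("t", 1:6)))
  h <- data.frame(unit = rownames(m),
                  pair = rep(c("p1", "p2"), each = 2))
  part <- additive_partition(abundance_matrix(m, "plot"), h)
  expect_equal(unname(part$alpha), c(6, 6))
  expect_equal(unname(part$beta), c(0, 0))
  expect_equal(part$gamma, 6)

  # 2 types x 2 forests x 2 plots with hand-built species sets
  sets <- list(
    c("a", "b"), c("b", "c"),          # forest f1 (type T1)
    c("a", "d"), c("d", "e"),          # forest f2 (type T1)
    c("f", "g"), c("g", "h"),          # forest f3 (type T2)
    c("f", "i"), c("i", "j")           # forest f4 (type T2)
  )
  taxa <- sort(unique(unlist(sets)))
  m2 <- t(vapply(sets, function(s) as.numeric(taxa %in% s),
                 numeric(length(taxa))))
  dimnames(m2) <- list(paste0("plot", 1:8), taxa)
  h2 <- data.frame(
    plot = rownames(m2),
    forest = rep(paste0("f", 1:4), each = 2),
    type = rep(c("T1", "T2"), each = 4)
  )
  part2 <- additive_partition(abundance_matrix(m2, "plot"), h2)
  # oracle: enumerate unions per level
  a1 <- mean(lengths(sets))
  a2 <- mean(c(length(union(sets[[1]], sets[[2]])),
               length(union(sets[[3]], sets[[4]])),
               length(union(sets[[5]], sets[[6]])),
               length(union(sets[[7]], sets[[8]]))))
  a3 <- mean(c(length(Reduce(union, sets[1:4])),
               length(Reduce(union, sets[5:8]))))
  g <- length(Reduce(union, sets))
  expect_equal(unname(part2$alpha), c(a1, a2, a3))
  expect_equal(unname(part2$beta), c(a2 - a1, a3 - a2, g - a3))
  expect_equal(part2$gamma, g)
})

test_that("partition agrees with vegan's adipart on a nested design", {
  skip_if_not_installed("vegan")
  set.seed(41)
  m <- matrix(stats::rpois(12 * 15, 1), 12, 15,
              dimnames = list(paste0("u", 1:12), paste0("t", 1:15)))
  h <- data.frame(plot = rownames(m),
                  cell = rep(paste0("c", 1:4), each = 3),
                  type = rep(c("T1", "T2"), each = 6))
  part <- additive_partition(abundance_matrix(m, "plot"), h)
  ad <- vegan::adipart(m, cbind(h, all = "all"),
                       index = "richness", weights = "unif", nsimul = 2)
  ref <- ad$statistic
  # vegan orders: alpha per level then gamma then beta per level
  expect_equal(unname(part$alpha),
               unname(ref[paste0("alpha.", 1:3)]), tolerance = 1e-9)
  expect_equal(unname(part$beta),
               unname(ref[paste0("beta.", 1:3)]), tolerance = 1e-9)
  expect_equal(part$gamma, unname(ref["gamma"]), tolerance = 1e-9)
})

test_that("partition invariants hold on generated surveys", {
  for (s in 1:5) {
    ds <- generate_survey(small_config(seed = s))
    pc <- aggregate_to_plots(ds$cover, ds$design)
    part <- additive_partition(pc, default_hierarchy(pc, ds$design))
    resid <- part$alpha[1] + sum(part$beta) - part$gamma
    expect_lt(abs(resid), 1e-9)
    expect_true(all(part$beta >= 0))
    expect_true(all(diff(part$alpha) >= 0))
    expect_equal(sum(part$percent), 100, tolerance = 0.1)
  }
})

test_that("plot gamma is invariant to subplot order and abundance splits", {
  m <- rand_cover(4, 8, seed = 51)
  des <- data.frame(subplot_id = rownames(m), plot_id = "P")
  g1 <- plot_diversity(abundance_matrix(m, "subplot"), des)$gamma
  perm <- m[c(3, 1, 4, 2), ]
  g2 <- plot_diversity(abundance_matrix(perm, "subplot"),
                       data.frame(subplot_id = rownames(perm),
                                  plot_id = "P"))$gamma
  expect_equal(g1, g2)
  # split taxon 1's abundance between two subplots
  split <- m
  split[2, 1] <- split[2, 1] + split[1, 1] / 2
  split[1, 1] <- split[1, 1] / 2
  g3 <- plot_diversity(abundance_matrix(split, "subplot"), des)$gamma
  expect_equal(g1, g3)
})

test_that("non-nested hierarchies are rejected with the violating unit", {
  m <- rand_cover(4, 5, seed = 61)
  h <- data.frame(plot = c("p1", "p1", "p2", "p2"),
                  type = c("A", "B", "A", "A"))
  expect_error(additive_partition(abundance_matrix(m, "plot"), h),
               "not nested.*p1")
})
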