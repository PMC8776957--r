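# Shared fixtures: all built in code at test time.

# small nested survey config (single island keeps runtime down)
small_config <- function(seed = 1, ...) {
  survey_config(islands = "PIC", plots_per_cell = 2,
                species_pool_size = 24, seed = seed, ...)
}

# null-community config: no type or island structure
null_config <- function(seed = 1, plots_per_cell = 4) {
  survey_config(islands = "PIC", plots_per_cell = plots_per_cell,
                species_pool_size = 30, type_effect = 0,
                island_effect = 0, seed = seed)
}

# random sparse non-negative cover matrix with unit/taxon names
rand_cover <- function(n_units, n_taxa, seed, sparsity = 0.4) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_units * n_taxa), n_units, n_taxa)
  m[stats::runif(length(m)) < sparsity] <- 0
  # every row keeps at least one positive entry
  for (i in seq_len(n_units)) {
    if (all(m[i, ] == 0)) m[i, 1] <- 1
  }
  dimnames(m) <- list(paste0("u", seq_len(n_units)),
                      paste0("t", seq_len(n_taxa)))
  m
}

# random distance matrix from points in a metric space
rand_distance <- function(n, seed, dim = 3) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(n * dim), n, dim)
  distance_matrix(as.matrix(stats::dist(pts)))
}

test_params <- function(ratio = 0.30, ...) {
  carbon_parameters(root_shoot_ratio = ratio, ...)
}

# distance matrix of labelled 1-D (or k-D) points
dist_from_points <- function(pts, labels = paste0("u", seq_len(NROW(pts)))) {
  m <- as.matrix(stats::dist(pts))
  dimnames(m) <- list(labels, labels)
  distance_matrix(m)
}

# n equidistant points at mutual distance val
const_dist <- function(n, val, labels = letters[seq_len(n)]) {
  m <- matrix(val, n, n)
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  distance_matrix(m)
}
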