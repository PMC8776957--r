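# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seeds: each named component of a run draws from
# its own seed derived by hashing (root seed, component index), so adding a
# component never shifts another component's draws.  Kept below 2^31 - 1.
derive_seed <- function(seed, component) {
  idx <- component_index(component)
  (as.numeric(seed) %% 1e9) * 1009 + 7919 * idx %% 2147483629
}

component_index <- function(component) {
  registry <- c(
    pool = 1L, occupancy = 2L, abundance = 3L, trees = 4L,
    litter = 5L, soil = 6L, nmds = 7L, permanova = 8L, indval = 9L,
    pipeline = 10L
  )
  if (!component %in% names(registry)) {
    stop("unknown seed component: ", component, call. = FALSE)
  }
  registry[[component]]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Configuration / schema error helpers carry a class so the CLI can map
# them to exit codes.
config_error <- function(...) {
  stop(structure(
    class = c("forestplots_config_error", "error", "condition"),
    list(message = sprintf(...), call = NULL)
  ))
}

data_error <- function(...) {
  stop(structure(
    class = c("forestplots_data_error", "error", "condition"),
    list(message = sprintf(...), call = NULL)
  ))
}

assert_numeric_vector <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    data_error("'%s' must be a finite numeric vector", name)
  }
  invisible(x)
}

#' Standard error of the mean, NA for n < 2
#' @noRd
std_error <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
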