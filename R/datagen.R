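# Synthetic nested vegetation surveys: 3 islands x 3 forest types x
# 10 plots x 4 subplots by default, with forest-type-dominant community
# structure, dendrometric distributions and litter/soil properties.

#' Configuration for a synthetic forest survey
#'
#' Describes the nested sampling design (islands > forest types > plots >
#' subplots) and the statistical structure of the generated communities:
#' per-type dominance, compositional effect sizes for forest type and
#' island, dendrometric distributions, and litter/soil parameters.
#'
#' @param islands character vector of island labels.
#' @param forest_types character vector of forest-type labels. The labels
#'   `"NF"` (natural forest), `"EW"` (exotic woodland) and `"PF"`
#'   (production forest) trigger type-specific dominant taxa: several
#'   endemic broadleaves for NF, one exotic broadleaf for EW and one
#'   exotic conifer for PF; any other label receives a single native
#'   broadleaf dominant.
#' @param plots_per_cell number of plots per island x forest-type cell.
#' @param subplots_per_plot number of subplots per plot.
#' @param subplot_area_m2 area of one subplot in m^2.
#' @param plot_area_m2 plot area in m^2; must equal
#'   `subplots_per_plot * subplot_area_m2`.
#' @param species_pool_size total number of taxa in the regional pool.
#' @param dominance per-forest-type concentration of the rank-abundance
#'   distribution (log-normal `sdlog` of cover conditional on presence);
#'   larger values concentrate cover in fewer taxa.
#' @param type_effect,island_effect non-negative effect magnitudes of
#'   forest type and island on community composition (logit-scale
#'   occupancy shifts and, for `type_effect`, the dominants' abundance
#'   boost). Setting both to zero yields a null community in which group
#'   labels are exchangeable.
#' @param base_occupancy baseline per-subplot presence probability of a
#'   taxon outside any type/island effect.
#' @param tree_density_mean per-type mean number of trees per plot
#'   (Poisson).
#' @param dbh_lognormal_params per-type `c(meanlog, sdlog)` of the branch
#'   DBH distribution in cm, truncated below at the 2.5 cm measurement
#'   threshold.
#' @param height_params per-type `c(mean, sd)` of tree height in m.
#' @param litter_params list with `mass_mean` (per-type mean litter dry
#'   mass, g m^-2), `mass_sdlog`, `conc_mean` and `conc_sd` (carbon
#'   concentration, g C kg^-1).
#' @param soil_params list with `om_island_mean` (per-island mean soil
#'   organic matter, g kg^-1), `om_type_mult` (per-type multiplier),
#'   `om_sdlog`, `bd_mean`/`bd_sd` (bulk density, kg m^-3) and
#'   `depth_range` (sampled soil depth window in m).
#' @param seed default integer seed used by [generate_survey()] when no
#'   explicit seed is given.
#'
#' @return An object of class `survey_config` (a validated list).
#' @seealso [generate_survey()], [generate_species_pool()]
#' @export
#' @examples
#' cfg <- survey_config(plots_per_cell = 2)
#' cfg$plots_per_cell
survey_config <- function(islands = c("PIC", "SMG", "TER"),
                          forest_types = c("NF", "EW", "PF"),
                          plots_per_cell = 10,
                          subplots_per_plot = 4,
                          subplot_area_m2 = 25,
                          plot_area_m2 = subplots_per_plot * subplot_area_m2,
                          species_pool_size = 108,
                          dominance = c(NF = 0.8, EW = 1.0, PF = 1.2),
                          type_effect = 1.75,
                          island_effect = 0.4,
                          base_occupancy = 0.09,
                          tree_density_mean = c(NF = 33, EW = 44, PF = 21),
                          dbh_lognormal_params = list(
                            NF = c(meanlog = log(9), sdlog = 0.60),
                            EW = c(meanlog = log(10), sdlog = 0.55),
                            PF = c(meanlog = log(30), sdlog = 0.35)
                          ),
                          height_params = list(
                            NF = c(mean = 4.8, sd = 1.2),
                            EW = c(mean = 8.8, sd = 2.0),
                            PF = c(mean = 22.7, sd = 4.0)
                          ),
                          litter_params = list(
                            mass_mean = c(NF = 350, EW = 480, PF = 780),
                            mass_sdlog = 0.35,
                            conc_mean = 400,
                            conc_sd = 40
                          ),
                          soil_params = list(
                            om_island_mean = c(PIC = 80, SMG = 210, TER = 245),
                            om_type_mult = c(NF = 0.9, EW = 1.1, PF = 1.0),
                            om_sdlog = 0.25,
                            bd_mean = 800,
                            bd_sd = 100,
                            depth_range = c(0.05, 0.10)
                          ),
                          seed = 1L) {
  cfg <- list(
    islands = as.character(islands),
    forest_types = as.character(forest_types),
    plots_per_cell = as.integer(plots_per_cell),
    subplots_per_plot = as.integer(subplots_per_plot),
    subplot_area_m2 = as.numeric(subplot_area_m2),
    plot_area_m2 = as.numeric(plot_area_m2),
    species_pool_size = as.integer(species_pool_size),
    dominance = dominance,
    type_effect = as.numeric(type_effect),
    island_effect = as.numeric(island_effect),
    base_occupancy = as.numeric(base_occupancy),
    tree_density_mean = tree_density_mean,
    dbh_lognormal_params = dbh_lognormal_params,
    height_params = height_params,
    litter_params = litter_params,
    soil_params = soil_params,
    seed = as.integer(seed)
  )
  class(cfg) <- "survey_config"
  validate_survey_config(cfg)
}

validate_survey_config <- function(cfg) {
  if (length(cfg$islands) < 1 || anyDuplicated(cfg$islands)) {
    config_error("'islands' must be a non-empty set of unique labels")
  }
  if (length(cfg$forest_types) < 1 || anyDuplicated(cfg$forest_types)) {
    config_error("'forest_types' must be a non-empty set of unique labels")
  }
  for (fld in c("plots_per_cell", "subplots_per_plot", "species_pool_size")) {
    if (is.na(cfg[[fld]]) || cfg[[fld]] < 1) {
      config_error("'%s' must be a count >= 1", fld)
    }
  }
  if (!isTRUE(all.equal(cfg$plot_area_m2,
                        cfg$subplots_per_plot * cfg$subplot_area_m2))) {
    config_error(
      "'plot_area_m2' (%g) must equal subplots_per_plot * subplot_area_m2 (%g)",
      cfg$plot_area_m2, cfg$subplots_per_plot * cfg$subplot_area_m2
    )
  }
  for (fld in c("type_effect", "island_effect")) {
    if (!is.finite(cfg[[fld]]) || cfg[[fld]] < 0) {
      config_error("'%s' must be a finite non-negative number", fld)
    }
  }
  if (!is.finite(cfg$base_occupancy) ||
      cfg$base_occupancy <= 0 || cfg$base_occupancy >= 1) {
    config_error("'base_occupancy' must lie in (0, 1)")
  }
  n_dom <- sum(vapply(cfg$forest_types, function(t) {
    if (t == "NF") 3L else 1L
  }, integer(1)))
  if (cfg$species_pool_size < n_dom + 3L) {
    config_error(
      "'species_pool_size' (%d) too small to host %d per-type dominants plus all status classes",
      cfg$species_pool_size, n_dom
    )
  }
  cfg
}

# Resolve a per-forest-type parameter: a single unnamed value recycles,
# otherwise every configured type must be named.
per_type <- function(param, types, field) {
  if (is.list(param)) {
    if (!all(types %in% names(param))) {
      config_error("'%s' must name every forest type (%s)",
                   field, paste(types, collapse = ", "))
    }
    return(param[types])
  }
  if (length(param) == 1 && is.null(names(param))) {
    return(stats::setNames(rep(param, length(types)), types))
  }
  if (!all(types %in% names(param))) {
    config_error("'%s' must name every forest type (%s)",
                 field, paste(types, collapse = ", "))
  }
  param[types]
}

per_island <- function(param, islands, field) {
  if (length(param) == 1 && is.null(names(param))) {
    return(stats::setNames(rep(param, length(islands)), islands))
  }
  if (!all(islands %in% names(param))) {
    config_error("'%s' must name every island (%s)",
                 field, paste(islands, collapse = ", "))
  }
  param[islands]
}

#' Generate the regional species pool
#'
#' Builds the taxon table for a survey: per-type dominant taxa (an exotic
#' conifer for PF, an exotic broadleaf for EW, three endemic broadleaves
#' for NF) plus a background pool spanning the endemic/native/exotic
#' status classes and the four growth forms, each taxon carrying a
#' forest-type affinity weight in [0, 1].
#'
#' @param config a [survey_config()].
#' @param seed integer seed; defaults to the config's seed.
#' @return A data frame with one row per taxon: `taxon_id`, `name`,
#'   `status`, `growth_form`, `leaf_type`, `home_type`, `dominant`, and
#'   one `affinity.<type>` column per forest type.
#' @export
#' @examples
#' pool <- generate_species_pool(survey_config(species_pool_size = 20))
#' table(pool$status)
generate_species_pool <- function(config, seed = config$seed) {
  config <- validate_survey_config(config)
  types <- config$forest_types
  with_seed(derive_seed(seed, "pool"), {
    dom <- do.call(rbind, lapply(types, function(t) {
      if (t == "NF") {
        data.frame(
          name = paste0("Endemic canopy dominant ", 1:3, " (", t, ")"),
          status = "endemic", growth_form = "tree", leaf_type = "broadleaf",
          home_type = t, dominant = TRUE, stringsAsFactors = FALSE
        )
      } else if (t == "PF") {
        data.frame(
          name = paste0("Plantation conifer dominant (", t, ")"),
          status = "exotic", growth_form = "tree", leaf_type = "conifer",
          home_type = t, dominant = TRUE, stringsAsFactors = FALSE
        )
      } else if (t == "EW") {
        data.frame(
          name = paste0("Invasive broadleaf dominant (", t, ")"),
          status = "exotic", growth_form = "tree", leaf_type = "broadleaf",
          home_type = t, dominant = TRUE, stringsAsFactors = FALSE
        )
      } else {
        data.frame(
          name = paste0("Canopy dominant (", t, ")"),
          status = "native", growth_form = "tree", leaf_type = "broadleaf",
          home_type = t, dominant = TRUE, stringsAsFactors = FALSE
        )
      }
    }))
    n_bg <- config$species_pool_size - nrow(dom)
    # Background pool skewed towards the natural forest: most of the
    # archipelago's species richness sits there.
    home_w <- stats::setNames(rep(0.15, length(types)), types)
    if ("NF" %in% types) home_w["NF"] <- 0.55
    if ("EW" %in% types) home_w["EW"] <- 0.30
    home_w <- home_w / sum(home_w)
    status <- sample(c("endemic", "native", "exotic"), n_bg,
                     replace = TRUE, prob = c(0.35, 0.40, 0.25))
    # Force all three status classes to be represented when there is room.
    if (n_bg >= 3) status[1:3] <- c("endemic", "native", "exotic")
    growth <- sample(c("tree", "shrub", "herb", "fern"), n_bg,
                     replace = TRUE, prob = c(0.30, 0.20, 0.30, 0.20))
    leaf <- ifelse(growth == "tree" & stats::runif(n_bg) < 0.05,
                   "conifer", "broadleaf")
    bg <- data.frame(
      name = paste0("Background taxon ", seq_len(n_bg)),
      status = status, growth_form = growth, leaf_type = leaf,
      home_type = sample(types, n_bg, replace = TRUE, prob = home_w),
      dominant = FALSE, stringsAsFactors = FALSE
    )
    pool <- rbind(dom, bg)
    pool$taxon_id <- sprintf("T%03d", seq_len(nrow(pool)))
    aff <- matrix(0.15, nrow(pool), length(types),
                  dimnames = list(NULL, paste0("affinity.", types)))
    for (j in seq_along(types)) {
      aff[pool$home_type == types[j], j] <- 1
    }
    aff[pool$dominant, ] <- 0.02
    for (j in seq_along(types)) {
      aff[pool$dominant & pool$home_type == types[j], j] <- 1
    }
    pool <- cbind(
      pool[, c("taxon_id", "name", "status", "growth_form", "leaf_type",
               "home_type", "dominant")],
      as.data.frame(aff)
    )
    rownames(pool) <- NULL
    pool
  })
}

#' Generate a complete synthetic survey
#'
#' Draws a full nested survey from a [survey_config()]: the design table,
#' a subplot-level cover matrix with forest-type-structured composition,
#' per-tree branch DBH and height records, and per-plot litter and soil
#' samples. With equal seed and config the result is identical between
#' calls.
#'
#' Composition model: a taxon occupies a subplot with probability
#' `plogis(qlogis(base_occupancy) + type_effect * s_type +
#' island_effect * s_island)` where `s_type` is +1 in the taxon's home
#' forest type and -1 elsewhere (double for dominants) and `s_island` is a
#' fixed standard-normal taxon x island score; cover conditional on
#' presence is log-normal on a percent scale, truncated at 100, with the
#' dominants' location raised by `1.25 * type_effect` in their home type.
#' With `type_effect = island_effect = 0` all group structure vanishes.
#'
#' @param config a [survey_config()].
#' @param seed integer seed; defaults to the config's seed.
#' @return An object of class `survey_dataset`: a list with elements
#'   `taxa`, `cover` (an [abundance_matrix()] at subplot level), `trees`,
#'   `litter`, `soil`, `design` and `config`.
#' @export
#' @examples
#' ds <- generate_survey(survey_config(plots_per_cell = 1, seed = 42))
#' nrow(ds$design)  # islands x types x 1 plot x 4 subplots
generate_survey <- function(config, seed = config$seed) {
  config <- validate_survey_config(config)
  taxa <- generate_species_pool(config, seed)
  design <- survey_design(config)
  plots <- unique(design[, c("plot_id", "cell_id", "forest_type", "island")])
  rownames(plots) <- NULL

  types <- config$forest_types
  islands <- config$islands
  n_taxa <- nrow(taxa)

  # Fixed taxon x island scores give islands a compositional signature
  # that scales with island_effect (zero effect => no signature).
  island_score <- with_seed(derive_seed(seed, "occupancy"), {
    matrix(stats::rnorm(n_taxa * length(islands)), n_taxa, length(islands),
           dimnames = list(taxa$taxon_id, islands))
  })

  type_score <- matrix(-1, n_taxa, length(types),
                       dimnames = list(taxa$taxon_id, types))
  for (j in seq_along(types)) {
    home <- taxa$home_type == types[j]
    type_score[home, j] <- 1
    type_score[taxa$dominant & !home, j] <- -2
    type_score[taxa$dominant & home, j] <- 2
  }

  sdlog_cover <- per_type(config$dominance, types, "dominance")

  cover <- with_seed(derive_seed(seed, "abundance"), {
    vals <- matrix(0, nrow(design), n_taxa,
                   dimnames = list(design$subplot_id, taxa$taxon_id))
    eta0 <- stats::qlogis(config$base_occupancy)
    for (i in seq_len(nrow(design))) {
      ty <- design$forest_type[i]
      isl <- design$island[i]
      p <- stats::plogis(eta0 + config$type_effect * type_score[, ty] +
                           config$island_effect * island_score[, isl])
      pres <- stats::runif(n_taxa) < p
      if (!any(pres)) next
      mu <- rep(log(5), n_taxa)
      boost <- taxa$dominant & taxa$home_type == ty
      mu[boost] <- mu[boost] + 1.25 * config$type_effect
      x <- stats::rlnorm(sum(pres), mu[pres], sdlog_cover[[ty]])
      vals[i, pres] <- pmin(x, 100)
    }
    vals
  })

  trees <- generate_trees(config, taxa, plots, seed)
  litter <- generate_litter(config, plots, seed)
  soil <- generate_soil(config, plots, seed)

  structure(
    list(
      taxa = taxa,
      cover = abundance_matrix(cover, level = "subplot"),
      trees = trees,
      litter = litter,
      soil = soil,
      design = design,
      config = config
    ),
    class = "survey_dataset"
  )
}

survey_design <- function(config) {
  grid <- expand.grid(
    plot = seq_len(config$plots_per_cell),
    forest_type = config$forest_types,
    island = config$islands,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$cell_id <- paste(grid$island, grid$forest_type, sep = ".")
  grid$plot_id <- sprintf("%s.%02d", grid$cell_id, grid$plot)
  design <- grid[rep(seq_len(nrow(grid)), each = config$subplots_per_plot), ]
  design$subplot <- rep(seq_len(config$subplots_per_plot), nrow(grid))
  design$subplot_id <- sprintf("%s.s%d", design$plot_id, design$subplot)
  rownames(design) <- NULL
  design[, c("subplot_id", "plot_id", "cell_id", "forest_type", "island")]
}

generate_trees <- function(config, taxa, plots, seed) {
  types <- config$forest_types
  dens <- per_type(config$tree_density_mean, types, "tree_density_mean")
  dbh_par <- per_type(config$dbh_lognormal_params, types,
                      "dbh_lognormal_params")
  h_par <- per_type(config$height_params, types, "height_params")
  woody <- taxa$growth_form %in% c("tree", "shrub")
  with_seed(derive_seed(seed, "trees"), {
    out <- vector("list", nrow(plots))
    for (i in seq_len(nrow(plots))) {
      ty <- plots$forest_type[i]
      n <- stats::rpois(1, dens[[ty]])
      if (n == 0) {
        out[[i]] <- NULL
        next
      }
      aff <- taxa[[paste0("affinity.", ty)]]
      w <- ifelse(woody, aff^2, 0)
      dom_home <- woody & taxa$dominant & taxa$home_type == ty
      w[dom_home] <- w[dom_home] * if (ty == "NF") 6 else 40
      tx <- sample(taxa$taxon_id, n, replace = TRUE, prob = w)
      ml <- dbh_par[[ty]][["meanlog"]]
      sl <- dbh_par[[ty]][["sdlog"]]
      nb <- 1L + stats::rpois(n, ifelse(
        taxa$growth_form[match(tx, taxa$taxon_id)] == "shrub", 0.8, 0.15))
      dbh <- lapply(seq_len(n), function(k) {
        # resample until the largest branch clears the 2.5 cm threshold
        for (attempt in 1:50) {
          d <- stats::rlnorm(nb[k], ml - 0.5 * log(nb[k]), sl)
          if (max(d) >= 2.5) return(round(d, 2))
        }
        round(pmax(d, 2.5), 2)
      })
      h <- pmax(1.4, stats::rnorm(n, h_par[[ty]][["mean"]],
                                  h_par[[ty]][["sd"]]))
      out[[i]] <- data.frame(
        tree_id = sprintf("%s.t%03d", plots$plot_id[i], seq_len(n)),
        plot_id = plots$plot_id[i],
        taxon_id = tx,
        branch_dbh_cm = vapply(dbh, paste, character(1), collapse = ";"),
        height_m = round(h, 2),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, out)
    if (is.null(out)) {
      out <- data.frame(
        tree_id = character(), plot_id = character(), taxon_id = character(),
        branch_dbh_cm = character(), height_m = numeric(),
        stringsAsFactors = FALSE
      )
    }
    rownames(out) <- NULL
    out
  })
}

generate_litter <- function(config, plots, seed) {
  lp <- config$litter_params
  types <- config$forest_types
  mass_mean <- per_type(lp$mass_mean, types, "litter_params$mass_mean")
  with_seed(derive_seed(seed, "litter"), {
    ty <- plots$forest_type
    mass <- stats::rlnorm(nrow(plots),
                          log(unlist(mass_mean[ty])) - lp$mass_sdlog^2 / 2,
                          lp$mass_sdlog)
    conc <- pmin(pmax(stats::rnorm(nrow(plots), lp$conc_mean, lp$conc_sd),
                      200), 600)
    data.frame(
      plot_id = plots$plot_id,
      dry_mass_g_per_m2 = round(mass, 1),
      carbon_conc_gC_per_kg = round(conc, 1),
      stringsAsFactors = FALSE
    )
  })
}

generate_soil <- function(config, plots, seed) {
  sp <- config$soil_params
  om_isl <- per_island(sp$om_island_mean, config$islands,
                       "soil_params$om_island_mean")
  om_ty <- per_type(sp$om_type_mult, config$forest_types,
                    "soil_params$om_type_mult")
  with_seed(derive_seed(seed, "soil"), {
    om_mean <- unlist(om_isl[plots$island]) * unlist(om_ty[plots$forest_type])
    om <- pmin(stats::rlnorm(nrow(plots), log(om_mean) - sp$om_sdlog^2 / 2,
                             sp$om_sdlog), 1000)
    bd <- pmin(pmax(stats::rnorm(nrow(plots), sp$bd_mean, sp$bd_sd),
                    400), 1200)
    depth <- stats::runif(nrow(plots), sp$depth_range[1], sp$depth_range[2])
    data.frame(
      plot_id = plots$plot_id,
      bulk_density_kg_per_m3 = round(bd, 1),
      organic_matter_g_per_kg = round(om, 1),
      depth_m = round(depth, 3),
      pH = round(stats::rnorm(nrow(plots), 5, 0.5), 2),
      stringsAsFactors = FALSE
    )
  })
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("Synthetic forest survey\n")
  cat(sprintf("  %d islands x %d forest types x %d plots/cell, %d subplots/plot\n",
              length(x$config$islands), length(x$config$forest_types),
              x$config$plots_per_cell, x$config$subplots_per_plot))
  cat(sprintf("  %d taxa, %d subplot cover rows, %d trees, %d litter, %d soil samples\n",
              nrow(x$taxa), nrow(x$cover$values), nrow(x$trees),
              nrow(x$litter), nrow(x$soil)))
  invisible(x)
}
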