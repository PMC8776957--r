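# Carbon-stock accounting in three pools: standing trees (allometric AGB
# + root:shoot BGB + leaf-type carbon fractions), leaf litter, and soil
# organic carbon (Van Bemmelen conversion). All stocks in Mg C ha^-1.

#' Carbon accounting parameters
#'
#' @param root_shoot_ratio below- to above-ground biomass ratio
#'   (mandatory; no biological default is assumed — the customary source
#'   is IPCC 2006 GHG Inventory Guidelines Table 4.4, temperate oceanic
#'   forest class).
#' @param carbon_fraction_broadleaf carbon content of broadleaf dry
#'   biomass (default 0.48).
#' @param carbon_fraction_conifer carbon content of conifer dry biomass
#'   (default 0.51).
#' @param van_bemmelen organic-matter-to-carbon conversion factor
#'   (default 0.58, i.e. OM = 1.724 C).
#' @param fraction_scope whether the carbon fraction applies to
#'   `"agb_plus_bgb"` (default: total tree biomass) or `"agb_only"`
#'   (sensitivity variant that ignores the root pool).
#' @return A validated list of class `carbon_parameters`.
#' @export
#' @examples
#' carbon_parameters(root_shoot_ratio = 0.25)
carbon_parameters <- function(root_shoot_ratio,
                              carbon_fraction_broadleaf = 0.48,
                              carbon_fraction_conifer = 0.51,
                              van_bemmelen = 0.58,
                              fraction_scope = c("agb_plus_bgb",
                                                 "agb_only")) {
  fraction_scope <- match.arg(fraction_scope)
  if (missing(root_shoot_ratio)) {
    config_error("'root_shoot_ratio' must be supplied explicitly")
  }
  if (!is.finite(root_shoot_ratio) || root_shoot_ratio < 0 ||
      root_shoot_ratio >= 1.5) {
    config_error("'root_shoot_ratio' must lie in [0, 1.5)")
  }
  for (f in c(carbon_fraction_broadleaf, carbon_fraction_conifer,
              van_bemmelen)) {
    if (!is.finite(f) || f <= 0 || f >= 1) {
      config_error("carbon fractions must lie in (0, 1)")
    }
  }
  structure(
    list(root_shoot_ratio = root_shoot_ratio,
         carbon_fraction_broadleaf = carbon_fraction_broadleaf,
         carbon_fraction_conifer = carbon_fraction_conifer,
         van_bemmelen = van_bemmelen,
         fraction_scope = fraction_scope),
    class = "carbon_parameters"
  )
}

# Closed registry of allometric forms. D: equivalent diameter (cm),
# H: height (m), BA: per-tree basal area (m^2), NB: branch count.
allometric_forms <- function() {
  list(
    power_D = list(
      required = "D",
      coefs = c("a", "b"),
      eval = function(co, pr) co[["a"]] * pr[["D"]]^co[["b"]]
    ),
    power_D2H = list(
      required = c("D", "H"),
      coefs = c("a", "b"),
      eval = function(co, pr) co[["a"]] * (pr[["D"]]^2 * pr[["H"]])^co[["b"]]
    ),
    loglinear_DH = list(
      required = c("D", "H"),
      coefs = c("a", "b", "c"),
      eval = function(co, pr) {
        exp(co[["a"]] + co[["b"]] * log(pr[["D"]]) +
              co[["c"]] * log(pr[["H"]]))
      }
    ),
    linear_BA = list(
      required = "BA",
      coefs = c("a", "b"),
      eval = function(co, pr) co[["a"]] + co[["b"]] * pr[["BA"]]
    ),
    linear = list(
      required = character(0),  # taken from the declared predictors
      coefs = NULL,             # intercept + coef_<predictor>
      eval = function(co, pr) {
        val <- co[["intercept"]] %||% 0
        for (nm in names(co)) {
          if (startsWith(nm, "coef_")) {
            val <- val + co[[nm]] * pr[[sub("coef_", "", nm)]]
          }
        }
        val
      }
    )
  )
}

#' Build an allometric-equation registry
#'
#' @param entries list of entries, each a list with `taxon_id` (or
#'   `"generic.broadleaf"` / `"generic.conifer"` / `"generic"` for
#'   fallbacks), `form` (one of `power_D`, `power_D2H`, `loglinear_DH`,
#'   `linear_BA`, `linear`), `coefficients` (named list), optional
#'   `predictors` (declared subset of D/H/BA/NB) and `source` citation.
#' @return Validated list of class `allometry_registry`, keyed by
#'   taxon_id.
#' @export
allometry_registry <- function(entries) {
  forms <- allometric_forms()
  out <- list()
  for (e in entries) {
    if (is.null(e$taxon_id) || is.null(e$form) || is.null(e$coefficients)) {
      config_error("registry entry needs taxon_id, form and coefficients")
    }
    if (!e$form %in% names(forms)) {
      config_error("unknown allometric form '%s' (entry '%s')",
                   e$form, e$taxon_id)
    }
    spec <- forms[[e$form]]
    if (e$form == "linear") {
      declared <- e$predictors %||%
        sub("coef_", "", grep("^coef_", names(e$coefficients), value = TRUE))
      used <- sub("coef_", "",
                  grep("^coef_", names(e$coefficients), value = TRUE))
      if (!setequal(declared, used)) {
        config_error("entry '%s': declared predictors (%s) differ from those used (%s)",
                     e$taxon_id, paste(declared, collapse = ","),
                     paste(used, collapse = ","))
      }
      e$predictors <- declared
    } else {
      missing_co <- setdiff(spec$coefs, names(e$coefficients))
      if (length(missing_co)) {
        config_error("entry '%s': missing coefficient(s) %s for form '%s'",
                     e$taxon_id, paste(missing_co, collapse = ", "), e$form)
      }
      e$predictors <- spec$required
    }
    bad <- setdiff(e$predictors, c("D", "H", "BA", "NB"))
    if (length(bad)) {
      config_error("entry '%s': unknown predictor(s) %s",
                   e$taxon_id, paste(bad, collapse = ", "))
    }
    e$source <- e$source %||% "unspecified"
    out[[e$taxon_id]] <- e
  }
  if (!any(startsWith(names(out), "generic"))) {
    config_error("registry needs at least one generic fallback entry")
  }
  class(out) <- "allometry_registry"
  out
}

#' Default synthetic allometric registry
#'
#' Generic broadleaf/conifer power-law equations with plausible
#' magnitudes for temperate trees. These are synthetic stand-in
#' coefficients for demonstration and simulation, not literature values.
#'
#' @return An [allometry_registry()].
#' @export
default_allometry <- function() {
  allometry_registry(list(
    list(taxon_id = "generic.broadleaf", form = "power_D",
         coefficients = list(a = 0.12, b = 2.4),
         source = "synthetic generic broadleaf power law"),
    list(taxon_id = "generic.conifer", form = "power_D2H",
         coefficients = list(a = 0.035, b = 0.95),
         source = "synthetic generic conifer D2H power law"),
    list(taxon_id = "generic", form = "power_D",
         coefficients = list(a = 0.10, b = 2.4),
         source = "synthetic generic fallback")
  ))
}

#' Read an allometric registry from a YAML file
#'
#' The file holds a top-level `equations:` list whose items carry the
#' [allometry_registry()] entry fields.
#'
#' @param path YAML file path.
#' @return An [allometry_registry()].
#' @export
read_allometry <- function(path) {
  if (!file.exists(path)) config_error("registry file not found: %s", path)
  doc <- yaml::read_yaml(path)
  entries <- doc$equations %||% doc
  allometry_registry(entries)
}

# predictor values of one tree record
tree_predictors <- function(branch_dbh_cm, height_m) {
  d <- as.numeric(branch_dbh_cm)
  list(
    D = sqrt(sum(d^2)),            # quadratic-mean equivalent diameter, cm
    H = height_m,
    BA = tree_basal_area(d),       # m^2 per tree
    NB = length(d)
  )
}

resolve_equation <- function(registry, taxon_id, leaf_type) {
  if (!is.null(registry[[taxon_id]])) {
    return(list(entry = registry[[taxon_id]], generic = FALSE))
  }
  for (key in c(paste0("generic.", leaf_type), "generic")) {
    if (!is.null(registry[[key]])) {
      return(list(entry = registry[[key]], generic = TRUE))
    }
  }
  data_error("no allometric equation resolves taxon '%s'", taxon_id)
}

#' Above-ground biomass of one tree
#'
#' Resolves the taxon in the registry (falling back to the leaf-type
#' generic entry) and evaluates the allometric form on the tree's
#' predictors. Multi-branch trees feed single-diameter forms through the
#' quadratic-mean equivalent diameter `sqrt(sum(d_i^2))`, which preserves
#' the tree's total basal area.
#'
#' @param branch_dbh_cm branch diameters, cm.
#' @param height_m tree height, m.
#' @param taxon_id taxon identifier.
#' @param registry an [allometry_registry()].
#' @param leaf_type `"broadleaf"` or `"conifer"` (used for fallback
#'   resolution).
#' @return AGB in kg dry mass (negative predictions clamp to 0 with a
#'   warning); attribute `generic` flags fallback use.
#' @export
#' @examples
#' reg <- allometry_registry(list(
#'   list(taxon_id = "generic", form = "power_D",
#'        coefficients = list(a = 0.1, b = 2))))
#' tree_agb(10, 8, "sp1", reg)  # 0.1 * 10^2 = 10 kg
tree_agb <- function(branch_dbh_cm, height_m, taxon_id, registry,
                     leaf_type = "broadleaf") {
  res <- resolve_equation(registry, taxon_id, leaf_type)
  entry <- res$entry
  pr <- tree_predictors(branch_dbh_cm, height_m)
  for (need in entry$predictors) {
    if (is.null(pr[[need]]) || !is.finite(pr[[need]])) {
      data_error("taxon '%s': predictor '%s' unavailable", taxon_id, need)
    }
  }
  val <- allometric_forms()[[entry$form]]$eval(entry$coefficients, pr)
  if (!is.finite(val)) {
    data_error("taxon '%s': non-finite biomass prediction", taxon_id)
  }
  if (val < 0) {
    warnf("taxon '%s': negative AGB prediction clamped to 0", taxon_id)
    val <- 0
  }
  structure(val, generic = res$generic)
}

#' Total tree carbon from AGB
#'
#' `BGB = root_shoot_ratio * AGB`; carbon is the leaf-type fraction of
#' `AGB + BGB` (or of AGB alone under the `"agb_only"` scope).
#'
#' @param agb_kg above-ground biomass, kg.
#' @param leaf_type `"broadleaf"` or `"conifer"`.
#' @param params a [carbon_parameters()].
#' @return Carbon in kg.
#' @export
#' @examples
#' p <- carbon_parameters(root_shoot_ratio = 0.30)
#' tree_total_carbon(100, "conifer", p)  # 0.51 * 130 = 66.3
tree_total_carbon <- function(agb_kg, leaf_type, params) {
  if (agb_kg < 0) data_error("AGB must be non-negative")
  frac <- switch(leaf_type,
    broadleaf = params$carbon_fraction_broadleaf,
    conifer = params$carbon_fraction_conifer,
    data_error("unknown leaf_type '%s'", leaf_type)
  )
  biomass <- if (params$fraction_scope == "agb_only") {
    agb_kg
  } else {
    agb_kg * (1 + params$root_shoot_ratio)
  }
  frac * biomass
}

#' Tree carbon stock of one plot
#'
#' Applies the DBH retention filter, evaluates per-tree AGB and carbon,
#' and scales the plot total to Mg C ha^-1.
#'
#' @param trees tree records of one plot (see [stand_structure()]).
#' @param taxa taxon table with `taxon_id` and `leaf_type`.
#' @param registry an [allometry_registry()].
#' @param params a [carbon_parameters()].
#' @param plot_area_m2 plot area, m^2.
#' @return List: `total_Mg_ha`, `per_taxon_Mg_ha` (named vector summing
#'   to the total), `n_generic` (trees served by a fallback equation).
#' @export
plot_tree_carbon <- function(trees, taxa, registry, params,
                             plot_area_m2 = 100) {
  kept <- retain_trees(trees)
  if (nrow(kept) == 0) {
    return(list(total_Mg_ha = 0, per_taxon_Mg_ha = numeric(0),
                n_generic = 0L))
  }
  leaf <- taxa$leaf_type[match(kept$taxon_id, taxa$taxon_id)]
  if (anyNA(leaf)) {
    data_error("taxa table does not resolve: %s",
               paste(unique(kept$taxon_id[is.na(leaf)]), collapse = ", "))
  }
  branches <- parse_branches(kept$branch_dbh_cm)
  carbon_kg <- numeric(nrow(kept))
  n_generic <- 0L
  for (i in seq_len(nrow(kept))) {
    agb <- tree_agb(branches[[i]], kept$height_m[i], kept$taxon_id[i],
                    registry, leaf[i])
    if (isTRUE(attr(agb, "generic"))) n_generic <- n_generic + 1L
    carbon_kg[i] <- tree_total_carbon(as.numeric(agb), leaf[i], params)
  }
  scale <- 1e-3 * 10000 / plot_area_m2  # kg -> Mg, plot -> ha
  per_taxon <- tapply(carbon_kg, kept$taxon_id, sum) * scale
  list(
    total_Mg_ha = sum(carbon_kg) * scale,
    per_taxon_Mg_ha = stats::setNames(as.numeric(per_taxon),
                                      names(per_taxon)),
    n_generic = n_generic
  )
}

#' Leaf-litter carbon stock
#'
#' `C (Mg ha^-1) = dry mass (g m^-2) x concentration (g C kg^-1) x 1e-5`
#' (g to kg on the concentration, m^2 to ha, g to Mg).
#'
#' @param dry_mass_g_per_m2 litter dry mass, g m^-2.
#' @param carbon_conc_gC_per_kg carbon concentration, g C per kg dry
#'   litter (<= 1000).
#' @return Carbon stock in Mg ha^-1.
#' @export
#' @examples
#' litter_carbon(500, 400)  # 2.0 Mg ha^-1
litter_carbon <- function(dry_mass_g_per_m2, carbon_conc_gC_per_kg) {
  if (any(dry_mass_g_per_m2 < 0)) data_error("litter mass must be >= 0")
  if (any(carbon_conc_gC_per_kg < 0 | carbon_conc_gC_per_kg > 1000)) {
    data_error("carbon concentration must lie in [0, 1000] g C kg^-1")
  }
  dry_mass_g_per_m2 * carbon_conc_gC_per_kg * 1e-5
}

#' Soil organic-carbon stock
#'
#' `C (Mg ha^-1) = OM (g kg^-1) x 1e-3 x van_bemmelen x bulk density
#' (kg m^-3) x depth (m) x 1e4 (m^2 ha^-1) x 1e-3 (Mg kg^-1)`, using the
#' measured per-site sampling depth.
#'
#' @param organic_matter_g_per_kg soil organic matter, g kg^-1.
#' @param bulk_density_kg_per_m3 bulk density, kg m^-3.
#' @param depth_m sampled depth, m, in (0, 0.30].
#' @param params a [carbon_parameters()] (supplies the Van Bemmelen
#'   factor).
#' @return Carbon stock in Mg ha^-1.
#' @export
#' @examples
#' p <- carbon_parameters(root_shoot_ratio = 0.25)
#' soil_carbon(100, 800, 0.10, p)  # 46.4 Mg ha^-1
soil_carbon <- function(organic_matter_g_per_kg, bulk_density_kg_per_m3,
                        depth_m, params) {
  if (any(organic_matter_g_per_kg < 0 | organic_matter_g_per_kg > 1000)) {
    data_error("organic matter must lie in [0, 1000] g kg^-1")
  }
  if (any(bulk_density_kg_per_m3 <= 0)) {
    data_error("bulk density must be positive")
  }
  if (any(depth_m <= 0 | depth_m > 0.30)) {
    data_error("soil depth must lie in (0, 0.30] m")
  }
  organic_matter_g_per_kg * 1e-3 * params$van_bemmelen *
    bulk_density_kg_per_m3 * depth_m * 1e4 * 1e-3
}

#' Carbon-stock report for a survey
#'
#' Per-plot stocks in the three pools (trees above+below ground, leaf
#' litter, soil) plus island x forest-type cell means and standard
#' errors. Plots lacking a litter or soil sample report `NA`, never a
#' silent zero.
#'
#' @param dataset a `survey_dataset`.
#' @param registry an [allometry_registry()] (default
#'   [default_allometry()]).
#' @param params a [carbon_parameters()].
#' @return List of class `carbon_report`: `plots` (per-plot data frame
#'   with `c_trees_Mg_ha`, `c_litter_Mg_ha`, `c_soil_Mg_ha`), `cells`
#'   (per-cell mean and se per pool), and `per_taxon` (named list of
#'   per-plot taxon breakdowns).
#' @export
carbon_report <- function(dataset, registry = default_allometry(), params) {
  if (!inherits(params, "carbon_parameters")) {
    config_error("'params' must come from carbon_parameters()")
  }
  key <- dataset$design[!duplicated(dataset$design$plot_id),
                        c("plot_id", "cell_id", "forest_type", "island")]
  area <- dataset$config$plot_area_m2 %||% 100
  per_taxon <- list()
  rows <- lapply(seq_len(nrow(key)), function(i) {
    p <- key$plot_id[i]
    tr <- dataset$trees[dataset$trees$plot_id == p, , drop = FALSE]
    tc <- plot_tree_carbon(tr, dataset$taxa, registry, params, area)
    per_taxon[[p]] <<- tc$per_taxon_Mg_ha
    li <- dataset$litter[dataset$litter$plot_id == p, , drop = FALSE]
    so <- dataset$soil[dataset$soil$plot_id == p, , drop = FALSE]
    data.frame(
      plot_id = p,
      c_trees_Mg_ha = tc$total_Mg_ha,
      c_litter_Mg_ha = if (nrow(li)) {
        mean(litter_carbon(li$dry_mass_g_per_m2, li$carbon_conc_gC_per_kg))
      } else NA_real_,
      c_soil_Mg_ha = if (nrow(so)) {
        mean(soil_carbon(so$organic_matter_g_per_kg,
                         so$bulk_density_kg_per_m3, so$depth_m, params))
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  plots <- merge(key, do.call(rbind, rows), by = "plot_id", sort = FALSE)
  cells <- do.call(rbind, lapply(split(plots, plots$cell_id), function(df) {
    data.frame(
      cell_id = df$cell_id[1], island = df$island[1],
      forest_type = df$forest_type[1], n = nrow(df),
      c_trees_mean = mean(df$c_trees_Mg_ha),
      c_trees_se = std_error(df$c_trees_Mg_ha),
      c_litter_mean = mean(df$c_litter_Mg_ha, na.rm = TRUE),
      c_litter_se = std_error(df$c_litter_Mg_ha),
      c_soil_mean = mean(df$c_soil_Mg_ha, na.rm = TRUE),
      c_soil_se = std_error(df$c_soil_Mg_ha),
      stringsAsFactors = FALSE
    )
  }))
  rownames(cells) <- NULL
  structure(list(plots = plots, cells = cells, per_taxon = per_taxon),
            class = "carbon_report")
}

#' @export
print.carbon_report <- function(x, ...) {
  cat("Carbon stock report (Mg C ha^-1)\n")
  print.data.frame(format(x$cells, digits = 3), row.names = FALSE)
  invisible(x)
}
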