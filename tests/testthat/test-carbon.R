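# Carbon pools: allometric engine, unit chains, report conservation.

test_that("allometric forms evaluate correctly with fallback resolution", {
  reg <- allometry_registry(list(
    list(taxon_id = "sp1", form = "power_D",
         coefficients = list(a = 0.1, b = 2.0)),
    list(taxon_id = "sp2", form = "loglinear_DH",
         coefficients = list(a = -2, b = 2.2, c = 0.5)),
    list(taxon_id = "generic", form = "power_D",
         coefficients = list(a = 0.05, b = 2.0))
  ))
  expect_equal(as.numeric(tree_agb(10, 8, "sp1", reg)), 10)
  expect_equal(as.numeric(tree_agb(10, 8, "sp2", reg)),
               exp(-2 + 2.2 * log(10) + 0.5 * log(8)), tolerance = 1e-12)
  # threshold diameter evaluates finitely
  expect_true(is.finite(tree_agb(2.5, 2, "sp1", reg)))
  # unknown taxon falls to generic and is flagged
  agb <- tree_agb(10, 8, "mystery", reg)
  expect_equal(as.numeric(agb), 5)
  expect_true(attr(agb, "generic"))
  expect_false(attr(tree_agb(10, 8, "sp1", reg), "generic"))
  # multi-branch trees use the quadratic-mean equivalent diameter
  expect_equal(as.numeric(tree_agb(c(6, 8), 8, "sp1", reg)),
               0.1 * sqrt(6^2 + 8^2)^2, tolerance = 1e-12)
})

test_that("registry validation rejects malformed entries", {
  expect_error(allometry_registry(list(
    list(taxon_id = "sp1", form = "nope", coefficients = list(a = 1))
  )), "unknown allometric form")
  expect_error(allometry_registry(list(
    list(taxon_id = "sp1", form = "power_D", coefficients = list(a = 1)),
    list(taxon_id = "generic", form = "power_D",
         coefficients = list(a = 1, b = 2))
  )), "missing coefficient")
  expect_error(allometry_registry(list(
    list(taxon_id = "sp1", form = "power_D",
         coefficients = list(a = 1, b = 2))
  )), "generic fallback")
  expect_error(allometry_registry(list(
    list(taxon_id = "generic", form = "linear", predictors = c("D", "H"),
         coefficients = list(intercept = 1, coef_D = 2))
  )), "declared predictors")
})

test_that("the YAML registry round-trips through the reader", {
  path <- system.file("extdata", "allometry_synthetic.yml",
                      package = "forestplots")
  reg <- read_allometry(path)
  expect_s3_class(reg, "allometry_registry")
  expect_true("generic.conifer" %in% names(reg))
  expect_equal(as.numeric(tree_agb(10, 8, "T005", reg)),
               0.13 * 10^2.35, tolerance = 1e-12)
  # linear form with branch count
  expect_equal(as.numeric(tree_agb(c(3, 4), 2, "T011", reg)),
               0.5 + 1.8 * 5 + 0.6 * 2, tolerance = 1e-12)
})

test_that("tree carbon applies root:shoot ratio and leaf-type fractions", {
  p <- test_params(0.30)
  expect_equal(tree_total_carbon(100, "conifer", p), 66.3, tolerance = 1e-9)
  expect_equal(tree_total_carbon(100, "broadleaf", p), 62.4,
               tolerance = 1e-9)
  expect_equal(tree_total_carbon(0, "conifer", p), 0)
  expect_error(tree_total_carbon(100, "palm", p), "leaf_type")
  p_agb <- test_params(0.30, fraction_scope = "agb_only")
  expect_equal(tree_total_carbon(100, "conifer", p_agb), 51)
  expect_error(carbon_parameters(), "root_shoot_ratio")
  expect_error(carbon_parameters(root_shoot_ratio = 2), "root_shoot_ratio")
})

test_that("litter and soil unit chains reproduce worked values", {
  expect_equal(litter_carbon(500, 400), 2.0, tolerance = 1e-12)
  expect_equal(litter_carbon(0, 400), 0)
  # pure-carbon limit: stock reduces to mass x 1e-2
  expect_equal(litter_carbon(500, 1000), 500 * 1e-2, tolerance = 1e-12)
  p <- test_params()
  expect_equal(soil_carbon(100, 800, 0.10, p), 46.4, tolerance = 1e-12)
  expect_equal(soil_carbon(0, 800, 0.10, p), 0)
  # halving depth halves the stock
  expect_equal(soil_carbon(100, 800, 0.05, p),
               soil_carbon(100, 800, 0.10, p) / 2, tolerance = 1e-12)
  expect_error(soil_carbon(100, 800, 0.5, p), "depth")
})

test_that("carbon is dimensionally stable and monotone in its inputs", {
  reg <- default_allometry()
  p <- test_params()
  # cm -> m -> cm round trip on diameters
  d <- c(7.3, 11.1)
  expect_equal(as.numeric(tree_agb(d, 9, "z", reg)),
               as.numeric(tree_agb((d / 100) * 100, 9, "z", reg)),
               tolerance = 1e-12)
  # increasing DBH increases power-law biomass
  expect_gt(as.numeric(tree_agb(20, 9, "z", reg)),
            as.numeric(tree_agb(10, 9, "z", reg)))
  # fraction bracketing for any mixed stand
  taxa <- data.frame(taxon_id = c("b1", "c1"),
                     leaf_type = c("broadleaf", "conifer"))
  trees <- data.frame(
    tree_id = c("t1", "t2", "t3"), plot_id = "P",
    taxon_id = c("b1", "c1", "b1"),
    branch_dbh_cm = c("12", "18", "7;5"), height_m = c(8, 15, 6),
    stringsAsFactors = FALSE
  )
  mixed <- plot_tree_carbon(trees, taxa, reg, p)$total_Mg_ha
  all_broad <- plot_tree_carbon(trees, within(taxa, leaf_type <- "broadleaf"),
                                reg, p)$total_Mg_ha
  all_conif <- plot_tree_carbon(trees, within(taxa, leaf_type <- "conifer"),
                                reg, p)$total_Mg_ha
  expect_gte(mixed, min(all_broad, all_conif))
  expect_lte(mixed, max(all_broad, all_conif))
  # breakdown conservation and area scaling
  res <- plot_tree_carbon(trees, taxa, reg, p, plot_area_m2 = 100)
  expect_equal(sum(res$per_taxon_Mg_ha), res$total_Mg_ha, tolerance = 1e-9)
  res25 <- plot_tree_carbon(trees, taxa, reg, p, plot_area_m2 = 25)
  expect_equal(res25$total_Mg_ha, 4 * res$total_Mg_ha, tolerance = 1e-9)
})

test_that("one tree of 66.3 kg C on 100 m2 scales to 6.63 Mg per hectare", {
  reg <- allometry_registry(list(
    list(taxon_id = "generic", form = "linear",
         predictors = "D", coefficients = list(intercept = 100, coef_D = 0))
  ))
  taxa <- data.frame(taxon_id = "c1", leaf_type = "conifer")
  trees <- data.frame(tree_id = "t1", plot_id = "P", taxon_id = "c1",
                      branch_dbh_cm = "10", height_m = 10,
                      stringsAsFactors = FALSE)
  res <- plot_tree_carbon(trees, taxa, reg, test_params(0.30), 100)
  expect_equal(res$total_Mg_ha, 6.63, tolerance = 1e-9)
})

test_that("the survey report conserves pools and flags missing samples", {
  ds <- generate_survey(small_config(seed = 8))
  p <- test_params(0.25)
  rep_full <- carbon_report(ds, default_allometry(), p)
  expect_equal(nrow(rep_full$plots), 6)
  for (pl in rep_full$plots$plot_id) {
    expect_equal(sum(rep_full$per_taxon[[pl]]),
                 rep_full$plots$c_trees_Mg_ha[rep_full$plots$plot_id == pl],
                 tolerance = 1e-9)
  }
  # missing litter -> NA, never zero
  ds2 <- ds
  ds2$litter <- ds$litter[-1, ]
  rep2 <- carbon_report(ds2, default_allometry(), p)
  expect_true(is.na(rep2$plots$c_litter_Mg_ha[1]))
  # single plot per cell: se undefined
  cfg1 <- survey_config(islands = "PIC", plots_per_cell = 1,
                        species_pool_size = 24, seed = 2)
  rep3 <- carbon_report(generate_survey(cfg1), default_allometry(), p)
  expect_true(all(is.na(rep3$cells$c_trees_se)))
})
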