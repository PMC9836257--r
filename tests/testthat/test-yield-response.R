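test_that("a noiseless in-family response is fitted exactly", {
  cfg <- quick_config(n = 120, noise_sd = 0, seed = 21)
  panel <- generate_panel(cfg)
  fit <- suppressWarnings(     # noiseless data: lm warns of a perfect fit
    yield_response(panel, crop = "wheat", orders = c(PH = 2, Fert = 2)))
  expect_gt(fit$adj_r_squared, 1 - 1e-9)
  expect_lt(fit$sigma, 1e-6)
  ## predictions reproduce the planted truth everywhere
  expect_equal(unname(predict(fit, panel)),
               true_yield(panel, cfg, "wheat"), tolerance = 1e-8)
})

test_that("stored basis round-trips the training design", {
  panel <- generate_panel(quick_config(n = 150, seed = 22))
  fit <- yield_response(panel, crop = "wheat", orders = c(PH = 2, Fert = 2))
  pr <- predict(fit, panel)
  expect_equal(max(abs(pr - fitted(fit)) / (abs(fitted(fit)) + 1e-12)), 0,
               tolerance = 1e-8)
  ## residuals + fitted reassemble the observed yields
  expect_equal(fitted(fit) + residuals(fit), panel$Yield[panel$crop ==
                                                           "wheat"])
})

test_that("order selection recovers planted polynomial degrees", {
  ## quadratic pH, quadratic fertilizer, everything else linear
  cfg <- synth_config(n_subkebeles = 715, crops = "wheat",
                      noise_sd = 0.05, seed = 23)
  panel <- generate_panel(cfg)
  spec <- model_spec(alpha = 0.01)
  ord <- select_orders(panel, spec, covariates = c("PH", "Fert", "SOC"))
  expect_equal(unname(ord["PH"]), 2L)
  expect_equal(unname(ord["Fert"]), 2L)
  expect_equal(unname(ord["SOC"]), 1L)  # planted linear-only covariate
})

test_that("alpha = 1 pushes every searched covariate to max_order", {
  panel <- generate_panel(quick_config(n = 120, seed = 24))
  spec <- model_spec(alpha = 1, max_order = 3)
  ord <- select_orders(panel, spec, covariates = "PH")
  expect_equal(unname(ord["PH"]), 3L)
})

test_that("order selection is invariant to affine covariate rescaling", {
  panel <- generate_panel(quick_config(n = 200, noise_sd = 0.1, seed = 25))
  spec <- model_spec(alpha = 0.05)
  ord1 <- select_orders(panel, spec, covariates = c("PH", "Elevation"))
  panel2 <- panel
  panel2$Elevation <- panel2$Elevation / 1000 + 3   # km with an offset
  panel2$PH <- 2 * panel2$PH - 1
  ord2 <- select_orders(panel2, spec, covariates = c("PH", "Elevation"))
  expect_identical(ord1, ord2)
})

test_that("dropping a zero-effect covariate barely moves the rest", {
  cfg <- quick_config(n = 400, noise_sd = 0.2, seed = 26)
  panel <- generate_panel(cfg)          # planted Irg.Area effect is zero
  full_spec <- model_spec()
  red_spec <- model_spec(continuous = setdiff(full_spec$continuous,
                                              "Irg.Area"))
  f1 <- yield_response(panel, "wheat", full_spec,
                       orders = c(PH = 2, Fert = 2))
  f2 <- yield_response(panel, "wheat", red_spec,
                       orders = c(PH = 2, Fert = 2))
  shared <- intersect(names(coef(f1)), names(coef(f2)))
  se1 <- sqrt(diag(vcov(f1)))[shared]
  expect_true(all(abs(coef(f1)[shared] - coef(f2)[shared]) <= se1))
})

test_that("marginal curve peaks near the planted optimum with sane CIs", {
  cfg <- synth_config(n_subkebeles = 715, crops = "wheat", seed = 27)
  panel <- generate_panel(cfg)
  fit <- yield_response(panel, "wheat", orders = c(PH = 2, Fert = 2))
  cur <- marginal_curve(fit, "PH")
  expect_true(all(diff(cur$value) > 0))
  expect_true(all(cur$lwr <= cur$fit & cur$fit <= cur$upr))
  peak <- cur$value[which.max(cur$fit)]
  expect_gt(peak, 6.3)
  expect_lt(peak, 6.7)
  ## pinning covariates at their means is a no-op
  cur2 <- marginal_curve(fit, "PH",
                         overrides = as.list(fit$means[c("Fert", "SOC")]))
  expect_equal(cur$fit, cur2$fit)
  ## a linear planted fertilizer response gives a constant curve slope
  lin_cfg <- synth_config(n_subkebeles = 120, crops = "wheat",
                          n_zones = 1, noise_sd = 0,
                          true_response = flat_truth(2, fert_lin = 16e-4),
                          seed = 28)
  lin_fit <- suppressWarnings(yield_response(generate_panel(lin_cfg),
                                             "wheat",
                                             orders = c(PH = 1, Fert = 1)))
  fcur <- marginal_curve(lin_fit, "Fert")
  slopes <- diff(fcur$fit) / diff(fcur$value)
  expect_equal(slopes, rep(16e-4, length(slopes)), tolerance = 1e-6)
  ## out-of-support grids warn but do not fail
  expect_warning(marginal_curve(fit, "PH", grid = seq(2.5, 9.5, 0.5)),
                 "outside the training support")
})

test_that("yield gains respect the minimum-target convention and add up", {
  panel <- generate_panel(synth_config(n_subkebeles = 300, crops = "wheat",
                                       seed = 29))
  fit <- yield_response(panel, "wheat", orders = c(PH = 2, Fert = 2))
  expect_equal(yield_gain(fit, 6.0, 6.0)$gain, 0)
  expect_equal(yield_gain(fit, 6.0, 6.0)$pct, 0)
  expect_equal(yield_gain(fit, 6.8, 6.5)$gain, 0)  # already above target
  ## with the convention off, gains are pure prediction differences
  g_ab <- yield_gain(fit, 5.0, 5.8, minimum_target = FALSE)$gain
  g_bc <- yield_gain(fit, 5.8, 6.4, minimum_target = FALSE)$gain
  g_ac <- yield_gain(fit, 5.0, 6.4, minimum_target = FALSE)$gain
  expect_equal(g_ab + g_bc, g_ac, tolerance = 1e-10)
  ## percentage uses the low-pH prediction as denominator
  g <- yield_gain(fit, 5.5, 6.5)
  expect_equal(g$pct, 100 * g$gain / g$baseline)
})

test_that("equivalent fertilizer inverts a planted linear response", {
  ## planted 0.16 mt/ha per 100 kg/ha; a 0.3 mt/ha gain needs 187.5 kg/ha
  cfg <- synth_config(n_subkebeles = 150, crops = "wheat", n_zones = 1,
                      noise_sd = 0,
                      true_response = flat_truth(2, fert_lin = 0.0016),
                      seed = 30)
  fit <- suppressWarnings(yield_response(generate_panel(cfg), "wheat",
                                         orders = c(PH = 1, Fert = 1)))
  fe <- equivalent_fertilizer(fit, 0.3, at_ph = 5.5, cap = 400)
  expect_true(fe$attainable)
  expect_equal(fe$kg_ha, 187.5, tolerance = 0.01)
  expect_equal(equivalent_fertilizer(fit, 0, at_ph = 5.5)$kg_ha, 0)
  expect_error(equivalent_fertilizer(fit, -0.1, at_ph = 5.5),
               "non-negative")
})

test_that("gains beyond the saturating fertilizer response are flagged", {
  ## concave planted response peaking at +200 kg/ha with max gain 0.08
  cfg <- synth_config(n_subkebeles = 150, crops = "wheat", n_zones = 1,
                      noise_sd = 0,
                      true_response = flat_truth(2, fert_lin = 8e-4,
                                                 fert_quad = -2e-6),
                      seed = 31)
  fit <- suppressWarnings(yield_response(generate_panel(cfg), "wheat",
                                         orders = c(PH = 1, Fert = 2)))
  fe <- equivalent_fertilizer(fit, 0.3, at_ph = 5.5, baseline_fert = 0,
                              cap = 400)
  expect_false(fe$attainable)
  expect_true(is.na(fe$kg_ha))
  expect_equal(fe$max_gain, 0.08, tolerance = 0.005)
})

test_that("duplicating the panel leaves the fert-pH slope, shrinks its SE", {
  panel <- generate_panel(synth_config(n_subkebeles = 200, seed = 32))
  est1 <- region_fert_ph_slope(panel, "Amhara")
  est2 <- region_fert_ph_slope(rbind(panel, panel), "Amhara")
  expect_equal(est2$slope, est1$slope, tolerance = 1e-10)
  expect_lt(est2$se, est1$se)
  expect_error(region_fert_ph_slope(panel[1:10, ], "Amhara"), ">= 30")
})

test_that("fit-time validation names empty cells and collinear columns", {
  panel <- generate_panel(quick_config(n = 150, seed = 33))
  broken <- panel[!(panel$year == 2011 &
                      panel$agro_eco_zone == "zone2"), ]
  expect_error(yield_response(broken, "wheat",
                              orders = c(PH = 2, Fert = 2)),
               "2011/zone2")
  dup <- panel
  dup$SOC <- dup$SND           # exact collinearity
  expect_error(yield_response(dup, "wheat", orders = c(PH = 1)),
               "collinear")
})

test_that("JSON serialization round-trips predictions and gains exactly", {
  panel <- generate_panel(quick_config(n = 200, seed = 34))
  fit <- yield_response(panel, "wheat", orders = c(PH = 2, Fert = 2))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(unname(predict(back, panel)), unname(predict(fit, panel)),
               tolerance = 1e-10)
  g1 <- yield_gain(fit, 5.5, 6.5)
  g2 <- yield_gain(back, 5.5, 6.5)
  expect_equal(g2$gain, g1$gain, tolerance = 1e-10)
  expect_equal(g2$se, g1$se, tolerance = 1e-8)
  expect_equal(back$orders, fit$orders)
})

test_that("summary and simulate behave like standard model methods", {
  panel <- generate_panel(quick_config(n = 150, seed = 35))
  fit <- yield_response(panel, "wheat", orders = c(PH = 2, Fert = 2))
  s <- summary(fit)
  expect_s3_class(s, "summary.yield_response")
  expect_equal(rownames(s$table), names(coef(fit)))
  expect_output(print(s), "Signif")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n, 3))
  expect_true(all(sims >= 0))
})
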