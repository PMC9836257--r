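test_that("panel generation is deterministic and leaves global RNG alone", {
  cfg <- synth_config(n_subkebeles = 150, seed = 1)
  p1 <- generate_panel(cfg)
  set.seed(999)                      # unrelated global state
  p2 <- generate_panel(cfg)
  expect_identical(p1, p2)
  ## a different master seed moves every stochastic column
  p3 <- generate_panel(synth_config(n_subkebeles = 150, seed = 2))
  expect_false(identical(p1$Yield, p3$Yield))
})

test_that("generated panels satisfy the structural invariants", {
  panel <- generate_panel(synth_config(n_subkebeles = 200, seed = 3))
  expect_silent(validate_panel(panel))
  expect_equal(nrow(panel), 200 * 7 * 2)
  expect_false(anyNA(panel))
  for (v in c("Ext.Area", "Imp.Seed", "Irg.Area", "Damage")) {
    expect_true(all(panel[[v]] >= 0 & panel[[v]] <= 100))
  }
  expect_true(all(panel$PH > 3 & panel$PH < 10))
  expect_true(all(panel$Yield >= 0))
  expect_true(all(table(panel$year, panel$agro_eco_zone) > 0))
  ## soil is a sub-kebele property: constant across years and crops
  expect_equal(nrow(unique(panel[c("subkebele_id", "PH", "CEC")])), 200)
})

test_that("degenerate noise with a flat planted response gives exact yields", {
  cfg <- synth_config(n_subkebeles = 60, n_zones = 1, noise_sd = 0,
                      true_response = flat_truth(intercept = 2), seed = 4)
  panel <- generate_panel(cfg)
  expect_true(all(panel$Yield == 2.0))
})

test_that("true_yield is the closed-form planted response", {
  cfg <- synth_config(seed = 1)
  ## all effects zero, intercept 1.5
  flat <- synth_config(n_zones = 1, true_response = flat_truth(1.5),
                       seed = 1)
  row <- data.frame(PH = 5.2, Fert = 120, PDSI = 1, Elevation = 2100,
                    SOC = 2, SND = 40, CEC = 12, Ext.Area = 50,
                    Imp.Seed = 10, Irg.Area = 0, Damage = 5, DistPP = 8,
                    PSNP = 1, AGP = 0)
  expect_equal(true_yield(row, flat, crop = "wheat"), 1.5)
  ## peak is a stationary point: no gain from moving to the peak
  tr <- cfg$true_response$wheat
  at_peak <- row; at_peak$PH <- tr$ph_peak
  near_peak <- row; near_peak$PH <- tr$ph_peak
  expect_equal(true_yield(at_peak, cfg, "wheat") -
                 true_yield(near_peak, cfg, "wheat"), 0)
  ## hand-computed quadratic difference for the 5.5 -> 6.5 move
  lo <- row; lo$PH <- 5.5
  hi <- row; hi$PH <- 6.5
  planted <- tr$ph_gain * ((5.5 - tr$ph_peak)^2 - (6.5 - tr$ph_peak)^2)
  expect_equal(true_yield(hi, cfg, "wheat") - true_yield(lo, cfg, "wheat"),
               planted)
  expect_equal(planted, tr$ph_gain)   # peak at 6.5 makes the gain the amplitude
  expect_error(true_yield(row[-1], cfg, "wheat"), "PH")
})

test_that("covariate moments and acidity mixture match the config", {
  cfg <- synth_config(n_subkebeles = 400, seed = 6)   # 5600 rows
  panel <- generate_panel(cfg)
  sk <- unique(panel[c("subkebele_id", "region", "PH", "SND")])
  n <- nrow(sk)
  ## SND: mean within 3 standard errors (mild truncation bias aside)
  expect_lt(abs(mean(sk$SND) - 35), 3 * 10 / sqrt(n) + 0.2)
  ## per-region pH means
  for (r in c("Amhara", "Oromia")) {
    reg <- cfg$regions[cfg$regions$region == r, ]
    ph <- sk$PH[sk$region == r]
    expect_lt(abs(mean(ph) - reg$ph_mean),
              3 * reg$ph_sd / sqrt(length(ph)) + 0.02)
  }
  ## fraction of highly acidic rows vs the mixture-implied probability
  p_high <- sum(cfg$regions$weight / sum(cfg$regions$weight) *
                  pnorm(5.5, cfg$regions$ph_mean, cfg$regions$ph_sd))
  obs <- mean(sk$PH <= 5.5)
  expect_lt(abs(obs - p_high), 3 * sqrt(p_high * (1 - p_high) / n))
})

test_that("planted fertilizer-pH slope is recovered by within-region OLS", {
  one_region <- data.frame(region = "Amhara", ph_mean = 5.6, ph_sd = 0.5,
                           weight = 1, fert_ph_slope = -45.8)
  cfg <- synth_config(n_subkebeles = 715, regions = one_region,
                      crops = "wheat", seed = 8)
  panel <- generate_panel(cfg)
  est <- region_fert_ph_slope(panel, "Amhara")
  expect_lt(abs(est$slope - (-45.8)), 3)
  expect_lt(est$p_value, 1e-10)
  ## a planted zero slope stays statistically quiet
  flat_region <- transform(one_region, fert_ph_slope = 0)
  p0 <- generate_panel(synth_config(n_subkebeles = 300,
                                    regions = flat_region,
                                    crops = "wheat", seed = 9))
  est0 <- region_fert_ph_slope(p0, "Amhara")
  expect_lt(abs(est0$slope / est0$se), 4)
})

test_that("config invariants are enforced with named errors", {
  expect_error(synth_config(n_subkebeles = 2), "n_subkebeles")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(true_response = modifyList(
    default_true_response(), list(wheat = list(intercept = 1, ph_peak = 9,
                                               ph_gain = 0.3,
                                               fert_lin = 0,
                                               fert_quad = 0)))),
    "ph_peak")
  expect_error(synth_config(n_crushers = 0), "n_crushers")
  expect_error(synth_config(crops = "teff"), "teff")
})

test_that("landscape generation is deterministic with crushers on roads", {
  cfg <- synth_config(seed = 7)
  l1 <- generate_landscape(cfg)
  l2 <- generate_landscape(cfg)
  expect_identical(l1$friction$time$data, l2$friction$time$data)
  expect_identical(as.data.frame(l1$crushers), as.data.frame(l2$crushers))
  expect_equal(nrow(l1$crushers), 3)
  ## crushers sit on road cells (fast cells)
  for (i in seq_len(nrow(l1$crushers))) {
    cells <- limeval:::grid_xy_cell(l1$roads, l1$crushers$x_km[i],
                                    l1$crushers$y_km[i])
    expect_gt(l1$roads$data[cells], 0)
  }
  ## slope in range, friction positive
  expect_true(all(l1$slope$data >= 0 & l1$slope$data <= 30))
  expect_true(all(l1$friction$time$data > 0))
})
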