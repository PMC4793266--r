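test_that("supported activity is an error-weighted mean of 226Ra", {
  sl <- data.frame(top_cm = 0:1, bottom_cm = 1:2,
                   ra226_bq_kg = c(3.5, 4.1), ra226_sd = c(0.6, 0.7))
  core <- sediment_core(sl, "c", treatment = "scar",
                        barrel_inserted_cm = 2, recovered_cm = 2)
  sup <- estimate_supported(core)
  # hand-computed weighted-mean oracle
  w <- 1 / c(0.6, 0.7)^2
  expect_equal(sup$value, sum(w * c(3.5, 4.1)) / sum(w), tolerance = 1e-12)
  expect_equal(sup$value, 3.8, tolerance = 0.1)
  expect_equal(sup$sd, sqrt(1 / sum(w)), tolerance = 1e-12)
  expect_equal(sup$method, "ra226")

  single <- sediment_core(data.frame(top_cm = 0, bottom_cm = 1,
                                     ra226_bq_kg = 10, ra226_sd = 1),
                          "c", treatment = "scar",
                          barrel_inserted_cm = 1, recovered_cm = 1)
  s1 <- estimate_supported(single)
  expect_equal(s1$value, 10)
  expect_equal(s1$sd, 1)
})

test_that("supported activity falls back to the deep total-210Pb plateau", {
  sl <- data.frame(top_cm = 0:5, bottom_cm = 1:6,
                   pb210_bq_kg = c(50, 30, 18, 10, 10, 10),
                   pb210_sd = rep(1, 6))
  core <- sediment_core(sl, "c", treatment = "meadow",
                        barrel_inserted_cm = 6, recovered_cm = 6)
  sup <- estimate_supported(core)
  expect_equal(sup$value, 10)
  expect_equal(sup$method, "deep_pb210")
  # invariant to slice input order
  core2 <- sediment_core(sl[sample(6), ], "c", treatment = "meadow",
                         barrel_inserted_cm = 6, recovered_cm = 6)
  expect_equal(estimate_supported(core2)$value, sup$value)
  # neither source available -> error
  bare <- sediment_core(data.frame(top_cm = 0:1, bottom_cm = 1:2), "c",
                        treatment = "meadow", barrel_inserted_cm = 2,
                        recovered_cm = 2)
  expect_error(estimate_supported(bare), "226Ra|210Pb")
})

test_that("excess profile subtracts supported with quadrature errors", {
  sl <- data.frame(top_cm = 0:2, bottom_cm = 1:3, dbd_g_cm3 = 1,
                   pb210_bq_kg = c(50, 50, 50), pb210_sd = 2)
  core <- sediment_core(sl, "c", treatment = "meadow",
                        barrel_inserted_cm = 3, recovered_cm = 3)
  prof <- compute_excess_profile(core, list(value = 10, sd = 1))
  expect_equal(prof$excess_bq_kg, rep(40, 3))
  expect_equal(prof$excess_sd, rep(sqrt(4 + 1), 3))
  expect_equal(attr(prof, "supported"), 10)
  # total equal to supported -> all-zero excess, retained (not truncated)
  prof0 <- compute_excess_profile(core, list(value = 50, sd = 0))
  expect_equal(prof0$excess_bq_kg, rep(0, 3))
  expect_error(compute_excess_profile(
    sediment_core(data.frame(top_cm = 0:1, bottom_cm = 1:2,
                             pb210_bq_kg = c(10, 10)), "c",
                  treatment = "meadow", barrel_inserted_cm = 2,
                  recovered_cm = 2), 10), ">= 3")
})

test_that("mixed-layer detection finds the surface plateau", {
  lam <- pb210_lambda()
  mid <- seq(0.5, 29.5, 1)
  excess <- ifelse(mid < 15, 30, 30 * exp(-lam * (mid - 15) / 0.1))
  prof <- make_profile(mid, excess, sd = 2, thick = 1)
  expect_equal(detect_mixed_layer(prof), 15)
  # strictly exponential noiseless profile: immediate decline
  expect_equal(detect_mixed_layer(exp_profile()), 0)
  # uniform excess over the whole core -> mixed layer = core depth
  flat <- make_profile(seq(0.5, 29.5, 1), rep(25, 30), sd = 2, thick = 1)
  expect_equal(detect_mixed_layer(flat), 30)
})

test_that("mixed-layer rule agrees with an independent re-implementation", {
  oracle <- function(prof, k = 2) {
    # independent: test every prefix, keep the deepest passing one
    best <- 0
    for (j in 2:nrow(prof)) {
      mu <- mean(prof$excess_bq_kg[1:j])
      if (max(abs(prof$excess_bq_kg[1:j] - mu) - k * prof$excess_sd[1:j]) <= 0) {
        best <- prof$mid_cm[j] + prof$thickness_cm[j] / 2
      }
    }
    best
  }
  set.seed(3)
  for (rep in 1:25) {
    mid <- seq(0.5, 39.5, 1)
    ml_true <- sample(c(0, 5, 10, 15), 1)
    base <- 30 * exp(-pb210_lambda() * pmax(mid - ml_true, 0) / 0.25)
    excess <- base * exp(rnorm(40, 0, 0.1))
    prof <- make_profile(mid, excess, sd = 0.1 * excess, thick = 1)
    expect_equal(detect_mixed_layer(prof), oracle(prof))
  }
})

test_that("excess horizon is the first sub-detection depth", {
  prof <- make_profile(seq(5, 30, 5), c(20, 10, 5, 0.5, 0.2, -0.3), sd = 1,
                       thick = 5)
  hz <- detect_excess_horizon(prof)
  expect_true(hz$reached)
  expect_equal(hz$horizon_cm, 20)          # depth of the 4th point
  # all ~ zero within sigma -> horizon 0 (undatable core)
  allz <- make_profile(seq(0.5, 10.5, 1), rnorm(11, 0, 0.3), sd = 1, thick = 1)
  expect_equal(detect_excess_horizon(allz)$horizon_cm, 0)
  # noiseless exponential never reaches zero -> not-reached flag
  hz2 <- detect_excess_horizon(exp_profile())
  expect_false(hz2$reached)
  expect_equal(hz2$horizon_cm, Inf)
})

test_that("CF:CS recovers the rate exactly on a noiseless exponential", {
  for (s_true in c(0.1, 0.25, 0.27, 1.5)) {
    prof <- exp_profile(n = 26, c0 = 18.5, s = s_true)
    am <- fit_cfcs(prof)
    expect_equal(am$status, "ok")
    expect_equal(am$sed_rate_cm_yr, s_true, tolerance = 1e-10)
  }
  # lambda as stated: ln(2) / 22.23
  expect_equal(pb210_lambda(), 0.031183, tolerance = 1e-4)
})

test_that("CF:CS flags flat or increasing profiles as undatable", {
  flat <- make_profile(seq(0.5, 25.5, 1), rep(12, 26), sd = 1, thick = 1)
  expect_equal(fit_cfcs(flat)$status, "undatable")
  expect_true(is.na(fit_cfcs(flat)$sed_rate_cm_yr))
  rising <- make_profile(seq(0.5, 25.5, 1), seq(1, 26), sd = 1, thick = 1)
  expect_equal(fit_cfcs(rising)$status, "undatable")
  few <- make_profile(c(1, 2), c(10, 5), sd = 0.1, thick = 1)
  expect_equal(fit_cfcs(few)$status, "undatable")
  expect_error(age_at_depth(10, fit_cfcs(flat)), "undatable")
})

test_that("noisy CF:CS estimate lies within 3 SE of truth (fixed seed)", {
  set.seed(101)
  lam <- pb210_lambda()
  mid <- seq(0.5, 25.5, 1)
  truth <- 20 * exp(-lam * mid / 0.25)
  excess <- truth * exp(rnorm(26, 0, sqrt(log(1.01))))
  prof <- make_profile(mid, excess, sd = 0.1 * excess, thick = 1)
  am <- fit_cfcs(prof)
  expect_equal(am$status, "ok")
  expect_lt(abs(am$sed_rate_cm_yr - 0.25), 3 * am$sed_rate_se)
})

test_that("mixed-layer exclusion marks the rate as an upper limit", {
  prof <- exp_profile(n = 30)
  am <- fit_cfcs(prof, mixed_layer_cm = 10)
  expect_equal(am$status, "mixed")
  expect_true(am$upper_limit)
  expect_equal(am$sed_rate_cm_yr, 0.25, tolerance = 1e-10)
})

test_that("inventory integrates excess over mass depth with unit factor 10", {
  flat <- make_profile(seq(0.5, 29.5, 1), rep(4, 30), sd = 0, thick = 1, dbd = 1)
  inv <- excess_inventory(flat)
  expect_equal(inv$inventory_bq_m2, 4 * 1 * 30 * 10)
  expect_equal(inv$flux_bq_m2_yr, pb210_lambda() * 1200)
  zero <- make_profile(seq(0.5, 29.5, 1), rep(0, 30), sd = 0, thick = 1, dbd = 1)
  expect_equal(excess_inventory(zero)$inventory_bq_m2, 0)
  # negative contributions clipped in inventory, kept in the unclipped sum
  mix <- make_profile(c(0.5, 1.5, 2.5), c(10, -2, 5), sd = 0, thick = 1, dbd = 1)
  invm <- excess_inventory(mix)
  expect_equal(invm$inventory_bq_m2, 150)
  expect_equal(invm$inventory_unclipped_bq_m2, 130)
  expect_equal(invm$n_clipped, 1)
  # missing DBD in range errors
  bad <- make_profile(c(0.5, 1.5, 2.5), c(10, 5, 2), sd = 0, thick = 1,
                      dbd = c(1, NA, 1))
  expect_error(excess_inventory(bad), "DBD")
})

test_that("noiseless constant-flux inventory closes to F/lambda, first order in dz", {
  lam <- pb210_lambda()
  inv_err <- function(thick) {
    p <- core_sim_params(activity_cv = 0, content_cv = 0, content_every = 1,
                         slice_cm = thick, length_cm = 200, seed = 1)
    sim <- simulate_core(p)
    core <- decompress_depths(sim$core)
    prof <- compute_excess_profile(core, list(value = p$supported_bq_kg, sd = 0))
    abs(excess_inventory(prof)$inventory_bq_m2 - 38 / lam)
  }
  e1 <- inv_err(1)
  expect_lt(e1 / (38 / lam), 0.01)
  # halving slice thickness at least halves the discretization error
  e05 <- inv_err(0.5)
  expect_lt(e05, e1 / 1.9)
})

test_that("atmospheric flux is linear in the inventory", {
  f1 <- atmospheric_flux(1225.5)
  expect_equal(f1$flux_bq_m2_yr, pb210_lambda() * 1225.5)
  expect_equal(atmospheric_flux(3 * 1225.5)$flux_bq_m2_yr, 3 * f1$flux_bq_m2_yr)
  expect_equal(atmospheric_flux(0)$flux_bq_m2_yr, 0)
  expect_equal(atmospheric_flux(1 / pb210_lambda())$flux_bq_m2_yr, 1)
  expect_error(atmospheric_flux(-5), ">= 0")
})

test_that("ages follow depth / rate with propagated SE and extrapolation flag", {
  prof <- exp_profile(s = 0.25)
  am <- fit_cfcs(prof)
  a <- age_at_depth(50, am)
  expect_equal(a$age_yr, 200, tolerance = 1e-9)
  expect_true(a$extrapolated)              # beyond ~5 half-lives
  expect_equal(age_at_depth(0, am)$age_yr, 0)
  a26 <- age_at_depth(26, am)
  expect_equal(a26$age_yr, 104, tolerance = 1e-9)
  expect_false(a26$extrapolated)
})

test_that("horizon refinement places the cutoff on the fitted curve", {
  set.seed(9)
  lam <- pb210_lambda()
  mid <- seq(0.5, 39.5, 1)
  truth <- 18.5 * exp(-lam * mid / 0.25)
  excess <- truth * exp(rnorm(40, 0, 0.1))
  prof <- make_profile(mid, excess, sd = pmax(0.1 * excess, 0.5), thick = 1)
  am <- fit_cfcs(prof)
  hz <- refine_horizon(prof, am)
  # analytic crossing of the true curve at 2 * median sigma
  sig <- median(prof$excess_sd)
  expected <- log(18.5 / (2 * sig)) * 0.25 / lam
  expect_equal(hz, expected, tolerance = 0.15 * expected)
  # no refinement for noiseless profiles or undatable models
  expect_true(is.na(refine_horizon(exp_profile(), fit_cfcs(exp_profile()))))
})
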