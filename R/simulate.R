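# Synthetic sediment cores and seascapes with known ground truth.
#
# The core generator follows the constant flux : constant sedimentation
# model: excess activity per unit mass C_xs(z) = F * exp(-lambda*z/s) /
# (10 * s * rho(z)), so that the depth-integrated inventory closes to F/lambda.
# Optional surface mixing homogenizes the top layer (mass-weighted, inventory-
# conserving) and optional erosion truncates the top of the profile before
# depths are re-indexed to zero.

#' Parameters for a synthetic sediment core
#'
#' Bundles the generating conditions of one simulated core. Defaults describe
#' a carbonate seagrass meadow: atmospheric flux 38 Bq/m^2/yr, sedimentation
#' 0.25 cm/yr, supported activity 5 Bq/kg, DBD 0.82 g/cm^3, organic carbon
#' decaying from 4% at the surface toward 1.2% at depth, 84% carbonate,
#' sand-dominated grain classes, 10% lognormal noise on activities and 5%
#' truncated-normal noise on contents, 1-cm slices to 40 cm.
#'
#' @param treatment `"meadow"` or `"scar"`.
#' @param flux_bq_m2_yr Atmospheric 210Pb flux F.
#' @param sed_rate_cm_yr Sedimentation rate s (cm/yr).
#' @param supported_bq_kg Supported 210Pb activity.
#' @param dbd_g_cm3 Surface dry bulk density.
#' @param dbd_trend_per_cm Linear DBD change with depth (g/cm^3 per cm).
#' @param corg_surface_pct,corg_decay_cm,corg_asymptote_pct Organic-carbon
#'   depth profile: `asymptote + (surface - asymptote) * exp(-z / decay)`.
#' @param caco3_pct Carbonate content (%).
#' @param d13c_permil Mean organic-matter carbon-isotope signature.
#' @param grain_means Named percentages for `coarse`, `medium`, `fine`,
#'   `vfine_mud` (renormalized to 100).
#' @param mixed_layer_cm Surface layer homogenized by mixing (0 = none).
#' @param erosion_truncation_cm Depth of surface sediment removed by erosion
#'   before re-indexing (0 = none).
#' @param activity_cv Lognormal coefficient of variation of activities.
#' @param content_cv Normal (truncated at physical bounds) CV of contents.
#' @param slice_cm Slice thickness (cm).
#' @param length_cm Recovered core length (cm).
#' @param compression_factor Barrel-inserted over recovered length (>= 1);
#'   1 means no coring compression.
#' @param content_every Analyze contents on every k-th slice (default 2,
#'   the usual alternate-slice design); 210Pb is measured on every slice and
#'   226Ra on every `ra_every`-th slice.
#' @param ra_every Spacing of 226Ra measurements (default 4).
#' @param water_depth_m Station water depth.
#' @param seed Integer seed fixing the full output; `NULL` uses the current
#'   RNG stream.
#' @return A list of class `core_sim_params`.
#' @seealso [simulate_core()], [sim_preset()]
#' @export
core_sim_params <- function(treatment = "meadow",
                            flux_bq_m2_yr = 38,
                            sed_rate_cm_yr = 0.25,
                            supported_bq_kg = 5,
                            dbd_g_cm3 = 0.82,
                            dbd_trend_per_cm = 0,
                            corg_surface_pct = 4,
                            corg_decay_cm = 8,
                            corg_asymptote_pct = 1.2,
                            caco3_pct = 84,
                            d13c_permil = -14,
                            grain_means = c(coarse = 9, medium = 38,
                                            fine = 39, vfine_mud = 14),
                            mixed_layer_cm = 0,
                            erosion_truncation_cm = 0,
                            activity_cv = 0.10,
                            content_cv = 0.05,
                            slice_cm = 1,
                            length_cm = 40,
                            compression_factor = 1,
                            content_every = 2L,
                            ra_every = 4L,
                            water_depth_m = 3,
                            seed = NULL) {
  p <- as.list(environment())
  if (p$flux_bq_m2_yr < 0 || p$sed_rate_cm_yr <= 0 || p$supported_bq_kg < 0 ||
      p$dbd_g_cm3 <= 0) {
    sc_validation_error("rates and activities must be non-negative (s, DBD > 0)")
  }
  if (p$activity_cv < 0 || p$activity_cv > 1 || p$content_cv < 0 || p$content_cv > 1) {
    sc_validation_error("CVs must lie in [0, 1]")
  }
  if (p$compression_factor < 1) sc_validation_error("compression_factor must be >= 1")
  if (p$length_cm * p$compression_factor <= p$mixed_layer_cm) {
    sc_validation_error("core length must exceed the mixed layer")
  }
  structure(p, class = "core_sim_params")
}

#' Shipped simulation presets
#'
#' Four configurations spanning the study conditions: two datable meadows
#' (`thomson_meadow`, `stark_meadow`, the latter with a 15-cm surface mixed
#' layer), a deeply mixed scar (`thomson_scar`, homogenized over 30 cm) and an
#' eroded scar (`stark_scar`, top 30 cm of the profile removed, leaving excess
#' indistinguishable from supported).
#'
#' @param name Preset name.
#' @param ... Overrides passed to [core_sim_params()].
#' @return A `core_sim_params`.
#' @export
sim_preset <- function(name = c("thomson_meadow", "stark_meadow",
                                "thomson_scar", "stark_scar"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    thomson_meadow = list(treatment = "meadow"),
    stark_meadow = list(treatment = "meadow", sed_rate_cm_yr = 0.27,
                        supported_bq_kg = 10, corg_surface_pct = 1.41,
                        corg_asymptote_pct = 1.41, d13c_permil = -13.8,
                        mixed_layer_cm = 15),
    thomson_scar = list(treatment = "scar", dbd_g_cm3 = 1.03,
                        supported_bq_kg = 3.8, corg_surface_pct = 0.30,
                        corg_asymptote_pct = 0.30, caco3_pct = 83,
                        d13c_permil = -15,
                        grain_means = c(coarse = 13, medium = 43,
                                        fine = 36, vfine_mud = 8),
                        mixed_layer_cm = 30),
    stark_scar = list(treatment = "scar", dbd_g_cm3 = 1.03,
                      supported_bq_kg = 10, corg_surface_pct = 0.30,
                      corg_asymptote_pct = 0.30, caco3_pct = 83,
                      d13c_permil = -14.6,
                      grain_means = c(coarse = 13, medium = 43,
                                      fine = 36, vfine_mud = 8),
                      erosion_truncation_cm = 30)
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(core_sim_params, args)
}

# mean-one lognormal multiplier with coefficient of variation cv
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

# normal noise truncated to [lo, hi] around x with sd = cv * x
tnoise <- function(x, cv, lo = 0, hi = 100) {
  if (cv == 0) return(x)
  pmin(pmax(stats::rnorm(length(x), x, cv * abs(x)), lo), hi)
}

#' Simulate a slice-resolved sediment core with known truth
#'
#' Generates a core under constant flux and constant sedimentation, with
#' optional surface mixing (mass-weighted homogenization of the top layer,
#' which conserves the inventory) and erosional truncation (removal of the
#' top of the profile before depths are re-indexed to zero). Multiplicative
#' lognormal noise is applied to activities, truncated normal noise to
#' contents; measurement sigmas are set to CV times the reported value. The
#' output is byte-identical under the same seed and parameters.
#'
#' @param params A [core_sim_params()].
#' @return List with `core` (a [sediment_core()] in as-recovered coordinates)
#'   and `truth` (a `synthetic_truth`: generating parameters plus closed-form
#'   surface excess `c0_bq_kg`, noiseless inventory, true 50-cm stock and
#'   accumulation rate).
#' @examples
#' sim <- simulate_core(core_sim_params(activity_cv = 0, content_cv = 0))
#' sim$truth$inventory_bq_m2
#' @export
simulate_core <- function(params) {
  stopifnot(inherits(params, "core_sim_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  lambda <- pb210_lambda()
  f <- p$compression_factor
  n <- ceiling(p$length_cm / p$slice_cm)
  top_c <- (seq_len(n) - 1L) * p$slice_cm        # compressed (as-recovered)
  bot_c <- top_c + p$slice_cm
  mid_true <- (top_c + bot_c) / 2 * f            # decompressed depth
  z_src <- mid_true + p$erosion_truncation_cm    # pre-erosion source depth

  rho_true <- pmax(p$dbd_g_cm3 + p$dbd_trend_per_cm * mid_true, 0.05)
  c0 <- p$flux_bq_m2_yr / (10 * p$sed_rate_cm_yr * p$dbd_g_cm3)
  excess <- p$flux_bq_m2_yr * exp(-lambda * z_src / p$sed_rate_cm_yr) /
    (10 * p$sed_rate_cm_yr * rho_true)

  if (p$mixed_layer_cm > 0) {
    ml <- mid_true + p$slice_cm * f / 2 <= p$mixed_layer_cm + 1e-9
    if (any(ml)) {
      w <- rho_true[ml]                           # equal thickness: mass weights
      excess[ml] <- sum(excess[ml] * w) / sum(w)
    }
  }

  dbd_measured <- rho_true * f                    # mass per compressed volume
  total_true <- excess + p$supported_bq_kg
  total_obs <- total_true * lnoise(n, p$activity_cv)
  total_sd <- p$activity_cv * total_obs

  corg_true <- p$corg_asymptote_pct +
    (p$corg_surface_pct - p$corg_asymptote_pct) * exp(-z_src / p$corg_decay_cm)

  content_idx <- seq(1L, n, by = p$content_every)
  ra_idx <- seq(1L, n, by = p$ra_every)

  corg <- rep(NA_real_, n)
  corg[content_idx] <- tnoise(corg_true[content_idx], p$content_cv)
  caco3 <- rep(NA_real_, n)
  caco3[content_idx] <- tnoise(rep(p$caco3_pct, length(content_idx)), p$content_cv)
  d13c <- rep(NA_real_, n)
  d13c[content_idx] <- stats::rnorm(length(content_idx), p$d13c_permil, 0.4)

  gm <- p$grain_means / sum(p$grain_means) * 100
  grains <- matrix(NA_real_, n, 4,
                   dimnames = list(NULL, c("coarse_pct", "medium_pct",
                                           "fine_pct", "vfine_mud_pct")))
  for (i in content_idx) {
    g <- pmax(stats::rnorm(4, gm, p$content_cv * gm), 0)
    grains[i, ] <- g / sum(g) * 100
  }

  ra <- rep(NA_real_, n); ra_sd <- rep(NA_real_, n)
  ra[ra_idx] <- p$supported_bq_kg * lnoise(length(ra_idx), p$activity_cv)
  ra_sd[ra_idx] <- pmax(p$activity_cv * ra[ra_idx],
                        if (p$activity_cv == 0) 0 else 1e-9)

  dbd_obs <- tnoise(dbd_measured, p$content_cv, lo = 0.05, hi = 3)
  dry_mass <- dbd_obs * pi * 3^2 * p$slice_cm

  slices <- data.frame(
    top_cm = top_c, bottom_cm = bot_c, dry_mass_g = dry_mass,
    dbd_g_cm3 = dbd_obs, corg_pct = corg, d13c_permil = d13c,
    caco3_pct = caco3, grains, pb210_bq_kg = total_obs,
    pb210_sd = total_sd, ra226_bq_kg = ra, ra226_sd = ra_sd)

  core <- sediment_core(
    slices, core_id = sprintf("sim_%s", p$treatment), site = "synthetic",
    treatment = p$treatment, barrel_inserted_cm = p$length_cm * f,
    recovered_cm = p$length_cm, water_depth_m = p$water_depth_m)

  truth <- synthetic_truth(p)
  list(core = core, truth = truth)
}

#' Closed-form implied quantities of a simulation configuration
#'
#' Recomputes, from the generating parameters alone, the surface excess
#' activity `C0 = F / (10 * s * rho0)`, the noiseless excess inventory (the
#' steady-state `F / lambda` reduced by erosion and finite core length), the
#' true organic-carbon stock to the reference thickness and the implied
#' accumulation rate.
#'
#' @param params A [core_sim_params()].
#' @param reference_thickness_cm Stock standardization depth (default 50).
#' @return List of class `synthetic_truth`.
#' @export
synthetic_truth <- function(params, reference_thickness_cm = 50) {
  p <- params
  lambda <- pb210_lambda()
  L <- p$length_cm * p$compression_factor         # decompressed extent
  trunc <- p$erosion_truncation_cm
  s <- p$sed_rate_cm_yr
  # inventory of the generated (possibly truncated, finite) profile; the
  # mixed-layer homogenization conserves it exactly
  inv <- p$flux_bq_m2_yr / lambda *
    (exp(-lambda * trunc / s) - exp(-lambda * (trunc + L) / s))
  corg_fun <- function(z) {
    p$corg_asymptote_pct +
      (p$corg_surface_pct - p$corg_asymptote_pct) * exp(-(z + trunc) / p$corg_decay_cm)
  }
  rho_fun <- function(z) pmax(p$dbd_g_cm3 + p$dbd_trend_per_cm * z, 0.05)
  stock <- stats::integrate(function(z) rho_fun(z) * corg_fun(z) / 100 * 10,
                            0, reference_thickness_cm)$value
  structure(list(
    params = p,
    c0_bq_kg = p$flux_bq_m2_yr / (10 * s * p$dbd_g_cm3),
    inventory_bq_m2 = inv,
    inventory_steady_state_bq_m2 = p$flux_bq_m2_yr / lambda,
    stock50_kg_m2 = stock,
    reference_thickness_cm = reference_thickness_cm,
    rate_g_m2_yr = stock / (reference_thickness_cm / s) * 1000
  ), class = "synthetic_truth")
}

#' Simulate a seascape grid with circular mooring scars
#'
#' Places moorings uniformly at random (with a minimum spacing, bounded
#' retries) on an all-seagrass grid and carves a circular bare scar of sampled
#' radius around each; cells belong to a scar when their center lies within
#' the radius. True per-mooring areas are recorded as brute-force cell counts
#' under the same center-in-circle rule, assigned to the nearest mooring.
#'
#' @param extent_m Side length of the square grid (m).
#' @param cell_size_m Cell size (m).
#' @param n_moorings Number of moorings.
#' @param radius_mean_m,radius_sd_m Normal distribution of scar radii
#'   (truncated at 0.5 m).
#' @param min_spacing_m Minimum distance between moorings (default twice the
#'   mean radius).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return List with `grid` (a [habitat_grid()]), `moorings` (data.frame
#'   `id`, `x`, `y`, `radius_m`) and `truth_areas` (data.frame `id`,
#'   `area_m2`).
#' @export
simulate_habitat_grid <- function(extent_m, cell_size_m = 1, n_moorings = 10,
                                  radius_mean_m = 4, radius_sd_m = 1,
                                  min_spacing_m = 2 * radius_mean_m,
                                  seed = NULL) {
  if (extent_m <= 0 || cell_size_m <= 0) {
    sc_validation_error("extent and cell size must be > 0")
  }
  if (!is.null(seed)) set.seed(seed)
  ncell <- ceiling(extent_m / cell_size_m)
  classes <- matrix(HABITAT_CLASSES[["seagrass"]], ncell, ncell)
  grid <- habitat_grid(classes, cell_size_m)

  margin <- radius_mean_m + 3 * radius_sd_m
  xs <- ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n_moorings) {
    tries <- tries + 1L
    if (tries > 1000L * max(n_moorings, 1L)) {
      sc_validation_error("could not place moorings at the requested spacing")
    }
    x <- stats::runif(1, margin, extent_m - margin)
    y <- stats::runif(1, margin, extent_m - margin)
    if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= min_spacing_m^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  radii <- pmax(stats::rnorm(n_moorings, radius_mean_m, radius_sd_m), 0.5)
  moorings <- data.frame(id = seq_len(n_moorings), x = xs, y = ys,
                         radius_m = radii)

  ctr <- grid_cell_centers(grid)
  xg <- matrix(ctr$x, ncell, ncell, byrow = TRUE)
  yg <- matrix(ctr$y, ncell, ncell)
  nearest <- matrix(NA_integer_, ncell, ncell)
  mind2 <- matrix(Inf, ncell, ncell)
  inscar <- matrix(FALSE, ncell, ncell)
  for (i in seq_len(n_moorings)) {
    d2 <- (xg - xs[i])^2 + (yg - ys[i])^2
    inscar <- inscar | d2 <= radii[i]^2
    upd <- d2 < mind2
    mind2[upd] <- d2[upd]
    nearest[upd] <- i
  }
  classes[inscar] <- HABITAT_CLASSES[["bare"]]
  grid$classes <- classes
  truth <- data.frame(id = seq_len(n_moorings),
                      area_m2 = vapply(seq_len(n_moorings), function(i) {
                        sum(inscar & nearest == i) * cell_size_m^2
                      }, numeric(1)))
  list(grid = grid, moorings = moorings[c("id", "x", "y")],
       radii_m = radii, truth_areas = truth)
}

#' Parameter-recovery experiment over replicated synthetic cores
#'
#' Simulates `n_replicates` cores from one configuration, runs each through
#' the full analysis (decompression, supported-activity estimation, excess
#' profile, CF:CS fit below a surface exclusion, inventory and flux, gap
#' interpolation, 50-cm stock, accumulation rate) and compares the estimates
#' with the generating truth.
#'
#' @param params A [core_sim_params()] (its `seed` is ignored; per-replicate
#'   seeds are `seed + 1 ... seed + n`).
#' @param n_replicates Number of replicate cores (>= 2).
#' @param seed Base integer seed.
#' @param surface_exclusion_cm Surface depth excluded from the CF:CS fit in
#'   addition to any detected mixed layer (default 2 cm, guarding the
#'   near-surface zone most prone to disturbance).
#' @return List of class `recovery_result`: per-replicate `estimates`
#'   data.frame, `truth`, and a `summary` data.frame of bias, relative bias,
#'   RMSE and 95% CI coverage for the sedimentation rate, flux, stock and
#'   rate, plus the count of undatable replicates.
#' @export
recovery_experiment <- function(params, n_replicates = 100, seed = 1,
                                surface_exclusion_cm = 2) {
  if (n_replicates < 2) sc_validation_error("need n_replicates >= 2")
  truth <- synthetic_truth(params)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    p <- params
    p$seed <- seed + r
    sim <- simulate_core(p)
    core <- decompress_depths(sim$core)
    dated <- date_core(core, surface_exclusion_cm = surface_exclusion_cm)
    am <- dated$age_model
    inv <- dated$inventory
    core <- interpolate_gaps(core, c("corg_pct"))
    st <- cumulative_stock(core, "Corg",
                           reference_thickness_cm = truth$reference_thickness_cm)
    rate <- if (am$status != "undatable") accumulation_rate(st, am) else NULL
    rows[[r]] <- data.frame(
      replicate = r, status = am$status,
      sed_rate = am$sed_rate_cm_yr, sed_rate_se = am$sed_rate_se,
      flux = inv$flux_bq_m2_yr, flux_sd = inv$flux_sd,
      stock = st$stock_kg_m2,
      rate = if (is.null(rate)) NA_real_ else rate$rate,
      stringsAsFactors = FALSE)
  }
  est <- do.call(rbind, rows)
  datable <- est$status != "undatable"
  summ_row <- function(name, x, se, true) {
    ok <- !is.na(x)
    cover <- if (!is.null(se)) {
      mean(abs(x[ok] - true) <= 1.96 * se[ok])
    } else NA_real_
    data.frame(parameter = name, truth = true, mean_estimate = mean(x[ok]),
               bias = mean(x[ok]) - true,
               rel_bias = (mean(x[ok]) - true) / true,
               rmse = sqrt(mean((x[ok] - true)^2)),
               coverage_95 = cover, n = sum(ok), stringsAsFactors = FALSE)
  }
  summary <- rbind(
    summ_row("sed_rate_cm_yr", est$sed_rate, est$sed_rate_se,
             params$sed_rate_cm_yr),
    summ_row("flux_bq_m2_yr", est$flux, est$flux_sd,
             truth$inventory_bq_m2 * pb210_lambda()),
    summ_row("stock50_kg_m2", est$stock, NULL, truth$stock50_kg_m2),
    summ_row("rate_g_m2_yr", est$rate, NULL, truth$rate_g_m2_yr))
  structure(list(estimates = est, truth = truth, summary = summary,
                 n_undatable = sum(!datable)),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> %d replicates (%d undatable)\n",
              nrow(x$estimates), x$n_undatable))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a simulated core to disk as a core table plus metadata sidecar
#'
#' @param sim Result of [simulate_core()].
#' @param dir Output directory.
#' @param stem File stem; writes `<stem>.csv`, `<stem>_meta.yml` and
#'   `<stem>_truth.json`.
#' @return Invisibly, the paths written.
#' @export
write_simulated_core <- function(sim, dir, stem = sim$core$core_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(sim$core$slices[setdiff(names(sim$core$slices), "measured")],
                   tab, row.names = FALSE, quote = FALSE)
  meta <- file.path(dir, paste0(stem, "_meta.yml"))
  yaml::write_yaml(list(core_id = sim$core$core_id, site = sim$core$site,
                        treatment = sim$core$treatment,
                        barrel_inserted_cm = sim$core$barrel_inserted_cm,
                        recovered_cm = sim$core$recovered_cm,
                        water_depth_m = sim$core$water_depth_m), meta)
  truth <- file.path(dir, paste0(stem, "_truth.json"))
  tr <- sim$truth
  tr$params <- unclass(tr$params)
  tr$params$grain_means <- as.list(tr$params$grain_means)
  jsonlite::write_json(unclass(tr), truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(table = tab, metadata = meta, truth = truth))
}
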