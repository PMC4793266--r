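# Excess 210Pb computation, CF:CS age-depth modelling, mixing/erosion
# diagnostics, inventories and atmospheric-flux closure.
#
# Model: under constant atmospheric flux and constant sedimentation the excess
# activity declines exponentially with depth, C_xs(z) = C0 * exp(-lambda*z/s),
# so ln C_xs is linear in z with slope -lambda/s.

#' Estimate supported 210Pb activity
#'
#' Supported 210Pb is the component sustained in situ by 226Ra decay. When
#' 226Ra measurements exist their error-weighted mean is returned
#' (`method = "ra226"`). Otherwise the mean of total 210Pb over the deepest
#' plateau — the longest run of deep measurements mutually indistinguishable
#' from their mean at the `k`-sigma level — is used (`method = "deep_pb210"`).
#' The estimate is invariant to the input order of slices.
#'
#' @param core A [sediment_core()] carrying `ra226_bq_kg` (with `ra226_sd`)
#'   and/or `pb210_bq_kg` columns.
#' @param k Indistinguishability threshold in sigma units for the deep
#'   plateau (default 2).
#' @return List with `value` (Bq/kg), `sd`, `method` and `n`.
#' @export
estimate_supported <- function(core, k = 2) {
  s <- core$slices[order(core$slices$top_cm), , drop = FALSE]
  ra <- if ("ra226_bq_kg" %in% names(s)) s$ra226_bq_kg else rep(NA_real_, nrow(s))
  ra_sd <- if ("ra226_sd" %in% names(s)) s$ra226_sd else rep(NA_real_, nrow(s))
  ok <- !is.na(ra)
  if (any(ok)) {
    v <- ra[ok]; e <- ra_sd[ok]
    if (any(is.na(e)) || any(e <= 0)) {
      out <- list(value = mean(v),
                  sd = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
                  method = "ra226", n = length(v))
    } else {
      w <- 1 / e^2
      out <- list(value = sum(w * v) / sum(w), sd = sqrt(1 / sum(w)),
                  method = "ra226", n = length(v))
    }
    return(out)
  }
  pb <- if ("pb210_bq_kg" %in% names(s)) s$pb210_bq_kg else rep(NA_real_, nrow(s))
  pb_sd <- if ("pb210_sd" %in% names(s)) s$pb210_sd else rep(NA_real_, nrow(s))
  ok <- !is.na(pb)
  if (sum(ok) < 3L) {
    sc_validation_error("need 226Ra measurements or >= 3 deep total 210Pb measurements")
  }
  v <- pb[ok]; e <- pb_sd[ok]
  e[is.na(e)] <- 0
  # grow the plateau upward from the core base while every member stays
  # within k*sigma of the running mean
  n <- length(v)
  run <- n
  while (run > 1L) {
    idx <- (run - 1L):n
    m <- mean(v[idx])
    if (all(abs(v[idx] - m) <= pmax(k * e[idx], 1e-12))) run <- run - 1L else break
  }
  idx <- run:n
  if (length(idx) < 3L) idx <- (n - 2L):n
  m <- mean(v[idx])
  sd_prop <- if (all(e[idx] > 0)) sqrt(sum(e[idx]^2)) / length(idx)
             else stats::sd(v[idx]) / sqrt(length(idx))
  list(value = m, sd = sd_prop, method = "deep_pb210", n = length(idx))
}

#' Excess 210Pb profile of a core
#'
#' Excess (unsupported) activity is total 210Pb minus the supported level,
#' with uncertainties combined in quadrature. Slices without a 210Pb
#' measurement are omitted; negative excess values are retained (they are
#' noise, never silently truncated).
#'
#' @param core A [sediment_core()] with `pb210_bq_kg` on at least 3 slices.
#' @param supported Result of [estimate_supported()], or a single number
#'   (taken as exact), or a list with `value` and `sd`.
#' @return A data.frame of class `pb210_profile` with columns `mid_cm`,
#'   `thickness_cm`, `excess_bq_kg`, `excess_sd`, `dbd_g_cm3`; the supported
#'   estimate is attached as attributes.
#' @export
compute_excess_profile <- function(core, supported = estimate_supported(core)) {
  if (is.numeric(supported)) supported <- list(value = supported, sd = 0, method = "given")
  if (is.null(supported$sd) || is.na(supported$sd)) supported$sd <- 0
  s <- core$slices
  ok <- !is.na(s$pb210_bq_kg)
  if (sum(ok) < 3L) sc_validation_error("need total 210Pb on >= 3 slices")
  tot <- s$pb210_bq_kg[ok]
  tot_sd <- if ("pb210_sd" %in% names(s)) s$pb210_sd[ok] else rep(0, sum(ok))
  tot_sd[is.na(tot_sd)] <- 0
  dbd <- working_dbd(core)
  prof <- data.frame(
    mid_cm = ((s$top_cm + s$bottom_cm) / 2)[ok],
    thickness_cm = (s$bottom_cm - s$top_cm)[ok],
    excess_bq_kg = tot - supported$value,
    excess_sd = sqrt(tot_sd^2 + supported$sd^2),
    dbd_g_cm3 = if (is.null(dbd)) NA_real_ else dbd[ok]
  )
  prof <- prof[order(prof$mid_cm), , drop = FALSE]
  rownames(prof) <- NULL
  structure(prof, class = c("pb210_profile", "data.frame"),
            supported = supported$value, supported_sd = supported$sd,
            supported_method = supported$method %||% "given")
}

#' Detect a surface mixed layer
#'
#' Physical or biological mixing homogenizes surface sediment, producing a
#' uniform excess-210Pb plateau that must be excluded from CF:CS fitting.
#' Returns the deepest depth `d` (bottom of the deepest qualifying slice) such
#' that all excess activities from the surface to `d` lie within `k` times
#' their own sigma of their common mean; returns 0 when the first two points
#' already decline significantly.
#'
#' @param profile A `pb210_profile` from [compute_excess_profile()].
#' @param k Indistinguishability threshold in sigma units (default 2).
#' @return Mixed-layer depth in cm (0 when no plateau).
#' @export
detect_mixed_layer <- function(profile, k = 2) {
  x <- profile$excess_bq_kg
  e <- profile$excess_sd
  e[is.na(e)] <- 0
  n <- length(x)
  if (n < 2L) return(0)
  for (j in seq(n, 2L)) {
    m <- mean(x[1:j])
    if (all(abs(x[1:j] - m) <= k * e[1:j])) {
      return(profile$mid_cm[j] + profile$thickness_cm[j] / 2)
    }
  }
  0
}

#' Detect the excess-210Pb horizon
#'
#' The horizon is the depth where excess activity first becomes
#' indistinguishable from zero (|C_xs| < k*sigma), i.e. where the datable
#' record ends. The first sub-detection point marks the horizon; requiring
#' every deeper point to qualify as well would let a single k-sigma
#' fluctuation at depth drag the horizon arbitrarily deep into the
#' noise-dominated zone. Returns 0 when the surface value is already
#' indistinguishable from zero (undatable) and `Inf` with `reached = FALSE`
#' when the horizon is never reached.
#'
#' @param profile A `pb210_profile`.
#' @param k Threshold in sigma units (default 2).
#' @return List with `horizon_cm` and logical `reached`.
#' @export
detect_excess_horizon <- function(profile, k = 2) {
  x <- profile$excess_bq_kg
  e <- profile$excess_sd
  e[is.na(e)] <- 0
  n <- length(x)
  if (n < 3L) sc_validation_error("need >= 3 excess points")
  zeroish <- abs(x) < k * e
  j <- which(zeroish)[1L]
  if (is.na(j)) return(list(horizon_cm = Inf, reached = FALSE))
  if (j == 1L) return(list(horizon_cm = 0, reached = TRUE))
  list(horizon_cm = profile$mid_cm[j], reached = TRUE)
}

#' Fit the constant flux : constant sedimentation (CF:CS) age model
#'
#' Ordinary least squares of ln(excess) on slice mid-depth over the window
#' strictly between the mixed layer and the excess horizon, using only
#' positive excess values. The sedimentation rate is `s = -lambda / slope`,
#' with `SE(s) = lambda * SE(slope) / slope^2`. The fit is declared `ok` when
#' the slope is significantly negative (p < 0.05); when a mixed layer was
#' excluded the status is `mixed` and the rate is an upper limit; otherwise
#' the core is `undatable`.
#'
#' @param profile A `pb210_profile`.
#' @param mixed_layer_cm Depth of surface mixing to exclude (default 0).
#' @param horizon_cm Depth where excess vanishes; `Inf` to use the whole
#'   profile (default).
#' @param lambda 210Pb decay constant per year (default [pb210_lambda()]).
#' @param weighted Use inverse-variance weights on ln(excess) (default FALSE,
#'   plain OLS). Weights are `(C_hat / sigma)^2` with the activity `C_hat`
#'   evaluated at the fitted values of a preliminary unweighted pass (one
#'   reweighted refit), so that weights do not reinforce individual
#'   fluctuations; profiles with zero sigmas fall back to the unweighted fit.
#' @return An object of class `age_model`: sedimentation rate +- SE (cm/yr),
#'   fit window, n, r-squared, residual SD, p-value, status flag in
#'   `ok | mixed | undatable`, and `upper_limit` tag.
#' @examples
#' z <- seq(0.5, 25.5, 1)
#' prof <- structure(data.frame(mid_cm = z, thickness_cm = 1,
#'   excess_bq_kg = 20 * exp(-pb210_lambda() * z / 0.25),
#'   excess_sd = 0, dbd_g_cm3 = 0.82),
#'   class = c("pb210_profile", "data.frame"))
#' fit_cfcs(prof)$sed_rate_cm_yr  # 0.25
#' @export
fit_cfcs <- function(profile, mixed_layer_cm = 0, horizon_cm = Inf,
                     lambda = pb210_lambda(), weighted = FALSE) {
  use <- profile$excess_bq_kg > 0 &
    profile$mid_cm > mixed_layer_cm &
    profile$mid_cm < horizon_cm
  use[is.na(use)] <- FALSE
  n_excluded_negative <- sum(profile$excess_bq_kg <= 0, na.rm = TRUE)
  base <- list(lambda_per_yr = lambda, sed_rate_cm_yr = NA_real_,
               sed_rate_se = NA_real_, mixed_layer_cm = mixed_layer_cm,
               horizon_cm = horizon_cm, n = sum(use), r_squared = NA_real_,
               residual_sd = NA_real_, p_value = NA_real_,
               upper_limit = FALSE, n_excluded_negative = n_excluded_negative,
               status = "undatable")
  if (sum(use) < 3L) {
    return(structure(base, class = "age_model"))
  }
  z <- profile$mid_cm[use]
  y <- log(profile$excess_bq_kg[use])
  fit <- stats::lm(y ~ z)
  if (weighted) {
    pred <- exp(stats::fitted(fit))
    w <- (pred / profile$excess_sd[use])^2
    if (all(is.finite(w)) && all(w > 0)) {
      w <- w / mean(w)
      fit <- stats::lm(y ~ z, weights = w)
    }
  }
  sm <- suppressWarnings(summary(fit))  # noiseless profiles fit perfectly
  slope <- sm$coefficients["z", "Estimate"]
  se_slope <- sm$coefficients["z", "Std. Error"]
  p <- sm$coefficients["z", "Pr(>|t|)"]
  base$r_squared <- sm$r.squared
  base$residual_sd <- sm$sigma
  base$p_value <- p
  if (!(slope < 0) || !(p < 0.05)) {
    return(structure(base, class = "age_model"))
  }
  base$sed_rate_cm_yr <- -lambda / slope
  base$sed_rate_se <- lambda * se_slope / slope^2
  base$status <- if (mixed_layer_cm > 0) "mixed" else "ok"
  base$upper_limit <- mixed_layer_cm > 0
  structure(base, class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat("<age_model> CF:CS, lambda =", format(x$lambda_per_yr, digits = 5), "/yr\n")
  if (x$status == "undatable") {
    cat("  status: undatable (no reliable rate)\n")
  } else {
    cat(sprintf("  s = %.4f +- %.4f cm/yr%s  [%s]\n", x$sed_rate_cm_yr,
                x$sed_rate_se, if (x$upper_limit) " (upper limit)" else "",
                x$status))
    cat(sprintf("  window (%.1f, %s) cm, n = %d, r2 = %.3f\n",
                x$mixed_layer_cm,
                if (is.finite(x$horizon_cm)) sprintf("%.1f", x$horizon_cm) else "base",
                x$n, x$r_squared))
  }
  invisible(x)
}

#' Refine the excess horizon from a fitted age model
#'
#' The pointwise horizon of [detect_excess_horizon()] ends the fit window at
#' an observed value, so the points kept just above it are those that happened
#' to fluctuate upward — a selection that flattens the CF:CS slope. This
#' helper instead places the cutoff where the fitted exponential (not the
#' noisy observations) falls below the detection level `k` times the median
#' measurement sigma, decoupling the window from individual fluctuations.
#'
#' @param profile A `pb210_profile`.
#' @param age_model A fitted `age_model` (status `ok` or `mixed`).
#' @param k Detection threshold in sigma units (default 2).
#' @return Refined horizon depth (cm), or `NA` when no refinement applies
#'   (undatable model, zero sigmas, or cutoff above the mixed layer).
#' @export
refine_horizon <- function(profile, age_model, k = 2) {
  if (age_model$status == "undatable") return(NA_real_)
  sig <- stats::median(profile$excess_sd, na.rm = TRUE)
  if (!is.finite(sig) || sig <= 0) return(NA_real_)
  lambda <- age_model$lambda_per_yr
  s <- age_model$sed_rate_cm_yr
  # ln C = ln C0 - (lambda/s) z; recover ln C0 from the model's fit window
  use <- profile$excess_bq_kg > 0 &
    profile$mid_cm > age_model$mixed_layer_cm &
    profile$mid_cm < age_model$horizon_cm
  use[is.na(use)] <- FALSE
  if (sum(use) < 3L) return(NA_real_)
  lnc0 <- mean(log(profile$excess_bq_kg[use]) +
                 lambda / s * profile$mid_cm[use])
  hz <- (lnc0 - log(k * sig)) * s / lambda
  if (!is.finite(hz) || hz <= age_model$mixed_layer_cm) NA_real_ else hz
}

#' Date a core: diagnostics, CF:CS fit and horizon refinement in one step
#'
#' Convenience wrapper running the full dating sequence on one core:
#' supported-activity estimation, excess profile, mixed-layer and horizon
#' detection, CF:CS fit, one fitted-curve horizon refinement
#' ([refine_horizon()]) with refit, and the excess inventory with its flux.
#'
#' @param core A [sediment_core()] (decompressed).
#' @param k Detection threshold in sigma units (default 2).
#' @param surface_exclusion_cm Minimum surface depth excluded from the fit in
#'   addition to any detected mixed layer (default 0).
#' @param weighted Inverse-variance weighting in the final fit (default TRUE;
#'   see [fit_cfcs()]).
#' @param refine Apply the horizon refinement step (default TRUE).
#' @param lambda Decay constant per year.
#' @return List with `supported`, `profile`, `age_model`, `inventory`.
#' @export
date_core <- function(core, k = 2, surface_exclusion_cm = 0, weighted = TRUE,
                      refine = TRUE, lambda = pb210_lambda()) {
  sup <- estimate_supported(core, k = k)
  prof <- compute_excess_profile(core, sup)
  ml_detected <- detect_mixed_layer(prof, k = k)
  ml <- max(ml_detected, surface_exclusion_cm)
  hz <- detect_excess_horizon(prof, k = k)
  am <- fit_cfcs(prof, mixed_layer_cm = ml, horizon_cm = hz$horizon_cm,
                 lambda = lambda)
  if (refine) {
    hz2 <- refine_horizon(prof, am, k = k)
    if (!is.na(hz2)) {
      am <- fit_cfcs(prof, mixed_layer_cm = ml, horizon_cm = hz2,
                     lambda = lambda, weighted = weighted)
    }
  } else if (weighted && am$status != "undatable") {
    am <- fit_cfcs(prof, mixed_layer_cm = ml, horizon_cm = hz$horizon_cm,
                   lambda = lambda, weighted = TRUE)
  }
  # a prophylactic surface exclusion is not evidence of mixing: only a
  # detected plateau makes the rate an upper limit
  am$mixed_layer_detected_cm <- ml_detected
  if (am$status == "mixed" && ml_detected == 0) {
    am$status <- "ok"
    am$upper_limit <- FALSE
  }
  inv <- excess_inventory(prof, lambda = lambda)
  list(supported = sup, profile = prof, age_model = am, inventory = inv)
}

#' Depth-integrated excess-210Pb inventory
#'
#' Integrates excess activity over depth, `I = sum C_xs_i * DBD_i * dz_i`,
#' converting Bq/kg x g/cm^3 x cm to Bq/m^2 (factor 10). Negative per-slice
#' contributions are clipped at zero for the inventory (the unclipped sum is
#' also reported); the uncertainty is combined in quadrature.
#'
#' @param profile A `pb210_profile` with DBD on every slice in range.
#' @param integrate_to_cm Depth to integrate to (default: base of the
#'   profile). A slice straddling the limit contributes pro-rata.
#' @return List of class `inventory_result`: `inventory_bq_m2`, `sd`,
#'   `inventory_unclipped_bq_m2`, `depth_cm`, `flux_bq_m2_yr`, `flux_sd`,
#'   `lambda_per_yr`.
#' @export
excess_inventory <- function(profile, integrate_to_cm = NULL,
                             lambda = pb210_lambda()) {
  top <- profile$mid_cm - profile$thickness_cm / 2
  bot <- profile$mid_cm + profile$thickness_cm / 2
  lim <- integrate_to_cm %||% max(bot)
  frac <- pmin(pmax((lim - top) / (bot - top), 0), 1)
  inrange <- frac > 0
  if (any(is.na(profile$dbd_g_cm3[inrange]))) {
    sc_validation_error("DBD missing for slices within the integration range")
  }
  dz <- profile$thickness_cm * frac
  contrib <- profile$excess_bq_kg * profile$dbd_g_cm3 * dz * 10
  sdc <- profile$excess_sd * profile$dbd_g_cm3 * dz * 10
  sdc[is.na(sdc)] <- 0
  inv <- sum(pmax(contrib, 0), na.rm = TRUE)
  res <- list(inventory_bq_m2 = inv,
              sd = sqrt(sum(sdc^2)),
              inventory_unclipped_bq_m2 = sum(contrib, na.rm = TRUE),
              n_clipped = sum(contrib < 0, na.rm = TRUE),
              depth_cm = min(lim, max(bot)),
              lambda_per_yr = lambda)
  fl <- atmospheric_flux(res$inventory_bq_m2, res$sd, lambda)
  res$flux_bq_m2_yr <- fl$flux_bq_m2_yr
  res$flux_sd <- fl$sd
  structure(res, class = "inventory_result")
}

#' Atmospheric 210Pb flux from an excess inventory
#'
#' At steady state the depositional flux balances decay of the accumulated
#' inventory: `F = lambda * I`, with `sd(F) = lambda * sd(I)`.
#'
#' @param inventory_bq_m2 Excess 210Pb inventory (Bq/m^2), >= 0.
#' @param sd 1-sigma uncertainty of the inventory (default 0).
#' @param lambda Decay constant per year.
#' @return List with `flux_bq_m2_yr` and `sd`.
#' @examples
#' atmospheric_flux(1225.5)  # ~38.2 Bq m-2 yr-1
#' @export
atmospheric_flux <- function(inventory_bq_m2, sd = 0, lambda = pb210_lambda()) {
  if (any(inventory_bq_m2 < 0)) sc_validation_error("inventory must be >= 0")
  list(flux_bq_m2_yr = lambda * inventory_bq_m2, sd = lambda * sd)
}

#' Age of a sediment depth under the CF:CS model
#'
#' With constant sedimentation, age is simply `depth / s`. The standard error
#' follows by first-order propagation of the rate uncertainty; ages beyond
#' five 210Pb half-lives are flagged as extrapolated beyond the datable range.
#'
#' @param depth_cm Depth below seafloor (cm), >= 0.
#' @param age_model An `age_model` with status `ok` or `mixed`.
#' @return List with `age_yr`, `se`, and logical `extrapolated`.
#' @examples
#' \dontrun{age_at_depth(50, model)  # 200 yr at s = 0.25 cm/yr}
#' @export
age_at_depth <- function(depth_cm, age_model) {
  if (age_model$status == "undatable") {
    sc_validation_error("age model is undatable; no age can be assigned")
  }
  if (any(depth_cm < 0)) sc_validation_error("depth must be >= 0")
  s <- age_model$sed_rate_cm_yr
  age <- depth_cm / s
  se <- depth_cm * age_model$sed_rate_se / s^2
  half_life <- log(2) / age_model$lambda_per_yr
  list(age_yr = age, se = se, extrapolated = age > 5 * half_life)
}

#' Write an age-model report
#'
#' Serializes an age model and (optionally) its inventory to a delimited text
#' table and a JSON file.
#'
#' @param age_model An `age_model`.
#' @param inventory Optional `inventory_result`.
#' @param path Output path without extension; `<path>.tsv` and `<path>.json`
#'   are written.
#' @return Invisibly, the report list.
#' @export
write_age_model_report <- function(age_model, inventory = NULL, path) {
  rep <- unclass(age_model)
  if (!is.null(inventory)) rep <- c(rep, unclass(inventory))
  df <- data.frame(field = names(rep),
                   value = vapply(rep, function(v) format(v, digits = 10), ""))
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(rep, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(rep)
}
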