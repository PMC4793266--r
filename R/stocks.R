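# Component stocks normalized to a reference thickness, accumulation rates
# and treatment-level summaries.

component_column <- function(component) {
  switch(component,
         Corg = "corg_pct", CaCO3 = "caco3_pct",
         sc_validation_error(sprintf("unknown component `%s`", component)))
}

#' Areal component density of a single slice
#'
#' Converts a slice's bulk density, component content and thickness into an
#' areal mass: `dbd * content/100 * thickness * 10`, turning
#' g/cm^3 x cm into kg/m^2.
#'
#' @param dbd_g_cm3 Dry bulk density (g/cm^3).
#' @param content_pct Component content (% of dry weight).
#' @param thickness_cm Slice thickness (cm).
#' @return Areal density in kg/m^2.
#' @examples
#' slice_component_density(0.82, 1.60, 1)  # 0.1312 kg m-2
#' @export
slice_component_density <- function(dbd_g_cm3, content_pct, thickness_cm) {
  if (any(dbd_g_cm3 < 0) || any(content_pct < 0) || any(thickness_cm < 0)) {
    sc_validation_error("density, content and thickness must be >= 0")
  }
  dbd_g_cm3 * content_pct / 100 * thickness_cm * 10
}

#' Cumulative component stock standardized to a reference thickness
#'
#' Sums per-slice areal densities from the sediment surface down to a
#' reference thickness (default 50 cm) so that stocks are comparable across
#' cores of different length. A slice straddling the reference depth
#' contributes pro-rata; longer cores are truncated. Cores shorter than the
#' reference are extrapolated by the mean areal density per cm of their
#' bottom quartile of measured depth (`extrapolated = TRUE`); extrapolating a
#' core shorter than half the reference is refused unless `force = TRUE`.
#' A linear-trend extrapolation of the bottom-quartile densities is available
#' with `extrapolation = "trend"`.
#'
#' @param core A [sediment_core()] with DBD and the component content
#'   available on every slice (interpolate gaps first).
#' @param component `"Corg"` or `"CaCO3"`.
#' @param reference_thickness_cm Standardization depth (cm), default 50.
#' @param extrapolation `"mean"` (default) or `"trend"`.
#' @param force Allow extrapolation of cores shorter than half the reference.
#' @return Object of class `stock_result`: `stock_kg_m2`, `sd` (NA unless
#'   slice-level sigmas exist), `reference_thickness_cm`,
#'   `measured_thickness_cm`, `extrapolated`, and the per-slice cumulative
#'   `profile` (depth, cumulative kg/m^2).
#' @examples
#' sl <- data.frame(top_cm = 0:49, bottom_cm = 1:50,
#'                  dbd_g_cm3 = 0.82, corg_pct = 1.60)
#' core <- sediment_core(sl, "demo", treatment = "meadow",
#'                       barrel_inserted_cm = 50, recovered_cm = 50)
#' cumulative_stock(core, "Corg")$stock_kg_m2  # 6.56
#' @export
cumulative_stock <- function(core, component = c("Corg", "CaCO3"),
                             reference_thickness_cm = 50,
                             extrapolation = c("mean", "trend"),
                             force = FALSE) {
  component <- match.arg(component)
  extrapolation <- match.arg(extrapolation)
  col <- component_column(component)
  s <- core$slices
  if (nrow(s) == 0L) sc_validation_error("empty core")
  if (!(col %in% names(s))) {
    sc_validation_error(sprintf("core lacks column `%s`", col))
  }
  dbd <- working_dbd(core)
  if (any(is.na(dbd)) || any(is.na(s[[col]]))) {
    sc_validation_error(sprintf(
      "DBD and %s must be available on every slice (run interpolate_gaps first)", col))
  }
  thick <- s$bottom_cm - s$top_cm
  dens <- slice_component_density(dbd, s[[col]], thick)     # kg/m2 per slice
  dens_per_cm <- dens / thick
  extent <- max(s$bottom_cm)
  ref <- reference_thickness_cm

  frac <- pmin(pmax((ref - s$top_cm) / thick, 0), 1)
  stock_measured <- sum(dens * frac)
  extrapolated <- extent < ref
  if (extrapolated) {
    if (extent < ref / 2 && !force) {
      sc_validation_error(sprintf(
        "core spans %.1f cm, less than half the %.0f cm reference; extrapolation refused (use force = TRUE)",
        extent, ref))
    }
    qstart <- 0.75 * extent
    qi <- s$bottom_cm > qstart
    stock_extra <- if (extrapolation == "mean") {
      mean(dens_per_cm[qi]) * (ref - extent)
    } else {
      mids <- (s$top_cm + s$bottom_cm) / 2
      fit <- stats::lm(dens_per_cm[qi] ~ mids[qi])
      co <- stats::coef(fit)
      zz <- seq(extent, ref, length.out = 101L)
      d <- pmax(co[1] + co[2] * zz, 0)
      sum((d[-1] + d[-length(d)]) / 2 * diff(zz))
    }
    stock <- stock_measured + stock_extra
  } else {
    stock <- stock_measured
  }
  cumprof <- data.frame(depth_cm = s$bottom_cm, cumulative_kg_m2 = cumsum(dens))
  structure(list(component = component, stock_kg_m2 = stock, sd = NA_real_,
                 reference_thickness_cm = ref, measured_thickness_cm = extent,
                 extrapolated = extrapolated, profile = cumprof),
            class = "stock_result")
}

#' @export
print.stock_result <- function(x, ...) {
  cat(sprintf("<stock_result> %s: %.3f kg m-2 over %d cm%s\n",
              x$component, x$stock_kg_m2, round(x$reference_thickness_cm),
              if (x$extrapolated)
                sprintf(" (extrapolated from %.1f cm)", x$measured_thickness_cm)
              else ""))
  invisible(x)
}

#' Component accumulation rate from a stock and an age model
#'
#' Divides the depth-standardized stock by the time needed to deposit the
#' reference thickness at the CF:CS sedimentation rate (constant accretion
#' assumed). Organic-carbon rates are reported in g/m^2/yr, carbonate rates
#' in kg/m^2/yr, matching field convention.
#'
#' @param stock A `stock_result`.
#' @param age_model An `age_model` with status `ok` or `mixed`.
#' @return Object of class `accumulation_rate` with `rate`, `sd`, `units`,
#'   `component` and the `basis` (stock, sed rate, reference thickness).
#' @examples
#' \dontrun{accumulation_rate(stock50, model)  # e.g. 33 g Corg m-2 yr-1}
#' @export
accumulation_rate <- function(stock, age_model) {
  if (age_model$status == "undatable") {
    sc_validation_error("cannot compute an accumulation rate from an undatable age model")
  }
  s <- age_model$sed_rate_cm_yr
  time_yr <- stock$reference_thickness_cm / s
  rate_kg <- stock$stock_kg_m2 / time_yr
  rel2 <- (age_model$sed_rate_se / s)^2
  if (!is.na(stock$sd) && stock$stock_kg_m2 > 0) {
    rel2 <- rel2 + (stock$sd / stock$stock_kg_m2)^2
  }
  sd_kg <- rate_kg * sqrt(rel2)
  scale <- if (stock$component == "Corg") 1000 else 1
  units <- if (stock$component == "Corg") "g m-2 yr-1" else "kg m-2 yr-1"
  structure(list(component = stock$component, rate = rate_kg * scale,
                 sd = sd_kg * scale, units = units,
                 basis = list(stock_kg_m2 = stock$stock_kg_m2,
                              sed_rate_cm_yr = s,
                              reference_thickness_cm = stock$reference_thickness_cm,
                              time_yr = time_yr,
                              upper_limit = isTRUE(age_model$upper_limit))),
            class = "accumulation_rate")
}

#' Propagate dated sedimentation rates to undated replicate cores
#'
#' In the usual design only one core per site and treatment is radiometrically
#' dated; replicate cores are assumed to share the mean accumulation regime of
#' the dated core in their group. Each undated core inherits its group's
#' sedimentation rate, and per-core accumulation rates are computed from each
#' core's own stock.
#'
#' @param stocks Named list of `stock_result` objects, one per core.
#' @param core_meta data.frame with columns `core_id`, `site`, `treatment`
#'   covering every core in `stocks`.
#' @param dated_rates data.frame with columns `site`, `treatment`,
#'   `sed_rate_cm_yr`, and optionally `sed_rate_se`, from the dated cores.
#' @return data.frame with one row per core: inherited `sed_rate_cm_yr`,
#'   `stock_kg_m2`, `rate`, `rate_sd` and `units`.
#' @export
propagate_rate_to_undated <- function(stocks, core_meta, dated_rates) {
  if (!("sed_rate_se" %in% names(dated_rates))) dated_rates$sed_rate_se <- 0
  keys <- paste(core_meta$site, core_meta$treatment, sep = "||")
  rkeys <- paste(dated_rates$site, dated_rates$treatment, sep = "||")
  missing <- setdiff(unique(keys), rkeys)
  if (length(missing)) {
    sc_validation_error(sprintf(
      "no dated core for group(s): %s", paste(gsub("\\|\\|", " / ", missing), collapse = "; ")))
  }
  out <- lapply(seq_len(nrow(core_meta)), function(i) {
    id <- core_meta$core_id[i]
    st <- stocks[[id]]
    if (is.null(st)) sc_validation_error(sprintf("no stock for core `%s`", id))
    j <- match(keys[i], rkeys)
    am <- structure(list(sed_rate_cm_yr = dated_rates$sed_rate_cm_yr[j],
                         sed_rate_se = dated_rates$sed_rate_se[j],
                         status = "ok", upper_limit = FALSE,
                         lambda_per_yr = pb210_lambda()),
                    class = "age_model")
    r <- accumulation_rate(st, am)
    data.frame(core_id = id, site = core_meta$site[i],
               treatment = core_meta$treatment[i],
               sed_rate_cm_yr = am$sed_rate_cm_yr,
               stock_kg_m2 = st$stock_kg_m2, rate = r$rate, rate_sd = r$sd,
               units = r$units, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean and standard error of a treatment group
#'
#' Descriptive group summary over per-core values: mean and SEM (sample SD
#' with n-1 denominator, divided by sqrt(n)). With a single core the SEM is
#' undefined and flagged.
#'
#' @param values Numeric vector of per-core values.
#' @param site Site label.
#' @param treatment Treatment label.
#' @param variable Label of the summarized variable.
#' @return Object of class `treatment_summary` with `n`, `mean`, `sem`,
#'   `sem_defined`.
#' @examples
#' summarize_treatment(c(6.0, 6.4, 6.8, 7.2), "Thomson Bay", "meadow",
#'                     "Corg stock (kg m-2)")
#' @export
summarize_treatment <- function(values, site = NA_character_,
                                treatment = NA_character_,
                                variable = NA_character_) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) sc_validation_error("empty group")
  sem <- if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_
  structure(list(site = site, treatment = treatment, variable = variable,
                 n = n, mean = mean(values), sem = sem,
                 sem_defined = n > 1L),
            class = "treatment_summary")
}

#' @export
print.treatment_summary <- function(x, ...) {
  cat(sprintf("<treatment_summary> %s / %s — %s: %.4g +- %s (n = %d)\n",
              x$site, x$treatment, x$variable, x$mean,
              if (x$sem_defined) sprintf("%.4g", x$sem) else "NA", x$n))
  invisible(x)
}
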