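# End-to-end study orchestration from a configuration file: per-core dating
# and stocks, group summaries, loss estimates and scar accounting, with
# machine- and human-readable reports.

#' Read a study configuration
#'
#' The configuration is a single YAML file. Recognized keys (all analysis
#' flags surface here with their documented defaults):
#'
#' * `cores`: list of entries with `table` (slice-table path) and `metadata`
#'   (sidecar path or inline mapping).
#' * `reference_thickness_cm` (50), `lambda_per_yr` ([pb210_lambda()]),
#'   `k_sigma` (2), `buffer_m` (10), `years_since_disturbance` (50),
#'   `surface_exclusion_cm` (0), `weighted_fit` (TRUE), `refine_horizon`
#'   (TRUE), `reference_flux_bq_m2_yr` (optional flux-closure check),
#'   `seed` (1), `core_diameter_cm` (6).
#' * `scar_counts`: list of `{site, n_moorings, mean_scar_m2, sem_scar_m2}`.
#' * `scar_grid`: `{grid, moorings}` file paths for the raster path.
#' * `out_dir`: where [write_report()] puts its files.
#'
#' Paths are resolved relative to the configuration file.
#'
#' @param path YAML file path.
#' @return A list of class `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  for (i in seq_along(cfg$cores)) {
    cfg$cores[[i]]$table <- resolve(cfg$cores[[i]]$table)
    if (is.character(cfg$cores[[i]]$metadata)) {
      cfg$cores[[i]]$metadata <- resolve(cfg$cores[[i]]$metadata)
    }
  }
  if (!is.null(cfg$scar_grid)) {
    cfg$scar_grid$grid <- resolve(cfg$scar_grid$grid)
    cfg$scar_grid$moorings <- resolve(cfg$scar_grid$moorings)
  }
  study_config(cfg)
}

#' @rdname read_study_config
#' @param cfg Named list of configuration values.
#' @export
study_config <- function(cfg) {
  defaults <- list(reference_thickness_cm = 50, lambda_per_yr = pb210_lambda(),
                   k_sigma = 2, buffer_m = 10, years_since_disturbance = 50,
                   surface_exclusion_cm = 0, seed = 1, core_diameter_cm = 6,
                   weighted_fit = TRUE, refine_horizon = TRUE,
                   out_dir = NULL, reference_flux_bq_m2_yr = NULL)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (f in vapply(cfg$cores, function(cc) cc$table, "")) {
    if (!file.exists(f)) sc_validation_error(sprintf("core table not found: %s", f))
  }
  structure(cfg, class = "study_config")
}

log_line <- function(log, stage, id, msg) {
  line <- sprintf("[%s] %s: %s", stage, id, msg)
  message(line)
  c(log, line)
}

#' Run the full study analysis
#'
#' For every configured core: read, decompress, fill bulk density from dry
#' mass where missing, interpolate alternate-slice gaps, fit the CF:CS age
#' model where 210Pb is present (with mixing and horizon diagnostics), and
#' integrate organic-carbon and carbonate stocks to the reference thickness.
#' Dated sedimentation rates are propagated to undated replicates within each
#' site and treatment. Group summaries, per-site and pooled meadow-scar loss
#' estimates, scar accounting (from counts and/or a habitat grid) and a
#' flux-closure check against a reference flux are then assembled. The
#' pipeline records undatable cores and skipped stages rather than failing.
#'
#' @param config A `study_config` (or path to one).
#' @return A list of class `study_report`; written to disk when `out_dir` is
#'   configured (see [write_report()]).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  log <- character(0)
  lambda <- cfg$lambda_per_yr

  cores <- list(); age_models <- list(); inventories <- list()
  stocks_corg <- list(); stocks_caco3 <- list()
  for (entry in cfg$cores) {
    core <- read_core_table(entry$table, entry$metadata)
    id <- core$core_id
    core <- decompress_depths(core)
    core <- fill_dbd_from_mass(core, cfg$core_diameter_cm)
    vars <- intersect(c("corg_pct", "caco3_pct", "dbd_g_cm3"),
                      names(core$slices))
    vars <- vars[vapply(vars, function(v) any(is.na(core$slices[[v]])), TRUE)]
    if (length(vars)) core <- interpolate_gaps(core, vars)
    log <- log_line(log, "core", id, sprintf(
      "%d slices, decompression factor %.3f%s", nrow(core$slices),
      core$compression_factor,
      if (length(vars)) paste0(", interpolated: ", paste(vars, collapse = "+")) else ""))

    if ("pb210_bq_kg" %in% names(core$slices) &&
        sum(!is.na(core$slices$pb210_bq_kg)) >= 3) {
      dated <- date_core(core, k = cfg$k_sigma,
                         surface_exclusion_cm = cfg$surface_exclusion_cm,
                         weighted = cfg$weighted_fit %||% TRUE,
                         refine = cfg$refine_horizon %||% TRUE,
                         lambda = lambda)
      am <- dated$age_model
      inv <- dated$inventory
      age_models[[id]] <- am
      inventories[[id]] <- inv
      log <- log_line(log, "agemodel", id, sprintf(
        "supported %.2f Bq/kg (%s), mixed %.1f cm, horizon %s, status %s%s",
        dated$supported$value, dated$supported$method, am$mixed_layer_cm,
        if (is.finite(am$horizon_cm)) sprintf("%.1f cm", am$horizon_cm) else "not reached",
        am$status,
        if (am$status != "undatable") sprintf(", s = %.3f +- %.3f cm/yr",
                                              am$sed_rate_cm_yr, am$sed_rate_se) else ""))
    } else {
      log <- log_line(log, "agemodel", id, "no 210Pb data; skipped")
    }

    for (comp in c("Corg", "CaCO3")) {
      col <- component_column(comp)
      if (col %in% names(core$slices) && !any(is.na(core$slices[[col]]))) {
        st <- try(cumulative_stock(core, comp,
                                   reference_thickness_cm = cfg$reference_thickness_cm),
                  silent = TRUE)
        if (inherits(st, "try-error")) {
          log <- log_line(log, "stock", id, sprintf("%s: %s", comp,
                          conditionMessage(attr(st, "condition"))))
        } else {
          if (comp == "Corg") stocks_corg[[id]] <- st else stocks_caco3[[id]] <- st
          log <- log_line(log, "stock", id, sprintf(
            "%s stock %.2f kg/m2 (%s)", comp, st$stock_kg_m2,
            if (st$extrapolated) "extrapolated" else "measured"))
        }
      }
    }
    cores[[id]] <- core
  }

  meta <- do.call(rbind, lapply(cores, function(cc) data.frame(
    core_id = cc$core_id, site = cc$site, treatment = cc$treatment,
    stringsAsFactors = FALSE)))
  rownames(meta) <- NULL

  dated <- do.call(rbind, lapply(names(age_models), function(id) {
    am <- age_models[[id]]
    if (am$status == "undatable") return(NULL)
    i <- match(id, meta$core_id)
    data.frame(core_id = id, site = meta$site[i], treatment = meta$treatment[i],
               sed_rate_cm_yr = am$sed_rate_cm_yr, sed_rate_se = am$sed_rate_se,
               upper_limit = am$upper_limit, stringsAsFactors = FALSE)
  }))

  rate_table <- NULL
  if (!is.null(dated) && nrow(dated) > 0 && length(stocks_corg)) {
    group_rates <- stats::aggregate(
      cbind(sed_rate_cm_yr, sed_rate_se) ~ site + treatment, data = dated, FUN = mean)
    have <- meta$core_id %in% names(stocks_corg) &
      paste(meta$site, meta$treatment) %in%
      paste(group_rates$site, group_rates$treatment)
    if (any(have)) {
      rate_table <- propagate_rate_to_undated(stocks_corg, meta[have, ],
                                              group_rates)
      log <- log_line(log, "rates", "study", sprintf(
        "accumulation rates for %d core(s); groups without a dated core: %s",
        nrow(rate_table),
        if (all(have)) "none" else
          paste(unique(paste(meta$site[!have], meta$treatment[!have])), collapse = "; ")))
    }
  } else {
    log <- log_line(log, "rates", "study", "no datable cores; rates skipped")
  }

  summarize_groups <- function(stocks, label) {
    ids <- names(stocks)
    if (!length(ids)) return(list())
    vals <- vapply(stocks, function(s) s$stock_kg_m2, numeric(1))
    grp <- split(seq_along(ids),
                 paste(meta$site[match(ids, meta$core_id)],
                       meta$treatment[match(ids, meta$core_id)], sep = "||"))
    out <- lapply(names(grp), function(g) {
      parts <- strsplit(g, "||", fixed = TRUE)[[1]]
      summarize_treatment(vals[grp[[g]]], site = parts[1], treatment = parts[2],
                          variable = label)
    })
    names(out) <- names(grp)
    out
  }
  sum_corg <- summarize_groups(stocks_corg, "Corg stock (kg m-2)")
  sum_caco3 <- summarize_groups(stocks_caco3, "CaCO3 stock (kg m-2)")

  # loss estimates: per site and pooled over sites
  losses <- list()
  mean_rate <- if (!is.null(rate_table)) {
    mr <- rate_table[rate_table$treatment == "meadow", "rate"]
    if (length(mr)) mean(mr) else NA_real_
  } else NA_real_
  loss_for <- function(meadow_sum, scar_sum, label) {
    er <- stock_loss(meadow_sum, scar_sum)
    fg <- if (!is.na(mean_rate)) {
      foregone_sequestration(mean_rate, cfg$years_since_disturbance)
    } else 0
    le <- loss_estimate(er, fg, cfg$years_since_disturbance)
    le$label <- label
    le
  }
  for (comp in list(list(s = sum_corg, tag = "Corg"),
                    list(s = sum_caco3, tag = "CaCO3"))) {
    sums <- comp$s
    if (!length(sums)) next
    sites <- unique(vapply(sums, function(x) x$site, ""))
    for (site in sites) {
      m <- sums[[paste(site, "meadow", sep = "||")]]
      s2 <- sums[[paste(site, "scar", sep = "||")]]
      if (!is.null(m) && !is.null(s2)) {
        losses[[paste(comp$tag, site)]] <- loss_for(m, s2, paste(comp$tag, site))
      }
    }
    tr_vals <- function(tr) unlist(lapply(sums, function(x)
      if (x$treatment == tr) rep(x$mean, 1) else NULL))
    mv <- tr_vals("meadow"); sv <- tr_vals("scar")
    if (length(mv) && length(sv)) {
      losses[[paste(comp$tag, "pooled")]] <- loss_for(
        summarize_treatment(mv, "all", "meadow", sums[[1]]$variable),
        summarize_treatment(sv, "all", "scar", sums[[1]]$variable),
        paste(comp$tag, "pooled"))
    } else {
      log <- log_line(log, "loss", comp$tag,
                      "meadow or scar group missing; loss stage skipped")
    }
  }

  # scar accounting
  scars <- list()
  if (!is.null(cfg$scar_counts)) {
    for (sc in cfg$scar_counts) {
      scars[[paste0("counts:", sc$site)]] <- scar_area_from_counts(
        sc$n_moorings, sc$mean_scar_m2, sc$sem_scar_m2 %||% NA_real_)
      log <- log_line(log, "scars", sc$site, sprintf(
        "counts path: %d x %.0f m2 = %.1f ha", sc$n_moorings, sc$mean_scar_m2,
        scars[[paste0("counts:", sc$site)]]$total_scar_ha))
    }
  }
  if (!is.null(cfg$scar_grid)) {
    grid <- read_habitat_grid(cfg$scar_grid$grid)
    moor <- read_moorings(cfg$scar_grid$moorings)
    mp <- map_scar_area(grid, moor, buffer_m = cfg$buffer_m)
    scars[["grid"]] <- mp
    log <- log_line(log, "scars", "grid", sprintf(
      "raster path: %d moorings, %.0f m2 scar (%.2f ha)",
      mp$summary$n_moorings, mp$summary$total_scar_m2, mp$summary$total_scar_ha))
  }

  flux_check <- NULL
  if (length(inventories)) {
    fl <- vapply(inventories, function(iv) iv$flux_bq_m2_yr, numeric(1))
    meadow_ids <- meta$core_id[meta$treatment == "meadow"]
    fl <- fl[names(fl) %in% meadow_ids]
    if (length(fl)) {
      flux_check <- list(mean_flux_bq_m2_yr = mean(fl), n = length(fl),
                         reference_flux_bq_m2_yr = cfg$reference_flux_bq_m2_yr)
      if (!is.null(cfg$reference_flux_bq_m2_yr)) {
        flux_check$ratio_to_reference <- mean(fl) / cfg$reference_flux_bq_m2_yr
      }
      log <- log_line(log, "flux", "study", sprintf(
        "mean meadow flux %.1f Bq/m2/yr over %d core(s)", mean(fl), length(fl)))
    }
  }

  report <- structure(list(
    config = unclass(cfg), cores = meta, age_models = age_models,
    inventories = inventories, stocks_corg = stocks_corg,
    stocks_caco3 = stocks_caco3, rates = rate_table,
    summaries = c(sum_corg, sum_caco3), losses = losses, scars = scars,
    flux_check = flux_check, log = log), class = "study_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

round_or_na <- function(x, d) if (is.null(x) || !is.numeric(x)) NA_real_ else round(x, d)

#' Write a study report to disk
#'
#' Emits a machine-readable JSON report (full precision, deterministically
#' ordered) and human-readable delimited tables: per-core age models and
#' stocks, group summaries, loss estimates and a scar-area table rounded to
#' field precision (hectares to 1 decimal, square meters to integers).
#' Rounding is applied only in this layer.
#'
#' @param report A `study_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  jr <- list(
    config = report$config[order(names(report$config))],
    age_models = lapply(report$age_models, unclass),
    inventories = lapply(report$inventories, unclass),
    stocks = list(
      Corg = lapply(report$stocks_corg, function(s) unclass(s)[names(s) != "profile"]),
      CaCO3 = lapply(report$stocks_caco3, function(s) unclass(s)[names(s) != "profile"])),
    rates = report$rates, summaries = lapply(report$summaries, unclass),
    losses = lapply(report$losses, unclass),
    scars = lapply(report$scars, function(s) {
      if (inherits(s, "scar_summary")) unclass(s)
      else list(per_mooring = s$per_mooring, summary = unclass(s$summary))
    }),
    flux_check = report$flux_check)
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(jr, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  paths <- c(paths, jp)

  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (length(report$age_models)) {
    wt(do.call(rbind, lapply(names(report$age_models), function(id) {
      a <- report$age_models[[id]]
      iv <- report$inventories[[id]]
      data.frame(core_id = id, status = a$status,
                 sed_rate_cm_yr = round_or_na(a$sed_rate_cm_yr, 4),
                 sed_rate_se = round_or_na(a$sed_rate_se, 4),
                 mixed_layer_cm = round_or_na(a$mixed_layer_cm, 1),
                 horizon_cm = round_or_na(a$horizon_cm, 1),
                 r_squared = round_or_na(a$r_squared, 3),
                 inventory_bq_m2 = round_or_na(iv$inventory_bq_m2, 0),
                 inventory_sd = round_or_na(iv$sd, 0),
                 flux_bq_m2_yr = round_or_na(iv$flux_bq_m2_yr, 1))
    })), "age_models.tsv")
  }
  stock_rows <- function(stocks, comp) {
    do.call(rbind, lapply(names(stocks), function(id) {
      s <- stocks[[id]]
      i <- match(id, report$cores$core_id)
      data.frame(core_id = id, site = report$cores$site[i],
                 treatment = report$cores$treatment[i], component = comp,
                 stock_kg_m2 = round(s$stock_kg_m2, 2),
                 extrapolated = s$extrapolated)
    }))
  }
  st <- rbind(
    if (length(report$stocks_corg)) stock_rows(report$stocks_corg, "Corg"),
    if (length(report$stocks_caco3)) stock_rows(report$stocks_caco3, "CaCO3"))
  if (!is.null(st)) wt(st, "stocks.tsv")
  if (!is.null(report$rates)) {
    r <- report$rates
    r$rate <- round(r$rate, 1); r$rate_sd <- round(r$rate_sd, 1)
    r$stock_kg_m2 <- round(r$stock_kg_m2, 2)
    wt(r, "rates.tsv")
  }
  if (length(report$summaries)) {
    wt(do.call(rbind, lapply(report$summaries, function(s) data.frame(
      site = s$site, treatment = s$treatment, variable = s$variable,
      n = s$n, mean = round(s$mean, 2), sem = round_or_na(s$sem, 2)))),
      "summaries.tsv")
  }
  if (length(report$losses)) {
    wt(do.call(rbind, lapply(report$losses, function(l) data.frame(
      label = l$label, eroded_kg_m2 = round(l$eroded_kg_m2, 1),
      eroded_sd = round_or_na(l$eroded_sd, 1),
      foregone_kg_m2 = round(l$foregone_kg_m2, 1),
      years = l$years_since_disturbance,
      total_kg_m2 = round(l$total_kg_m2, 1)))), "losses.tsv")
  }
  if (length(report$scars)) {
    wt(do.call(rbind, lapply(names(report$scars), function(k) {
      s <- report$scars[[k]]
      if (!inherits(s, "scar_summary")) s <- s$summary
      data.frame(source = k, n_moorings = s$n_moorings,
                 mean_scar_m2 = round(s$mean_scar_m2, 0),
                 total_scar_m2 = round(s$total_scar_m2, 0),
                 total_scar_ha = round(s$total_scar_ha, 1))
    })), "scars.tsv")
  }
  writeLines(report$log, file.path(out_dir, "run.log"))
  paths <- c(paths, file.path(out_dir, "run.log"))
  invisible(paths)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d cores, %d age models, %d loss estimate(s)\n",
              nrow(x$cores), length(x$age_models), length(x$losses)))
  for (l in x$losses) {
    cat(sprintf("  %s: eroded %.2f + foregone %.2f = %.2f kg m-2\n",
                l$label, l$eroded_kg_m2, l$foregone_kg_m2, l$total_kg_m2))
  }
  invisible(x)
}
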