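# Mooring-impact accounting: eroded-stock loss, foregone sequestration, and
# scar-area quantification from mooring counts or rasterized seascapes.

HABITAT_CLASSES <- c(seagrass = 1L, bare = 2L, reef = 3L)

#' Eroded-stock loss between meadow and scar sediments
#'
#' The carbon eroded by a disturbance is estimated as the difference between
#' the mean depth-standardized stocks of undisturbed meadows and of the
#' disturbed (scar) sediments, with SEMs combined in quadrature. A negative
#' difference (scar richer than meadow) is allowed but flagged.
#'
#' @param meadow,scar `treatment_summary` objects of per-core stocks for the
#'   same component and reference thickness.
#' @return List of class `loss_component`: `eroded_kg_m2`, `sd`, `negative`.
#' @examples
#' m <- summarize_treatment(c(6.6, 6.2), variable = "Corg stock")
#' s <- summarize_treatment(c(1.4, 1.8), variable = "Corg stock")
#' stock_loss(m, s)$eroded_kg_m2  # 4.8
#' @export
stock_loss <- function(meadow, scar) {
  if (!identical(meadow$variable, scar$variable)) {
    sc_validation_error("meadow and scar summaries describe different variables")
  }
  eroded <- meadow$mean - scar$mean
  structure(list(eroded_kg_m2 = eroded,
                 sd = sqrt(sum(c(meadow$sem, scar$sem)^2, na.rm = TRUE)),
                 negative = eroded < 0),
            class = "loss_component")
}

#' Foregone carbon sequestration after habitat loss
#'
#' Once the habitat is destroyed, accumulation stops; the carbon that would
#' have been sequestered is the accumulation rate times the elapsed time,
#' `rate * years / 1000` (g/m^2/yr x yr -> kg/m^2).
#'
#' @param rate_g_m2_yr Accumulation rate (g/m^2/yr), >= 0.
#' @param years Years since disturbance, >= 0 (default 50).
#' @return Foregone sequestration in kg/m^2.
#' @examples
#' foregone_sequestration(34, 50)  # 1.7 kg m-2
#' @export
foregone_sequestration <- function(rate_g_m2_yr, years = 50) {
  if (any(rate_g_m2_yr < 0) || any(years < 0)) {
    sc_validation_error("rate and years must be >= 0")
  }
  rate_g_m2_yr * years / 1000
}

#' Combine eroded and foregone components into a loss estimate
#'
#' @param eroded A `loss_component` from [stock_loss()].
#' @param foregone_kg_m2 Foregone sequestration (kg/m^2).
#' @param years_since_disturbance Years used for the foregone component.
#' @param scar_area_m2 Optional total scar area to scale the per-m^2 loss to
#'   a habitat-wide total (reported in Mg).
#' @return Object of class `loss_estimate`.
#' @export
loss_estimate <- function(eroded, foregone_kg_m2 = 0,
                          years_since_disturbance = 50,
                          scar_area_m2 = NULL) {
  total <- eroded$eroded_kg_m2 + foregone_kg_m2
  out <- list(eroded_kg_m2 = eroded$eroded_kg_m2, eroded_sd = eroded$sd,
              foregone_kg_m2 = foregone_kg_m2,
              years_since_disturbance = years_since_disturbance,
              total_kg_m2 = total)
  if (!is.null(scar_area_m2)) {
    out$scar_area_m2 <- scar_area_m2
    out$total_loss_mg <- total * scar_area_m2 / 1000  # kg -> Mg
  }
  structure(out, class = "loss_estimate")
}

#' Scar-area summary from mooring counts
#'
#' Scales a mean per-mooring scar area by the number of moorings:
#' `total = n * mean`, with hectare conversion and, when a SEM of the mean
#' scar size is given, `SEM(total) = n * SEM(mean)`.
#'
#' @param n_moorings Number of moorings (>= 0).
#' @param mean_scar_m2 Mean scar area per mooring (m^2).
#' @param sem_scar_m2 Optional SEM of the mean scar area.
#' @return Object of class `scar_summary` with `n_moorings`, `mean_scar_m2`,
#'   `sem_scar_m2`, `total_scar_m2`, `total_scar_ha`, `sem_total_m2`.
#' @examples
#' scar_area_from_counts(893, 54)$total_scar_ha  # 4.8
#' @export
scar_area_from_counts <- function(n_moorings, mean_scar_m2,
                                  sem_scar_m2 = NA_real_) {
  if (n_moorings < 0 || mean_scar_m2 < 0) {
    sc_validation_error("counts and areas must be >= 0")
  }
  total <- n_moorings * mean_scar_m2
  structure(list(n_moorings = n_moorings, mean_scar_m2 = mean_scar_m2,
                 sem_scar_m2 = sem_scar_m2, total_scar_m2 = total,
                 total_scar_ha = total / 1e4,
                 sem_total_m2 = n_moorings * sem_scar_m2),
            class = "scar_summary")
}

#' @export
print.scar_summary <- function(x, ...) {
  cat(sprintf("<scar_summary> %d moorings x %.0f m2 = %.0f m2 (%.1f ha)\n",
              x$n_moorings, x$mean_scar_m2, x$total_scar_m2, x$total_scar_ha))
  invisible(x)
}

#' Construct a rasterized habitat grid
#'
#' A regular grid of habitat classes (`seagrass`, `bare`, `reef`) in a local
#' metric frame. Row 1 of the matrix is the northernmost row (max y), as in
#' the ESRI ASCII-grid dialect; cell `[i, j]` has its center at
#' `x = x0 + (j - 0.5) * cell`, `y = y0 + (nrow - i + 0.5) * cell`.
#'
#' @param classes Character or integer matrix of habitat codes
#'   (1 = seagrass, 2 = bare, 3 = reef).
#' @param cell_size_m Cell edge length (m), > 0.
#' @param origin Numeric `c(x0, y0)`, the lower-left corner.
#' @return Object of class `habitat_grid`.
#' @export
habitat_grid <- function(classes, cell_size_m, origin = c(0, 0)) {
  if (cell_size_m <= 0) sc_validation_error("cell_size_m must be > 0")
  if (is.character(classes)) {
    m <- matrix(HABITAT_CLASSES[classes], nrow = nrow(classes))
    if (any(is.na(m))) sc_validation_error("unknown habitat class code")
    classes <- m
  }
  if (!all(classes %in% HABITAT_CLASSES)) {
    sc_validation_error("habitat codes must be 1 (seagrass), 2 (bare) or 3 (reef)")
  }
  structure(list(classes = classes, cell_size_m = cell_size_m,
                 origin = as.numeric(origin)),
            class = "habitat_grid")
}

#' @export
print.habitat_grid <- function(x, ...) {
  tab <- table(factor(x$classes, levels = HABITAT_CLASSES,
                      labels = names(HABITAT_CLASSES)))
  cat(sprintf("<habitat_grid> %d x %d cells of %.2f m (%.2f ha)\n",
              nrow(x$classes), ncol(x$classes), x$cell_size_m,
              length(x$classes) * x$cell_size_m^2 / 1e4))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

grid_cell_centers <- function(grid) {
  nr <- nrow(grid$classes); nc <- ncol(grid$classes)
  cs <- grid$cell_size_m
  list(x = grid$origin[1] + (seq_len(nc) - 0.5) * cs,
       y = grid$origin[2] + (nr - seq_len(nr) + 0.5) * cs)
}

#' Read / write a habitat grid in the ESRI ASCII-grid dialect
#'
#' Plain-text raster with a six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of integer class
#' codes (1 = seagrass, 2 = bare, 3 = reef), northernmost row first.
#'
#' @param path File path.
#' @return `read_habitat_grid` returns a [habitat_grid()];
#'   `write_habitat_grid` returns the path invisibly.
#' @export
read_habitat_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(as.integer(vals), nrow = h[["nrows"]], ncol = h[["ncols"]],
              byrow = TRUE)
  habitat_grid(m, cell_size_m = h[["cellsize"]],
               origin = c(h[["xllcorner"]], h[["yllcorner"]]))
}

#' @rdname read_habitat_grid
#' @param grid A [habitat_grid()].
#' @export
write_habitat_grid <- function(grid, path) {
  hdr <- c(sprintf("ncols %d", ncol(grid$classes)),
           sprintf("nrows %d", nrow(grid$classes)),
           sprintf("xllcorner %.6f", grid$origin[1]),
           sprintf("yllcorner %.6f", grid$origin[2]),
           sprintf("cellsize %.6f", grid$cell_size_m),
           "NODATA_value -9999")
  rows <- apply(grid$classes, 1L, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read mooring points from delimited text
#'
#' Expects a header with columns `id`, `x`, `y` (meters, same frame as the
#' habitat grid); comma or tab delimited.
#'
#' @param path File path.
#' @return data.frame with `id`, `x`, `y`.
#' @export
read_moorings <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = detect_delim(path),
                         stringsAsFactors = FALSE)
  if (!all(c("id", "x", "y") %in% names(m))) {
    sc_format_error("moorings table must have columns id, x, y")
  }
  if (any(!is.finite(m$x)) || any(!is.finite(m$y))) {
    sc_validation_error("mooring coordinates must be finite")
  }
  m
}

#' Map mooring-induced scar area with a Euclidean buffer
#'
#' A bare-sediment cell is attributed to mooring scarring when its center
#' lies within `buffer_m` of at least one mooring; bare cells outside all
#' buffers are not counted. Shared cells are assigned to the nearest mooring
#' (ties to the lowest id), so per-mooring areas partition the union without
#' double counting. Moorings outside the grid extent are excluded with a
#' warning.
#'
#' @param grid A [habitat_grid()].
#' @param moorings data.frame with `id`, `x`, `y`.
#' @param buffer_m Buffer radius in meters (default 10, the typical swing
#'   reach of a mooring chain).
#' @return List with `per_mooring` (data.frame `id`, `area_m2`), `summary`
#'   (a `scar_summary`), and `scar_mask` (logical matrix of scar cells).
#' @export
map_scar_area <- function(grid, moorings, buffer_m = 10) {
  if (buffer_m <= 0) sc_validation_error("buffer must be > 0")
  cs <- grid$cell_size_m
  nr <- nrow(grid$classes); nc <- ncol(grid$classes)
  xmax <- grid$origin[1] + nc * cs
  ymax <- grid$origin[2] + nr * cs
  inside <- moorings$x >= grid$origin[1] & moorings$x <= xmax &
            moorings$y >= grid$origin[2] & moorings$y <= ymax
  if (any(!inside)) {
    warning(sprintf("excluding %d mooring(s) outside the grid extent: %s",
                    sum(!inside),
                    paste(moorings$id[!inside], collapse = ", ")))
    moorings <- moorings[inside, , drop = FALSE]
  }
  moorings <- moorings[order(moorings$id), , drop = FALSE]
  ctr <- grid_cell_centers(grid)
  bare <- grid$classes == HABITAT_CLASSES[["bare"]]
  nearest <- matrix(NA_integer_, nr, nc)
  mind2 <- matrix(Inf, nr, nc)
  xg <- matrix(ctr$x, nr, nc, byrow = TRUE)
  yg <- matrix(ctr$y, nr, nc)
  for (i in seq_len(nrow(moorings))) {
    d2 <- (xg - moorings$x[i])^2 + (yg - moorings$y[i])^2
    upd <- d2 < mind2            # strict: earlier (lower) id keeps ties
    mind2[upd] <- d2[upd]
    nearest[upd] <- i
  }
  scar <- bare & mind2 <= buffer_m^2
  per <- data.frame(id = moorings$id,
                    area_m2 = vapply(seq_len(nrow(moorings)), function(i) {
                      sum(scar & nearest == i) * cs^2
                    }, numeric(1)))
  n <- nrow(per)
  summ <- structure(list(
    n_moorings = n,
    mean_scar_m2 = if (n) mean(per$area_m2) else 0,
    sem_scar_m2 = if (n > 1L) stats::sd(per$area_m2) / sqrt(n) else NA_real_,
    total_scar_m2 = sum(scar) * cs^2,
    total_scar_ha = sum(scar) * cs^2 / 1e4,
    sem_total_m2 = NA_real_), class = "scar_summary")
  list(per_mooring = per, summary = summ, scar_mask = scar)
}
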