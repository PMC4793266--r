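# Domain model and I/O for slice-resolved sediment cores.
#
# A sediment_core is a list with coring metadata and a data.frame of ordered,
# contiguous depth slices. Depths are in cm below the seafloor, positive
# downward; slice intervals are half-open [top, bottom) and a slice value
# refers to the whole interval.

#' Recognized slice-table columns
#'
#' Column names accepted by [read_core_table()] and carried by the `slices`
#' data.frame of a [sediment_core()].
#'
#' @return Character vector of column names.
#' @export
core_table_columns <- function() {
  c("top_cm", "bottom_cm", "dry_mass_g", "dbd_g_cm3", "corg_pct",
    "d13c_permil", "caco3_pct", "coarse_pct", "medium_pct", "fine_pct",
    "vfine_mud_pct", "pb210_bq_kg", "pb210_sd", "ra226_bq_kg", "ra226_sd")
}

GRAIN_COLS <- c("coarse_pct", "medium_pct", "fine_pct", "vfine_mud_pct")
PCT_COLS <- c("corg_pct", "caco3_pct", GRAIN_COLS)

#' Construct a slice-resolved sediment core
#'
#' Bundles coring metadata with an ordered, contiguous, non-overlapping set of
#' depth slices. Slices must tile the depth axis: each slice's top equals the
#' previous slice's bottom. All geochemical columns are optional; missing
#' values are `NA`.
#'
#' @param slices data.frame with at least `top_cm` and `bottom_cm`, plus any of
#'   [core_table_columns()]. Unrecognized columns are preserved.
#' @param core_id Core identifier.
#' @param site Site label (e.g. a bay name).
#' @param treatment Either `"meadow"` or `"scar"`.
#' @param barrel_inserted_cm Length of core barrel inserted into the sediment.
#' @param recovered_cm Length of sediment recovered (compressed), with
#'   `0 < recovered_cm <= barrel_inserted_cm`.
#' @param water_depth_m Water depth at the coring station (m), optional.
#' @param decompressed Logical; whether depths are already decompressed.
#'   Fresh field cores are `FALSE`; see [decompress_depths()].
#' @return An object of class `sediment_core`.
#' @seealso [read_core_table()], [decompress_depths()], [interpolate_gaps()]
#' @examples
#' sl <- data.frame(top_cm = 0:4, bottom_cm = 1:5, dbd_g_cm3 = 0.82,
#'                  corg_pct = 1.6)
#' sediment_core(sl, core_id = "TB-M1", site = "Thomson Bay",
#'               treatment = "meadow", barrel_inserted_cm = 80,
#'               recovered_cm = 64)
#' @export
sediment_core <- function(slices, core_id, site = NA_character_,
                          treatment = c("meadow", "scar"),
                          barrel_inserted_cm = NA_real_,
                          recovered_cm = NA_real_,
                          water_depth_m = NA_real_,
                          decompressed = FALSE) {
  treatment <- match.arg(treatment)
  if (!is.data.frame(slices)) sc_validation_error("`slices` must be a data.frame")
  if (!all(c("top_cm", "bottom_cm") %in% names(slices))) {
    sc_format_error("slice table must contain columns `top_cm` and `bottom_cm`")
  }
  slices <- as.data.frame(slices, stringsAsFactors = FALSE)
  slices <- slices[order(slices$top_cm), , drop = FALSE]
  rownames(slices) <- NULL
  if (!("measured" %in% names(slices))) {
    geochem <- intersect(c("corg_pct", "caco3_pct", GRAIN_COLS, "d13c_permil"),
                         names(slices))
    slices$measured <- if (length(geochem)) {
      apply(!is.na(slices[, geochem, drop = FALSE]), 1L, any)
    } else {
      rep(TRUE, nrow(slices))
    }
  }
  core <- structure(
    list(core_id = core_id, site = site, treatment = treatment,
         barrel_inserted_cm = barrel_inserted_cm,
         recovered_cm = recovered_cm, water_depth_m = water_depth_m,
         decompressed = isTRUE(decompressed), slices = slices),
    class = "sediment_core"
  )
  validate_sediment_core(core)
  core
}

validate_sediment_core <- function(core) {
  s <- core$slices
  if (nrow(s) == 0L) sc_validation_error("core has no slices")
  bad <- which(!(s$bottom_cm > s$top_cm))
  if (length(bad)) {
    sc_validation_error(sprintf(
      "slice bottom must exceed top; offending rows: %s",
      paste(bad, collapse = ", ")))
  }
  if (any(s$top_cm < 0)) sc_validation_error("slice tops must be >= 0")
  if (nrow(s) > 1L) {
    gaps <- which(!near(s$top_cm[-1L], s$bottom_cm[-nrow(s)]))
    if (length(gaps)) {
      sc_validation_error(sprintf(
        "slices must be contiguous (top equals previous bottom); offending rows: %s",
        paste(gaps + 1L, collapse = ", ")))
    }
  }
  for (col in intersect(PCT_COLS, names(s))) {
    v <- s[[col]]
    if (any(v < 0 | v > 100, na.rm = TRUE)) {
      sc_validation_error(sprintf("%s must lie in [0, 100]", col))
    }
  }
  if (all(GRAIN_COLS %in% names(s))) {
    g <- as.matrix(s[GRAIN_COLS])
    full <- stats::complete.cases(g)
    tot <- rowSums(g[full, , drop = FALSE])
    if (any(!near(tot, 100, 1e-4))) {
      sc_validation_error("grain-size percentages must sum to 100 where all four classes are present")
    }
  }
  for (col in intersect(c("dbd_g_cm3", "dry_mass_g", "pb210_bq_kg",
                          "ra226_bq_kg", "pb210_sd", "ra226_sd"), names(s))) {
    if (any(s[[col]] < 0, na.rm = TRUE)) {
      sc_validation_error(sprintf("%s must be non-negative", col))
    }
  }
  if (!is.na(core$recovered_cm)) {
    if (core$recovered_cm <= 0) sc_validation_error("recovered_cm must be > 0")
    if (!is.na(core$barrel_inserted_cm) &&
        core$recovered_cm > core$barrel_inserted_cm + 1e-9) {
      sc_validation_error("recovered_cm cannot exceed barrel_inserted_cm")
    }
  }
  invisible(core)
}

#' @export
print.sediment_core <- function(x, ...) {
  s <- x$slices
  cat(sprintf("<sediment_core> %s  [%s, %s]\n", x$core_id, x$site, x$treatment))
  cat(sprintf("  %d slices spanning %.1f-%.1f cm (%s depths)\n",
              nrow(s), min(s$top_cm), max(s$bottom_cm),
              if (x$decompressed) "decompressed" else "as-recovered"))
  cat(sprintf("  barrel inserted %.1f cm, recovered %.1f cm\n",
              x$barrel_inserted_cm, x$recovered_cm))
  vars <- intersect(core_table_columns(), names(s))
  have <- vars[vapply(vars, function(v) any(!is.na(s[[v]])), logical(1))]
  cat("  variables:", paste(setdiff(have, c("top_cm", "bottom_cm")), collapse = ", "), "\n")
  invisible(x)
}

slice_mids <- function(core) {
  (core$slices$top_cm + core$slices$bottom_cm) / 2
}

slice_thickness <- function(core) {
  core$slices$bottom_cm - core$slices$top_cm
}

# Density paired with the core's current depth coordinates: the measured lab
# DBD before decompression, the volume-rescaled DBD afterwards (so that
# DBD x thickness always equals dry mass per area).
working_dbd <- function(core) {
  s <- core$slices
  if (core$decompressed && "dbd_decomp_g_cm3" %in% names(s)) {
    s$dbd_decomp_g_cm3
  } else {
    s$dbd_g_cm3
  }
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

parse_metadata_sidecar <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt)) & !grepl("^\\s*#", txt)]
  if (any(grepl("=", txt, fixed = TRUE)) && !any(grepl(":", txt, fixed = TRUE))) {
    kv <- strsplit(txt, "=", fixed = TRUE)
    meta <- lapply(kv, function(p) trimws(paste(p[-1L], collapse = "=")))
    names(meta) <- trimws(vapply(kv, `[`, "", 1L))
  } else {
    meta <- yaml::yaml.load(paste(txt, collapse = "\n"))
  }
  num <- c("barrel_inserted_cm", "recovered_cm", "water_depth_m")
  for (k in intersect(num, names(meta))) meta[[k]] <- as.numeric(meta[[k]])
  meta
}

#' Read a slice table into a sediment core
#'
#' Parses a delimited text file (comma or tab, auto-detected; decimal point
#' only) with one row per slice and a header naming recognized columns (see
#' [core_table_columns()]). Unrecognized columns are preserved as opaque
#' extras. Metadata may be supplied as a list or as the path of a sidecar file
#' in `key = value` or YAML form with keys `core_id`, `site`, `treatment`,
#' `barrel_inserted_cm`, `recovered_cm`, `water_depth_m`.
#'
#' @param path Path to the slice table.
#' @param metadata Named list of core metadata, or path to a metadata sidecar.
#' @return A validated [sediment_core()] with slices ordered by depth.
#' @export
read_core_table <- function(path, metadata) {
  if (!file.exists(path)) sc_format_error(sprintf("core table not found: %s", path))
  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- parse_metadata_sidecar(metadata)
  }
  tab <- utils::read.table(path, header = TRUE, sep = detect_delim(path),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  if (!all(c("top_cm", "bottom_cm") %in% names(tab))) {
    sc_format_error("core table must contain columns `top_cm` and `bottom_cm`")
  }
  sediment_core(
    tab,
    core_id = metadata$core_id %||% basename(path),
    site = metadata$site %||% NA_character_,
    treatment = metadata$treatment %||% "meadow",
    barrel_inserted_cm = metadata$barrel_inserted_cm %||% NA_real_,
    recovered_cm = metadata$recovered_cm %||% NA_real_,
    water_depth_m = metadata$water_depth_m %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correct slice depths for core-barrel compression
#'
#' Coring compresses soft sediment: the recovered column is shorter than the
#' barrel penetration. Depths are restored by a uniform linear stretch, every
#' slice boundary multiplied by `barrel_inserted_cm / recovered_cm`. Slice dry
#' masses are unchanged; dry bulk density is re-expressed per decompressed
#' volume in `dbd_decomp_g_cm3` (the measured lab value is kept in
#' `dbd_g_cm3`), so cumulative mass-depth is exactly conserved. Applying the
#' correction twice is an error.
#'
#' @param core A [sediment_core()] with `barrel_inserted_cm` and
#'   `recovered_cm` set.
#' @return The core with decompressed depths and `decompressed = TRUE`.
#' @export
decompress_depths <- function(core) {
  stopifnot(inherits(core, "sediment_core"))
  if (core$decompressed) sc_validation_error("core is already decompressed")
  if (is.na(core$recovered_cm) || core$recovered_cm <= 0) {
    sc_validation_error("recovered_cm must be set and > 0")
  }
  if (is.na(core$barrel_inserted_cm)) {
    sc_validation_error("barrel_inserted_cm must be set")
  }
  f <- core$barrel_inserted_cm / core$recovered_cm
  s <- core$slices
  s$measured_thickness_cm <- s$bottom_cm - s$top_cm
  s$top_cm <- s$top_cm * f
  s$bottom_cm <- s$bottom_cm * f
  if ("dbd_g_cm3" %in% names(s)) s$dbd_decomp_g_cm3 <- s$dbd_g_cm3 / f
  core$slices <- s
  core$decompressed <- TRUE
  core$compression_factor <- f
  validate_sediment_core(core)
  core
}

#' Dry bulk density from the cylinder formula
#'
#' Oven-dry slice mass divided by the cylindrical slice volume. Thickness is
#' the measured (compressed) slice thickness, matching how the laboratory
#' quantity is defined.
#'
#' @param dry_mass_g Oven-dry mass (g).
#' @param core_diameter_cm Internal core diameter (cm), default 6.
#' @param measured_thickness_cm Measured slice thickness (cm).
#' @return Dry bulk density in g per cubic cm.
#' @examples
#' compute_dry_bulk_density(23.18, 6, 1)  # ~0.82
#' @export
compute_dry_bulk_density <- function(dry_mass_g, core_diameter_cm = 6,
                                     measured_thickness_cm = 1) {
  if (any(dry_mass_g <= 0) || any(core_diameter_cm <= 0) ||
      any(measured_thickness_cm <= 0)) {
    sc_validation_error("dry mass, diameter and thickness must all be > 0")
  }
  dry_mass_g / (pi * (core_diameter_cm / 2)^2 * measured_thickness_cm)
}

# Fill missing DBD from dry mass using the measured (pre-decompression)
# thickness; no-op where DBD is present.
fill_dbd_from_mass <- function(core, core_diameter_cm = 6) {
  s <- core$slices
  if (!("dry_mass_g" %in% names(s))) return(core)
  if (!("dbd_g_cm3" %in% names(s))) s$dbd_g_cm3 <- NA_real_
  thick <- if (core$decompressed && "measured_thickness_cm" %in% names(s)) {
    s$measured_thickness_cm
  } else {
    s$bottom_cm - s$top_cm
  }
  need <- is.na(s$dbd_g_cm3) & !is.na(s$dry_mass_g)
  if (any(need)) {
    s$dbd_g_cm3[need] <- compute_dry_bulk_density(
      s$dry_mass_g[need], core_diameter_cm, thick[need])
    if (core$decompressed) {
      if (!("dbd_decomp_g_cm3" %in% names(s))) s$dbd_decomp_g_cm3 <- NA_real_
      s$dbd_decomp_g_cm3[need] <- s$dbd_g_cm3[need] / core$compression_factor
    }
  }
  core$slices <- s
  core
}

#' Fill unanalyzed slices by linear interpolation
#'
#' Sampling designs often analyze every second slice; the rest are filled by
#' linear interpolation of the measured values at slice mid-depths. Above the
#' shallowest and below the deepest measurement the nearest measured value is
#' used. Measured values are never modified, and filled slices keep
#' `measured = FALSE`.
#'
#' @param core A [sediment_core()].
#' @param variables Character vector of slice columns to fill (e.g.
#'   `c("corg_pct", "dbd_g_cm3")`).
#' @return The core with the requested variables filled on all slices.
#' @export
interpolate_gaps <- function(core, variables) {
  stopifnot(inherits(core, "sediment_core"))
  s <- core$slices
  mids <- slice_mids(core)
  for (v in variables) {
    if (!(v %in% names(s))) sc_validation_error(sprintf("variable `%s` not present", v))
    ok <- !is.na(s[[v]])
    if (sum(ok) < 2L) {
      sc_validation_error(sprintf("variable `%s` has fewer than 2 measurements", v))
    }
    filled <- stats::approx(mids[ok], s[[v]][ok], xout = mids, rule = 2,
                            ties = "ordered")$y
    s[[v]][!ok] <- filled[!ok]
    if (v == "dbd_g_cm3" && core$decompressed) {
      if (!("dbd_decomp_g_cm3" %in% names(s))) s$dbd_decomp_g_cm3 <- NA_real_
      s$dbd_decomp_g_cm3[!ok] <- s$dbd_g_cm3[!ok] / core$compression_factor
    }
  }
  core$slices <- s
  core$interpolated <- union(core$interpolated, variables)
  core
}

#' Bin a raw grain-size distribution into sand/mud classes
#'
#' Classifies particle mass below 1 mm into coarse sand (0.5-1 mm), medium
#' sand (0.25-0.5 mm), fine sand (0.125-0.25 mm) and very fine sand plus mud
#' (< 0.125 mm), renormalized to percentages of the total mass below 1 mm.
#'
#' @param raw data.frame or list with `size_mm` and `weight_fraction`
#'   (arbitrary positive weights; sizes must be < 1 mm).
#' @return A named numeric vector of class `grain_size_composition` with
#'   components `coarse`, `medium`, `fine`, `vfine_mud` summing to 100.
#' @examples
#' classify_grain_sizes(data.frame(size_mm = c(0.6, 0.3, 0.15, 0.05),
#'                                 weight_fraction = c(1, 1, 1, 1)))
#' @export
classify_grain_sizes <- function(raw) {
  size <- raw$size_mm
  w <- raw$weight_fraction
  if (length(size) != length(w) || !length(size)) {
    sc_validation_error("size_mm and weight_fraction must be equal-length, non-empty")
  }
  if (any(size >= 1)) sc_validation_error("all particle sizes must be < 1 mm")
  if (any(w < 0)) sc_validation_error("weight fractions must be >= 0")
  tot <- sum(w)
  if (tot <= 0) sc_validation_error("total weight is zero; nothing to classify")
  cls <- ifelse(size > 0.5, "coarse",
         ifelse(size > 0.25, "medium",
         ifelse(size > 0.125, "fine", "vfine_mud")))
  out <- vapply(c("coarse", "medium", "fine", "vfine_mud"),
                function(k) sum(w[cls == k]) / tot * 100, numeric(1))
  structure(out, class = "grain_size_composition")
}
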