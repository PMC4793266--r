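test_that("core tables parse with auto-detected delimiter and sidecar metadata", {
  dir <- withr::local_tempdir()
  tab <- file.path(dir, "core.csv")
  df <- data.frame(top_cm = 0:49, bottom_cm = 1:50, dbd_g_cm3 = 0.8,
                   corg_pct = rep(c(2, NA), 25), extra_col = 7)
  write.csv(df, tab, row.names = FALSE, quote = FALSE)
  meta <- file.path(dir, "core_meta.txt")
  writeLines(c("core_id = TB-M1", "site = Thomson Bay", "treatment = meadow",
               "barrel_inserted_cm = 80", "recovered_cm = 64"), meta)
  core <- read_core_table(tab, meta)
  expect_s3_class(core, "sediment_core")
  expect_equal(nrow(core$slices), 50)
  expect_equal(core$barrel_inserted_cm, 80)
  expect_equal(sum(core$slices$measured), 25)   # alternate slices analyzed
  expect_true("extra_col" %in% names(core$slices))

  # tab-delimited variant with YAML sidecar
  tab2 <- file.path(dir, "core.tsv")
  write.table(df, tab2, sep = "\t", row.names = FALSE, quote = FALSE)
  meta2 <- file.path(dir, "m.yml")
  writeLines(c("core_id: SB-S1", "treatment: scar", "barrel_inserted_cm: 70",
               "recovered_cm: 70"), meta2)
  core2 <- read_core_table(tab2, meta2)
  expect_equal(core2$treatment, "scar")
  expect_equal(core2$slices$dbd_g_cm3, core$slices$dbd_g_cm3)
})

test_that("slice validation rejects inverted, overlapping and out-of-range rows", {
  bad <- data.frame(top_cm = c(0, 10), bottom_cm = c(1, 9))
  expect_error(sediment_core(bad, "x", treatment = "meadow",
                             barrel_inserted_cm = 10, recovered_cm = 10),
               "contiguous|bottom")
  inv <- data.frame(top_cm = 10, bottom_cm = 9)
  expect_error(sediment_core(inv, "x", treatment = "meadow",
                             barrel_inserted_cm = 10, recovered_cm = 10),
               "bottom")
  gap <- data.frame(top_cm = c(0, 2), bottom_cm = c(1, 3))
  expect_error(sediment_core(gap, "x", treatment = "meadow",
                             barrel_inserted_cm = 3, recovered_cm = 3),
               "contiguous")
  pct <- data.frame(top_cm = 0, bottom_cm = 1, corg_pct = 120)
  expect_error(sediment_core(pct, "x", treatment = "meadow",
                             barrel_inserted_cm = 1, recovered_cm = 1),
               "\\[0, 100\\]")
  expect_error(sediment_core(data.frame(top_cm = 0, bottom_cm = 1), "x",
                             treatment = "meadow", barrel_inserted_cm = 1,
                             recovered_cm = 2),
               "recovered")
})

test_that("decompression stretches depths linearly and conserves mass", {
  sl <- data.frame(top_cm = 0:39, bottom_cm = 1:40, dry_mass_g = runif(40, 20, 30))
  sl$dbd_g_cm3 <- compute_dry_bulk_density(sl$dry_mass_g, 6, 1)
  core <- sediment_core(sl, "c", treatment = "meadow",
                        barrel_inserted_cm = 80, recovered_cm = 40)
  dec <- decompress_depths(core)
  # factor 2 stretch
  expect_equal(max(dec$slices$bottom_cm), 80)
  expect_equal(dec$slices$top_cm, core$slices$top_cm * 2)
  # thickness ratios preserved
  expect_equal(diff(range(dec$slices$bottom_cm - dec$slices$top_cm)), 0)
  # per-slice and total dry mass unchanged
  expect_identical(dec$slices$dry_mass_g, core$slices$dry_mass_g)
  # cumulative mass-depth at the base invariant: sum dbd * dz equal before/after
  m_before <- sum(core$slices$dbd_g_cm3 * (core$slices$bottom_cm - core$slices$top_cm))
  m_after <- sum(dec$slices$dbd_decomp_g_cm3 * (dec$slices$bottom_cm - dec$slices$top_cm))
  expect_equal(m_after, m_before, tolerance = 1e-12)
  # idempotence guard and bad metadata
  expect_error(decompress_depths(dec), "already")
  core$recovered_cm <- NA_real_
  expect_error(decompress_depths(core), "recovered")
})

test_that("specific decompression factors map boundaries as expected", {
  sl <- data.frame(top_cm = c(10), bottom_cm = c(11))
  # single-slice core: relax contiguity by providing exactly one slice
  core <- sediment_core(sl, "c", treatment = "meadow",
                        barrel_inserted_cm = 80, recovered_cm = 64)
  dec <- decompress_depths(core)
  expect_equal(dec$slices$top_cm, 12.5)
  expect_equal(dec$slices$bottom_cm, 13.75)
  # identity when barrel equals recovered
  core2 <- sediment_core(sl, "c", treatment = "meadow",
                         barrel_inserted_cm = 64, recovered_cm = 64)
  dec2 <- decompress_depths(core2)
  expect_equal(dec2$slices$top_cm, 10)
  expect_equal(dec2$slices$bottom_cm, 11)
})

test_that("dry bulk density follows the cylinder formula", {
  expect_equal(compute_dry_bulk_density(23.18, 6, 1), 23.18 / (pi * 9),
               tolerance = 1e-12)
  expect_equal(compute_dry_bulk_density(23.18, 6, 1), 0.820, tolerance = 1e-3)
  expect_equal(compute_dry_bulk_density(29.12, 6, 1), 1.030, tolerance = 1e-3)
  expect_error(compute_dry_bulk_density(0, 6, 1), "> 0")
  expect_error(compute_dry_bulk_density(10, -6, 1), "> 0")
})

test_that("gap interpolation is linear at mid-depths with nearest-value ends", {
  sl <- data.frame(top_cm = 0:4, bottom_cm = 1:5,
                   corg_pct = c(4.0, NA, 2.0, NA, NA))
  core <- sediment_core(sl, "c", treatment = "meadow",
                        barrel_inserted_cm = 5, recovered_cm = 5)
  out <- interpolate_gaps(core, "corg_pct")
  expect_equal(out$slices$corg_pct, c(4.0, 3.0, 2.0, 2.0, 2.0))
  # top-end nearest value
  sl2 <- data.frame(top_cm = 0:3, bottom_cm = 1:4,
                    corg_pct = c(NA, 3.0, NA, 1.0))
  core2 <- sediment_core(sl2, "c", treatment = "meadow",
                         barrel_inserted_cm = 4, recovered_cm = 4)
  out2 <- interpolate_gaps(core2, "corg_pct")
  expect_equal(out2$slices$corg_pct[1], 3.0)
  expect_equal(out2$slices$corg_pct[3], 2.0)
  # errors when under-determined
  sl3 <- data.frame(top_cm = 0:2, bottom_cm = 1:3, corg_pct = c(2, NA, NA))
  core3 <- sediment_core(sl3, "c", treatment = "meadow",
                         barrel_inserted_cm = 3, recovered_cm = 3)
  expect_error(interpolate_gaps(core3, "corg_pct"), "corg_pct")
})

test_that("interpolation never modifies measured values nor exceeds their range", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 30
    vals <- runif(n, 0.5, 4)
    keep <- sort(sample(n, sample(5:15, 1)))
    sl <- data.frame(top_cm = 0:(n - 1), bottom_cm = 1:n,
                     corg_pct = replace(rep(NA_real_, n), keep, vals[keep]))
    core <- sediment_core(sl, "c", treatment = "meadow",
                          barrel_inserted_cm = n, recovered_cm = n)
    out <- interpolate_gaps(core, "corg_pct")
    expect_equal(out$slices$corg_pct[keep], vals[keep])
    expect_true(all(out$slices$corg_pct >= min(vals[keep]) - 1e-12))
    expect_true(all(out$slices$corg_pct <= max(vals[keep]) + 1e-12))
    expect_false(any(out$slices$measured[setdiff(seq_len(n), keep)]))
  }
})

test_that("grain-size classification bins and renormalizes correctly", {
  one <- classify_grain_sizes(data.frame(size_mm = 0.3, weight_fraction = 1))
  expect_equal(unname(one["medium"]), 100)
  sym <- classify_grain_sizes(data.frame(size_mm = c(0.6, 0.3, 0.15, 0.05),
                                         weight_fraction = rep(0.25, 4)))
  expect_equal(unname(sym), c(25, 25, 25, 25))
  expect_error(classify_grain_sizes(data.frame(size_mm = 0.3, weight_fraction = 0)),
               "zero")
  expect_error(classify_grain_sizes(data.frame(size_mm = 1.2, weight_fraction = 1)),
               "< 1 mm")
})

test_that("grain-size classes match a brute-force re-binning oracle", {
  set.seed(42)
  size <- runif(1000, 0.001, 0.999)
  w <- rexp(1000)
  got <- classify_grain_sizes(data.frame(size_mm = size, weight_fraction = w))
  # independent oracle: explicit interval sums
  oracle <- c(
    coarse = sum(w[size > 0.5 & size < 1]),
    medium = sum(w[size > 0.25 & size <= 0.5]),
    fine = sum(w[size > 0.125 & size <= 0.25]),
    vfine_mud = sum(w[size <= 0.125])) / sum(w) * 100
  expect_equal(unclass(got), oracle, tolerance = 1e-12)
  expect_equal(sum(got), 100, tolerance = 1e-6)
})
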