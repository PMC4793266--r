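# Builders for small in-code fixtures.

uniform_core <- function(n = 50, thick = 1, dbd = 0.82, corg = 1.60,
                         caco3 = 84, treatment = "meadow",
                         barrel = n * thick, recovered = n * thick, ...) {
  sl <- data.frame(top_cm = (seq_len(n) - 1) * thick,
                   bottom_cm = seq_len(n) * thick,
                   dbd_g_cm3 = dbd, corg_pct = corg, caco3_pct = caco3)
  sediment_core(sl, core_id = "fix", site = "fixture", treatment = treatment,
                barrel_inserted_cm = barrel, recovered_cm = recovered, ...)
}

# exponential excess profile wrapped as a pb210_profile
exp_profile <- function(n = 26, thick = 1, c0 = 20, s = 0.25,
                        lambda = pb210_lambda(), sd = 0, dbd = 0.82) {
  mid <- (seq_len(n) - 0.5) * thick
  structure(data.frame(mid_cm = mid, thickness_cm = thick,
                       excess_bq_kg = c0 * exp(-lambda * mid / s),
                       excess_sd = sd, dbd_g_cm3 = dbd),
            class = c("pb210_profile", "data.frame"),
            supported = 0, supported_sd = 0, supported_method = "given")
}

make_profile <- function(mid, excess, sd = 1, thick = NULL, dbd = 1) {
  if (is.null(thick)) thick <- c(diff(mid), diff(mid)[length(mid) - 1])
  structure(data.frame(mid_cm = mid, thickness_cm = thick,
                       excess_bq_kg = excess,
                       excess_sd = rep_len(sd, length(mid)),
                       dbd_g_cm3 = rep_len(dbd, length(mid))),
            class = c("pb210_profile", "data.frame"),
            supported = 0, supported_sd = 0, supported_method = "given")
}

write_core_fixture <- function(dir, core_id, site, treatment, params) {
  sim <- simulate_core(params)
  sim$core$core_id <- core_id
  sim$core$site <- site
  write_simulated_core(sim, dir, stem = core_id)
  sim
}
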