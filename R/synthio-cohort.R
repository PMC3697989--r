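#' Study-condition parameters for a three-group cohort
#'
#' Group means and SEMs for every endpoint of the fructose-overload
#' study design: control (C), sedentary fructose (F) and low-intensity
#' trained fructose (FT), n = 8 per group, fructose at 100 g/L and an
#' insulin bolus of 0.75 U/kg.  The defaults are the published group
#' scales of the model (post-protocol values where an endpoint was
#' measured before and after); per-animal SDs are reconstructed as
#' `SEM * sqrt(8)`.
#'
#' @param n_per_group animals per group (>= 2).
#' @param seed master seed; every per-animal simulation seed derives
#'   from it.
#' @param duration_s,fs length and sampling rate of each simulated
#'   pressure recording.
#' @param fructose_conc_g_per_l,insulin_dose_U_per_kg protocol
#'   constants (metadata).
#' @return A list of class `cohort_spec`; `$endpoints` is a data frame
#'   with columns `endpoint`, `C`, `F`, `FT`, `sem_C`, `sem_F`,
#'   `sem_FT`.
#' @export
cohort_spec <- function(n_per_group = 8, seed = 1,
                        duration_s = 180, fs = 500,
                        fructose_conc_g_per_l = 100,
                        insulin_dose_U_per_kg = 0.75) {
  stopifnot(n_per_group >= 2)
  e <- function(name, C, F, FT, sC, sF, sFT)
    data.frame(endpoint = name, C = C, F = F, FT = FT,
               sem_C = sC, sem_F = sF, sem_FT = sFT)
  endpoints <- rbind(
    # metabolic / somatic
    e("glycemia",      84,    76,    88,    5,    4,    3),
    e("triglycerides", 96,    240,   160,   4,    6,    10),
    e("kitt",          5.0,   2.8,   3.5,   0.3,  0.3,  0.1),
    e("body_weight",   440,   438,   446,   9,    10,   11),
    e("wat",           3.2,   6.1,   3.1,   0.1,  0.2,  0.2),
    e("htw",           1.31,  1.42,  1.25,  0.04, 0.01, 0.03),
    e("htw_bw",        2.8,   3.4,   2.7,   0.1,  0.1,  0.1),
    # hemodynamics / variability
    e("sap",           122,   151,   142,   2,    3,    2),
    e("dap",           95,    118,   112,   2,    3,    4),
    e("map",           111,   140,   125,   3,    6,    5),
    e("hr",            325,   344,   352,   12,   10,   4),
    e("tr",            3.23,  1.91,  2.55,  0.42, 0.12, 0.11),
    e("br",            -1.71, -1.32, -1.41, 0.12, 0.11, 0.08),
    e("sap_var",       23.5,  41.9,  21.7,  2.6,  6.5,  4.4),
    e("lf",            3.0,   8.1,   3.4,   0.5,  0.6,  0.6),
    # right atrium ANP apparatus
    e("nv_gr",         22.1,  10.8,  18.7,  2.3,  1.4,  1.5),
    e("vv_gr",         5.3,   3.7,   4.8,   0.6,  0.6,  0.5),
    e("gr_area",       1785,  2030,  1754,  40,   66,   35),
    e("vv_mit",        25.8,  14.1,  32.7,  2.1,  1.2,  1.9),
    e("vv_miofib",     23.9,  23.1,  23.7,  2.1,  1.9,  2.3),
    # left ventricle
    e("a_my",          479,   588,   674,   18,   22,   48),
    e("nv_my",         6.3,   9.7,   8.0,   0.3,  0.3,  0.5),
    e("nv_cap",        5.4,   3.9,   5.2,   0.3,  0.1,  0.2),
    e("vv_cf_lv",      7.7,   13.7,  8.7,   0.8,  1.5,  1.5),
    e("vv_my",         73.2,  81.4,  74.8,  1.8,  1.2,  1.6),
    e("vv_cap",        3.6,   3.1,   3.6,   0.5,  0.3,  0.4),
    # ascending aorta
    e("lumen_area",    0.71,  0.96,  0.65,  0.04, 0.02, 0.01),
    e("diameter",      0.95,  1.15,  0.86,  0.02, 0.05, 0.04),
    e("imt",           158.1, 177.3, 153.4, 0.7,  3.1,  1.1),
    e("vv_cf_ao",      1.51,  7.92,  1.92,  0.22, 0.61, 0.04),
    e("el_number",     13.3,  10.4,  12.5,  0.1,  0.3,  0.2),
    e("cwt",           62,    81,    61,    3,    5,    5)
  )
  structure(list(
    n_per_group = n_per_group, seed = seed,
    duration_s = duration_s, fs = fs,
    fructose_conc_g_per_l = fructose_conc_g_per_l,
    insulin_dose_U_per_kg = insulin_dose_U_per_kg,
    sem_n = 8,                       # the SEMs correspond to n = 8
    endpoints = endpoints
  ), class = "cohort_spec")
}

# per-animal endpoint truth: group mean + SD * z, with WAT and LV
# collagen sharing a latent factor (rho = 0.9) so pooled adiposity ->
# fibrosis correlations emerge as they do in the animal data
draw_truth <- function(spec, group) {
  ep <- spec$endpoints
  mu <- ep[[group]]
  sdv <- ep[[paste0("sem_", group)]] * sqrt(spec$sem_n)
  names(mu) <- names(sdv) <- ep$endpoint
  z <- setNames(rnorm(nrow(ep)), ep$endpoint)
  rho <- 0.9
  z["vv_cf_lv"] <- rho * z["wat"] + sqrt(1 - rho^2) * z["vv_cf_lv"]
  tr <- mu + sdv * z
  # keep physiologic orderings and positivity
  tr["dap"] <- min(tr["dap"], tr["sap"] - 10)
  tr["kitt"] <- max(tr["kitt"], 0.5)
  tr["lf"] <- max(tr["lf"], 0.3)
  tr["sap_var"] <- max(tr["sap_var"], tr["lf"] + 1)
  for (p in c("wat", "tr", "nv_gr", "vv_gr", "gr_area", "nv_cap",
              "vv_cf_lv", "vv_cf_ao", "lumen_area", "imt"))
    tr[p] <- max(tr[p], 0.05 * mu[p])
  tr["el_number"] <- max(1, round(tr["el_number"]))
  tr["br"] <- min(tr["br"], -0.05)
  tr
}

#' Simulate a complete three-group cohort
#'
#' Draws per-animal ground-truth endpoint values around the group means
#' of a [cohort_spec()] and synthesises the full input bundle for each
#' animal: an arterial-pressure waveform whose systogram carries the
#' animal's LF variance, an ITT glucose series matching its Kitt,
#' pressor and depressor baroreflex trials matching its BR/TR gains,
#' and a vessel-geometry table.  Tissue fields and ring masks are large
#' and are generated on demand by [run_pipeline()] from the stored
#' truth rather than materialised here.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `cohort`; `$animals` is a list with one
#'   entry per animal (`id`, `group`, `truth`, `waveform`, `itt`,
#'   `baro_pressor`, `baro_depressor`, `vessel`, `seed`).
#' @export
sim_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    animals <- list()
    id <- 0L
    for (group in c("C", "F", "FT")) {
      for (j in seq_len(spec$n_per_group)) {
        id <- id + 1L
        truth <- draw_truth(spec, group)
        aseed <- sample.int(2^30, 1)
        lf_var <- truth[["lf"]]
        rem <- max(truth[["sap_var"]] - lf_var, 0.5)
        hf_var <- 0.25 * rem
        noise_var <- 0.75 * rem
        wf <- sim_ap_waveform(
          spec$duration_s, spec$fs, hr_bpm = truth[["hr"]],
          sap_mmHg = truth[["sap"]], dap_mmHg = truth[["dap"]],
          lf_sd_mmHg = sqrt(lf_var), hf_sd_mmHg = sqrt(hf_var),
          noise_sd_mmHg = sqrt(noise_var), seed = aseed)
        itt <- sim_itt(max(truth[["glycemia"]], 40),
                       t_half = 69.3 / truth[["kitt"]],
                       noise_sd = 3, seed = aseed + 1L)
        baro_p <- sim_baro_trial(truth[["br"]], c(10, 20, 30, 40),
                                 noise_sd = 2, drug = "pressor",
                                 seed = aseed + 2L)
        baro_d <- sim_baro_trial(-truth[["tr"]], -c(10, 20, 30, 40),
                                 noise_sd = 2, drug = "depressor",
                                 seed = aseed + 3L)
        vessel <- list(
          lumen_area_mm2 = pi * (truth[["diameter"]] / 2)^2,
          imt_measures_um = pmax(truth[["imt"]] + rnorm(4, 0, 2), 5),
          n_lamellae = as.integer(truth[["el_number"]]))
        animals[[id]] <- list(
          id = sprintf("%s%02d", group, j), group = group,
          truth = truth, waveform = wf, itt = itt,
          baro_pressor = baro_p, baro_depressor = baro_d,
          vessel = vessel, seed = aseed)
      }
    }
    structure(list(spec = spec, animals = animals), class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  g <- table(vapply(x$animals, `[[`, "", "group"))
  cat(sprintf("<cohort> %d animals (%s), seed %s\n",
              length(x$animals),
              paste(names(g), g, sep = "=", collapse = ", "),
              format(x$spec$seed)))
  invisible(x)
}
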