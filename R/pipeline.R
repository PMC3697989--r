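#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end in-silico study: the cohort
#' conditions plus segmentation policy, band edges, point-system sizes
#' and the significance level.  A YAML file with any subset of these
#' fields can be loaded with [read_pipeline_config()].
#'
#' @param spec a [cohort_spec()].
#' @param segment_length,overlap systogram segmentation policy (beats).
#' @param bands a [band_definition()].
#' @param n_points_atrium,n_points_lv,n_points_aorta stereological test
#'   system sizes for atrial EM, LV EM and aorta histology fields.
#' @param lv_fields,granule_fields fields generated per animal for LV
#'   and atrial morphometry.
#' @param alpha significance level for the group statistics.
#' @param out_dir optional output directory for the report files.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = cohort_spec(),
                            segment_length = 300, overlap = 0.5,
                            bands = band_definition(),
                            n_points_atrium = 82, n_points_lv = 140,
                            n_points_aorta = 200,
                            lv_fields = 2, granule_fields = 3,
                            alpha = 0.05, out_dir = NULL) {
  structure(list(spec = spec, segment_length = segment_length,
                 overlap = overlap, bands = bands,
                 n_points_atrium = n_points_atrium,
                 n_points_lv = n_points_lv,
                 n_points_aorta = n_points_aorta,
                 lv_fields = lv_fields, granule_fields = granule_fields,
                 alpha = alpha, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; recognised top-level fields are the arguments
#'   of [pipeline_config()] and [cohort_spec()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec_args <- y[intersect(names(y), names(formals(cohort_spec)))]
  spec <- do.call(cohort_spec, spec_args)
  cfg_args <- y[intersect(names(y), setdiff(names(formals(pipeline_config)),
                                            c("spec", "bands")))]
  if (!is.null(y$bands))
    cfg_args$bands <- band_definition(lf = y$bands$lf, hf = y$bands$hf)
  do.call(pipeline_config, c(list(spec = spec), cfg_args))
}

# analyse one simulated animal with the full measurement chain
analyze_animal <- function(an, cfg) {
  tr <- an$truth
  seed <- an$seed

  peaks <- detect_beats(an$waveform)
  hemo <- summarize_hemodynamics(beat_series(an$waveform, peaks))
  spec_res <- sap_variability(hemo,
                              segment_length = cfg$segment_length,
                              overlap = cfg$overlap, bands = cfg$bands)
  kt <- kitt(an$itt)
  br <- reflex_gain(an$baro_pressor)
  tr_gain <- reflex_gain(an$baro_depressor)

  # LV fields: collagen fraction + capillary profiles at the true density
  vv_cf <- nv_cap <- numeric(cfg$lv_fields)
  for (i in seq_len(cfg$lv_fields)) {
    fld <- sim_tissue_field(
      width = 500, height = 500,
      fractions = c(collagen = unname(tr[["vv_cf_lv"]])),
      object_density = tr[["nv_cap"]], object_radius_px = 8,
      px_per_um = 0.25, seed = seed + 10L + i)
    ft <- attr(fld, "truth")
    g <- overlay_grid(fld, cfg$n_points_lv, seed = seed + 20L + i)
    vv_cf[i] <- volume_density(g, 1)
    n_obj <- max(EBImage::bwlabel(fld == ft$object_label))
    nv_cap[i] <- numerical_density(n_obj, ft$area_mm2)$density
  }

  # atrial EM fields: granules at the true per-field count and profile
  # area; 90 x 90 px at 10 nm/px (0.9 um field, area 8.1e-7 mm2) keeps
  # count, granule area and Vv mutually consistent at the atrial scale
  r_gr <- max(1.5, sqrt(tr[["gr_area"]] / pi) / 10)        # px at 10 nm/px
  gr_fields <- lapply(seq_len(cfg$granule_fields), function(i)
    sim_tissue_field(width = 90, height = 90, fractions = numeric(0),
                     object_density = tr[["nv_gr"]] / 8.1e-7,
                     object_radius_px = r_gr, px_per_um = 100,
                     seed = seed + 30L + i))
  gs <- granule_stats(gr_fields, granule_label = 1, px_size_nm = 10,
                      n_points = cfg$n_points_atrium, seed = seed + 40L)

  # aorta: geometry, lamellae from a synthesised ring, collagen field
  d <- lumen_diameter(an$vessel$lumen_area_mm2)
  im <- intima_media(an$vessel$imt_measures_um, d)
  ring <- sim_aorta_ring(lumen_d_mm = d, imt_um = im$imt_um,
                         n_lamellae = an$vessel$n_lamellae,
                         px_per_um = 0.6, seed = seed + 50L)
  el <- count_lamellae(ring)$count
  ao_field <- sim_tissue_field(
    width = 400, height = 400,
    fractions = c(collagen = unname(tr[["vv_cf_ao"]])),
    object_radius_px = 6, seed = seed + 60L)
  vv_cf_ao <- volume_density(overlay_grid(ao_field, cfg$n_points_aorta,
                                          seed = seed + 61L), 1)
  cwt <- wall_tension(hemo$sap, d)

  c(list(id = an$id, group = an$group),
    # assay endpoints pass through from the simulated animal
    glycemia = unname(tr[["glycemia"]]),
    triglycerides = unname(tr[["triglycerides"]]),
    body_weight = unname(tr[["body_weight"]]),
    wat = unname(tr[["wat"]]),
    htw = unname(tr[["htw"]]), htw_bw = unname(tr[["htw_bw"]]),
    a_my = unname(tr[["a_my"]]), nv_my = unname(tr[["nv_my"]]),
    vv_my = unname(tr[["vv_my"]]), vv_cap = unname(tr[["vv_cap"]]),
    vv_gr = unname(gs$vv_percent), vv_mit = unname(tr[["vv_mit"]]),
    vv_miofib = unname(tr[["vv_miofib"]]),
    # measured endpoints
    kitt = kt$kitt,
    sap = hemo$sap, dap = hemo$dap, map = hemo$map, hr = hemo$hr,
    sap_var = spec_res$variance, lf = spec_res$lf_power,
    hf = spec_res$hf_power,
    tr = tr_gain$gain, br = br$gain,
    nv_gr = gs$granules_per_field, gr_area = gs$mean_area_nm2,
    nv_cap = mean(nv_cap), vv_cf_lv = mean(vv_cf),
    lumen_area = an$vessel$lumen_area_mm2, diameter = d,
    imt = im$imt_um, ima = im$ima_mm2,
    vv_cf_ao = vv_cf_ao, el_number = el,
    cwt = cwt$cwt_mmHg_mm)
}

#' Run the full in-silico study pipeline
#'
#' Simulates a three-group cohort and pushes every animal through the
#' complete measurement chain — beat detection, spectral variability,
#' baroreflex gains, Kitt, stereology and vessel morphometry — then
#' computes per-endpoint group statistics (one-way ANOVA with SNK
#' post-test) and the abstract-style percent-change summary.
#' Deterministic under the cohort seed.  When `cfg$out_dir` is set the
#' per-animal table, the group table and a Markdown summary are written
#' there together with a parameter log.
#'
#' @param cfg a [pipeline_config()].
#' @return A list of class `study_report`: `animals` (per-animal
#'   measurements), `groups` (per-endpoint group means, SEMs, ANOVA and
#'   SNK flags: `*` vs C, `+` vs F), `percent_changes`, `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$spec$n_per_group < 4)
    warning("fewer than 4 animals per group: statistics are low-powered")
  cohort <- sim_cohort(cfg$spec)
  rows <- lapply(cohort$animals, analyze_animal, cfg = cfg)
  animals <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))

  endpoints <- setdiff(names(animals), c("id", "group"))
  groups <- do.call(rbind, lapply(endpoints, function(ep) {
    v <- animals[[ep]]
    g <- animals$group
    a <- one_way_anova(v, g)
    snk <- snk_posthoc(v, g, anova = a, alpha = cfg$alpha)
    sig <- function(g1, g2) {
      hit <- (snk$group1 == g1 & snk$group2 == g2) |
             (snk$group1 == g2 & snk$group2 == g1)
      any(snk$significant[hit])
    }
    data.frame(
      endpoint = ep,
      C_mean = a$group_means[["C"]], C_sem = a$group_sem[["C"]],
      F_mean = a$group_means[["F"]], F_sem = a$group_sem[["F"]],
      FT_mean = a$group_means[["FT"]], FT_sem = a$group_sem[["FT"]],
      f = a$f, p_value = a$p_value,
      F_vs_C = sig("F", "C"), FT_vs_C = sig("FT", "C"),
      FT_vs_F = sig("FT", "F"))
  }))
  report <- structure(list(animals = animals, groups = groups,
                           config = cfg), class = "study_report")
  report$percent_changes <- abstract_summary(report)
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Abstract-style percent-change summary
#'
#' Signed FT-versus-F percent changes for the headline endpoints, under
#' both denominator conventions plus the `auto` convention (decreases
#' on the sedentary-fructose reference, increases on the trained
#' value).
#'
#' @param report a `study_report`, or a data frame with columns
#'   `endpoint`, `F_mean`, `FT_mean`.
#' @param endpoints endpoints to summarise (defaults to the headline
#'   set).
#' @return Data frame: `endpoint`, `F_mean`, `FT_mean`, `pct_ref`,
#'   `pct_value`, `pct_auto`.
#' @export
abstract_summary <- function(report,
                             endpoints = c("wat", "triglycerides", "sap",
                                           "htw_bw", "vv_cf_lv",
                                           "vv_cf_ao", "nv_cap", "nv_gr",
                                           "el_number", "imt", "cwt")) {
  tab <- if (inherits(report, "study_report")) report$groups else report
  if (!all(c("endpoint", "F_mean", "FT_mean") %in% names(tab)))
    stop("need columns endpoint, F_mean, FT_mean")
  tab <- tab[tab$endpoint %in% endpoints, ]
  if (!nrow(tab)) stop("none of the requested endpoints present")
  data.frame(
    endpoint = tab$endpoint,
    F_mean = tab$F_mean, FT_mean = tab$FT_mean,
    pct_ref = mapply(percent_change, tab$F_mean, tab$FT_mean,
                     MoreArgs = list(denominator = "reference")),
    pct_value = mapply(percent_change, tab$F_mean, tab$FT_mean,
                       MoreArgs = list(denominator = "value")),
    pct_auto = mapply(percent_change, tab$F_mean, tab$FT_mean,
                      MoreArgs = list(denominator = "auto")))
}

write_report <- function(report, out_dir) {
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  write.csv(report$animals, file.path(out_dir, "tables", "animals.csv"),
            row.names = FALSE)
  write.csv(report$groups, file.path(out_dir, "tables", "groups.csv"),
            row.names = FALSE)
  write.csv(report$percent_changes,
            file.path(out_dir, "tables", "percent_changes.csv"),
            row.names = FALSE)
  g <- report$groups
  lines <- c(
    "# In-silico study report", "",
    sprintf("Cohort: %d animals/group, seed %s.",
            report$config$spec$n_per_group,
            format(report$config$spec$seed)),
    "", "| endpoint | C | F | FT | flags |", "|---|---|---|---|---|",
    sprintf("| %s | %.3g +/- %.2g | %.3g +/- %.2g | %.3g +/- %.2g | %s%s%s |",
            g$endpoint, g$C_mean, g$C_sem, g$F_mean, g$F_sem,
            g$FT_mean, g$FT_sem,
            ifelse(g$F_vs_C, "F*", ""), ifelse(g$FT_vs_C, " FT*", ""),
            ifelse(g$FT_vs_F, " FT+", "")),
    "", "## Percent changes (FT vs F)", "",
    sprintf("- %s: %+.0f%%", report$percent_changes$endpoint,
            report$percent_changes$pct_auto))
  writeLines(lines, file.path(out_dir, "summary.md"))
  cfg <- report$config
  writeLines(c(
    sprintf("n_per_group: %d", cfg$spec$n_per_group),
    sprintf("seed: %s", format(cfg$spec$seed)),
    sprintf("duration_s: %g  fs: %g", cfg$spec$duration_s, cfg$spec$fs),
    sprintf("segment_length: %d  overlap: %g", cfg$segment_length,
            cfg$overlap),
    sprintf("bands: LF %g-%g Hz, HF %g-%g Hz", cfg$bands$lf[1],
            cfg$bands$lf[2], cfg$bands$hf[1], cfg$bands$hf[2]),
    sprintf("points: atrium %d, LV %d, aorta %d", cfg$n_points_atrium,
            cfg$n_points_lv, cfg$n_points_aorta),
    sprintf("alpha: %g", cfg$alpha)),
    file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d animals, %d endpoints\n",
              nrow(x$animals), nrow(x$groups)))
  print(utils::head(x$groups[, c("endpoint", "C_mean", "F_mean",
                                 "FT_mean", "p_value")], 12))
  invisible(x)
}
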