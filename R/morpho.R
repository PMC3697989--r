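#' Overlay a stereological point grid on a field
#'
#' Systematic uniform random sampling: a near-square regular lattice of
#' exactly `n_points` positions with a single seeded uniform random
#' offset, the standard unbiased design for point-counting stereology.
#' The classic test systems in cardiac/vascular work use 82 points
#' (atrial electron micrographs), 140 (left-ventricle EM) and 200
#' (aorta histology).
#'
#' @param field integer label mask (matrix; 0 = background).
#' @param n_points number of test points (>= 4, at most the pixel
#'   count).
#' @param seed integer seed for the lattice offset.
#' @return A list of class `point_grid`: `n_points`, `x`, `y` (pixel
#'   coordinates), `labels` (label hit by each point).
#' @export
overlay_grid <- function(field, n_points, seed = NULL) {
  stopifnot(is.matrix(field), n_points >= 4)
  h <- nrow(field)
  w <- ncol(field)
  if (n_points > h * w) stop("more test points than pixels")
  with_seed(seed, {
    nx <- max(1L, round(sqrt(n_points * w / h)))
    ny <- ceiling(n_points / nx)
    dx <- w / nx
    dy <- h / ny
    xs <- runif(1, 0, dx) + (seq_len(nx) - 1) * dx
    ys <- runif(1, 0, dy) + (seq_len(ny) - 1) * dy
    g <- expand.grid(x = xs, y = ys)[seq_len(n_points), ]
    px <- pmin(pmax(ceiling(g$x), 1L), w)
    py <- pmin(pmax(ceiling(g$y), 1L), h)
    structure(list(n_points = n_points, x = g$x, y = g$y,
                   labels = field[cbind(py, px)]),
              class = "point_grid")
  })
}

#' Volume density by point counting
#'
#' `Vv = 100 * PP / PT` percent, where PP is the number of test points
#' hitting the structure and PT the total test points.
#'
#' @param x a `point_grid` from [overlay_grid()], or a hit count PP.
#' @param label structure label to count (when `x` is a grid).
#' @param total total test points PT (when `x` is a count).
#' @return Volume density, percent.
#' @export
volume_density <- function(x, label = NULL, total = NULL) {
  if (inherits(x, "point_grid")) {
    if (is.null(label)) stop("`label` is required with a point grid")
    return(100 * sum(x$labels == label) / x$n_points)
  }
  if (is.null(total) || total <= 0) stop("`total` test points must be > 0")
  if (x < 0 || x > total) stop("hits must lie in [0, total]")
  100 * x / total
}

#' Numerical density of profiles
#'
#' Object count per unit of reference space (area or volume), averaged
#' across fields when vectors are supplied.
#'
#' @param count object counts, one per field.
#' @param reference reference area/volume per field (> 0; recycled).
#' @param unit unit tag carried through to the result.
#' @return List: `density` (mean across fields), `per_field`, `unit`.
#' @export
numerical_density <- function(count, reference, unit = "mm^-2") {
  if (any(reference <= 0)) stop("reference area/volume must be > 0")
  if (any(count < 0)) stop("counts must be non-negative")
  per_field <- count / reference
  list(density = mean(per_field), per_field = per_field, unit = unit)
}

#' ANP granule morphometry over electron-micrograph fields
#'
#' Counts secretory granules per field by connected-component
#' labelling, measures each profile's area and equivalent-circle
#' diameter (`2 * sqrt(area / pi)`, apt for near-circular EM
#' profiles), and estimates the granule volume density with an 82-point
#' grid per field.
#'
#' @param fields list of integer masks (granule pixels carry
#'   `granule_label`).
#' @param granule_label label value of granules in the masks.
#' @param px_size_nm pixel edge length in nanometres.
#' @param n_points test points per field for Vv.
#' @param seed integer seed for the grids.
#' @return A list of class `granule_stats`: `granules_per_field` (mean
#'   count), `counts`, `areas_nm2` (all granules), `mean_area_nm2`,
#'   `diameters_nm`, `vv_percent`, `n_fields`.
#' @export
granule_stats <- function(fields, granule_label = 1, px_size_nm = 10,
                          n_points = 82, seed = NULL) {
  if (!length(fields)) stop("need at least one field")
  with_seed(seed, {
    counts <- integer(length(fields))
    areas <- numeric(0)
    vv <- numeric(length(fields))
    for (i in seq_along(fields)) {
      m <- fields[[i]]
      lab <- EBImage::bwlabel(m == granule_label)
      counts[i] <- max(lab)
      if (counts[i] > 0)
        areas <- c(areas, tabulate(as.integer(lab)) * px_size_nm^2)
      g <- overlay_grid(m, n_points)
      vv[i] <- volume_density(g, granule_label)
    }
    structure(list(
      granules_per_field = mean(counts), counts = counts,
      areas_nm2 = areas,
      mean_area_nm2 = if (length(areas)) mean(areas) else NaN,
      diameters_nm = 2 * sqrt(areas / pi),
      vv_percent = mean(vv), n_fields = length(fields)
    ), class = "granule_stats")
  })
}

#' Lumen diameter from lumen area
#'
#' `d = 2 * sqrt(a / pi)`: the diameter of the circle with the traced
#' lumen area.
#'
#' @param a lumen area, mm^2 (>= 0, vectorised).
#' @return Lumen diameter, mm.
#' @export
lumen_diameter <- function(a) {
  if (any(a < 0)) stop("lumen area must be non-negative")
  2 * sqrt(a / pi)
}

#' Intima-media thickness and cross-sectional area
#'
#' IMT is the arithmetic mean of the four radial wall measures taken at
#' 0, 90, 180 and 270 degrees.  The intima-media area is the annulus
#' `IMA = pi (d/2 + IMT)^2 - pi (d/2)^2`, corrected for fixation
#' shrinkage by the factor 1.28.
#'
#' @param thickness_um wall thickness measures, micrometres (typically
#'   4 values, all > 0).
#' @param d_mm lumen diameter, mm.
#' @param shrinkage multiplicative shrinkage correction for IMA.
#' @return List: `imt_um`, `ima_raw_mm2`, `ima_mm2` (corrected),
#'   `shrinkage`.
#' @export
intima_media <- function(thickness_um, d_mm, shrinkage = 1.28) {
  stopifnot(length(thickness_um) >= 1, all(thickness_um > 0), d_mm >= 0)
  imt_um <- mean(thickness_um)
  imt_mm <- imt_um / 1000
  if (d_mm > 0 && imt_mm >= d_mm)
    stop("IMT exceeds the lumen diameter: check units (um vs mm)")
  ima_raw <- pi * ((d_mm / 2 + imt_mm)^2 - (d_mm / 2)^2)
  list(imt_um = imt_um, ima_raw_mm2 = ima_raw,
       ima_mm2 = shrinkage * ima_raw, shrinkage = shrinkage)
}

#' Count elastic lamellae in an aortic ring mask
#'
#' Walks `n_rays` radial profiles from the ring centre, median-smooths
#' each binary lamellae profile to suppress isolated noise pixels, and
#' counts the rising band crossings; the reported count is the median
#' over rays, rounded to the nearest integer — robust to local staining
#' noise and small wall defects.
#'
#' @param mask integer ring mask (see [sim_aorta_ring()]).
#' @param lamellae_label label value of the elastic lamellae.
#' @param n_rays number of radial profiles.
#' @return List: `count` (integer), `per_ray` counts.
#' @export
count_lamellae <- function(mask, lamellae_label = 2, n_rays = 36) {
  stopifnot(is.matrix(mask), n_rays >= 4)
  if (!any(mask == lamellae_label)) stop("no lamellae label found in mask")
  h <- nrow(mask)
  w <- ncol(mask)
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  rmax <- floor(min(h, w) / 2) - 1L
  per_ray <- integer(n_rays)
  for (j in seq_len(n_rays)) {
    th <- 2 * pi * (j - 1) / n_rays
    rr <- seq_len(rmax)
    px <- round(cx + rr * cos(th))
    py <- round(cy + rr * sin(th))
    ok <- px >= 1 & px <= w & py >= 1 & py <= h
    prof <- as.numeric(mask[cbind(py[ok], px[ok])] == lamellae_label)
    if (length(prof) >= 3) prof <- runmed(prof, 3)
    per_ray[j] <- sum(diff(c(0, prof)) == 1)
  }
  list(count = as.integer(round(median(per_ray))), per_ray = per_ray)
}

#' Circumferential wall tension (Laplace's law)
#'
#' `CWT = MSAP * d / 2`.  The primary value is in mmHg·mm (the scale on
#' which rat aorta tables are comparable); the dyne/cm conversion
#' (1 mmHg = 1333.22 dyne/cm^2, 1 mm = 0.1 cm) is also returned.
#'
#' @param msap_mmHg mean systolic arterial pressure, mmHg (>= 0).
#' @param d_mm lumen diameter, mm (>= 0).
#' @return List: `cwt_mmHg_mm`, `cwt_dyne_cm`.
#' @export
wall_tension <- function(msap_mmHg, d_mm) {
  if (any(msap_mmHg < 0) || any(d_mm < 0))
    stop("pressure and diameter must be non-negative")
  cwt <- msap_mmHg * d_mm / 2
  list(cwt_mmHg_mm = cwt, cwt_dyne_cm = cwt * 1333.22 / 10)
}

#' Signed percent change between two group values
#'
#' `100 * (value - reference) / denominator`.  The denominator is the
#' reference value, the comparison value, or `"auto"`: decreases are
#' expressed on the reference and increases on the comparison value —
#' the convention under which abstract-style percent summaries of
#' trained-versus-sedentary contrasts are internally consistent.
#'
#' @param reference reference group value (e.g. sedentary fructose).
#' @param value comparison group value (e.g. trained).
#' @param denominator `"reference"`, `"value"` or `"auto"`.
#' @return Signed percent change.
#' @export
percent_change <- function(reference, value,
                           denominator = c("auto", "reference", "value")) {
  denominator <- match.arg(denominator)
  den <- switch(denominator,
    reference = reference,
    value = value,
    auto = if (value < reference) reference else value)
  if (den == 0) stop("zero denominator")
  100 * (value - reference) / den
}
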