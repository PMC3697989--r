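# disk pixel offsets for stamping round structures (fractional radii ok)
disk_offsets <- function(r) {
  d <- seq(-ceiling(r), ceiling(r))
  g <- expand.grid(dy = d, dx = d)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

#' Simulate a labelled tissue field
#'
#' Builds an integer-labelled mask (0 = background) emulating a
#' calibrated micrograph: each requested structure label is laid down as
#' non-overlapping random disks until its target area fraction is
#' reached, and an optional population of discrete objects (capillary
#' profiles, granules) is placed at a requested density.  Achieved
#' fractions and object counts are recorded as ground truth; by
#' construction the achieved fraction is within one disk (well under
#' 1 %) of the request.
#'
#' @param width,height field size in pixels.
#' @param fractions named numeric vector of target area fractions (%)
#'   per structure label; must sum to <= 100.
#' @param object_density objects per mm^2 for a discrete `object` label
#'   appended after the fraction labels (NULL to skip).
#' @param object_radius_px disk radius in pixels for all structures.
#' @param px_per_um pixel calibration (pixels per micrometre).
#' @param seed integer seed.
#' @return Integer matrix mask (labels 1..k in the order of
#'   `fractions`, then the object label), with `attr(,"truth")`:
#'   `labels`, `achieved_fractions` (%), `n_objects`, `object_label`,
#'   `area_mm2`, `px_per_um`.
#' @export
sim_tissue_field <- function(width = 500, height = 500,
                             fractions = c(structure = 50),
                             object_density = NULL,
                             object_radius_px = 8, px_per_um = 1,
                             seed = NULL) {
  stopifnot(width >= 32, height >= 32, px_per_um > 0,
            object_radius_px >= 1)
  if (any(fractions < 0) || sum(fractions) > 100)
    stop("label fractions must be non-negative and sum to <= 100")
  area_mm2 <- width * height / (px_per_um * 1000)^2
  n_obj <- 0L
  if (!is.null(object_density)) {
    stopifnot(object_density >= 0)
    n_obj <- round(object_density * area_mm2)
  }
  off <- disk_offsets(object_radius_px)
  disk_px <- nrow(off)
  budget <- sum(fractions) / 100 * width * height + n_obj * disk_px
  if (budget > 0.7 * width * height)
    stop("impossible packing: requested structures exceed 70% of the field")

  with_seed(seed, {
    mask <- matrix(0L, nrow = height, ncol = width)
    # partial stamps are fine for area fractions: only background is painted
    stamp_fraction <- function(value) {
      cy <- sample.int(height, 1)
      cx <- sample.int(width, 1)
      yy <- cy + off$dy
      xx <- cx + off$dx
      ok <- yy >= 1 & yy <= height & xx >= 1 & xx <= width
      idx <- cbind(yy[ok], xx[ok])
      idx <- idx[mask[idx] == 0L, , drop = FALSE]
      mask[idx] <<- value
      nrow(idx)
    }
    # objects need full disks with 1 px clearance so they stay countable
    clear <- disk_offsets(object_radius_px + 1)
    place_object <- function(value) {
      m <- as.integer(ceiling(object_radius_px)) + 1L
      cy <- sample.int(height - 2L * m, 1) + m
      cx <- sample.int(width - 2L * m, 1) + m
      if (any(mask[cbind(cy + clear$dy, cx + clear$dx)] != 0L))
        return(FALSE)
      mask[cbind(cy + off$dy, cx + off$dx)] <<- value
      TRUE
    }
    labels <- names(fractions)
    if (is.null(labels)) labels <- paste0("label", seq_along(fractions))
    achieved <- numeric(0)
    for (i in seq_along(fractions)) {
      target <- fractions[i] / 100 * width * height
      placed <- 0
      tries <- 0
      max_tries <- 100 * ceiling(target / max(disk_px, 1)) + 100
      while (placed < target && tries < max_tries) {
        placed <- placed + stamp_fraction(i)
        tries <- tries + 1
      }
      if (placed < target * 0.98)
        stop(sprintf("could not pack label '%s' to %g%%",
                     labels[i], fractions[i]))
      achieved[labels[i]] <- 100 * placed / (width * height)
    }
    object_label <- NA_integer_
    if (n_obj > 0L) {
      object_label <- length(fractions) + 1L
      labels <- c(labels, "object")
      placed_obj <- 0L
      tries <- 0
      while (placed_obj < n_obj && tries < 500 * n_obj + 500) {
        if (place_object(object_label)) placed_obj <- placed_obj + 1L
        tries <- tries + 1
      }
      if (placed_obj < n_obj)
        stop("impossible packing: object density too high for object size")
      achieved["object"] <- 100 * sum(mask == object_label) /
        (width * height)
    }
    attr(mask, "truth") <- list(
      labels = labels, achieved_fractions = achieved,
      n_objects = n_obj, object_label = object_label,
      area_mm2 = area_mm2, px_per_um = px_per_um)
    mask
  })
}

#' Simulate an aortic ring section
#'
#' Annular mask of an aortic cross-section: label 1 is the media
#' (smooth muscle), label 2 marks `n_lamellae` concentric elastic
#' lamellae evenly spaced through the wall, and label 3 is collagen
#' scattered through the media at a requested fraction.  Optional
#' salt-and-pepper noise reassigns a fraction of wall pixels to random
#' labels, emulating staining artefacts.
#'
#' @param lumen_d_mm lumen diameter, mm.
#' @param imt_um intima-media (wall) thickness, micrometres.
#' @param n_lamellae number of elastic lamellae (>= 1).
#' @param collagen_fraction collagen percentage of the media.
#' @param px_per_um pixel calibration (pixels per micrometre).
#' @param noise_prob per-pixel probability of label corruption in the
#'   wall.
#' @param seed integer seed.
#' @return Integer matrix mask with `attr(,"truth")`: geometry, label
#'   codes and lamellae radii (pixels).
#' @export
sim_aorta_ring <- function(lumen_d_mm = 0.95, imt_um = 158,
                           n_lamellae = 13, collagen_fraction = 0,
                           px_per_um = 1, noise_prob = 0, seed = NULL) {
  stopifnot(lumen_d_mm > 0, imt_um > 0, n_lamellae >= 1,
            collagen_fraction >= 0, collagen_fraction <= 100,
            px_per_um > 0, noise_prob >= 0, noise_prob < 1)
  if (imt_um >= lumen_d_mm * 500)
    stop("wall thicker than the lumen radius: check units (IMT in um, d in mm)")
  rl <- lumen_d_mm / 2 * 1000 * px_per_um      # lumen radius, px
  wt <- imt_um * px_per_um                     # wall thickness, px
  band <- max(2, floor(wt / n_lamellae / 3))   # lamella thickness, px
  spacing <- wt / n_lamellae
  if (spacing < band + 2)
    stop(sprintf("%d lamellae do not fit in a %g um wall at %g px/um",
                 n_lamellae, imt_um, px_per_um))
  with_seed(seed, {
    size <- ceiling(2 * (rl + wt) + 20)
    ctr <- (size + 1) / 2
    r <- sqrt(outer((seq_len(size) - ctr)^2,
                    (seq_len(size) - ctr)^2, "+"))
    mask <- matrix(0L, size, size)
    wall <- r >= rl & r < rl + wt
    mask[wall] <- 1L
    centers <- rl + wt * (seq_len(n_lamellae) - 0.5) / n_lamellae
    for (rc in centers) mask[abs(r - rc) < band / 2] <- 2L
    if (collagen_fraction > 0) {
      media <- which(mask == 1L)
      n_cf <- round(collagen_fraction / 100 * sum(wall))
      mask[sample(media, min(n_cf, length(media)))] <- 3L
    }
    if (noise_prob > 0) {
      widx <- which(wall)
      hit <- widx[runif(length(widx)) < noise_prob]
      mask[hit] <- sample(0:2, length(hit), replace = TRUE)
    }
    attr(mask, "truth") <- list(
      lumen_d_mm = lumen_d_mm, imt_um = imt_um,
      n_lamellae = n_lamellae, collagen_fraction = collagen_fraction,
      px_per_um = px_per_um, lamellae_radii_px = centers,
      labels = c(media = 1L, lamellae = 2L, collagen = 3L))
    mask
  })
}
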