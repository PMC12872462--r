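#' Two-channel ratiometric image container
#'
#' Holds the two emission-channel intensity matrices of a ratiometric dye
#' image (Em1 ~ 580 nm, Em2 ~ 650 nm for SNARF-4F) plus an optional integer
#' label mask (0 = dilute/background, k >= 1 = dense feature k).
#'
#' @param em1,em2 numeric matrices of identical shape, intensities >= 0.
#' @param mask optional integer matrix of the same shape.
#' @return object of class `two_channel_image`.
#' @export
two_channel_image <- function(em1, em2, mask = NULL) {
  stopifnot(is.matrix(em1), is.matrix(em2), all(dim(em1) == dim(em2)))
  if (any(em1 < 0) || any(em2 < 0)) stop("intensities must be >= 0")
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(em1)))
    mask <- matrix(as.integer(round(mask)), nrow(mask), ncol(mask))
    if (any(mask < 0)) stop("mask labels must be >= 0")
  }
  structure(list(em1 = em1, em2 = em2, mask = mask),
            class = "two_channel_image")
}

#' Ratiometric dye calibration from endpoint images
#'
#' Builds the ratio-to-pH calibration from reference images taken at the
#' acid and base endpoint pH: the endpoint emission ratios are ratios of
#' channel means, and `F_ratio` is the Em2 brightness ratio between the
#' acid and base forms, as in the dye supplier's ratiometric equation.
#'
#' @param acid_img,base_img [two_channel_image()]s acquired at `ph_acid`
#'   and `ph_base`.
#' @param pKa dye pKa (default 6.4, the SNARF-4F vendor value).
#' @param ph_acid,ph_base calibration endpoint pH values.
#' @return object of class `snarf_calibration` with fields `R_acid`,
#'   `R_base`, `F_ratio`, `pKa`, `ph_acid`, `ph_base`.
#' @export
snarf_calibrate <- function(acid_img, base_img, pKa = 6.4,
                            ph_acid = 3.5, ph_base = 9.0) {
  stopifnot(inherits(acid_img, "two_channel_image"),
            inherits(base_img, "two_channel_image"),
            ph_acid < ph_base)
  m2a <- mean(acid_img$em2); m2b <- mean(base_img$em2)
  if (m2a == 0 || m2b == 0) stop("zero-mean Em2 reference image")
  R_acid <- mean(acid_img$em1) / m2a
  R_base <- mean(base_img$em1) / m2b
  if (R_acid == R_base)
    stop("degenerate calibration: identical endpoint ratios")
  snarf_calibration(R_acid, R_base, F_ratio = m2a / m2b, pKa = pKa,
                    ph_acid = ph_acid, ph_base = ph_base)
}

#' @rdname snarf_calibrate
#' @param R_acid,R_base endpoint emission ratios Em1/Em2.
#' @param F_ratio Em2 brightness ratio acid/base.
#' @export
snarf_calibration <- function(R_acid, R_base, F_ratio, pKa = 6.4,
                              ph_acid = 3.5, ph_base = 9.0) {
  stopifnot(R_acid != R_base, F_ratio > 0, ph_acid < ph_base)
  structure(list(R_acid = R_acid, R_base = R_base, F_ratio = F_ratio,
                 pKa = pKa, ph_acid = ph_acid, ph_base = ph_base),
            class = "snarf_calibration")
}

#' @export
print.snarf_calibration <- function(x, ...) {
  cat(sprintf("snarf_calibration: R_acid = %.4f (pH %.1f), R_base = %.4f (pH %.1f), F = %.4f, pKa = %.2f\n",
              x$R_acid, x$ph_acid, x$R_base, x$ph_base, x$F_ratio, x$pKa))
  invisible(x)
}

#' Convert an emission ratio to pH (and back)
#'
#' The ratiometric equation
#' `pH = pKa + log10((R - R_acid) / (R_base - R) * F_ratio)` is strictly
#' monotone in `R` between the endpoint ratios. Values outside the
#' calibrated range `[ph_acid, ph_base]` are clamped and flagged via the
#' `"clamped"` attribute rather than extrapolated, since the calibration is
#' defined only between its endpoints. `ph_to_ratio()` is the exact
#' inverse, used for forward simulation.
#'
#' @param R emission ratio(s) Em1/Em2.
#' @param cal a [snarf_calibration()].
#' @return pH value(s) with a logical `"clamped"` attribute.
#' @export
ratio_to_ph <- function(R, cal) {
  stopifnot(inherits(cal, "snarf_calibration"))
  if (any(!is.finite(R))) stop("non-finite ratio")
  arg <- (R - cal$R_acid) / (cal$R_base - R) * cal$F_ratio
  ph <- ifelse(arg > 0, cal$pKa + log10(arg),
               # beyond an endpoint: assign the endpoint the ratio overshot
               ifelse(abs(R - cal$R_acid) < abs(R - cal$R_base),
                      cal$ph_acid, cal$ph_base))
  clamped <- ph < cal$ph_acid | ph > cal$ph_base | arg <= 0
  ph <- pmin(pmax(ph, cal$ph_acid), cal$ph_base)
  attr(ph, "clamped") <- clamped
  ph
}

#' @rdname ratio_to_ph
#' @param ph pH value(s).
#' @export
ph_to_ratio <- function(ph, cal) {
  stopifnot(inherits(cal, "snarf_calibration"))
  t <- 10^(ph - cal$pKa) / cal$F_ratio
  (cal$R_acid + t * cal$R_base) / (1 + t)
}

#' Per-feature and dilute-phase pH from a labelled two-channel image
#'
#' For every labelled dense-phase feature, averages Em1 and Em2 over the
#' feature's pixels, forms the ratio of means (not the mean of ratios,
#' matching the averaging order of the imaging readout) and converts it to
#' pH; the dilute-phase pH comes from the pooled background (label 0)
#' pixels. Features smaller than `min_pixels` are skipped with a warning.
#'
#' @param image a [two_channel_image()] with a label mask.
#' @param cal a [snarf_calibration()].
#' @param min_pixels minimum feature size in pixels (default 5).
#' @return list with `features` (data frame: feature_id, n_pixels,
#'   em1_mean, em2_mean, ratio, ph, clamped_flag) and `dilute` (one-row
#'   data frame for the background).
#' @export
feature_ph <- function(image, cal, min_pixels = 5L) {
  stopifnot(inherits(image, "two_channel_image"))
  if (is.null(image$mask)) stop("image has no label mask")
  m <- image$mask
  if (!any(m == 0)) stop("empty background: no label-0 pixels")
  labels <- sort(setdiff(unique(as.vector(m)), 0L))
  rows <- lapply(labels, function(k) {
    idx <- m == k
    np <- sum(idx)
    if (np < min_pixels) {
      warning("feature ", k, " has ", np, " pixel(s) < min_pixels; skipped")
      return(NULL)
    }
    e1 <- mean(image$em1[idx]); e2 <- mean(image$em2[idx])
    r <- e1 / e2
    ph <- ratio_to_ph(r, cal)
    data.frame(feature_id = k, n_pixels = np, em1_mean = e1, em2_mean = e2,
               ratio = r, ph = as.numeric(ph),
               clamped_flag = attr(ph, "clamped"))
  })
  bg <- m == 0
  e1 <- mean(image$em1[bg]); e2 <- mean(image$em2[bg])
  r <- e1 / e2
  ph <- ratio_to_ph(r, cal)
  dilute <- data.frame(feature_id = 0L, n_pixels = sum(bg), em1_mean = e1,
                       em2_mean = e2, ratio = r, ph = as.numeric(ph),
                       clamped_flag = attr(ph, "clamped"))
  feats <- do.call(rbind, rows)
  if (is.null(feats))
    feats <- dilute[0, , drop = FALSE]
  list(features = feats, dilute = dilute)
}

#' TIFF input/output for two-channel images and masks
#'
#' Channel order on disk: Em1 (~580 nm) first, Em2 (~650 nm) second.
#' Intensities are stored as 32-bit floats; masks as integer-valued floats.
#'
#' @param image a [two_channel_image()].
#' @param path base path; channels go to one multi-slice TIFF and the mask
#'   (if any) to `<path>_mask.tiff`.
#' @export
write_two_channel_tiff <- function(image, path) {
  stopifnot(inherits(image, "two_channel_image"))
  sc <- max(image$em1, image$em2, 1)
  tiff::writeTIFF(list(image$em1 / sc, image$em2 / sc), path,
                  bits.per.sample = 32L)
  attr_path <- sub("\\.tiff?$", "", path)
  jsonlite::write_json(list(intensity_scale = sc),
                       paste0(attr_path, "_scale.json"), auto_unbox = TRUE)
  if (!is.null(image$mask))
    tiff::writeTIFF(image$mask / 65535, paste0(attr_path, "_mask.tiff"),
                    bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_two_channel_tiff
#' @export
read_two_channel_tiff <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(slices) >= 2)
  base <- sub("\\.tiff?$", "", path)
  sc <- 1
  scale_file <- paste0(base, "_scale.json")
  if (file.exists(scale_file))
    sc <- jsonlite::read_json(scale_file)$intensity_scale
  mask <- NULL
  mask_file <- paste0(base, "_mask.tiff")
  if (file.exists(mask_file)) {
    mraw <- tiff::readTIFF(mask_file)
    mask <- matrix(as.integer(round(mraw * 65535)), nrow(mraw), ncol(mraw))
  }
  two_channel_image(slices[[1]] * sc, slices[[2]] * sc, mask = mask)
}
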