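#' Ground truth for a synthetic droplet experiment
#'
#' Defines the generative model behind a combinatorial microdroplet scan:
#' a U-shaped saturation boundary `c_sat(pH) = c_min * exp(alpha * (pH -
#' pI)^2)` with its minimum at the pI, proton-partitioning tie-line tilts
#' prescribing the dilute-phase contour slopes on each arm (`k_low > 0`:
#' protons excluded from the dense phase at the low-pH boundary;
#' `k_high < 0`: protons taken up at the high-pH boundary), a dilute-phase
#' response gradient for dominance slabs, a classification flip
#' probability and a measurement noise scale. All generation is seeded.
#'
#' @param pI boundary minimum position in pH units.
#' @param c_min minimum saturation concentration (concentration units of
#'   the experiment, e.g. mg/ml).
#' @param alpha boundary curvature per (pH unit)^2.
#' @param k_low,k_high prescribed dilute-phase contour slopes
#'   (concentration per pH) on the low- and high-pH arms.
#' @param R_true dilute-phase response gradient for dominance slabs.
#' @param flip_prob probability of misclassifying a droplet, in `[0, 0.5)`.
#' @param noise_sd Gaussian noise s.d. on measured concentrations.
#' @param c_stock peptide stock concentration; `c_tot = c_stock *
#'   frac_peptide`.
#' @param seed integer RNG seed.
#' @return object of class `droplet_truth`.
#' @export
droplet_truth <- function(pI = 6.8, c_min = 0.5, alpha = 0.8,
                          k_low = 2, k_high = -2, R_true = 0.54,
                          flip_prob = 0, noise_sd = 0.02,
                          c_stock = 10, seed = 1L) {
  stopifnot(c_min > 0, alpha > 0, flip_prob >= 0, flip_prob < 0.5,
            noise_sd >= 0, c_stock > 0)
  structure(list(pI = pI, c_min = c_min, alpha = alpha,
                 k_low = k_low, k_high = k_high, R_true = R_true,
                 flip_prob = flip_prob, noise_sd = noise_sd,
                 c_stock = c_stock, seed = as.integer(seed)),
            class = "droplet_truth")
}

#' @rdname droplet_truth
#' @param ph pH value(s).
#' @param truth a `droplet_truth`.
#' @return `c_sat()` returns the boundary concentration at `ph`.
#' @export
c_sat <- function(truth, ph) truth$c_min * exp(truth$alpha * (ph - truth$pI)^2)

c_sat_slope <- function(truth, ph) {
  truth$c_min * 2 * truth$alpha * (ph - truth$pI) *
    exp(truth$alpha * (ph - truth$pI)^2)
}

# synthetic monotone buffer calibration: endpoint-normalized tanh over the
# H/S-like range 3.5-9
synthetic_buffer_calibration <- function(n_knots = 21, steep = 2.5) {
  f <- seq(0, 1, length.out = n_knots)
  g <- (tanh(steep * (f - 0.5)) / tanh(steep * 0.5) + 1) / 2
  buffer_calibration(f, 3.5 + 5.5 * g)
}

#' Generate a synthetic combinatorial droplet scan
#'
#' Draws stock fractions over the flow-scan range (buffer share fixed at
#' 0.5, split between low- and high-pH stocks; peptide share uniform),
#' derives the droplet pH from a synthetic monotone buffer calibration,
#' classifies each droplet against the ground-truth boundary (flipping
#' with the stated probability) and assigns dilute-phase concentrations
#' with a tie-line tilt: the effective boundary pH is offset in proportion
#' to the dense-phase excess, with the per-arm coefficient chosen so that
#' the dilute-phase contour slope equals the prescribed `k_low`/`k_high`.
#'
#' @param truth a [droplet_truth()].
#' @param n number of droplets.
#' @return droplet data frame (see [read_droplets_csv()] for the schema)
#'   with the truth record attached as attribute `"truth"`.
#' @export
synth_droplets <- function(truth, n) {
  stopifnot(inherits(truth, "droplet_truth"), n >= 1)
  set.seed(truth$seed)
  cal <- synthetic_buffer_calibration()
  u <- stats::runif(n)                       # high-pH share of the buffer
  frac_peptide <- stats::runif(n, 0.02, 0.5)
  frac_water <- 0.5 - frac_peptide
  frac_high <- 0.5 * u
  frac_low <- 0.5 * (1 - u)
  ph <- ph_from_fraction(cal, u)
  c_tot <- truth$c_stock * frac_peptide
  sat <- c_sat(truth, ph)
  ps_true <- c_tot > sat
  flip <- stats::runif(n) < truth$flip_prob
  phase_class <- as.integer(xor(ps_true, flip))
  # tie-line tilt: pH offset proportional to the dense-phase excess, with
  # the coefficient inverted from the target contour slope at a
  # representative arm pH (one unit off the pI)
  low_side <- ph < truth$pI
  s_low <- 1 / (c_sat_slope(truth, truth$pI - 1) - truth$k_low)
  s_high <- 1 / (c_sat_slope(truth, truth$pI + 1) - truth$k_high)
  s <- ifelse(low_side, s_low, s_high)
  ph_eff <- ph + s * pmax(c_tot - sat, 0)
  ph_eff <- pmin(pmax(ph_eff, min(cal$ph)), max(cal$ph))
  c_dil <- ifelse(ps_true, pmin(c_tot, c_sat(truth, ph_eff)), c_tot)
  c_dil <- c_dil + stats::rnorm(n, 0, truth$noise_sd)
  c_dil <- pmin(pmax(c_dil, 0), c_tot)
  out <- data.frame(droplet_id = sprintf("d%06d", seq_len(n)),
                    frac_peptide = frac_peptide, frac_water = frac_water,
                    frac_lowpH = frac_low, frac_highpH = frac_high,
                    phase_class = phase_class, c_tot = c_tot,
                    c_dil = c_dil, ph = ph)
  attr(out, "truth") <- truth
  out
}

#' Generate a dominance slab at fixed pH
#'
#' Phase-separated droplets in a narrow pH slab whose dilute-phase
#' concentration responds to the total concentration with the prescribed
#' gradient: `c_dil = R_true * c_tot + (1 - R_true) * c_sat(ph_centre) +
#' noise`, continuous with the boundary at `c_tot = c_sat`.
#'
#' @param truth a [droplet_truth()].
#' @param ph_centre slab centre.
#' @param n droplets in the slab.
#' @param ph_jitter half-width of the uniform pH jitter.
#' @param c_max largest total concentration sampled.
#' @return droplet data frame with attribute `"truth"`.
#' @export
synth_dominance_slab <- function(truth, ph_centre, n = 200,
                                 ph_jitter = 0.15, c_max = NULL) {
  stopifnot(inherits(truth, "droplet_truth"))
  set.seed(truth$seed + 1L)
  sat <- c_sat(truth, ph_centre)
  if (is.null(c_max)) c_max <- min(truth$c_stock / 2, 6 * sat)
  c_tot <- stats::runif(n, sat, c_max)
  ph <- ph_centre + stats::runif(n, -ph_jitter, ph_jitter)
  c_dil <- truth$R_true * c_tot + (1 - truth$R_true) * sat +
    stats::rnorm(n, 0, truth$noise_sd)
  c_dil <- pmin(pmax(c_dil, 0), c_tot)
  frac_peptide <- c_tot / truth$c_stock
  u <- (ph - 3.5) / 5.5
  out <- data.frame(droplet_id = sprintf("s%06d", seq_len(n)),
                    frac_peptide = frac_peptide,
                    frac_water = 0.5 - frac_peptide,
                    frac_lowpH = 0.5 * (1 - u), frac_highpH = 0.5 * u,
                    phase_class = 1L, c_tot = c_tot, c_dil = c_dil,
                    ph = ph)
  attr(out, "truth") <- truth
  out
}

#' Write a generated dataset with its machine-readable truth record
#'
#' @param droplets a generated droplet data frame (attribute `"truth"`).
#' @param path CSV path; the truth record goes to `<path
#'   sans .csv>_truth.json`.
#' @export
write_synth_droplets <- function(droplets, path) {
  write_droplets_csv(droplets, path)
  truth <- attr(droplets, "truth")
  jsonlite::write_json(unclass(truth),
                       paste0(sub("\\.csv$", "", path), "_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Ground truth for a synthetic two-channel ratiometric scene
#'
#' Disk-shaped dense-phase features at prescribed internal pH on a dilute
#' background at another pH, rendered through the inverse ratiometric
#' calibration: Em2 is a per-region brightness, Em1 is ratio times Em2,
#' and Gaussian noise is added to both channels.
#'
#' @param shape image dimensions `c(rows, cols)`.
#' @param centres two-column matrix of disk centres (row, col).
#' @param radii disk radii in pixels.
#' @param dense_ph pH inside each disk (recycled).
#' @param dilute_ph background pH.
#' @param cal a [snarf_calibration()].
#' @param brightness_dense,brightness_dilute Em2 levels.
#' @param noise_sd Gaussian channel noise s.d. (intensity units).
#' @param seed integer RNG seed.
#' @return object of class `snarf_scene_truth`.
#' @export
snarf_scene_truth <- function(shape = c(120, 120),
                              centres = rbind(c(40, 40), c(80, 85)),
                              radii = c(12, 9),
                              dense_ph = 6.0, dilute_ph = 7.3,
                              cal = snarf_calibration(1.6, 0.2, 4),
                              brightness_dense = 200,
                              brightness_dilute = 100,
                              noise_sd = 0, seed = 1L) {
  centres <- rbind(centres)
  stopifnot(nrow(centres) == length(radii) || length(radii) == 1)
  radii <- rep_len(radii, nrow(centres))
  dense_ph <- rep_len(dense_ph, nrow(centres))
  structure(list(shape = shape, centres = centres, radii = radii,
                 dense_ph = dense_ph, dilute_ph = dilute_ph, cal = cal,
                 brightness_dense = brightness_dense,
                 brightness_dilute = brightness_dilute,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "snarf_scene_truth")
}

#' Render a synthetic ratiometric scene
#'
#' @param truth a [snarf_scene_truth()].
#' @return a [two_channel_image()] with the exact label mask, and the
#'   truth record attached as attribute `"truth"`. Disks clipped by the
#'   frame edge trigger a warning.
#' @export
synth_snarf_scene <- function(truth) {
  stopifnot(inherits(truth, "snarf_scene_truth"))
  set.seed(truth$seed)
  nr <- truth$shape[1]; nc <- truth$shape[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- matrix(0L, nr, nc)
  ph_map <- matrix(truth$dilute_ph, nr, nc)
  dye <- matrix(truth$brightness_dilute, nr, nc)
  for (k in seq_len(nrow(truth$centres))) {
    cr <- truth$centres[k, 1]; cc <- truth$centres[k, 2]; r <- truth$radii[k]
    if (cr - r < 1 || cr + r > nr || cc - r < 1 || cc + r > nc)
      warning("disk ", k, " overlaps the frame edge; clipped")
    inside <- (rows - cr)^2 + (cols - cc)^2 <= r^2
    mask[inside] <- k
    ph_map[inside] <- truth$dense_ph[k]
    dye[inside] <- truth$brightness_dense
  }
  # two-state dye photophysics: Em2 brightness interpolates between the
  # base form (1) and the acid form (F_ratio) with the acid fraction, so
  # endpoint references and the ratio model are mutually consistent
  x_acid <- 1 / (1 + 10^(ph_map - truth$cal$pKa))
  em2 <- dye * (x_acid * truth$cal$F_ratio + (1 - x_acid))
  em1 <- ph_to_ratio(ph_map, truth$cal) * em2
  if (truth$noise_sd > 0) {
    em1 <- em1 + stats::rnorm(length(em1), 0, truth$noise_sd)
    em2 <- em2 + stats::rnorm(length(em2), 0, truth$noise_sd)
  }
  img <- two_channel_image(pmax(em1, 0), pmax(em2, 0), mask = mask)
  attr(img, "truth") <- truth
  img
}

#' @rdname synth_snarf_scene
#' @param cal a [snarf_calibration()].
#' @param form `"acid"` or `"base"`: which pure dye form to render.
#' @param shape image dimensions.
#' @param brightness dye amount (base-form Em2 level).
#' @return `synth_snarf_reference()` returns a pure-form endpoint
#'   reference image whose channel means reproduce the calibration's
#'   endpoint ratios exactly.
#' @export
synth_snarf_reference <- function(cal, form = c("acid", "base"),
                                  shape = c(64, 64), brightness = 100) {
  form <- match.arg(form)
  stopifnot(inherits(cal, "snarf_calibration"))
  em2_level <- if (form == "acid") brightness * cal$F_ratio else brightness
  ratio <- if (form == "acid") cal$R_acid else cal$R_base
  em2 <- matrix(em2_level, shape[1], shape[2])
  two_channel_image(ratio * em2, em2)
}

#' Composition-controlled synthetic proteome
#'
#' Draws labelled sequence classes (each a composition, length and count)
#' through the randomized-proteome machinery, with a per-class truth
#' record of the expected pI regime.
#'
#' @param classes list of lists with elements `composition` (named
#'   probability vector), `length`, `count` and optional `label`.
#' @param seed integer RNG seed.
#' @return a [proteome_set()]; attribute `"truth"` holds the per-class
#'   records (label, count, expected pI of an average-composition
#'   sequence).
#' @export
synth_proteome <- function(classes, seed) {
  stopifnot(is.list(classes), length(classes) >= 1)
  all_seqs <- list()
  records <- list()
  for (i in seq_along(classes)) {
    cl <- classes[[i]]
    stopifnot(!is.null(cl$composition), !is.null(cl$length),
              !is.null(cl$count), cl$count >= 1)
    label <- if (is.null(cl$label)) sprintf("class%d", i) else cl$label
    spec <- random_proteome_spec(cl$count, composition = cl$composition,
                                 length_model = cl$length,
                                 seed = seed + i)
    ps <- sample_proteome(spec)
    seqs <- ps$sequences
    for (j in seq_along(seqs)) seqs[[j]]$id <- sprintf("%s_%05d", label, j)
    names(seqs) <- vapply(seqs, `[[`, character(1), "id")
    all_seqs <- c(all_seqs, seqs)
    # expected pI regime from one representative composition-exact profile
    rep_pi <- tryCatch(
      isoelectric_point(seqs[[1]]), error = function(e) NA_real_)
    records[[i]] <- data.frame(label = label, count = cl$count,
                               length = cl$length, example_pi = rep_pi)
  }
  out <- proteome_set(all_seqs, source_label = sprintf("synth(seed=%d)", seed))
  attr(out, "truth") <- do.call(rbind, records)
  out
}
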