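#' Buffer-fraction to pH calibration
#'
#' Combinatorial droplet scans set the droplet pH through the volume
#' fraction of the high-pH buffer stock; a bench calibration of (fraction,
#' pH) pairs is interpolated piecewise-linearly to convert fractions to pH.
#' Both columns must be strictly increasing.
#'
#' @param fraction volume fractions of the high-pH stock, in `[0, 1]`.
#' @param ph measured pH at each fraction.
#' @return object of class `buffer_calibration`.
#' @export
buffer_calibration <- function(fraction, ph) {
  stopifnot(length(fraction) == length(ph), length(fraction) >= 2)
  if (any(fraction < 0 | fraction > 1)) stop("fractions must lie in [0, 1]")
  if (is.unsorted(fraction, strictly = TRUE))
    stop("fractions must be strictly increasing")
  if (is.unsorted(ph, strictly = TRUE))
    stop("pH must be strictly increasing with fraction")
  structure(list(fraction = fraction, ph = ph),
            class = "buffer_calibration")
}

#' @rdname buffer_calibration
#' @param cal a `buffer_calibration`.
#' @param f fraction(s) to convert.
#' @return `ph_from_fraction()` returns interpolated pH value(s).
#' @export
ph_from_fraction <- function(cal, f) {
  stopifnot(inherits(cal, "buffer_calibration"))
  if (any(f < 0 | f > 1)) stop("fraction outside [0, 1]")
  stats::approx(cal$fraction, cal$ph, xout = f, rule = 2)$y
}

#' Read/write droplet tables and calibrations as CSV
#'
#' The droplet schema carries one row per microdroplet: stock fractions
#' (peptide, water, low-pH buffer, high-pH buffer; summing to 1), optional
#' channel intensities, the binary phase class (0 mixed, 1 phase
#' separated), the total biomolecule concentration `c_tot`, optionally the
#' dilute-phase concentration `c_dil`, and the derived `ph`.
#'
#' @param path CSV file.
#' @return data frame of droplet records.
#' @export
read_droplets_csv <- function(path) {
  d <- utils::read.csv(path)
  validate_droplets(d)
  d
}

#' @rdname read_droplets_csv
#' @param droplets droplet data frame.
#' @export
write_droplets_csv <- function(droplets, path) {
  validate_droplets(droplets)
  utils::write.csv(droplets, path, row.names = FALSE)
  invisible(path)
}

validate_droplets <- function(d) {
  need <- c("droplet_id", "frac_peptide", "frac_water", "frac_lowpH",
            "frac_highpH", "phase_class", "c_tot")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("droplet table missing columns: ",
                         paste(miss, collapse = ", "))
  fr <- d$frac_peptide + d$frac_water + d$frac_lowpH + d$frac_highpH
  if (any(abs(fr - 1) > 1e-6)) stop("stock fractions must sum to 1")
  if (!all(d$phase_class %in% c(0, 1))) stop("phase_class must be 0/1")
  if ("c_dil" %in% names(d)) {
    bad <- !is.na(d$c_dil) & d$c_dil > d$c_tot + 1e-9
    if (any(bad)) stop("c_dil must not exceed c_tot")
  }
  invisible(TRUE)
}

#' Binned phase-fraction grid
#'
#' Bins droplets on a (pH, total concentration) grid and evaluates the
#' local fraction of phase-separated conditions `F_PS` as the per-bin mean
#' of the binary phase class. Binning is half-open `[left, right)` with the
#' last bin closed, so every in-range droplet is counted exactly once.
#' Bins with fewer than `min_count` droplets are masked (NA in `fps`).
#'
#' @param droplets droplet data frame with columns `ph`, `c_tot`,
#'   `phase_class`.
#' @param ph_edges,conc_edges ascending bin edges.
#' @param min_count minimum droplets per reported bin (default 3).
#' @return object of class `phase_grid` with `ph_edges`, `conc_edges`,
#'   `count` and `fps` matrices (rows = pH bins), and `n_outside`.
#' @export
bin_phase_fraction <- function(droplets, ph_edges, conc_edges,
                               min_count = 3L) {
  stopifnot(is.data.frame(droplets), "ph" %in% names(droplets))
  if (length(ph_edges) < 2 || length(conc_edges) < 2 ||
      is.unsorted(ph_edges, strictly = TRUE) ||
      is.unsorted(conc_edges, strictly = TRUE))
    stop("degenerate bin edges")
  ix <- findInterval(droplets$ph, ph_edges, rightmost.closed = TRUE)
  iy <- findInterval(droplets$c_tot, conc_edges, rightmost.closed = TRUE)
  nx <- length(ph_edges) - 1L
  ny <- length(conc_edges) - 1L
  inside <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  count <- matrix(0L, nx, ny)
  sums <- matrix(0, nx, ny)
  for (k in which(inside)) {
    count[ix[k], iy[k]] <- count[ix[k], iy[k]] + 1L
    sums[ix[k], iy[k]] <- sums[ix[k], iy[k]] + droplets$phase_class[k]
  }
  fps <- ifelse(count >= min_count, sums / pmax(count, 1L), NA_real_)
  structure(list(ph_edges = ph_edges, conc_edges = conc_edges,
                 count = count, fps = fps, min_count = min_count,
                 n_outside = sum(!inside)),
            class = "phase_grid")
}

#' @export
print.phase_grid <- function(x, ...) {
  cat(sprintf("phase_grid: %d x %d bins, %d droplets (%d outside), %d bins masked\n",
              nrow(x$count), ncol(x$count), sum(x$count) + x$n_outside,
              x$n_outside, sum(is.na(x$fps))))
  invisible(x)
}

#' @rdname bin_phase_fraction
#' @param grid a `phase_grid`.
#' @export
as.data.frame.phase_grid <- function(x, ...) {
  phc <- bin_centres(x$ph_edges)
  cc <- bin_centres(x$conc_edges)
  data.frame(ph_bin = rep(phc, times = length(cc)),
             conc_bin = rep(cc, each = length(phc)),
             count = as.vector(x$count),
             fps = as.vector(x$fps))
}

bin_centres <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' Phase-boundary contour from a phase grid
#'
#' Extracts the `F_PS = level` contour (default 0.5, the phase boundary)
#' from the binned grid by marching squares over bin centres; masked bins
#' are excluded. Coordinates are reported in (pH, concentration) space.
#'
#' @param grid a `phase_grid`.
#' @param level contour level, strictly inside (0, 1).
#' @return data frame with columns `contour`, `ph`, `conc` (empty, with a
#'   warning, if the grid does not cross the level).
#' @export
extract_boundary <- function(grid, level = 0.5) {
  stopifnot(inherits(grid, "phase_grid"))
  if (!(level > 0 && level < 1)) stop("level must lie strictly in (0, 1)")
  z <- grid$fps
  ok <- z[!is.na(z)]
  if (!length(ok) || !(any(ok < level) && any(ok > level))) {
    warning("F_PS does not cross the requested level; empty contour")
    return(data.frame(contour = integer(), ph = numeric(),
                      conc = numeric()))
  }
  cl <- grDevices::contourLines(x = bin_centres(grid$ph_edges),
                                y = bin_centres(grid$conc_edges),
                                z = z, levels = level)
  if (!length(cl)) {
    warning("no contour found at the requested level")
    return(data.frame(contour = integer(), ph = numeric(),
                      conc = numeric()))
  }
  do.call(rbind, lapply(seq_along(cl), function(i)
    data.frame(contour = i, ph = cl[[i]]$x, conc = cl[[i]]$y)))
}

#' Dilute-phase contour slope K
#'
#' Sections the phase-separated droplets whose dilute-phase concentration
#' falls in the window `a < c_dil < b` on one side of the boundary minimum
#' and fits the least-squares slope of `c_tot` against pH. Within the
#' window these droplets trace a contour of constant dilute-phase
#' concentration, whose slope bounds the tie-line direction: `K > 0` at
#' the low-pH arm means protons are excluded from the dense phase, `K < 0`
#' at the high-pH arm means they partition into it. The uncertainty is a
#' perturbation estimate: `n_perturb` refits after adding Gaussian noise at
#' the residual standard deviation to the response.
#'
#' @param droplets droplet data frame with `ph`, `c_tot`, `c_dil`,
#'   `phase_class`.
#' @param a,b dilute-phase concentration window, `a < b`.
#' @param side `"low_pH"` or `"high_pH"` relative to `ph_split`.
#' @param ph_split pH separating the two boundary arms (typically the pI).
#' @param n_perturb number of perturbation refits.
#' @param seed optional seed for the perturbation noise.
#' @return object of class `contour_slope` with `K`, `uncertainty`, `side`,
#'   `window`, `n`.
#' @export
section_dilute_contour <- function(droplets, a, b,
                                   side = c("low_pH", "high_pH"),
                                   ph_split, n_perturb = 200L,
                                   seed = NULL) {
  side <- match.arg(side)
  stopifnot(a < b, is.numeric(ph_split))
  sel <- droplets$phase_class == 1 & !is.na(droplets$c_dil) &
    droplets$c_dil > a & droplets$c_dil < b &
    (if (side == "low_pH") droplets$ph < ph_split
     else droplets$ph > ph_split)
  d <- droplets[sel, , drop = FALSE]
  if (nrow(d) < 3) stop("window too narrow: fewer than 3 droplets selected")
  fit <- stats::lm(c_tot ~ ph, data = d)
  K <- unname(stats::coef(fit)[["ph"]])
  sigma <- stats::sd(stats::residuals(fit))
  if (!is.null(seed)) set.seed(seed)
  Ks <- vapply(seq_len(n_perturb), function(i) {
    y <- d$c_tot + stats::rnorm(nrow(d), 0, sigma)
    unname(stats::lsfit(d$ph, y)$coefficients[2])
  }, numeric(1))
  structure(list(K = K, uncertainty = stats::sd(Ks), side = side,
                 window = c(a = a, b = b), n = nrow(d)),
            class = "contour_slope")
}

#' @export
print.contour_slope <- function(x, ...) {
  cat(sprintf("contour_slope (%s): K = %.4g +/- %.4g (n = %d, window %.3g-%.3g)\n",
              x$side, x$K, x$uncertainty, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' Energy dominance from the dilute-phase response gradient
#'
#' Within a pH slab, fits the ordinary least-squares slope `R` of the
#' dilute-phase concentration against the total concentration and derives
#' the dominance `D = 1 - R`: `D = 1` is pure one-component behaviour (the
#' dilute phase is pinned), `D = 0` means no phase separation response.
#' The error is the standard deviation of `D` over `n_perturb` refits with
#' Gaussian noise at the residual standard deviation added to `c_dil`.
#'
#' @param droplets droplet data frame with `ph`, `c_tot`, `c_dil`.
#' @param ph_centre slab centre in pH units.
#' @param ph_halfwidth slab half-width.
#' @param n_perturb number of perturbation refits (default 200).
#' @param seed optional seed for the perturbation noise.
#' @return object of class `dominance_fit` with `ph_centre`, `R`, `D`,
#'   `error`, `n`.
#' @export
dominance <- function(droplets, ph_centre, ph_halfwidth = 0.25,
                      n_perturb = 200L, seed = NULL) {
  sel <- !is.na(droplets$c_dil) &
    abs(droplets$ph - ph_centre) <= ph_halfwidth
  d <- droplets[sel, , drop = FALSE]
  if (nrow(d) < 4) stop("insufficient droplets in the pH slab")
  if (stats::sd(d$c_tot) == 0) stop("zero c_tot spread in the pH slab")
  fit <- stats::lm(c_dil ~ c_tot, data = d)
  R <- unname(stats::coef(fit)[["c_tot"]])
  sigma <- stats::sd(stats::residuals(fit))
  if (!is.null(seed)) set.seed(seed)
  Ds <- vapply(seq_len(n_perturb), function(i) {
    y <- d$c_dil + stats::rnorm(nrow(d), 0, sigma)
    1 - unname(stats::lsfit(d$c_tot, y)$coefficients[2])
  }, numeric(1))
  structure(list(ph_centre = ph_centre, R = R, D = 1 - R,
                 error = stats::sd(Ds), n = nrow(d)),
            class = "dominance_fit")
}

#' @export
print.dominance_fit <- function(x, ...) {
  cat(sprintf("dominance_fit @ pH %.2f: R = %.3f, D = %.3f +/- %.3f (n = %d)\n",
              x$ph_centre, x$R, x$D, x$error, x$n))
  invisible(x)
}
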