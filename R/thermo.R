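#' Parameters of the three-charge-state polymer model
#'
#' A minimal lattice model of pH-dependent phase separation: a polymer of
#' `N` monomers whose sites exchange protons with a buffered solvent and
#' can be positive, neutral or negative. Protonation is fast, so at proton
#' concentration `c_h` the state fractions follow from two constants,
#' `pKa_plus` (below which sites protonate to +) and `pKa_minus` (above
#' which they deprotonate to -); the model pI is their midpoint. The free
#' energy per lattice site combines ideal mixing entropies with a generic
#' attraction `0.5 * chi_f * phi_p^2` (`chi_f < 0` is attractive: making
#' `chi_f` more negative strengthens attraction) and a mean-field
#' electrostatic repulsion `lam * (z * phi_p)^2` proportional to the
#' squared charge density.
#'
#' @param N polymer chain length in monomers.
#' @param chi_f attraction parameter (kT per site; negative = attractive).
#' @param lam electrostatic repulsion coefficient (kT per squared charge
#'   density), `lam >= 0`.
#' @param pKa_plus,pKa_minus protonation constants, `pKa_plus < pKa_minus`;
#'   the model pI is `(pKa_plus + pKa_minus) / 2`.
#' @param site_molarity molar concentration of lattice sites at volume
#'   fraction 1 (default 55.5 M, the molarity of water).
#' @return object of class `thermo_params` (with derived field `pI`).
#' @export
thermo_params <- function(N = 100, chi_f = -2, lam = 10,
                          pKa_plus = 6, pKa_minus = 8,
                          site_molarity = 55.5) {
  stopifnot(N >= 1, lam >= 0, pKa_plus < pKa_minus, site_molarity > 0)
  structure(list(N = N, chi_f = chi_f, lam = lam,
                 pKa_plus = pKa_plus, pKa_minus = pKa_minus,
                 pI = (pKa_plus + pKa_minus) / 2,
                 site_molarity = site_molarity),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("thermo_params: N = %g, chi_f = %g, lam = %g, pKa +/- = %g/%g (pI %g)\n",
              x$N, x$chi_f, x$lam, x$pKa_plus, x$pKa_minus, x$pI))
  invisible(x)
}

#' Charge-state fractions at a proton concentration
#'
#' Fast acid-base equilibrium of the three states: with `h = c_h`,
#' `K+ = 10^-pKa_plus`, `K- = 10^-pKa_minus`, the unnormalized statistical
#' weights are `h/K+` (positive), 1 (neutral) and `K-/h` (negative). The
#' mean charge per monomer `z = f_plus - f_minus` is antisymmetric about
#' the pI on a log-proton axis and vanishes exactly at `pH = pI`.
#'
#' @param c_h proton concentration(s) in M, `> 0`.
#' @param params a [thermo_params()].
#' @return data frame with columns `c_h`, `f_plus`, `f_zero`, `f_minus`,
#'   `z`.
#' @export
state_fractions <- function(c_h, params = thermo_params()) {
  stopifnot(inherits(params, "thermo_params"))
  if (any(c_h <= 0)) stop("c_h must be positive")
  a <- c_h / 10^(-params$pKa_plus)
  b <- 10^(-params$pKa_minus) / c_h
  S <- 1 + a + b
  data.frame(c_h = c_h, f_plus = a / S, f_zero = 1 / S, f_minus = b / S,
             z = (a - b) / S)
}

# deriv3-generated free energy with gradient and Hessian in (phi_p, phi_h).
# Two charge-response conventions:
#  - "fluctuating": z is expanded algebraically in phi_h, so local proton
#    fluctuations re-equilibrate the polymer charge; symbolic derivatives
#    are exact through z(phi_h).
#  - "clamped": z is held at the value set by the buffered proton
#    reservoir while differentiating (the buffer clamps local pH
#    fluctuations); z enters the derivatives as a constant.
free_energy_expr_fluct <- quote(
  (phi_p / N) * log(phi_p) + phi_h * log(phi_h) +
    (1 - phi_p - phi_h) * log(1 - phi_p - phi_h) +
    0.5 * chi_f * phi_p^2 +
    lam * (((phi_h * M / Kp - Km / (phi_h * M)) /
              (1 + phi_h * M / Kp + Km / (phi_h * M))) * phi_p)^2
)

free_energy_fun_fluct <- stats::deriv3(
  free_energy_expr_fluct, c("phi_p", "phi_h"),
  function.arg = c("phi_p", "phi_h", "N", "chi_f", "lam", "Kp", "Km", "M"))

free_energy_expr_clamped <- quote(
  (phi_p / N) * log(phi_p) + phi_h * log(phi_h) +
    (1 - phi_p - phi_h) * log(1 - phi_p - phi_h) +
    0.5 * chi_f * phi_p^2 + lam * (z * phi_p)^2
)

free_energy_fun_clamped <- stats::deriv3(
  free_energy_expr_clamped, c("phi_p", "phi_h"),
  function.arg = c("phi_p", "phi_h", "N", "chi_f", "lam", "z"))

#' Free energy density of the three-state model
#'
#' Per-site free energy (in kT)
#' `f = (phi_p/N) ln phi_p + phi_h ln phi_h + phi_s ln phi_s
#'    + 0.5 chi_f phi_p^2 + lam (z(phi_h) phi_p)^2`,
#' with solvent fraction `phi_s = 1 - phi_p - phi_h` and proton molarity
#' `c_h = phi_h * site_molarity`. Defined on the open simplex.
#'
#' The `charge_response` convention matters only for the derivatives: the
#' free-energy value itself is identical. With `"clamped"` (default for
#' spinodal work) the polymer charge `z` is pinned to the value set by the
#' buffered proton reservoir at the evaluation point, so charge-density
#' fluctuations do not feed back into the curvature; with `"fluctuating"`
#' the full chain rule through `z(phi_h)` is applied. Because free protons
#' are extremely dilute, the fluctuating convention lets the charge
#' response dominate the proton sector and buries the polymer-density
#' instability; the clamped convention is what a buffered experiment
#' realizes.
#'
#' @param phi_p polymer volume fraction(s), in (0, 1).
#' @param phi_h proton-carrier volume fraction(s), in (0, 1).
#' @param params a [thermo_params()].
#' @param derivatives if `TRUE`, also return the analytic gradient and
#'   Hessian entries.
#' @param charge_response `"clamped"` or `"fluctuating"` (see Details).
#' @return numeric vector of free energies, or (with derivatives) a data
#'   frame adding `f_p`, `f_h`, `f_pp`, `f_ph`, `f_hh`.
#' @export
free_energy_density <- function(phi_p, phi_h, params = thermo_params(),
                                derivatives = FALSE,
                                charge_response = c("clamped",
                                                    "fluctuating")) {
  charge_response <- match.arg(charge_response)
  stopifnot(inherits(params, "thermo_params"))
  if (any(phi_p <= 0) || any(phi_h <= 0) || any(phi_p + phi_h >= 1))
    stop("compositions must lie in the open simplex")
  if (charge_response == "fluctuating") {
    v <- free_energy_fun_fluct(phi_p, phi_h, params$N, params$chi_f,
                               params$lam, 10^(-params$pKa_plus),
                               10^(-params$pKa_minus),
                               params$site_molarity)
  } else {
    z <- state_fractions(phi_h * params$site_molarity, params)$z
    v <- free_energy_fun_clamped(phi_p, phi_h, params$N, params$chi_f,
                                 params$lam, z)
  }
  if (!derivatives) return(as.numeric(v))
  g <- attr(v, "gradient")
  H <- attr(v, "hessian")
  data.frame(f = as.numeric(v),
             f_p = g[, "phi_p"], f_h = g[, "phi_h"],
             f_pp = H[, "phi_p", "phi_p"],
             f_ph = H[, "phi_p", "phi_h"],
             f_hh = H[, "phi_h", "phi_h"])
}

#' Hessian-determinant field over composition space
#'
#' Evaluates the determinant of the 2x2 Hessian of the free energy with
#' respect to `(phi_p, phi_h)` on a grid of polymer volume fractions and pH
#' values (protons log-spaced via `phi_h = 10^-pH / site_molarity`). The
#' homogeneous phase is locally unstable (inside the spinodal) where the
#' determinant is negative. Derivatives are analytic (symbolically
#' generated); a scaled determinant (divided by the ideal-solution
#' `1/phi_h + 1/phi_s` curvature) is stored for well-conditioned
#' contouring.
#'
#' @param params a [thermo_params()].
#' @param phi_p_grid polymer volume fractions (default log-spaced
#'   `1e-6`-`0.5`, 200 points).
#' @param ph_grid pH values (default 3-11, 160 points).
#' @param charge_response derivative convention, see
#'   [free_energy_density()].
#' @return object of class `spinodal_result` with matrices `det` and
#'   `det_scaled` (rows = pH, cols = phi_p), the grids, and the polymer
#'   molar concentration axis `c_p = phi_p * site_molarity / N`.
#' @export
hessian_det_field <- function(params = thermo_params(),
                              phi_p_grid = 10^seq(-6, log10(0.5),
                                                  length.out = 200),
                              ph_grid = seq(3, 11, length.out = 160),
                              charge_response = c("clamped",
                                                  "fluctuating")) {
  charge_response <- match.arg(charge_response)
  stopifnot(inherits(params, "thermo_params"))
  phi_h_grid <- 10^(-ph_grid) / params$site_molarity
  if (any(phi_p_grid <= 0) || any(phi_p_grid + max(phi_h_grid) >= 1))
    stop("grid touches the simplex boundary")
  gg <- expand.grid(ph = ph_grid, phi_p = phi_p_grid)
  gg$phi_h <- 10^(-gg$ph) / params$site_molarity
  d <- free_energy_density(gg$phi_p, gg$phi_h, params, derivatives = TRUE,
                           charge_response = charge_response)
  det_v <- d$f_pp * d$f_hh - d$f_ph^2
  phi_s <- 1 - gg$phi_p - gg$phi_h
  det_s <- det_v / (1 / gg$phi_h + 1 / phi_s)
  nx <- length(ph_grid)
  structure(list(params = params,
                 ph_grid = ph_grid, phi_p_grid = phi_p_grid,
                 c_p_grid = phi_p_grid * params$site_molarity / params$N,
                 det = matrix(det_v, nx, length(phi_p_grid)),
                 det_scaled = matrix(det_s, nx, length(phi_p_grid)),
                 sweep = NULL),
            class = "spinodal_result")
}

#' @export
print.spinodal_result <- function(x, ...) {
  cat(sprintf("spinodal_result: %d pH x %d phi_p nodes, det sign: %d neg / %d pos\n",
              length(x$ph_grid), length(x$phi_p_grid),
              sum(x$det < 0), sum(x$det > 0)))
  invisible(x)
}

#' Spinodal contour from a Hessian-determinant field
#'
#' Marching-squares zero contour of the (scaled) determinant, reported in
#' (pH, polymer molarity) coordinates, together with the location of the
#' contour's minimum polymer concentration - the most phase-separation-
#' prone pH, which tracks the model pI.
#'
#' @param result a `spinodal_result` from [hessian_det_field()].
#' @return list with `points` (data frame: contour, ph, c_p, phi_p) and
#'   `minimum` (one-row data frame at the lowest polymer concentration);
#'   empty with a warning when the field does not change sign.
#' @export
spinodal_contour <- function(result) {
  stopifnot(inherits(result, "spinodal_result"))
  z <- result$det_scaled
  if (!(any(z < 0) && any(z > 0))) {
    warning("Hessian determinant is single-signed; no spinodal in range")
    return(list(points = data.frame(contour = integer(), ph = numeric(),
                                    c_p = numeric(), phi_p = numeric()),
                minimum = NULL))
  }
  # contour on a log phi_p axis for even resolution
  cl <- grDevices::contourLines(x = result$ph_grid,
                                y = log10(result$phi_p_grid),
                                z = z, levels = 0)
  pts <- do.call(rbind, lapply(seq_along(cl), function(i) {
    phi_p <- 10^cl[[i]]$y
    data.frame(contour = i, ph = cl[[i]]$x,
               c_p = phi_p * result$params$site_molarity / result$params$N,
               phi_p = phi_p)
  }))
  minimum <- pts[which.min(pts$c_p), , drop = FALSE]
  list(points = pts, minimum = minimum)
}

#' Sweep one control parameter of the spinodal model
#'
#' Recomputes the Hessian-determinant field for each value of a varied
#' parameter. Sweeping `pI` translates both pKa values (the gap is kept),
#' and hence the contour minimum; making `chi_f` more negative lowers the
#' spinodal; increasing `lam` narrows the pH window of instability at
#' fixed polymer concentration.
#'
#' @param base a [thermo_params()].
#' @param vary one of `"pI"`, `"chi_f"`, `"lam"`.
#' @param values numeric values for the varied parameter.
#' @param ... passed to [hessian_det_field()] (grids).
#' @return list of `spinodal_result`s, each with `sweep` metadata.
#' @export
parameter_sweep <- function(base, vary = c("pI", "chi_f", "lam"), values,
                            ...) {
  vary <- match.arg(vary)
  stopifnot(inherits(base, "thermo_params"), all(is.finite(values)))
  lapply(values, function(v) {
    p <- base
    if (vary == "pI") {
      gap <- (base$pKa_minus - base$pKa_plus) / 2
      p <- thermo_params(base$N, base$chi_f, base$lam,
                         pKa_plus = v - gap, pKa_minus = v + gap,
                         site_molarity = base$site_molarity)
    } else if (vary == "chi_f") {
      p <- thermo_params(base$N, v, base$lam, base$pKa_plus,
                         base$pKa_minus, base$site_molarity)
    } else {
      p <- thermo_params(base$N, base$chi_f, v, base$pKa_plus,
                         base$pKa_minus, base$site_molarity)
    }
    res <- hessian_det_field(p, ...)
    res$sweep <- list(vary = vary, value = v)
    res
  })
}

#' Width in pH of the unstable window at fixed polymer fraction
#'
#' Helper for sweep diagnostics: the pH extent over which the determinant
#' is negative at the grid column nearest `phi_p`.
#'
#' @param result a `spinodal_result`.
#' @param phi_p polymer volume fraction at which to section the field.
#' @return pH width (0 when stable everywhere at that composition).
#' @export
instability_ph_width <- function(result, phi_p) {
  j <- which.min(abs(result$phi_p_grid - phi_p))
  neg <- result$det[, j] < 0
  if (!any(neg)) return(0)
  diff(range(result$ph_grid[neg]))
}
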