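test_that("charge-state fractions normalize and vanish at the model pI", {
  p <- thermo_params(pKa_plus = 6, pKa_minus = 8)
  sf <- state_fractions(10^(-p$pI), p)
  expect_equal(sf$f_plus + sf$f_zero + sf$f_minus, 1)
  expect_equal(sf$z, 0, tolerance = 1e-14)
  # strongly acidic limit: fully protonated, z -> +1
  hi <- state_fractions(10^(-1), p)
  expect_gt(hi$f_plus, 0.999)
  expect_equal(hi$z, 1, tolerance = 1e-3)
  # antisymmetry of z about the pI on a log-proton grid
  for (delta in c(0.5, 1, 2)) {
    zp <- state_fractions(10^(-(p$pI + delta)), p)$z
    zm <- state_fractions(10^(-(p$pI - delta)), p)$z
    expect_equal(zp, -zm, tolerance = 1e-12)
  }
  expect_error(state_fractions(-1, p), "positive")
  expect_error(thermo_params(pKa_plus = 8, pKa_minus = 6))
})

test_that("free energy reduces to ideal mixing without interactions", {
  ideal <- thermo_params(chi_f = 0, lam = 0)
  d <- free_energy_density(c(0.05, 0.2, 0.4), rep(1e-8, 3), ideal,
                           derivatives = TRUE)
  expect_true(all(d$f_pp > 0))
  expect_true(all(d$f_pp * d$f_hh - d$f_ph^2 > 0))
  # at pH = pI the electrostatic term vanishes for every phi_p
  p0 <- thermo_params(lam = 0)
  p1 <- thermo_params(lam = 25)
  phi_h_pI <- 10^(-p1$pI) / p1$site_molarity
  phis <- c(0.01, 0.1, 0.3)
  expect_equal(free_energy_density(phis, rep(phi_h_pI, 3), p1),
               free_energy_density(phis, rep(phi_h_pI, 3), p0),
               tolerance = 1e-12)
  expect_error(free_energy_density(0.6, 0.5), "simplex")
})

test_that("analytic derivatives match central finite differences", {
  p <- thermo_params()
  # spec-style check on the polymer curvature, absolute step 1e-6
  for (phi_p in c(0.02, 0.1, 0.3)) {
    phi_h <- 10^(-6.5) / p$site_molarity
    for (cr in c("clamped", "fluctuating")) {
      h <- 1e-5
      fd <- (free_energy_density(phi_p + h, phi_h, p, charge_response = cr) -
               2 * free_energy_density(phi_p, phi_h, p, charge_response = cr) +
               free_energy_density(phi_p - h, phi_h, p, charge_response = cr)) / h^2
      an <- free_energy_density(phi_p, phi_h, p, derivatives = TRUE,
                                charge_response = cr)$f_pp
      expect_equal(an, fd, tolerance = 1e-4)
    }
  }
  # full Hessian of the fully differentiated form on random interior points,
  # relative steps sized to each coordinate
  set.seed(1)
  n <- 100
  phi_p <- 10^stats::runif(n, -4, log10(0.4))
  ph <- stats::runif(n, 4, 10)
  phi_h <- 10^(-ph) / p$site_molarity
  an <- free_energy_density(phi_p, phi_h, p, derivatives = TRUE,
                            charge_response = "fluctuating")
  f <- function(a, b) free_energy_density(a, b, p,
                                          charge_response = "fluctuating")
  hp <- phi_p * 1e-3
  hh <- phi_h * 1e-3
  fd_pp <- (f(phi_p + hp, phi_h) - 2 * f(phi_p, phi_h) +
              f(phi_p - hp, phi_h)) / hp^2
  fd_hh <- (f(phi_p, phi_h + hh) - 2 * f(phi_p, phi_h) +
              f(phi_p, phi_h - hh)) / hh^2
  fd_ph <- (f(phi_p + hp, phi_h + hh) - f(phi_p + hp, phi_h - hh) -
              f(phi_p - hp, phi_h + hh) + f(phi_p - hp, phi_h - hh)) /
    (4 * hp * hh)
  expect_equal(an$f_pp, fd_pp, tolerance = 1e-4)
  expect_equal(an$f_hh, fd_hh, tolerance = 1e-4)
  expect_equal(an$f_ph, fd_ph, tolerance = 1e-3)
})

test_that("determinant field flags instability only for attractive systems", {
  ideal <- hessian_det_field(thermo_params(chi_f = 0, lam = 0),
                             phi_p_grid = 10^seq(-4, log10(0.4), length.out = 40),
                             ph_grid = seq(4, 10, length.out = 30))
  expect_true(all(ideal$det > 0))
  # attractive chi_f at the pI: an intermediate unstable phi_p band whose
  # edges match the one-variable Flory spinodal condition
  p <- thermo_params(chi_f = -2, lam = 10)
  res <- hessian_det_field(p)
  i_pI <- which.min(abs(res$ph_grid - p$pI))
  neg <- res$det[i_pI, ] < 0
  expect_true(any(neg) && !all(neg))
  phi <- res$phi_p_grid
  phi_h <- 10^(-res$ph_grid[i_pI]) / p$site_molarity
  flory <- 1 / (p$N * phi) + 1 / (1 - phi - phi_h) + p$chi_f  # z = 0 at pI
  expect_equal(which(neg), which(flory < 0))
  expect_error(hessian_det_field(p, phi_p_grid = c(0.5, 1.0)),
               "simplex|boundary")
})

test_that("spinodal contour bottoms out at the pI and tracks pI sweeps", {
  res <- hessian_det_field()
  sc <- spinodal_contour(res)
  step <- diff(res$ph_grid[1:2])
  expect_lt(abs(sc$minimum$ph - thermo_params()$pI), step + 1e-9)
  for (r in parameter_sweep(thermo_params(), "pI", c(5, 6, 7))) {
    m <- spinodal_contour(r)$minimum
    expect_lt(abs(m$ph - r$sweep$value), step + 1e-9)
  }
  # single-signed field: empty contour with a warning
  stable <- hessian_det_field(thermo_params(chi_f = 0, lam = 0),
                              phi_p_grid = 10^seq(-4, -1, length.out = 20),
                              ph_grid = seq(5, 9, length.out = 20))
  expect_warning(empty <- spinodal_contour(stable), "single-signed")
  expect_equal(nrow(empty$points), 0)
})

test_that("without electrostatics the spinodal is flat at the Flory locus", {
  p0 <- thermo_params(lam = 0)
  res <- hessian_det_field(p0)
  pts <- spinodal_contour(res)$points
  lower <- subset(pts, contour == 1)
  # flat in pH
  expect_lt(diff(range(lower$phi_p)) / mean(lower$phi_p), 0.02)
  # matches the closed-form locus 1/(N phi) + 1/phi_s + chi_f = 0
  flory_root <- stats::uniroot(function(phi)
    1 / (p0$N * phi) + 1 / (1 - phi) + p0$chi_f, c(1e-4, 0.09))$root
  grid_tol <- mean(lower$phi_p) *
    (10^diff(log10(res$phi_p_grid[1:2])) - 1) * 2
  expect_lt(abs(mean(lower$phi_p) - flory_root), grid_tol)
})

test_that("attraction lowers the spinodal and repulsion narrows its pH window", {
  sw <- parameter_sweep(thermo_params(), "chi_f", c(-1.6, -2, -2.6))
  mins <- vapply(sw, function(r) spinodal_contour(r)$minimum$c_p, numeric(1))
  expect_true(all(diff(mins) < 0))   # more attractive -> lower boundary
  widths <- vapply(parameter_sweep(thermo_params(), "lam", c(2, 10, 40)),
                   instability_ph_width, numeric(1), phi_p = 0.09)
  expect_true(all(diff(widths) < 0))
  # chi_f towards zero: instability disappears
  weak <- hessian_det_field(thermo_params(chi_f = -0.5))
  expect_true(all(weak$det > 0))
})

test_that("polymer-sector curvature is symmetric about the pI", {
  p <- thermo_params()
  for (delta in c(0.5, 1.5)) {
    lo <- free_energy_density(0.1, 10^(-(p$pI - delta)) / p$site_molarity,
                              p, derivatives = TRUE)
    hi <- free_energy_density(0.1, 10^(-(p$pI + delta)) / p$site_molarity,
                              p, derivatives = TRUE)
    expect_equal(lo$f_pp, hi$f_pp, tolerance = 1e-6)
  }
})
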