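test_that("buffer calibration interpolates monotonically through its knots", {
  cal <- buffer_calibration(c(0, 0.25, 0.5, 0.75, 1),
                            c(3.5, 4.2, 6.0, 8.1, 9.0))
  expect_equal(ph_from_fraction(cal, c(0, 0.5, 1)), c(3.5, 6.0, 9.0))
  f <- seq(0, 1, by = 0.05)
  expect_true(all(diff(ph_from_fraction(cal, f)) > 0))
  expect_error(ph_from_fraction(cal, 1.2), "outside")
  expect_error(buffer_calibration(c(0, 0.5, 0.4), c(3, 4, 5)), "increasing")
  expect_error(buffer_calibration(c(0, 0.5, 1), c(3, 5, 4)), "increasing")
  # logistic calibration round trip at the knots
  fr <- seq(0, 1, length.out = 41)
  ph <- 3.5 + 5.5 * stats::plogis(6 * (fr - 0.5))
  ph <- (ph - min(ph)) / diff(range(ph)) * 5.5 + 3.5
  cal2 <- buffer_calibration(fr, ph)
  back <- stats::approx(cal2$ph, cal2$fraction,
                        xout = ph_from_fraction(cal2, fr))$y
  expect_equal(back, fr, tolerance = 1e-6)
})

test_that("phase-fraction binning matches brute force and conserves counts", {
  d <- data.frame(droplet_id = sprintf("d%d", 1:10),
                  frac_peptide = 0.25, frac_water = 0.25,
                  frac_lowpH = 0.25, frac_highpH = 0.25,
                  ph = c(4.1, 4.2, 4.3, 5.1, 5.2, 5.0, 6.9, 6.8, 6.7, 6.6),
                  c_tot = c(1, 1.2, 1.4, 2.1, 2.2, 2.3, 0.4, 0.5, 0.6, 0.7),
                  phase_class = c(1, 1, 0, 1, 0, 0, 1, 1, 1, 0))
  g <- bin_phase_fraction(d, ph_edges = c(4, 5, 6, 7),
                          conc_edges = c(0, 1, 2, 3), min_count = 1)
  expect_equal(sum(g$count) + g$n_outside, nrow(d))
  # brute-force per-bin means
  for (i in 1:3) for (j in 1:3) {
    sel <- d$ph >= g$ph_edges[i] & d$ph < g$ph_edges[i + 1] &
      d$c_tot >= g$conc_edges[j] & d$c_tot < g$conc_edges[j + 1]
    if (any(sel)) expect_equal(g$fps[i, j], mean(d$phase_class[sel]))
  }
  expect_true(all(g$fps >= 0 & g$fps <= 1, na.rm = TRUE))
  # half-open convention: an edge droplet lands in the right-hand bin once
  d1 <- d[1, ]; d1$ph <- 5; d1$c_tot <- 1
  g1 <- bin_phase_fraction(d1, c(4, 5, 6), c(0, 1, 2), min_count = 1)
  expect_equal(sum(g1$count), 1L)
  expect_equal(g1$count[2, 2], 1L)
  # all phase separated: F_PS = 1 in every populated bin
  d$phase_class <- 1
  g2 <- bin_phase_fraction(d, c(4, 5, 6, 7), c(0, 1, 2, 3), min_count = 1)
  expect_true(all(g2$fps[g2$count > 0] == 1))
  expect_equal(sum(is.na(g2$fps)), sum(g2$count == 0))
  expect_error(bin_phase_fraction(d, c(4, 4), c(0, 1)), "degenerate")
})

test_that("boundary extraction finds a step and a U-shaped boundary", {
  # step grid: F_PS = 1 below the step concentration, 0 above
  ph_e <- seq(0, 10, by = 1); c_e <- seq(0, 10, by = 1)
  g <- structure(list(ph_edges = ph_e, conc_edges = c_e,
                      count = matrix(5L, 10, 10),
                      fps = matrix(rep(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                                       each = 10), 10, 10),
                      min_count = 3L, n_outside = 0L),
                 class = "phase_grid")
  b <- extract_boundary(g)
  expect_true(all(abs(b$conc - 5) <= 0.5))
  expect_error(extract_boundary(g, level = 1.2), "strictly in")
  flat <- g; flat$fps[] <- 1
  expect_warning(e <- extract_boundary(flat), "does not cross")
  expect_equal(nrow(e), 0)
  # synthetic U-shaped boundary: contour minimum near the generator pI
  tr <- droplet_truth(seed = 42, flip_prob = 0, noise_sd = 0)
  d <- synth_droplets(tr, 6000)
  grid <- bin_phase_fraction(d, seq(3.5, 9, by = 0.25), seq(0, 5, by = 0.2))
  bb <- extract_boundary(grid)
  # minimum located as the mid-range of the contour's bottom region (the
  # boundary is nearly flat over the lowest bin, so the single lowest
  # vertex is noisier than the bottom plateau)
  bottom <- bb[bb$conc <= min(bb$conc) + 0.1, ]
  expect_lt(abs(mean(range(bottom$ph)) - tr$pI), 0.25 + 1e-9)
})

test_that("dilute-phase contour slopes recover exact collinear constructions", {
  ph <- seq(4, 6, by = 0.1)
  d <- data.frame(droplet_id = seq_along(ph), frac_peptide = 0.2,
                  frac_water = 0.3, frac_lowpH = 0.3, frac_highpH = 0.2,
                  ph = ph, c_tot = 2 + 3 * ph, phase_class = 1,
                  c_dil = 0.8)
  d$c_tot <- pmax(d$c_tot, d$c_dil)
  fit <- section_dilute_contour(d, 0.5, 1, "low_pH", ph_split = 7,
                                n_perturb = 10, seed = 1)
  expect_equal(fit$K, 3, tolerance = 1e-9)
  expect_equal(fit$n, length(ph))
  expect_error(section_dilute_contour(d[1:2, ], 0.5, 1, "low_pH",
                                      ph_split = 7), "too narrow")
})

test_that("contour slope signs follow the generator's proton partitioning", {
  hits <- c(low = 0L, high = 0L)
  for (seed in 1:10) {
    tr <- droplet_truth(seed = seed)
    d <- synth_droplets(tr, 1500)
    kl <- section_dilute_contour(d, 0.6, 1.2, "low_pH", ph_split = tr$pI,
                                 n_perturb = 10, seed = seed)
    kh <- section_dilute_contour(d, 0.6, 1.2, "high_pH", ph_split = tr$pI,
                                 n_perturb = 10, seed = seed)
    hits["low"] <- hits["low"] + (kl$K > 0)
    hits["high"] <- hits["high"] + (kh$K < 0)
    expect_gte(kl$uncertainty, 0)
  }
  expect_gte(hits[["low"]], 9L)
  expect_gte(hits[["high"]], 9L)
})

test_that("dominance is one minus the dilute-phase response gradient", {
  base <- data.frame(droplet_id = 1:20, frac_peptide = 0.2,
                     frac_water = 0.3, frac_lowpH = 0.25, frac_highpH = 0.25,
                     ph = 6.1, c_tot = seq(1, 3, length.out = 20),
                     phase_class = 1)
  # pinned dilute phase: R = 0, D = 1
  d1 <- base; d1$c_dil <- 0.5
  f1 <- dominance(d1, 6.1, 0.25, n_perturb = 20, seed = 1)
  expect_equal(f1$R, 0, tolerance = 1e-12)
  expect_equal(f1$D, 1)
  expect_equal(f1$D + f1$R, 1)
  # no phase separation: c_dil tracks c_tot, R = 1, D = 0
  d2 <- base; d2$c_dil <- d2$c_tot
  f2 <- dominance(d2, 6.1, 0.25, n_perturb = 20, seed = 1)
  expect_equal(f2$R, 1, tolerance = 1e-12)
  expect_equal(f2$D, 0)
  expect_error(dominance(base[1:3, ], 6.1), "insufficient|c_dil")
  d3 <- base[1:5, ]; d3$c_tot <- 2; d3$c_dil <- 1
  expect_error(dominance(d3, 6.1, 0.25), "spread")
})

test_that("dominance recovery stays within three reported errors of truth", {
  for (R_true in c(0.54, 0.2)) {
    tr <- droplet_truth(R_true = R_true, seed = 17)
    slab <- synth_dominance_slab(tr, 6.1, 250)
    fit <- dominance(slab, 6.1, 0.25, n_perturb = 200, seed = 3)
    expect_lt(abs(fit$D - (1 - R_true)), 3 * fit$error)
  }
})

test_that("droplet CSV round trip validates the schema", {
  tr <- droplet_truth(seed = 5)
  d <- synth_droplets(tr, 50)
  f <- tempfile(fileext = ".csv")
  write_synth_droplets(d, f)
  back <- read_droplets_csv(f)
  expect_equal(nrow(back), 50)
  expect_equal(back$c_dil, d$c_dil, tolerance = 1e-9)
  truth <- jsonlite::read_json(sub("\\.csv$", "_truth.json", f))
  expect_equal(truth$pI, tr$pI)
  bad <- d; bad$frac_water <- bad$frac_water + 0.1
  expect_error(write_droplets_csv(bad, f), "sum to 1")
})
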