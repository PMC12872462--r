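test_that("a single-component mixture reproduces the component profile", {
  cp <- charge_profile(strrep("K", 12))
  mix <- mixture_charge_profile(list(cp))
  expect_equal(mix$C, cp$Q)
  expect_equal(mix$mixture_pI, isoelectric_point(strrep("K", 12)),
               tolerance = 0.005)
  # mixing a sequence with itself changes nothing (per-sequence mean)
  mix2 <- mixture_charge_profile(list(cp, cp))
  expect_equal(mix2$C, cp$Q)
  expect_equal(mix2$mixture_pI, mix$mixture_pI)
  expect_error(mixture_charge_profile(list()), "empty")
})

test_that("mixture pI matches a brute-force weighted grid scan", {
  # cationic FUS-like RGG peptide vs a poly-A 20-mer
  pep <- charge_profile("GRGGRGGYGGRGGSRGGYGGRGGS")
  rna <- rna_charge_profile(strrep("A", 20))
  w <- c(5, 1)   # molar weights
  mix <- mixture_charge_profile(list(mixture_component(pep, w[1]),
                                     mixture_component(rna, w[2],
                                                       kind = "rna")),
                                normalization = "weighted")
  # oracle: direct sign-change scan of the weighted sum at 1e-3 resolution
  ph <- seq(0, 14, by = 1e-3)
  Csum <- w[1] * protein_net_charge("GRGGRGGYGGRGGSRGGYGGRGGS", ph) +
    w[2] * rna_net_charge(strrep("A", 20), ph)
  i <- max(which(Csum > 0))
  oracle <- ph[i] + (0 - Csum[i]) * 1e-3 / (Csum[i + 1] - Csum[i])
  expect_equal(mix$mixture_pI, oracle, tolerance = 1e-2)
})

test_that("zero crossing is invariant under positive rescaling", {
  pep <- charge_profile(random_protein_string(40, 7))
  rna <- rna_charge_profile(strrep("AC", 10))
  comps <- list(mixture_component(pep, 3),
                mixture_component(rna, 1, kind = "rna"))
  mw <- mixture_charge_profile(comps, "weighted")
  mb <- mixture_charge_profile(comps, "bounded", reference = 1)
  expect_equal(mw$mixture_pI, mb$mixture_pI)
  expect_equal(max(mb$C), max(pep$Q))
  # doubling all weights rescales C but not the crossing
  m2 <- mixture_charge_profile(list(mixture_component(pep, 6),
                                    mixture_component(rna, 2,
                                                      kind = "rna")),
                               "weighted")
  expect_equal(m2$mixture_pI, mw$mixture_pI)
  expect_equal(m2$C, 2 * mw$C)
})

test_that("mixture pI is bracketed by component pIs and NA without neutrality", {
  pk <- charge_profile(strrep("K", 15))
  pd <- charge_profile(strrep("D", 15))
  mix <- mixture_charge_profile(list(pk, pd))
  lo <- isoelectric_point(strrep("D", 15))
  hi <- isoelectric_point(strrep("K", 15))
  expect_gt(mix$mixture_pI, lo)
  expect_lt(mix$mixture_pI, hi)
  # all-RNA mixture: no neutrality anywhere in [0, 14]
  rna <- rna_charge_profile(strrep("U", 5))
  expect_message(m <- mixture_charge_profile(list(
    mixture_component(rna, 1, kind = "rna"))), "no neutrality")
  expect_true(is.na(m$mixture_pI))
})

test_that("neutral pH map is monotone in the RNA axis with correct limits", {
  pk <- charge_profile(strrep("KG", 10))
  rna <- rna_charge_profile(strrep("A", 20))
  suppressMessages(
    nm <- neutral_ph_map(pk, rna, protein_concs = seq(0.5, 2.5, length.out = 5),
                         rna_concs = c(0, 10^seq(-2, 0, length.out = 4))))
  expect_equal(dim(nm), c(5, 5))
  # zero-RNA column: the protein's own pI
  expect_equal(unname(nm[, 1]),
               rep(isoelectric_point(strrep("KG", 10)), 5), tolerance = 0.005)
  # more RNA never raises the neutral pH
  for (i in 1:5) {
    row <- nm[i, ]
    row <- row[!is.na(row)]
    expect_true(all(diff(row) <= 1e-9))
  }
})

test_that("RNA mass fraction shifts the mixture pI downward as constructed", {
  prot <- mixture_charge_profile(list(
    charge_profile(strrep("KGG", 30)), charge_profile(strrep("KAG", 30))))
  rna <- rna_charge_profile(strrep("ACGU", 25))
  expect_identical(mass_fraction_mixture(prot, rna, 0), prot)
  mf <- mass_fraction_mixture(prot, rna, 0.075)
  expect_lt(mf$mixture_pI, prot$mixture_pI)
  expect_error(mass_fraction_mixture(prot, rna, 1), "\\[0, 1\\)")
  # oracle: solve sum(w * Q) = 0 directly with the same molar weights
  f <- 0.075
  w_p <- (1 - f) / (110 * prot$mean_n_units)
  w_r <- f / (330 * rna$n_units)
  g <- function(ph) {
    w_p * stats::approx(prot$ph, prot$C, ph)$y +
      w_r * stats::approx(rna$ph, rna$Q, ph)$y
  }
  root <- stats::uniroot(g, c(1, 13), tol = 1e-8)$root
  expect_equal(mf$mixture_pI, root, tolerance = 1e-2)
})

test_that("charge slope at the mixture pI is a central difference, scaling linearly", {
  lin <- linear_mixture_profile(k = 2.5)
  expect_equal(charge_slope_at_pI(lin), 2.5, tolerance = 1e-9)
  lin2 <- lin; lin2$C <- 2 * lin$C; lin2$q <- 2 * lin$q
  expect_equal(charge_slope_at_pI(lin2), 5, tolerance = 1e-9)
  # random peptide: matches a fine numerical derivative within 1%
  mix <- mixture_charge_profile(list(
    charge_profile(random_protein_string(60, 21), seq(0, 14, by = 0.001))))
  pI <- mix$mixture_pI
  d <- 1e-4
  num <- -(protein_net_charge(random_protein_string(60, 21), pI + d) -
             protein_net_charge(random_protein_string(60, 21), pI - d)) / (2 * d)
  expect_equal(charge_slope_at_pI(mix), num, tolerance = 0.01)
  noneutral <- linear_mixture_profile(1)
  noneutral$mixture_pI <- NA_real_
  expect_error(charge_slope_at_pI(noneutral), "no mixture pI")
})

test_that("mixture specs load from YAML with per-component weights", {
  dir <- tempfile(); dir.create(dir)
  write_fasta(list(protein_sequence("KKRKG", id = "pepK")),
              file.path(dir, "pep.fasta"))
  write_fasta(list(nucleic_acid_sequence("AAAA", id = "a4")),
              file.path(dir, "rna.fasta"))
  yaml::write_yaml(list(components = list(
    list(id = "pepK", fasta = "pep.fasta", weight = 2, kind = "protein"),
    list(id = "a4", fasta = "rna.fasta", weight = 1, kind = "rna"))),
    file.path(dir, "mix.yaml"))
  comps <- read_mixture_spec(file.path(dir, "mix.yaml"),
                             ph_grid = seq(0, 14, by = 0.05))
  expect_length(comps, 2)
  expect_equal(comps[[1]]$weight, 2)
  expect_equal(comps[[2]]$kind, "rna")
  mix <- mixture_charge_profile(comps, "weighted")
  expect_s3_class(mix, "mixture_profile")
})
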