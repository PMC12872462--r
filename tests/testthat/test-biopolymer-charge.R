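test_that("group_charge follows Henderson-Hasselbalch with correct sign and limits", {
  expect_equal(group_charge(7.5, 7.5, +1), 0.5)
  expect_equal(group_charge(4.0, 4.0, -1), -0.5)
  # closed-form check: 1/(1 + 10^-0.5)
  expect_equal(group_charge(7, 7.5, +1), 1 / (1 + 10^-0.5), tolerance = 1e-12)
  expect_equal(group_charge(7, 7.5, +1), 0.7597, tolerance = 1e-4)
  # asymptotes of an acidic group
  expect_lt(abs(group_charge(0, 7, -1)), 1e-6)
  expect_equal(group_charge(14, 7, -1), -1, tolerance = 1e-6)
  expect_error(group_charge(NaN, 7, 1), "non-finite")
  expect_error(group_charge(7, Inf, 1), "non-finite")
  expect_error(group_charge(15, 7, 1), "\\[0, 14\\]")
})

test_that("protein net charge sums termini and ionizable side chains", {
  # glycine: only the two termini ionize
  expect_equal(protein_net_charge("G", 7), 0.7597 - 0.9996, tolerance = 1e-3)
  expect_equal(protein_net_charge("G", 7), -0.2398984, tolerance = 1e-6)
  ph <- seq(0, 14, by = 0.5)
  expect_equal(protein_net_charge("GGG", ph), protein_net_charge("G", ph))
  expect_error(protein_sequence(""), "empty")
  # ambiguity codes: no charge, but counted in N
  expect_warning(px <- protein_sequence("GXG"), "ambiguity")
  expect_equal(px$n, 3L)
  expect_equal(protein_net_charge(px, ph), protein_net_charge("GG", ph))
})

test_that("isoelectric point is the unique neutrality root", {
  expect_equal(isoelectric_point("GGG"), 5.525, tolerance = 1e-3)
  # amphoteric two-group midpoint with the default table
  expect_equal(isoelectric_point("GGG"), (3.55 + 7.5) / 2, tolerance = 1e-2)
  for (seed in 1:10) {
    s <- random_protein_string(80, seed)
    pI <- isoelectric_point(s)
    expect_lt(abs(protein_net_charge(s, pI)), 1e-3)
  }
})

test_that("insulin and its glargine variant reproduce the reference pI values", {
  ins <- insulin_fixture()
  expect_equal(isoelectric_point(ins$insulin), 5.4, tolerance = 0.1 / 5.4)
  expect_equal(isoelectric_point(ins$insulin_glargine), 6.8,
               tolerance = 0.1 / 6.8)
})

test_that("net charge is monotone non-increasing in pH for random sequences", {
  ph <- seq(0, 14, by = 0.05)
  for (seed in 1:20) {
    Q <- protein_net_charge(random_protein_string(60, seed), ph)
    expect_true(all(diff(Q) <= 0))
  }
})

test_that("charge is additive up to the extra pair of termini", {
  ph <- seq(1, 13, by = 0.5)
  tab <- default_pka_table()
  a <- random_protein_string(40, 101)
  b <- random_protein_string(25, 102)
  extra <- group_charge(ph, tab$basic_groups[["Nterm"]], +1) +
    group_charge(ph, tab$acidic_groups[["Cterm"]], -1)
  expect_equal(protein_net_charge(paste0(a, b), ph),
               protein_net_charge(a, ph) + protein_net_charge(b, ph) - extra,
               tolerance = 1e-10)
})

test_that("bisection pI agrees with the fine grid-scan oracle", {
  for (seed in 1:20) {
    s <- random_protein_string(50, seed + 500)
    expect_equal(isoelectric_point(s), pi_gridscan(s), tolerance = 1e-3)
  }
})

test_that("charge profiles have non-negative q2 with its minimum at the pI", {
  for (seed in c(3, 14)) {
    s <- random_protein_string(70, seed)
    cp <- charge_profile(s)
    expect_true(all(diff(cp$Q) <= 0))
    expect_true(all(cp$q2 >= 0))
    pI <- isoelectric_point(s)
    expect_lt(abs(cp$ph[which.min(cp$q2)] - pI), 0.011)
  }
  # purely basic chain: q2 minimal at the top of the range
  cpk <- charge_profile(strrep("K", 10))
  expect_gt(cpk$ph[which.min(cpk$q2)], 10.5)
  expect_lt(abs(cpk$ph[which.min(cpk$q2)] -
                  isoelectric_point(strrep("K", 10))), 0.011)
  expect_error(charge_profile("GG", ph_grid = c(2, 1)), "ascending")
})

test_that("Kyte-Doolittle hydropathy is tabled per residue and additive", {
  expect_equal(hydropathy("III")$kd_mean, 4.5)
  expect_equal(hydropathy("RRR")$kd_mean, -4.5)
  a <- "GAVL"; b <- "WYPH"
  expect_equal(hydropathy(paste0(a, b))$kd_sum,
               hydropathy(a)$kd_sum + hydropathy(b)$kd_sum)
  px <- suppressWarnings(protein_sequence("IXI"))
  expect_warning(hx <- hydropathy(px), "ambiguity")
  expect_equal(hx$kd_mean, 4.5)
})

test_that("diprotic phosphate speciation runs from 0 to -2", {
  expect_lt(abs(phosphate_charge(0, 3, 7)), 1e-2)
  expect_equal(phosphate_charge(14, 1, 6.5), -2, tolerance = 1e-6)
  expect_equal(phosphate_charge(7, 1, 6.5), -1.76, tolerance = 1e-2)
  # first deprotonation half-point when the steps are well separated
  expect_equal(phosphate_charge(3, 3, 7.5), -0.5, tolerance = 0.01)
  expect_error(phosphate_charge(7, 6.5, 1), "smaller")
})

test_that("RNA net charge sums base protonation and phosphates", {
  expect_lt(rna_net_charge("ACGU", 7), 0)
  ph <- seq(0, 14, by = 0.25)
  expect_true(all(diff(rna_net_charge("ACGU", ph)) <= 0))
  # additivity of a homopolymer
  expect_equal(rna_net_charge(strrep("A", 10), 7),
               10 * rna_net_charge("A", 7), tolerance = 1e-12)
  expect_error(nucleic_acid_sequence("ACGX"), "unknown base")
  expect_warning(nucleic_acid_sequence("ACGT"), "mapped to U")
})

test_that("pKa tables validate and round-trip through JSON", {
  expect_error(ionizable_group_table(c(Nterm = 7.5, K = 10, R = 12, H = 6),
                                     c(Cterm = 3.55, D = 4, E = 4.4,
                                       C = 9, Y = 10),
                                     phosphate_pka1 = 7,
                                     phosphate_pka2 = 1),
               "smaller")
  expect_error(default_pka_table("nope"))
  tab <- default_pka_table("emboss")
  f <- tempfile(fileext = ".json")
  write_pka_table(tab, f)
  tab2 <- read_pka_table(f)
  expect_equal(tab2$basic_groups, tab$basic_groups)
  expect_equal(tab2$phosphate_pka2, tab$phosphate_pka2)
  # pI depends on the preset as expected
  expect_gt(isoelectric_point("GGG", tab), isoelectric_point("GGG"))
})

test_that("FASTA round trip preserves sequences and ids", {
  seqs <- list(protein_sequence("GIVEQ", id = "p1"),
               protein_sequence("KKDDE", id = "p2"))
  f <- tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta_protein(f)
  expect_equal(names(back), c("p1", "p2"))
  expect_equal(back$p2$residues, "KKDDE")
})
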