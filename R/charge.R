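#' Fractional charge of a single ionizable group
#'
#' Henderson-Hasselbalch protonation of one site. A basic group
#' (`sign = +1`) carries `+1 / (1 + 10^(ph - pka))`; an acidic group
#' (`sign = -1`) carries `-1 / (1 + 10^(pka - ph))`. Results lie in
#' `[-1, +1]` and decrease monotonically with pH.
#'
#' @param ph pH value(s) in `[0, 14]`.
#' @param pka group pKa.
#' @param sign `+1` for a basic group, `-1` for an acidic group.
#' @return fractional charge, vectorized over `ph`.
#' @examples
#' group_charge(7, 7.5, +1)   # 0.7597
#' @export
group_charge <- function(ph, pka, sign) {
  if (any(!is.finite(ph)) || any(!is.finite(pka)))
    stop("non-finite ph or pka")
  if (any(ph < 0 | ph > 14)) stop("ph must lie in [0, 14]")
  if (length(sign) != 1L || !(sign %in% c(-1, 1)))
    stop("sign must be a single +1 or -1")
  if (sign > 0) 1 / (1 + 10^(ph - pka)) else -1 / (1 + 10^(pka - ph))
}

#' Net charge of a protein at a given pH
#'
#' Sums Henderson-Hasselbalch group charges over one N-terminal amine, one
#' C-terminal carboxyl and every K, R, H (basic) and D, E, C, Y (acidic)
#' residue. Ambiguity codes contribute zero charge but still count towards
#' the sequence length `N`.
#'
#' @param seq a [protein_sequence()] (a bare string is accepted).
#' @param ph pH value(s).
#' @param table an [ionizable_group_table()].
#' @return net charge in elementary charges, vectorized over `ph`.
#' @examples
#' protein_net_charge("G", 7)   # -0.240
#' @export
protein_net_charge <- function(seq, ph, table = default_pka_table()) {
  if (is.character(seq)) seq <- protein_sequence(seq)
  stopifnot(inherits(seq, "protein_sequence"),
            inherits(table, "ionizable_group_table"))
  counts <- seq$counts
  q <- group_charge(ph, table$basic_groups[["Nterm"]], +1) +
       group_charge(ph, table$acidic_groups[["Cterm"]], -1)
  for (res in c("K", "R", "H")) {
    n <- counts[[res]]
    if (n > 0) q <- q + n * group_charge(ph, table$basic_groups[[res]], +1)
  }
  for (res in c("D", "E", "C", "Y")) {
    n <- counts[[res]]
    if (n > 0) q <- q + n * group_charge(ph, table$acidic_groups[[res]], -1)
  }
  q
}

#' Isoelectric point of a protein sequence
#'
#' Finds the unique root of [protein_net_charge()] in (0, 14) by bisection.
#' Uniqueness follows from the strict monotonicity of every group charge in
#' pH. The default free termini guarantee one basic and one acidic group,
#' so a neutrality point always exists; with a customized table lacking one
#' side the function errors.
#'
#' @inheritParams protein_net_charge
#' @param tol bisection tolerance in pH units.
#' @param max_iter iteration cap.
#' @return the pI in pH units.
#' @examples
#' isoelectric_point("GGG")   # 5.525 with the default table
#' @export
isoelectric_point <- function(seq, table = default_pka_table(),
                              tol = 1e-4, max_iter = 100L) {
  if (is.character(seq)) seq <- protein_sequence(seq)
  lo <- 0; hi <- 14
  qlo <- protein_net_charge(seq, lo, table)
  qhi <- protein_net_charge(seq, hi, table)
  if (!(qlo > 0 && qhi < 0))
    stop("no neutrality point: net charge does not change sign in [0, 14]")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(seq, mid, table) > 0) lo <- mid else hi <- mid
    if ((hi - lo) < tol) break
  }
  (lo + hi) / 2
}

#' Charge profile of a protein over a pH grid
#'
#' Evaluates net charge `Q`, charge density `q = Q/N` and its square `q^2`
#' (the electrostatic repulsion proxy) on an ascending pH grid.
#'
#' @inheritParams protein_net_charge
#' @param ph_grid ascending pH grid; default 0-14 in steps of 0.01.
#' @return object of class `charge_profile` with fields `ph`, `Q`, `q`,
#'   `q2`, `source_id`, `n_units`.
#' @export
charge_profile <- function(seq, ph_grid = seq(0, 14, by = 0.01),
                           table = default_pka_table()) {
  if (is.character(seq)) seq <- protein_sequence(seq)
  if (is.unsorted(ph_grid, strictly = TRUE))
    stop("ph_grid must be strictly ascending")
  Q <- protein_net_charge(seq, ph_grid, table)
  new_charge_profile(ph_grid, Q, n_units = seq$n, source_id = seq$id,
                     kind = "protein")
}

new_charge_profile <- function(ph, Q, n_units, source_id, kind) {
  q <- Q / n_units
  structure(list(ph = ph, Q = Q, q = q, q2 = q^2,
                 source_id = source_id, n_units = n_units, kind = kind),
            class = "charge_profile")
}

#' @export
print.charge_profile <- function(x, ...) {
  cat(sprintf("charge_profile '%s' (%s, N = %d): pH %.2f-%.2f (%d points), Q in [%.2f, %.2f]\n",
              x$source_id, x$kind, x$n_units, min(x$ph), max(x$ph),
              length(x$ph), min(x$Q), max(x$Q)))
  invisible(x)
}

#' @export
as.data.frame.charge_profile <- function(x, ...) {
  data.frame(ph = x$ph, Q = x$Q, q = x$q, q2 = x$q2)
}

#' Write a charge profile as CSV (columns ph, Q, q, q2)
#' @param profile a `charge_profile` or `mixture_profile`.
#' @param path output file.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Kyte-Doolittle hydropathy of a protein sequence
#'
#' Sum and mean of the per-residue Kyte-Doolittle index. Ambiguity codes
#' are excluded from both with a warning (they have no tabled value).
#'
#' @inheritParams protein_net_charge
#' @return list with `kd_sum` and `kd_mean`.
#' @examples
#' hydropathy("III")$kd_mean   # 4.5
#' @export
hydropathy <- function(seq) {
  if (is.character(seq)) seq <- protein_sequence(seq)
  if (seq$n_ambiguous > 0)
    warning("ambiguity residues excluded from hydropathy")
  counts <- seq$counts[standard_residues]
  kd_sum <- sum(counts * kd_scale)
  n_std <- sum(counts)
  if (n_std == 0) stop("no standard residues")
  list(kd_sum = unname(kd_sum), kd_mean = unname(kd_sum / n_std))
}

#' Charge of a diprotic phosphate group
#'
#' Two sequential deprotonation steps with constants `pka1 < pka2` give the
#' speciation-weighted mean charge
#' `-(a1 + 2 a1 a2) / (1 + a1 + a1 a2)` with `a1 = 10^(ph - pka1)`,
#' `a2 = 10^(ph - pka2)`; the result runs from 0 (fully protonated) to -2.
#'
#' @param ph pH value(s).
#' @param pka1,pka2 first and second deprotonation pKa; `pka1 < pka2`.
#' @return charge in `[-2, 0]`, vectorized over `ph`.
#' @export
phosphate_charge <- function(ph, pka1, pka2) {
  if (!(pka1 < pka2)) stop("pka1 must be smaller than pka2")
  if (any(!is.finite(ph))) stop("non-finite ph")
  a1 <- 10^(ph - pka1)
  a2 <- 10^(ph - pka2)
  -(a1 + 2 * a1 * a2) / (1 + a1 + a1 * a2)
}

#' Net charge of an RNA at a given pH
#'
#' Site-based model: every nucleotide contributes the protonation charge of
#' its nucleobase (Henderson-Hasselbalch with the tabled base pKa; bases
#' without a pKa, e.g. U, contribute zero) plus one diprotic phosphate
#' group. The total is monotone non-increasing in pH and strictly negative
#' at neutral pH, where the phosphates dominate.
#'
#' @param seq a [nucleic_acid_sequence()] (a bare string is accepted).
#' @inheritParams protein_net_charge
#' @return net charge in elementary charges, vectorized over `ph`.
#' @export
rna_net_charge <- function(seq, ph, table = default_pka_table()) {
  if (is.character(seq)) seq <- nucleic_acid_sequence(seq)
  stopifnot(inherits(seq, "nucleic_acid_sequence"))
  q <- seq$n * phosphate_charge(ph, table$phosphate_pka1, table$phosphate_pka2)
  for (base in names(seq$counts)) {
    n <- seq$counts[[base]]
    pka <- table$rna_base_pka[base]
    if (n > 0 && !is.na(pka)) q <- q + n * group_charge(ph, pka, +1)
  }
  q
}

#' @rdname charge_profile
#' @export
rna_charge_profile <- function(seq, ph_grid = seq(0, 14, by = 0.01),
                               table = default_pka_table()) {
  if (is.character(seq)) seq <- nucleic_acid_sequence(seq)
  if (is.unsorted(ph_grid, strictly = TRUE))
    stop("ph_grid must be strictly ascending")
  Q <- rna_net_charge(seq, ph_grid, table)
  new_charge_profile(ph_grid, Q, n_units = seq$n, source_id = seq$id,
                     kind = "rna")
}
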