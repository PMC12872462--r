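#' Mixture components and mixture charge profiles
#'
#' A multi-component system (protein-protein, protein-RNA, or a whole
#' condensate proteome) is reconstituted electrochemically by summing the
#' per-molecule charge profiles of its components with non-negative weights
#' (molar concentration, copy number or abundance). The resulting mixture
#' charge `C(pH)` inherits monotonicity from its parts, so it crosses zero
#' at most once; that crossing is the mixture pI.
#'
#' @param profile a [charge_profile()].
#' @param weight non-negative weight.
#' @param kind `"protein"` or `"rna"`.
#' @return `mixture_component()` returns a tagged component list.
#' @export
mixture_component <- function(profile, weight = 1, kind = profile$kind) {
  stopifnot(inherits(profile, "charge_profile"), is.numeric(weight),
            length(weight) == 1L, weight >= 0)
  kind <- match.arg(kind, c("protein", "rna"))
  structure(list(profile = profile, weight = weight, kind = kind),
            class = "mixture_component")
}

resample_profile <- function(profile, ph_grid) {
  if (length(profile$ph) == length(ph_grid) &&
      all(profile$ph == ph_grid)) return(profile)
  if (min(ph_grid) < min(profile$ph) || max(ph_grid) > max(profile$ph))
    stop("cannot resample profile '", profile$source_id,
         "' onto a wider pH grid")
  Q <- stats::approx(profile$ph, profile$Q, xout = ph_grid)$y
  new_charge_profile(ph_grid, Q, profile$n_units, profile$source_id,
                     profile$kind)
}

#' Combine component charge profiles into a mixture profile
#'
#' The mixture charge is `C(pH) = sum_i w_i Q_i(pH)`, optionally rescaled:
#' * `per_sequence` - all weights equal; the sum is divided by the number
#'   of components, so `C` is the mean per-molecule charge.
#' * `weighted` - raw weighted sum (weights are molar concentrations,
#'   copy numbers or abundances).
#' * `bounded` - weighted sum rescaled by a positive constant so that its
#'   maximum equals the maximum charge of a designated reference component;
#'   a display normalization that provably never moves the zero crossing.
#'
#' Profiles on different grids are linearly resampled onto the first
#' component's grid.
#'
#' @param components list of [mixture_component()] (bare `charge_profile`s
#'   are promoted with weight 1).
#' @param normalization `"per_sequence"`, `"weighted"` or `"bounded"`.
#' @param reference index of the reference component for `"bounded"`.
#' @return object of class `mixture_profile` with fields `ph`, `C`, `q`,
#'   `q2`, `mixture_pI`, `mean_n_units`, `normalization`, `components`.
#' @export
mixture_charge_profile <- function(components,
                                   normalization = c("per_sequence",
                                                     "weighted", "bounded"),
                                   reference = 1L) {
  normalization <- match.arg(normalization)
  if (inherits(components, "mixture_component") ||
      inherits(components, "charge_profile")) components <- list(components)
  if (length(components) == 0) stop("empty component list")
  components <- lapply(components, function(x) {
    if (inherits(x, "charge_profile")) mixture_component(x) else x
  })
  stopifnot(all(vapply(components, inherits, TRUE, "mixture_component")))
  w <- vapply(components, `[[`, numeric(1), "weight")
  if (normalization == "per_sequence" && length(unique(w)) > 1L)
    stop("per_sequence normalization requires all weights equal")
  ph <- components[[1]]$profile$ph
  profs <- lapply(components, function(cm) resample_profile(cm$profile, ph))
  C <- Reduce(`+`, Map(function(p, wi) wi * p$Q, profs, w))
  scale_factor <- 1
  if (normalization == "per_sequence") {
    scale_factor <- 1 / (length(components) * w[1])
  } else if (normalization == "bounded") {
    ref_max <- max(profs[[reference]]$Q)
    if (max(C) > 0 && ref_max > 0) scale_factor <- ref_max / max(C)
  }
  C <- C * scale_factor
  # weighted mean molecule size: gives the mixture charge density q = C/<N>
  mean_n <- sum(w * vapply(profs, `[[`, numeric(1), "n_units")) / sum(w)
  out <- structure(list(ph = ph, C = C, q = C / mean_n, q2 = (C / mean_n)^2,
                        mixture_pI = NA_real_, mean_n_units = mean_n,
                        normalization = normalization,
                        scale_factor = scale_factor,
                        components = data.frame(
                          id = vapply(profs, `[[`, character(1), "source_id"),
                          weight = w,
                          kind = vapply(components, `[[`, character(1), "kind"))),
                   class = "mixture_profile")
  out$mixture_pI <- mixture_pI(out)
  out
}

#' Mixture isoelectric point
#'
#' pH at which the mixture charge profile crosses zero, located by linear
#' interpolation between the bracketing grid points of the unique sign
#' change. Returns `NA` (sentinel for "none") when the profile has constant
#' sign on the grid.
#'
#' @param profile a `mixture_profile` (or `charge_profile`).
#' @return pH of neutrality, or `NA_real_`.
#' @export
mixture_pI <- function(profile) {
  C <- if (inherits(profile, "mixture_profile")) profile$C else profile$Q
  ph <- profile$ph
  if (any(diff(C) > 1e-9 * max(1, max(abs(C)))))
    stop("non-monotone mixture profile; upstream profiles are inconsistent")
  pos <- C > 0
  if (all(pos) || all(!pos)) {
    if (all(C == 0)) return(ph[1])
    message("no neutrality point in [", min(ph), ", ", max(ph), "]")
    return(NA_real_)
  }
  i <- max(which(pos))           # last positive point; C is non-increasing
  if (i == length(C)) return(NA_real_)
  c1 <- C[i]; c2 <- C[i + 1]
  if (c2 == c1) return(ph[i])
  ph[i] + (0 - c1) * (ph[i + 1] - ph[i]) / (c2 - c1)
}

#' @export
print.mixture_profile <- function(x, ...) {
  cat(sprintf("mixture_profile: %d components (%s), mixture pI = %s\n",
              nrow(x$components), x$normalization,
              ifelse(is.na(x$mixture_pI), "none",
                     sprintf("%.3f", x$mixture_pI))))
  invisible(x)
}

#' @export
as.data.frame.mixture_profile <- function(x, ...) {
  data.frame(ph = x$ph, Q = x$C, q = x$q, q2 = x$q2)
}

#' Neutral-pH map over a two-component composition grid
#'
#' For every (protein concentration, RNA concentration) pair, computes the
#' mixture pI of the weighted two-component profile. Cells with no
#' neutrality in range carry `NA`. Increasing the RNA weight never raises
#' the neutral pH.
#'
#' @param protein,rna [charge_profile()]s of the two components.
#' @param protein_concs,rna_concs positive concentration grids (molar
#'   weights; `rna_concs` may include 0 for the protein-only limit).
#' @return matrix (rows = protein concs, cols = RNA concs) of neutral pH.
#' @export
neutral_ph_map <- function(protein, rna, protein_concs, rna_concs) {
  stopifnot(all(protein_concs > 0), all(rna_concs >= 0))
  out <- matrix(NA_real_, length(protein_concs), length(rna_concs),
                dimnames = list(protein = signif(protein_concs, 6),
                                rna = signif(rna_concs, 6)))
  for (i in seq_along(protein_concs)) {
    for (j in seq_along(rna_concs)) {
      if (rna_concs[j] == 0) {
        out[i, j] <- mixture_pI(protein)
      } else {
        mix <- mixture_charge_profile(
          list(mixture_component(protein, protein_concs[i]),
               mixture_component(rna, rna_concs[j], kind = "rna")),
          normalization = "weighted")
        out[i, j] <- mix$mixture_pI
      }
    }
  }
  out
}

#' Protein-RNA mixture from an RNA mass fraction
#'
#' Converts a mass fraction of RNA into molar weights using mean residue
#' and nucleotide masses (defaults 110 and 330 Da), then forms the weighted
#' mixture of a proteome-level profile and an RNA profile. With
#' `rna_mass_fraction = 0` the input proteome profile is returned
#' unchanged.
#'
#' @param proteome_profile `mixture_profile` (or `charge_profile`)
#'   representing the protein part; its `mean_n_units`/`n_units` supplies
#'   the mean protein length.
#' @param rna_profile [charge_profile()] of the RNA.
#' @param rna_mass_fraction fraction of total biopolymer mass that is RNA,
#'   in `[0, 1)`.
#' @param residue_mass,nucleotide_mass mean monomer masses in Da.
#' @return a `mixture_profile`.
#' @export
mass_fraction_mixture <- function(proteome_profile, rna_profile,
                                  rna_mass_fraction,
                                  residue_mass = 110,
                                  nucleotide_mass = 330) {
  if (!(rna_mass_fraction >= 0 && rna_mass_fraction < 1))
    stop("rna_mass_fraction must lie in [0, 1)")
  if (rna_mass_fraction == 0) return(proteome_profile)
  if (inherits(proteome_profile, "mixture_profile")) {
    n_prot <- proteome_profile$mean_n_units
    prot_as_profile <- new_charge_profile(
      proteome_profile$ph, proteome_profile$C, n_prot,
      source_id = "proteome_mean", kind = "protein")
  } else {
    n_prot <- proteome_profile$n_units
    prot_as_profile <- proteome_profile
  }
  f <- rna_mass_fraction
  # moles of molecules per unit total mass
  w_prot <- (1 - f) / (residue_mass * n_prot)
  w_rna <- f / (nucleotide_mass * rna_profile$n_units)
  mixture_charge_profile(
    list(mixture_component(prot_as_profile, w_prot, kind = "protein"),
         mixture_component(rna_profile, w_rna, kind = "rna")),
    normalization = "weighted")
}

#' Slope of the mixture charge at the mixture pI
#'
#' Central finite difference of `C(pH)` at the mixture pI, sign-flipped so
#' that the reported `-(dC/dpH)` is non-negative for a monotone-decreasing
#' profile. Note the slope scales with the profile normalization (doubling
#' all weights doubles it); only its ratio between systems normalized the
#' same way is meaningful.
#'
#' @param profile a `mixture_profile`.
#' @param delta half-width of the finite difference in pH units.
#' @return non-negative slope in charge per pH unit.
#' @export
charge_slope_at_pI <- function(profile, delta = 0.05) {
  pI <- profile$mixture_pI
  if (is.na(pI)) stop("profile has no mixture pI")
  C <- stats::approx(profile$ph, profile$C, xout = c(pI - delta, pI + delta))$y
  -(C[2] - C[1]) / (2 * delta)
}
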