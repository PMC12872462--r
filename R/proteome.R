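#' Proteome sets and condensate proteomes
#'
#' A `proteome_set` bundles protein sequences with optional abundances; a
#' `condensate_proteome` names a membership list (an MLO annotation or an
#' interaction-network cluster) to be resolved against a proteome set.
#'
#' @param sequences list of [protein_sequence()] objects.
#' @param abundances optional named non-negative numeric vector; names must
#'   be a subset of the sequence ids.
#' @param source_label free-text provenance label.
#' @return object of class `proteome_set`.
#' @export
proteome_set <- function(sequences, abundances = NULL,
                         source_label = "proteome") {
  stopifnot(is.list(sequences), length(sequences) >= 1L,
            all(vapply(sequences, inherits, TRUE, "protein_sequence")))
  ids <- vapply(sequences, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  names(sequences) <- ids
  if (!is.null(abundances)) {
    stopifnot(is.numeric(abundances), all(abundances >= 0))
    if (!all(names(abundances) %in% ids))
      stop("abundance ids must be a subset of sequence ids")
  }
  structure(list(sequences = sequences, abundances = abundances,
                 source_label = source_label),
            class = "proteome_set")
}

#' @export
print.proteome_set <- function(x, ...) {
  cat(sprintf("proteome_set '%s': %d sequences%s\n", x$source_label,
              length(x$sequences),
              if (is.null(x$abundances)) "" else
                sprintf(" (%d abundances)", length(x$abundances))))
  invisible(x)
}

#' @rdname proteome_set
#' @param name condensate label.
#' @param member_ids protein ids belonging to the condensate.
#' @param scaffold_flags optional logical vector parallel to `member_ids`.
#' @export
condensate_proteome <- function(name, member_ids, scaffold_flags = NULL) {
  stopifnot(is.character(name), length(member_ids) >= 1L)
  if (!is.null(scaffold_flags))
    stopifnot(is.logical(scaffold_flags),
              length(scaffold_flags) == length(member_ids))
  structure(list(name = name, member_ids = as.character(member_ids),
                 scaffold_flags = scaffold_flags),
            class = "condensate_proteome")
}

#' Isoelectric-point distribution of a proteome
#'
#' Computes a per-sequence pI, a histogram over pH 2-13 and the window
#' fractions used to describe the bimodal charge bias of natural proteomes:
#' the near-neutral valley `7 < pI < 8` and the fraction above 7. Strict
#' inequalities; boundary values excluded. Sequences whose pI cannot be
#' computed are skipped and tallied.
#'
#' @param proteome a [proteome_set()].
#' @param bin_width histogram bin width in pH units.
#' @param table an [ionizable_group_table()].
#' @return object of class `pi_distribution` with fields `pi_values`,
#'   `breaks`, `counts`, `n`, `skipped` and `window_fractions`.
#' @export
pi_distribution <- function(proteome, bin_width = 0.25,
                            table = default_pka_table()) {
  stopifnot(inherits(proteome, "proteome_set"))
  pis <- vapply(proteome$sequences, function(s) {
    tryCatch(isoelectric_point(s, table), error = function(e) NA_real_)
  }, numeric(1))
  skipped <- sum(is.na(pis))
  vals <- pis[!is.na(pis)]
  breaks <- seq(2, 13, by = bin_width)
  if (max(breaks) < 13) breaks <- c(breaks, 13)
  clipped <- pmin(pmax(vals, 2), 13)
  counts <- graphics::hist(clipped, breaks = breaks, plot = FALSE)$counts
  wf <- c(near_neutral_7_8 = mean(vals > 7 & vals < 8),
          above_7 = mean(vals > 7),
          acidic_shoulder_4.5_6.5 = mean(vals > 4.5 & vals < 6.5),
          basic_shoulder_8.5_10.5 = mean(vals > 8.5 & vals < 10.5))
  structure(list(pi_values = pis, breaks = breaks, counts = counts,
                 n = length(pis), skipped = skipped,
                 window_fractions = wf),
            class = "pi_distribution")
}

#' @export
print.pi_distribution <- function(x, ...) {
  cat(sprintf("pi_distribution: n = %d (skipped %d), 7<pI<8 fraction = %.3f\n",
              x$n, x$skipped, x$window_fractions[["near_neutral_7_8"]]))
  invisible(x)
}

#' Mixture charge profile of a condensate proteome
#'
#' Resolves condensate members against a proteome set, computes per-member
#' charge profiles and delegates to [mixture_charge_profile()], either
#' unweighted (per-sequence mean) or abundance-weighted.
#'
#' @inheritParams pi_distribution
#' @param condensate a [condensate_proteome()].
#' @param weighting `"unweighted"` or `"abundance"`.
#' @param ph_grid pH grid for the member profiles.
#' @return a `mixture_profile` (with `mixture_pI`).
#' @export
condensate_mixture_profile <- function(proteome, condensate,
                                       weighting = c("unweighted",
                                                     "abundance"),
                                       ph_grid = seq(0, 14, by = 0.01),
                                       table = default_pka_table()) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(condensate, "condensate_proteome"))
  members <- intersect(condensate$member_ids, names(proteome$sequences))
  if (length(members) == 0)
    stop("no condensate members resolve against the proteome set")
  if (weighting == "abundance") {
    if (is.null(proteome$abundances))
      stop("abundance weighting requires proteome abundances")
    members <- intersect(members, names(proteome$abundances))
    if (length(members) == 0) stop("no members with abundances")
    w <- proteome$abundances[members]
  } else {
    w <- rep(1, length(members))
  }
  comps <- Map(function(id, wi) {
    mixture_component(charge_profile(proteome$sequences[[id]], ph_grid,
                                     table), wi)
  }, members, w)
  mixture_charge_profile(unname(comps),
                         normalization = if (weighting == "unweighted")
                           "per_sequence" else "weighted")
}

#' Select the most-annotated membraneless organelles from a membership table
#'
#' Filters a PhaSepDB-v2-like annotation table to one organism (the
#' "Homo sapiens"/"Homosapien" spelling dialects are matched
#' case-insensitively), ranks MLOs by membership count and keeps the
#' `top_k` largest, breaking ties by name.
#'
#' @param records data frame with columns `organism`, `mlo`, `protein_id`.
#' @param organism organism to keep.
#' @param top_k number of MLOs to keep (default 9).
#' @return list of [condensate_proteome()] objects, largest first.
#' @export
filter_phasepdb <- function(records, organism = "Homo sapiens", top_k = 9L) {
  need <- c("organism", "mlo", "protein_id")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  dialect <- function(x) gsub("[[:space:]]", "", tolower(x))
  wanted <- dialect(organism)
  # the human entries appear under several spellings in the wild
  if (wanted %in% c("homosapiens", "homosapien"))
    wanted <- c("homosapiens", "homosapien")
  keep <- dialect(records$organism) %in% wanted
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0) {
    warning("no rows for organism '", organism, "'")
    return(list())
  }
  sizes <- sort(table(records$mlo), decreasing = TRUE)
  # deterministic tie-break by name
  ord <- order(-as.integer(sizes), names(sizes))
  sizes <- sizes[ord]
  if (top_k > length(sizes)) {
    warning("top_k exceeds the number of distinct MLOs; returning all")
    top_k <- length(sizes)
  }
  lapply(names(sizes)[seq_len(top_k)], function(m) {
    condensate_proteome(m, unique(records$protein_id[records$mlo == m]))
  })
}

#' Select condensate clusters by scaffold fraction
#'
#' Keeps clusters from a Condensate-Atlas-like table in which strictly more
#' than `min_scaffold_fraction` of the members are flagged as scaffolds.
#'
#' @param clusters data frame with columns `condensate`, `protein_id`,
#'   `scaffold_flag` (logical or 0/1).
#' @param min_scaffold_fraction threshold (default 0.5, strict).
#' @return list of [condensate_proteome()] objects.
#' @export
filter_atlas <- function(clusters, min_scaffold_fraction = 0.5) {
  need <- c("condensate", "protein_id", "scaffold_flag")
  if (!all(need %in% names(clusters)))
    stop("clusters must have columns: ", paste(need, collapse = ", "))
  flags <- as.logical(clusters$scaffold_flag)
  if (any(is.na(flags))) stop("scaffold_flag must be logical or 0/1")
  out <- lapply(split(seq_len(nrow(clusters)), clusters$condensate),
                function(idx) {
    if (mean(flags[idx]) > min_scaffold_fraction)
      condensate_proteome(clusters$condensate[idx[1]],
                          clusters$protein_id[idx],
                          scaffold_flags = flags[idx])
    else NULL
  })
  out[!vapply(out, is.null, TRUE)]
}

#' Range of the q-squared repulsion proxy around the mixture pI
#'
#' For each mixture profile, evaluates the charge-density square `q^2` at
#' `pI - offset` and `pI + offset` and reports the larger of the two; the
#' cross-profile spread is the order-of-magnitude ratio
#' `log10(max / min)`. A floor on `q^2` avoids minus infinity at exact
#' neutrality. Profiles without a mixture pI are skipped with a warning.
#'
#' @param profiles list of `mixture_profile`s.
#' @param offset pH offset from the mixture pI (default 1.5).
#' @param floor lower bound applied to `q^2` before ratios.
#' @return list with `per_profile` (data frame: id, pI, q2_low, q2_high,
#'   q2_max) and `spread_orders`.
#' @export
q2_response_range <- function(profiles, offset = 1.5, floor = 1e-8) {
  stopifnot(length(profiles) >= 1L)
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    pI <- p$mixture_pI
    if (is.na(pI)) {
      warning("profile ", i, " has no mixture pI; skipped")
      return(NULL)
    }
    q <- stats::approx(p$ph, p$q, xout = c(pI - offset, pI + offset),
                       rule = 2)$y
    q2 <- pmax(q^2, floor)
    data.frame(id = i, pI = pI, q2_low = q2[1], q2_high = q2[2],
               q2_max = max(q2))
  })
  per <- do.call(rbind, rows)
  if (is.null(per)) stop("no profiles with a mixture pI")
  list(per_profile = per,
       spread_orders = log10(max(per$q2_max) / min(per$q2_max)))
}
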