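#' Read a mixture specification from YAML
#'
#' A mixture spec is a YAML list of components, each with `id`, `fasta`
#' (path, resolved relative to the spec file), `weight` and `kind`
#' (`protein` or `rna`). Profiles are computed on `ph_grid` and wrapped as
#' [mixture_component()]s ready for [mixture_charge_profile()].
#'
#' @param path YAML file.
#' @param ph_grid pH grid for the component profiles.
#' @param table an [ionizable_group_table()].
#' @return list of [mixture_component()]s.
#' @export
read_mixture_spec <- function(path, ph_grid = seq(0, 14, by = 0.01),
                              table = default_pka_table()) {
  spec <- yaml::read_yaml(path)
  comps <- if (!is.null(spec$components)) spec$components else spec
  lapply(comps, function(cm) {
    stopifnot(!is.null(cm$fasta), !is.null(cm$kind))
    fasta <- cm$fasta
    if (!file.exists(fasta))
      fasta <- file.path(dirname(path), cm$fasta)
    w <- if (is.null(cm$weight)) 1 else cm$weight
    if (cm$kind == "protein") {
      s <- read_fasta_protein(fasta)[[1]]
      if (!is.null(cm$id)) s$id <- cm$id
      mixture_component(charge_profile(s, ph_grid, table), w,
                        kind = "protein")
    } else {
      s <- read_fasta_rna(fasta)[[1]]
      if (!is.null(cm$id)) s$id <- cm$id
      mixture_component(rna_charge_profile(s, ph_grid, table), w,
                        kind = "rna")
    }
  })
}

#' Read an abundance table (TSV with columns id, abundance)
#'
#' @param path TSV file.
#' @return named numeric vector of abundances.
#' @export
read_abundance_tsv <- function(path) {
  d <- utils::read.delim(path)
  if (!all(c("id", "abundance") %in% names(d)))
    stop("abundance table needs columns: id, abundance")
  stats::setNames(d$abundance, d$id)
}

#' Read a condensate membership table
#'
#' CSV with columns `condensate`, `protein_id` and optionally
#' `scaffold_flag` (for atlas-style tables) or `organism`/`mlo` (for
#' PhaSepDB-style tables, where `mlo` is used as the condensate label).
#'
#' @param path CSV file.
#' @return data frame.
#' @export
read_membership_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!("condensate" %in% names(d)) && "mlo" %in% names(d))
    d$condensate <- d$mlo
  if (!all(c("protein_id") %in% names(d)))
    stop("membership table needs a protein_id column")
  d
}
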