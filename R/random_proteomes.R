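#' Randomized proteome specification
#'
#' Describes how to draw a synthetic proteome: number of sequences, residue
#' composition (probabilities over the 20 standard amino acids), a length
#' model (a single fixed length, or an empirical length vector resampled
#' with replacement) and a mandatory seed. The "fully randomized" preset of
#' the study uses a uniform composition at a fixed length of 560 residues,
#' the mean human protein length.
#'
#' @param n_sequences number of sequences to draw.
#' @param composition named probability vector over the 20 standard
#'   residues (missing residues get probability 0); must sum to 1.
#' @param length_model single integer length, or an integer vector of
#'   lengths to resample empirically.
#' @param seed integer RNG seed (mandatory; generation is deterministic).
#' @return object of class `random_proteome_spec`.
#' @export
random_proteome_spec <- function(n_sequences,
                                 composition = uniform_composition(),
                                 length_model = 560L,
                                 seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_sequences >= 1, is.numeric(composition),
            all(composition >= 0), all(length_model >= 1))
  comp <- stats::setNames(rep(0, 20), standard_residues)
  bad <- setdiff(names(composition), standard_residues)
  if (length(bad)) stop("non-standard residues in composition: ",
                        paste(bad, collapse = ", "))
  comp[names(composition)] <- composition
  if (abs(sum(comp) - 1) > 1e-9) stop("composition must sum to 1")
  structure(list(n_sequences = as.integer(n_sequences), composition = comp,
                 length_model = as.integer(length_model),
                 seed = as.integer(seed)),
            class = "random_proteome_spec")
}

#' @rdname random_proteome_spec
#' @export
uniform_composition <- function() {
  stats::setNames(rep(1 / 20, 20), standard_residues)
}

#' @rdname random_proteome_spec
#' @details `human_like_composition()` returns approximate human-proteome
#'   amino-acid frequencies (literature consensus values, normalized); use
#'   [humanized_spec()] to match an actual reference proteome instead.
#' @export
human_like_composition <- function() {
  f <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, Q = 4.8, E = 7.1,
         G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.1, F = 3.7,
         P = 6.3, S = 8.3, T = 5.3, W = 1.2, Y = 2.7, V = 6.0)
  f / sum(f)
}

#' Draw a randomized proteome
#'
#' Samples sequences by concatenating residues independently at the spec's
#' composition probabilities, at lengths given by the length model.
#' Deterministic for a given seed (R's default Mersenne-Twister stream,
#' restored on exit).
#'
#' @param spec a [random_proteome_spec()].
#' @return a [proteome_set()] with ids `rp000001`, `rp000002`, ...
#' @export
sample_proteome <- function(spec) {
  stopifnot(inherits(spec, "random_proteome_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  lens <- if (length(spec$length_model) == 1L)
    rep(spec$length_model, spec$n_sequences)
  else
    sample(spec$length_model, spec$n_sequences, replace = TRUE)
  draws <- sample(standard_residues, sum(lens), replace = TRUE,
                  prob = spec$composition)
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seqs <- lapply(seq_len(spec$n_sequences), function(i) {
    protein_sequence(paste(draws[starts[i]:ends[i]], collapse = ""),
                     id = sprintf("rp%06d", i))
  })
  proteome_set(seqs, source_label = sprintf("random(seed=%d)", spec$seed))
}

#' Composition-matched ("humanized") spec from a reference proteome
#'
#' Pools the residue frequencies of a reference proteome and takes its
#' empirical length distribution, so that sampled proteomes match the
#' reference in composition and length statistics.
#'
#' @param reference a [proteome_set()].
#' @param n number of sequences for the derived spec.
#' @param seed RNG seed for the derived spec.
#' @return a [random_proteome_spec()].
#' @export
humanized_spec <- function(reference, n, seed) {
  stopifnot(inherits(reference, "proteome_set"))
  counts <- Reduce(`+`, lapply(reference$sequences,
                               function(s) s$counts[standard_residues]))
  lens <- vapply(reference$sequences, `[[`, integer(1), "n")
  random_proteome_spec(n, composition = counts / sum(counts),
                       length_model = lens, seed = seed)
}

#' Bimodality statistics of a pI distribution
#'
#' Descriptive window criterion: the distribution is called bimodal when
#' the near-neutral valley fraction (7 < pI < 8) falls below both shoulder
#' fractions (4.5-6.5 acidic, 8.5-10.5 basic). All inequalities strict.
#'
#' @param dist a [pi_distribution()].
#' @return list with `valley_fraction`, `shoulder_fractions` (length 2) and
#'   `is_bimodal`.
#' @export
bimodality_stats <- function(dist) {
  stopifnot(inherits(dist, "pi_distribution"))
  if (dist$n - dist$skipped < 100)
    warning("fewer than 100 pI values; bimodality verdict is unstable")
  wf <- dist$window_fractions
  valley <- wf[["near_neutral_7_8"]]
  shoulders <- c(acidic = wf[["acidic_shoulder_4.5_6.5"]],
                 basic = wf[["basic_shoulder_8.5_10.5"]])
  list(valley_fraction = valley, shoulder_fractions = shoulders,
       is_bimodal = valley < min(shoulders))
}
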