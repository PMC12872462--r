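#' Protein and nucleic-acid sequence objects
#'
#' Light containers around a residue string. A `protein_sequence` keeps the
#' residue string, the per-residue counts used by the charge model and the
#' length `N` that normalizes the charge density `q = Q/N`. Ambiguity codes
#' (X, B, Z, U, O, J) are tolerated: they are flagged and counted towards
#' `N` but never carry charge, so the length normalization is never silently
#' changed.
#'
#' @param residues character scalar of one-letter residue codes.
#' @param id sequence identifier.
#' @return object of class `protein_sequence` with fields `id`, `residues`,
#'   `n` (length), `counts` (named residue counts) and `n_ambiguous`.
#' @examples
#' p <- protein_sequence("GIVEQ", id = "demo")
#' p$n
#' @export
protein_sequence <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]*]", "", residues))
  if (nchar(residues) < 1L) stop("empty sequence")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  known <- c(standard_residues, ambiguity_residues)
  bad <- setdiff(unique(chars), known)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(chars, levels = known))
  n_amb <- sum(counts[ambiguity_residues])
  if (n_amb > 0)
    warning(sprintf("%d ambiguity residue(s) in '%s': zero charge, counted in N",
                    n_amb, id))
  structure(list(id = id, residues = residues, n = length(chars),
                 counts = c(counts), n_ambiguous = n_amb),
            class = "protein_sequence")
}

#' @rdname protein_sequence
#' @param bases character scalar over A, C, G, U (T is mapped to U with a
#'   warning, so DNA input is read as its transcript).
#' @export
nucleic_acid_sequence <- function(bases, id = "rna") {
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(gsub("[[:space:]]", "", bases))
  if (nchar(bases) < 1L) stop("empty sequence")
  if (grepl("T", bases, fixed = TRUE)) {
    warning("T bases mapped to U")
    bases <- gsub("T", "U", bases, fixed = TRUE)
  }
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "U"))
  if (length(bad)) stop("unknown base(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(chars, levels = c("A", "C", "G", "U")))
  structure(list(id = id, bases = bases, n = length(chars),
                 counts = c(counts)),
            class = "nucleic_acid_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("protein_sequence '%s': %d aa (%d ambiguous)\n",
              x$id, x$n, x$n_ambiguous))
  invisible(x)
}

#' @export
print.nucleic_acid_sequence <- function(x, ...) {
  cat(sprintf("nucleic_acid_sequence '%s': %d nt\n", x$id, x$n))
  invisible(x)
}

#' FASTA input/output
#'
#' Thin wrappers over Biostrings readers/writers returning package sequence
#' objects. Output is wrapped at 60 columns.
#'
#' @param path FASTA file.
#' @return `read_fasta_protein()` returns a list of [protein_sequence()];
#'   `read_fasta_rna()` a list of [nucleic_acid_sequence()].
#' @export
read_fasta_protein <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i)
    protein_sequence(as.character(set[[i]]), id = ids[i]))
  names(out) <- ids
  out
}

#' @rdname read_fasta_protein
#' @export
read_fasta_rna <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i)
    nucleic_acid_sequence(as.character(set[[i]]), id = ids[i]))
  names(out) <- ids
  out
}

#' @rdname read_fasta_protein
#' @param seqs list of sequence objects.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "protein_sequence") ||
      inherits(seqs, "nucleic_acid_sequence")) seqs <- list(seqs)
  txt <- unlist(lapply(seqs, function(s) {
    body <- if (inherits(s, "protein_sequence")) s$residues else s$bases
    c(paste0(">", s$id),
      substring(body, seq(1, nchar(body), 60),
                pmin(seq(1, nchar(body), 60) + 59, nchar(body))))
  }))
  writeLines(txt, path)
  invisible(path)
}
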