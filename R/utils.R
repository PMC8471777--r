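`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")

# residues allowed in a ProteinRecord: 20 amino acids plus X (unknown) and
# O (pre-marked hydroxyproline)
VALID_RESIDUES <- c(AA_LETTERS, "X", "O")

#' Normalize a residue string
#'
#' Uppercases a residue string and validates it against the allowed
#' alphabet (20 amino-acid letters plus `X` and `O`).
#'
#' @param residues character scalar.
#' @param id identifier used in error messages.
#' @return the uppercased string.
#' @keywords internal
#' @noRd
normalize_residues <- function(residues, id = "<sequence>") {
  res <- toupper(residues)
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% VALID_RESIDUES)
  if (length(bad)) {
    stop(sprintf("illegal residue '%s' at position %d in record '%s'",
                 chars[bad[1]], bad[1], id), call. = FALSE)
  }
  res
}

# O (hydroxyproline) counts as P for all composition and motif purposes
o_to_p <- function(residues) gsub("O", "P", residues, fixed = TRUE)

seq_chars <- function(residues) strsplit(residues, "", fixed = TRUE)[[1]]

#' Positions of hydroxylated prolines in a sequence
#'
#' Combines pre-marked `O` residues (treated as probability 1) with an
#' optional table of per-proline hydroxylation probabilities, and returns
#' the sorted positions whose probability reaches `threshold`.
#'
#' @param residues residue string (may contain `O`).
#' @param hyp_probs named numeric vector of probabilities; names are
#'   1-based proline positions. May be `NULL`.
#' @param threshold probability at or above which a proline is called
#'   hydroxylated.
#' @return integer vector of 1-based positions.
#' @export
hyp_positions <- function(residues, hyp_probs = NULL, threshold = 0.5) {
  chars <- seq_chars(toupper(residues))
  probs <- stats::setNames(numeric(0), character(0))
  if (!is.null(hyp_probs) && length(hyp_probs)) {
    stopifnot(!is.null(names(hyp_probs)))
    probs <- hyp_probs
  }
  o_pos <- which(chars == "O")
  if (length(o_pos)) {
    probs[as.character(o_pos)] <- 1
  }
  pos <- as.integer(names(probs))
  bad <- pos[pos < 1L | pos > length(chars) | !chars[pos] %in% c("P", "O")]
  if (length(bad)) {
    stop(sprintf("hydroxyproline probability given for position %d which does not hold P/O",
                 bad[1]), call. = FALSE)
  }
  sort(pos[probs >= threshold])
}
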