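# Arabinogalactan (AG) glycomodule scanning.
#
# An AG glycomodule is a dipeptide from a small alphabet (PA, PS, PT, AP,
# SP, TP, and in the extended alphabet also VP, PV, GP, PG) whose proline
# is hydroxylated. Motifs whose P/O member sits in a run of three or more
# contiguous prolines/hydroxyprolines (extensin-style, e.g. AOOO) are not
# AG motifs and are excluded before clustering.

AG_CORE_ALPHABET <- c("PA", "PS", "PT", "AP", "SP", "TP")
AG_EXTENDED_ALPHABET <- c(AG_CORE_ALPHABET, "VP", "PV", "GP", "PG")

#' AG glycomodule dipeptide alphabet
#'
#' @param extended include the four tentative dipeptides (VP, PV, GP, PG)
#'   in addition to the six canonical ones. The scanner defaults to the
#'   extended alphabet; MAAB motif coverage uses the conservative core.
#' @return character vector of dipeptides (P stands for the hydroxylated
#'   proline member).
#' @export
ag_alphabet <- function(extended = TRUE) {
  if (extended) AG_EXTENDED_ALPHABET else AG_CORE_ALPHABET
}

#' Scan parameter sets for AG motif clustering
#'
#' The relaxed scan requires at least three motifs no more than ten
#' residues apart; the strict scan at least four motifs no more than four
#' residues apart.
#'
#' @param mode `"relaxed"` or `"strict"`.
#' @return list with `min_motifs` and `max_gap`.
#' @export
scan_params <- function(mode = c("relaxed", "strict")) {
  mode <- match.arg(mode)
  if (mode == "relaxed") list(min_motifs = 3L, max_gap = 10L)
  else list(min_motifs = 4L, max_gap = 4L)
}

# positions lying in a run of >= 3 contiguous P/O residues
poly_po_positions <- function(chars) {
  po <- chars %in% c("P", "O")
  r <- rle(po)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] >= 3L) out <- c(out, starts[i]:ends[i])
  }
  out
}

#' Find AG glycomodules in a sequence
#'
#' Reports every dipeptide window matching the AG alphabet whose P/O
#' member is hydroxylated and does not lie inside a run of three or more
#' contiguous P/O residues. Overlapping motifs are all reported, sorted by
#' start.
#'
#' @param residues residue string (may contain `O`).
#' @param hyp integer vector of hydroxylated positions; defaults to the
#'   positions of pre-marked `O` residues.
#' @param extended use the 10-dipeptide alphabet (default) or the 6-motif
#'   core.
#' @return `data.frame` with columns `start`, `end`, `dipeptide`,
#'   `hyp_position`.
#' @examples
#' find_ag_motifs("QAOAOAOAATSD")   # motifs at starts 2..7
#' find_ag_motifs("AOOO")           # empty: O in a poly-O run
#' @export
find_ag_motifs <- function(residues, hyp = NULL, extended = TRUE) {
  residues <- toupper(residues)
  chars <- seq_chars(residues)
  if (is.null(hyp)) hyp <- which(chars == "O")
  alphabet <- ag_alphabet(extended)
  excluded <- poly_po_positions(chars)
  out <- data.frame(start = integer(0), end = integer(0),
                    dipeptide = character(0), hyp_position = integer(0),
                    stringsAsFactors = FALSE)
  n <- length(chars)
  if (n < 2L) return(out)
  norm <- ifelse(chars == "O", "P", chars)
  for (i in seq_len(n - 1L)) {
    dip <- paste0(norm[i], norm[i + 1L])
    if (!dip %in% alphabet) next
    p_off <- if (substr(dip, 1, 1) == "P") 0L else 1L
    p_pos <- i + p_off
    if (!p_pos %in% hyp) next
    if (p_pos %in% excluded) next
    out <- rbind(out, data.frame(start = i, end = i + 1L, dipeptide = dip,
                                 hyp_position = p_pos,
                                 stringsAsFactors = FALSE))
  }
  out[order(out$start), , drop = FALSE]
}

#' Cluster AG motifs into glycomodule spans
#'
#' Chains consecutive motifs whose gap (residues strictly between the
#' previous motif's end and the next motif's start) is at most `max_gap`,
#' and keeps maximal chains with at least `min_motifs` motifs. A chain is
#' reported once, not as all of its sub-chains.
#'
#' @param motifs motif data frame from [find_ag_motifs()], sorted by start.
#' @param params list with `min_motifs` and `max_gap` (see [scan_params()]).
#' @return list of clusters; each cluster is a list with elements
#'   `motifs` (data frame), `span_start`, `span_end` and `motif_count`.
#' @export
cluster_motifs <- function(motifs, params) {
  out <- list()
  m <- nrow(motifs)
  if (m == 0L) return(out)
  gaps <- if (m > 1L) motifs$start[-1L] - motifs$end[-m] - 1L else integer(0)
  breaks <- which(gaps > params$max_gap)
  chain_starts <- c(1L, breaks + 1L)
  chain_ends <- c(breaks, m)
  for (j in seq_along(chain_starts)) {
    idx <- chain_starts[j]:chain_ends[j]
    if (length(idx) < params$min_motifs) next
    sub <- motifs[idx, , drop = FALSE]
    out[[length(out) + 1L]] <- list(motifs = sub,
                                    span_start = sub$start[1L],
                                    span_end = sub$end[nrow(sub)],
                                    motif_count = nrow(sub))
  }
  out
}

#' Scan a sequence for AG glycomodule clusters
#'
#' @inheritParams find_ag_motifs
#' @param params scan parameters (see [scan_params()]).
#' @return list with `passes` (logical: at least one cluster found) and
#'   `clusters`.
#' @export
scan_sequence <- function(residues, hyp = NULL,
                          params = scan_params("relaxed"),
                          extended = TRUE) {
  motifs <- find_ag_motifs(residues, hyp, extended = extended)
  clusters <- cluster_motifs(motifs, params)
  list(passes = length(clusters) > 0L, clusters = clusters)
}

#' Count hydroxyprolines in AG-motif context
#'
#' Number of hydroxylated positions that are the P/O member of at least
#' one AG glycomodule. This is the quantity used to describe mature AG
#' peptides (e.g. four hydroxyprolines in AG-motif context in a 16-residue
#' mature peptide).
#'
#' @inheritParams find_ag_motifs
#' @return integer count.
#' @examples
#' hyp_in_motif_context("AOFEAFAOAOAOTAES")  # 4
#' hyp_in_motif_context("QAOAOAOAATSD")      # 3
#' @export
hyp_in_motif_context <- function(residues, hyp = NULL, extended = TRUE) {
  motifs <- find_ag_motifs(residues, hyp, extended = extended)
  length(unique(motifs$hyp_position))
}
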