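# The HRGP filtering funnel: secretion majority vote, probable
# hydroxyproline count, and stage-count reporting across the downstream
# MAAB and AG-scan stages.

#' Combine secretory-signal predictor votes
#'
#' Majority vote (2 of 3) over three boolean N-terminal secretory signal
#' predictions. When secreted, the signal end is the median cleavage
#' position among the predictors that voted "secreted"; if none of them
#' reported a cleavage site a warning is raised and the end is `NA`.
#'
#' @param votes logical vector of exactly three votes.
#' @param cleavages integer vector of three cleavage positions (last
#'   residue of the signal), `NA` where a predictor reported none.
#' @return list with `secreted` (logical) and `nsp_end` (integer or `NA`).
#' @examples
#' combine_nsp_votes(c(TRUE, TRUE, FALSE), c(26L, 26L, NA))
#' combine_nsp_votes(c(TRUE, TRUE, TRUE), c(24L, 26L, 30L))  # median: 26
#' @export
combine_nsp_votes <- function(votes, cleavages = rep(NA_integer_, 3)) {
  if (length(votes) != 3L) stop("exactly three votes required", call. = FALSE)
  secreted <- sum(votes) >= 2L
  if (!secreted) return(list(secreted = FALSE, nsp_end = NA_integer_))
  agreeing <- cleavages[votes]
  agreeing <- agreeing[!is.na(agreeing)]
  if (!length(agreeing)) {
    warning("secreted by majority vote but no agreeing predictor reported a cleavage site")
    return(list(secreted = TRUE, nsp_end = NA_integer_))
  }
  list(secreted = TRUE, nsp_end = as.integer(round(stats::median(agreeing))))
}

#' Tabulate hydroxyproline calls
#'
#' @param residues residue string (may contain pre-marked `O`).
#' @param hyp_probs named numeric vector of per-proline hydroxylation
#'   probabilities (names are 1-based positions). Pre-marked `O` residues
#'   are treated as probability 1.
#' @param threshold probability threshold for a positive call.
#' @return `data.frame` with columns `position`, `probability`, `is_hyp`.
#' @export
hyp_calls <- function(residues, hyp_probs = NULL, threshold = 0.5) {
  chars <- seq_chars(toupper(residues))
  probs <- stats::setNames(numeric(0), character(0))
  if (!is.null(hyp_probs)) probs <- hyp_probs
  o_pos <- which(chars == "O")
  if (length(o_pos)) probs[as.character(o_pos)] <- 1
  if (!length(probs)) {
    return(data.frame(position = integer(0), probability = numeric(0),
                      is_hyp = logical(0)))
  }
  pos <- as.integer(names(probs))
  ord <- order(pos)
  data.frame(position = pos[ord], probability = unname(probs)[ord],
             is_hyp = unname(probs)[ord] >= threshold)
}

#' Count probable hydroxyprolines
#'
#' @inheritParams hyp_calls
#' @return integer: number of prolines with hydroxylation probability at
#'   or above `threshold`.
#' @export
count_probable_hyp <- function(residues, hyp_probs = NULL, threshold = 0.5) {
  sum(hyp_calls(residues, hyp_probs, threshold)$is_hyp)
}

#' Rule-based hydroxylation stand-in predictor
#'
#' A transparent stand-in for a machine-learning proline hydroxylation
#' predictor, used where no external probability table is supplied: a
#' proline is marked hydroxylated (probability 1) when the P/A/S/T
#' fraction of its +/-`window` residue neighbourhood (O counting as P)
#' reaches `past_min`, else probability 0. This is a documented heuristic,
#' not a reimplementation of any published model.
#'
#' @param residues residue string.
#' @param window half-width of the neighbourhood (default 5).
#' @param past_min minimum P/A/S/T fraction (default 0.6).
#' @return named numeric vector of probabilities keyed by P/O position.
#' @export
predict_hyp_rule <- function(residues, window = 5L, past_min = 0.6) {
  chars <- seq_chars(toupper(residues))
  n <- length(chars)
  pos <- which(chars %in% c("P", "O"))
  probs <- vapply(pos, function(p) {
    lo <- max(1L, p - window); hi <- min(n, p + window)
    win <- chars[lo:hi]
    frac <- mean(win %in% c("P", "O", "A", "S", "T"))
    if (frac >= past_min) 1 else 0
  }, numeric(1))
  stats::setNames(probs, as.character(pos))
}

#' Apply the HRGP filtering funnel
#'
#' Runs the secretion majority vote and the probable-hydroxyproline count
#' over a proteome, retains sequences that are secreted and carry at least
#' `min_hyp` probable hydroxyprolines, and reports counts at every stage
#' of the funnel, including downstream MAAB classification and the relaxed
#' and strict AG motif scans on the retained set.
#'
#' @param proteome proteome data frame (see [read_fasta()]).
#' @param bundles named list of prediction bundles
#'   (see [read_prediction_table()]).
#' @param min_hyp minimum number of probable hydroxyprolines (default 3).
#' @param hyp_threshold hydroxylation probability threshold (default 0.5).
#' @return list with `records` (retained proteome rows), `bundles`
#'   (matching subset) and `report`, a `funnel_report` with counts
#'   `n_input`, `n_secreted`, `n_hyp`, `n_maab`, `n_relaxed`, `n_strict`.
#' @export
apply_funnel <- function(proteome, bundles, min_hyp = 3L,
                         hyp_threshold = 0.5) {
  n <- nrow(proteome)
  secreted <- logical(n)
  hyp_ok <- logical(n)
  for (i in seq_len(n)) {
    b <- bundles[[proteome$id[i]]]
    if (is.null(b)) stop("no prediction bundle for protein ",
                         proteome$id[i], call. = FALSE)
    v <- combine_nsp_votes(b$nsp_votes, b$nsp_cleavages)
    secreted[i] <- v$secreted
    if (secreted[i]) {
      hyp_ok[i] <- count_probable_hyp(proteome$residues[i], b$hyp_probs,
                                      hyp_threshold) >= min_hyp
    }
  }
  keep <- secreted & hyp_ok
  retained <- proteome[keep, , drop = FALSE]
  n_maab <- 0L; n_relaxed <- 0L; n_strict <- 0L
  relaxed <- scan_params("relaxed"); strict <- scan_params("strict")
  for (i in which(keep)) {
    b <- bundles[[proteome$id[i]]]
    res <- proteome$residues[i]
    hyp <- hyp_positions(res, b$hyp_probs, hyp_threshold)
    bias <- compute_bias(res)
    cov <- compute_motif_coverage(res, hyp)
    cls <- classify_maab(res, bias, cov, gpi = !is.na(b$omega_site))
    if (!is.na(cls$class_id)) n_maab <- n_maab + 1L
    if (scan_sequence(res, hyp, relaxed)$passes) n_relaxed <- n_relaxed + 1L
    if (scan_sequence(res, hyp, strict)$passes) n_strict <- n_strict + 1L
  }
  report <- structure(list(n_input = n, n_secreted = sum(secreted),
                           n_hyp = sum(keep), n_maab = n_maab,
                           n_relaxed = n_relaxed, n_strict = n_strict,
                           min_hyp = min_hyp,
                           hyp_threshold = hyp_threshold),
                      class = "funnel_report")
  list(records = retained,
       bundles = bundles[retained$id],
       report = report)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("HRGP filtering funnel\n")
  cat(sprintf("  input proteins:               %d\n", x$n_input))
  cat(sprintf("  with secretory signal:        %d\n", x$n_secreted))
  cat(sprintf("  with >= %d probable Hyp:       %d\n", x$min_hyp, x$n_hyp))
  cat(sprintf("  MAAB-classified:              %d\n", x$n_maab))
  cat(sprintf("  relaxed AG scan positive:     %d\n", x$n_relaxed))
  cat(sprintf("  strict AG scan positive:      %d\n", x$n_strict))
  invisible(x)
}
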