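# Motif and amino acid bias (MAAB) classification of candidate HRGPs.
#
# The published framework assigns 24 descriptive classes from residue-bias
# thresholds (45%) and HRGP motif coverage (15%). Only the semantics of
# classes 1 (classical GPI-AGP), 4 (classical AGP without GPI) and 24
# (biased but motif-poor) are fixed here from first principles; the
# remaining class numbers are a documented reconstruction shipped as a
# replaceable table (see maab_class_table()).

#' Amino-acid bias profile
#'
#' Fractions of the sequence made of the residue sets that constitute the
#' three HRGP motif families: P/A/S/T (AGP bias), P/S/K/Y (extensin bias)
#' and P/V/K/C (PRP bias). `O` counts as `P`.
#'
#' @param residues residue string; must be non-empty.
#' @return list with `past_fraction`, `psky_fraction`, `pvkc_fraction`.
#' @export
compute_bias <- function(residues) {
  chars <- seq_chars(o_to_p(toupper(residues)))
  if (!length(chars)) stop("cannot compute bias of an empty sequence",
                           call. = FALSE)
  list(past_fraction = mean(chars %in% c("P", "A", "S", "T")),
       psky_fraction = mean(chars %in% c("P", "S", "K", "Y")),
       pvkc_fraction = mean(chars %in% c("P", "V", "K", "C")))
}

# residues covered by regex matches (on the O->P normalized sequence)
regex_cover <- function(norm, pattern) {
  n <- nchar(norm)
  cover <- logical(n)
  count <- 0L
  m <- gregexpr(pattern, norm, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    lens <- attr(m, "match.length")
    count <- length(m)
    for (j in seq_along(m)) cover[m[j]:(m[j] + lens[j] - 1L)] <- TRUE
  }
  list(cover = cover, count = count)
}

#' HRGP motif coverage
#'
#' Fraction of the sequence covered by motifs of the three HRGP families:
#' AGP glycomodules (hydroxyproline-aware dipeptides; the conservative
#' 6-motif alphabet by default), extensin SP(3-5) motifs (S followed by
#' three to five P/O) and PRP motifs (PPVX\[KT\] and KKPCPP). Overlapping
#' residues are counted once in the union.
#'
#' @param residues residue string.
#' @param hyp hydroxylated positions (default: pre-marked `O` residues).
#' @param extended_agp use the 10-dipeptide AG alphabet instead of the
#'   6-motif core for AGP coverage (default `FALSE`).
#' @return list with per-family `count`/`fraction` (`agp`, `ext`, `prp`),
#'   the `union_fraction`, and `ext_motif_count` (number of SP(3-5) hits).
#' @export
compute_motif_coverage <- function(residues, hyp = NULL,
                                   extended_agp = FALSE) {
  residues <- toupper(residues)
  chars <- seq_chars(residues)
  n <- length(chars)
  if (!n) stop("cannot compute coverage of an empty sequence", call. = FALSE)
  norm <- o_to_p(residues)

  agp_cover <- logical(n)
  motifs <- find_ag_motifs(residues, hyp, extended = extended_agp)
  for (j in seq_len(nrow(motifs))) {
    agp_cover[motifs$start[j]:motifs$end[j]] <- TRUE
  }
  ext <- regex_cover(norm, "SP{3,5}")
  prp1 <- regex_cover(norm, "PPV.[KT]")
  prp2 <- regex_cover(norm, "KKPCPP")
  prp_cover <- prp1$cover | prp2$cover
  union_cover <- agp_cover | ext$cover | prp_cover
  cov <- function(cover) list(count = sum(cover), fraction = mean(cover))
  out <- list(agp = cov(agp_cover), ext = cov(ext$cover),
              prp = cov(prp_cover),
              union_fraction = mean(union_cover),
              ext_motif_count = ext$count)
  out
}

#' MAAB thresholds
#'
#' @param bias_min minimum residue-bias fraction (default 0.45).
#' @param coverage_min minimum motif-coverage fraction (default 0.15).
#' @param ext_motif_min minimum number of SP(3-5) motifs for an extensin
#'   call (default 2).
#' @return list of thresholds.
#' @export
maab_thresholds <- function(bias_min = 0.45, coverage_min = 0.15,
                            ext_motif_min = 2L) {
  list(bias_min = bias_min, coverage_min = coverage_min,
       ext_motif_min = ext_motif_min)
}

#' MAAB class-number table (reconstruction)
#'
#' Maps a motif-family pattern to a class number. Only classes 1, 4 and
#' 24 are anchored to their published semantics; the remaining numbers
#' are a reconstruction from the MAAB framework (family dominance by
#' motif coverage, hybrids when two families qualify) and can be replaced
#' by supplying a different table to [classify_maab()].
#'
#' @return `data.frame` with columns `key` and `class_id`.
#' @export
maab_class_table <- function() {
  data.frame(
    key = c("AGP+GPI", "AGP", "EXT", "PRP",
            "AGP/EXT", "AGP/PRP", "EXT/PRP", "AGP/EXT/PRP",
            "LOW_COVERAGE"),
    class_id = c(1L, 4L, 2L, 3L, 9L, 10L, 11L, 12L, 24L),
    stringsAsFactors = FALSE)
}

#' MAAB classification
#'
#' Assigns a MAAB class from a bias profile, motif coverage and GPI
#' status. Total and deterministic: every input receives exactly one
#' class or none.
#'
#' Decision tree: a sequence with no residue bias at or above
#' `bias_min` is unclassified; a biased sequence whose union motif
#' coverage is below `coverage_min` (or with no single family reaching
#' it) is class 24; otherwise the qualifying families (extensin calls
#' additionally require `ext_motif_min` SP(3-5) motifs) determine the
#' class via the class table, with classical AGPs split by GPI presence
#' (class 1 with, class 4 without).
#'
#' @param residues residue string (used only for validation).
#' @param bias bias profile from [compute_bias()].
#' @param coverage coverage from [compute_motif_coverage()].
#' @param gpi logical: GPI omega site predicted.
#' @param thresholds see [maab_thresholds()].
#' @param class_table replaceable class-number table
#'   (see [maab_class_table()]).
#' @param partial_c_terminus when `TRUE` the sequence lacks a C-terminus
#'   and GPI is forced to `FALSE` (GPI prediction on truncated sequences
#'   is unreliable); the result carries a `partial` flag.
#' @return list with `class_id` (integer or `NA`), `family` (`"AGP"`,
#'   `"EXT"`, `"PRP"`, a hybrid label, or `"none"`), `gpi` and `partial`.
#' @export
classify_maab <- function(residues, bias, coverage, gpi,
                          thresholds = maab_thresholds(),
                          class_table = maab_class_table(),
                          partial_c_terminus = FALSE) {
  if (partial_c_terminus) gpi <- FALSE
  none <- list(class_id = NA_integer_, family = "none", gpi = gpi,
               partial = partial_c_terminus)
  biased <- c(AGP = bias$past_fraction >= thresholds$bias_min,
              EXT = bias$psky_fraction >= thresholds$bias_min,
              PRP = bias$pvkc_fraction >= thresholds$bias_min)
  if (!any(biased)) return(none)

  lookup <- function(key) {
    hit <- class_table$class_id[class_table$key == key]
    if (!length(hit)) NA_integer_ else hit[1]
  }
  bias_family <- c("AGP", "EXT", "PRP")[which.max(c(bias$past_fraction,
                                                    bias$psky_fraction,
                                                    bias$pvkc_fraction))]
  fams <- character(0)
  if (coverage$agp$fraction >= thresholds$coverage_min) fams <- c(fams, "AGP")
  if (coverage$ext$fraction >= thresholds$coverage_min &&
      coverage$ext_motif_count >= thresholds$ext_motif_min) {
    fams <- c(fams, "EXT")
  }
  if (coverage$prp$fraction >= thresholds$coverage_min) fams <- c(fams, "PRP")

  if (coverage$union_fraction < thresholds$coverage_min || !length(fams)) {
    return(list(class_id = lookup("LOW_COVERAGE"), family = bias_family,
                gpi = gpi, partial = partial_c_terminus))
  }
  key <- paste(fams, collapse = "/")
  if (identical(fams, "AGP") && gpi) key <- "AGP+GPI"
  list(class_id = lookup(key),
       family = if (length(fams) == 1L) fams else key,
       gpi = gpi, partial = partial_c_terminus)
}

#' MAAB classification over a proteome
#'
#' Convenience wrapper running bias, coverage and classification per
#' protein.
#'
#' @param proteome proteome data frame.
#' @param bundles named list of prediction bundles.
#' @param hyp_threshold hydroxylation probability threshold.
#' @param thresholds see [maab_thresholds()].
#' @return `data.frame` with one row per protein: `id`, `class_id`,
#'   `family`, `gpi`, `past`, `psky`, `pvkc`, `coverage`.
#' @export
maab_classify_proteome <- function(proteome, bundles, hyp_threshold = 0.5,
                                   thresholds = maab_thresholds()) {
  rows <- lapply(seq_len(nrow(proteome)), function(i) {
    id <- proteome$id[i]
    res <- proteome$residues[i]
    b <- bundles[[id]] %||% empty_bundle()
    hyp <- hyp_positions(res, b$hyp_probs, hyp_threshold)
    bias <- compute_bias(res)
    cov <- compute_motif_coverage(res, hyp)
    cls <- classify_maab(res, bias, cov, gpi = !is.na(b$omega_site),
                         thresholds = thresholds)
    data.frame(id = id, class_id = cls$class_id, family = cls$family,
               gpi = cls$gpi, past = bias$past_fraction,
               psky = bias$psky_fraction, pvkc = bias$pvkc_fraction,
               coverage = cov$union_fraction, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
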