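# Per-protein architecture: integrates the secretory signal, GPI omega
# site, transmembrane topology, domain hits, hydroxyprolines and AG motif
# spans into one model; derives the mature peptide and assigns the
# chimeric-AGP family (FLA / KLA / AG peptide / classical AGP).

FASCICLIN_ACCESSION <- "PF02469"
KINASE_ACCESSIONS <- c("PF07714", "PF00069")
AG_PEPTIDE_DOMAIN <- "PF06376"
AGP_MAX_LENGTH <- 90L

#' Derive the mature peptide
#'
#' Removes the N-terminal secretory signal (residues 1..`nsp_end`) and,
#' when a GPI omega site is present, the C-terminal GPI signal from the
#' omega residue onward. The omega residue itself is excluded from the
#' mature span (matching printed spans such as 27-42 for an omega at 43);
#' it is returned separately in `omega_residue` for users preferring the
#' inclusive convention.
#'
#' @param residues full pro-peptide residue string.
#' @param nsp_end last residue of the secretory signal (`NA` if none).
#' @param omega_site GPI omega position (`NA` if none).
#' @param hyp hydroxylated positions on the full sequence (default:
#'   pre-marked `O`).
#' @return list with `start`, `end`, `residues`, `length`,
#'   `n_hyp_in_motif_context` (computed on the mature span) and
#'   `omega_residue` (single character or `NA`).
#' @export
derive_mature_peptide <- function(residues, nsp_end = NA, omega_site = NA,
                                  hyp = NULL) {
  residues <- toupper(residues)
  n <- nchar(residues)
  if (!is.na(nsp_end) && !is.na(omega_site) && nsp_end >= omega_site) {
    stop("secretory signal end (", nsp_end,
         ") must precede the omega site (", omega_site, ")", call. = FALSE)
  }
  start <- if (is.na(nsp_end)) 1L else nsp_end + 1L
  end <- if (is.na(omega_site)) n else omega_site - 1L
  if (start > end) stop("empty mature span", call. = FALSE)
  mature <- substr(residues, start, end)
  if (is.null(hyp)) hyp <- which(seq_chars(residues) == "O")
  local_hyp <- hyp[hyp >= start & hyp <= end] - start + 1L
  list(start = start, end = end, residues = mature,
       length = end - start + 1L,
       n_hyp_in_motif_context = hyp_in_motif_context(mature, local_hyp),
       omega_residue = if (is.na(omega_site)) NA_character_ else
         substr(residues, omega_site, omega_site))
}

#' Assign membrane topology
#'
#' Partitions `[1, length]` into regions. With a secretory signal the
#' region before the first transmembrane segment is extracellular; sides
#' alternate across each TM segment; without TM segments the whole
#' protein is extracellular (secreted).
#'
#' @param length sequence length.
#' @param nsp_end secretory signal end (unused for sides, kept for
#'   bookkeeping; the N-terminal side is extracellular for secreted
#'   proteins).
#' @param tm_segments data frame with columns `start`, `end`, sorted and
#'   non-overlapping.
#' @return `data.frame` with columns `start`, `end`, `side` (one of
#'   `"extracellular"`, `"membrane"`, `"intracellular"`); regions tile
#'   the sequence.
#' @export
assign_topology <- function(length, nsp_end = NA, tm_segments = NULL) {
  if (is.null(tm_segments) || nrow(tm_segments) == 0L) {
    return(data.frame(start = 1L, end = as.integer(length),
                      side = "extracellular", stringsAsFactors = FALSE))
  }
  tm <- tm_segments[order(tm_segments$start), , drop = FALSE]
  out <- data.frame(start = integer(0), end = integer(0),
                    side = character(0), stringsAsFactors = FALSE)
  side <- "extracellular"
  cursor <- 1L
  for (j in seq_len(nrow(tm))) {
    if (cursor < tm$start[j]) {
      out <- rbind(out, data.frame(start = cursor, end = tm$start[j] - 1L,
                                   side = side, stringsAsFactors = FALSE))
    }
    out <- rbind(out, data.frame(start = tm$start[j], end = tm$end[j],
                                 side = "membrane", stringsAsFactors = FALSE))
    side <- if (side == "extracellular") "intracellular" else "extracellular"
    cursor <- tm$end[j] + 1L
  }
  if (cursor <= length) {
    out <- rbind(out, data.frame(start = cursor, end = as.integer(length),
                                 side = side, stringsAsFactors = FALSE))
  }
  out
}

#' Build a per-protein architecture model
#'
#' Integrates all annotations for one protein: secretory signal end (by
#' majority vote), omega site, TM topology, domain hits, hydroxyproline
#' positions, relaxed-scan AG motif spans, and the mature peptide.
#'
#' @param id protein id.
#' @param residues residue string.
#' @param bundle prediction bundle (see [read_prediction_table()]).
#' @param domains optional domain-hit data frame for this protein; when
#'   `NULL` the bundle's `domain_hits` are used.
#' @param hyp_threshold hydroxylation probability threshold.
#' @param partial_c_terminus sequence lacks a C-terminus.
#' @return object of class `agp_architecture`.
#' @export
build_architecture <- function(id, residues, bundle, domains = NULL,
                               hyp_threshold = 0.5,
                               partial_c_terminus = FALSE) {
  residues <- toupper(residues)
  n <- nchar(residues)
  vote <- combine_nsp_votes(bundle$nsp_votes, bundle$nsp_cleavages)
  nsp_end <- if (vote$secreted) vote$nsp_end else NA_integer_
  hyp <- hyp_positions(residues, bundle$hyp_probs, hyp_threshold)
  spans <- cluster_motifs(find_ag_motifs(residues, hyp),
                          scan_params("relaxed"))
  if (is.null(domains)) domains <- bundle$domain_hits
  domains <- domains[domains$protein_id == id | !nzchar(domains$protein_id),
                     , drop = FALSE]
  mature <- tryCatch(
    derive_mature_peptide(residues, nsp_end, bundle$omega_site, hyp),
    error = function(e) NULL)
  structure(list(id = id, residues = residues, length = n,
                 nsp_end = nsp_end, omega_site = bundle$omega_site,
                 tm_segments = bundle$tm_segments,
                 domains = domains, hyp_positions = hyp,
                 ag_spans = spans,
                 topology = assign_topology(n, nsp_end, bundle$tm_segments),
                 mature = mature,
                 partial_c_terminus = partial_c_terminus),
            class = "agp_architecture")
}

span_side <- function(topology, pos) {
  row <- which(topology$start <= pos & topology$end >= pos)
  if (!length(row)) NA_character_ else topology$side[row[1]]
}

#' Assign a chimeric-AGP family label
#'
#' Priority FLA > KLA > AG peptide > classical AGP > other:
#' \itemize{
#'   \item FLA: a fasciclin (PF02469) hit plus either an AG motif span or
#'     at least three hydroxyprolines in AG-motif context;
#'   \item KLA: a protein-kinase hit (PF07714 or PF00069) plus an AG motif
#'     span; when every AG span lies intracellular the label carries an
#'     `intracellular-AG-span` warning (such calls deserve great caution);
#'   \item AG peptide: pro-peptide shorter than 90 residues (signals
#'     included) with at least one AG motif;
#'   \item classical AGP: MAAB class 1 or 4.
#' }
#'
#' @param arch an `agp_architecture`.
#' @param kinase_accessions Pfam accessions counted as kinase domains.
#' @param fasciclin_accession Pfam accession of the fasciclin domain.
#' @param agp_max_length maximum AG peptide length (default 90).
#' @return list with `label`, `evidence` (character trace) and
#'   `warnings` (character vector, possibly empty).
#' @export
assign_family <- function(arch, kinase_accessions = KINASE_ACCESSIONS,
                          fasciclin_accession = FASCICLIN_ACCESSION,
                          agp_max_length = AGP_MAX_LENGTH) {
  acc <- sub("\\..*$", "", unique(arch$domains$accession))
  motifs <- find_ag_motifs(arch$residues, arch$hyp_positions)
  n_ctx <- length(unique(motifs$hyp_position))
  warnings <- character(0)
  if (fasciclin_accession %in% acc &&
      (length(arch$ag_spans) >= 1L || n_ctx >= 3L)) {
    return(list(label = "FLA",
                evidence = sprintf("fasciclin domain + %d AG span(s), %d Hyp in motif context",
                                   length(arch$ag_spans), n_ctx),
                warnings = warnings))
  }
  if (any(kinase_accessions %in% acc) && length(arch$ag_spans) >= 1L) {
    sides <- vapply(arch$ag_spans, function(cl) {
      mid <- (cl$span_start + cl$span_end) %/% 2L
      span_side(arch$topology, mid)
    }, character(1))
    if (all(sides == "intracellular", na.rm = TRUE)) {
      warnings <- c(warnings, "intracellular-AG-span")
    }
    return(list(label = "KLA",
                evidence = sprintf("kinase domain + %d AG span(s)",
                                   length(arch$ag_spans)),
                warnings = warnings))
  }
  if (arch$length < agp_max_length && nrow(motifs) >= 1L) {
    return(list(label = "AGp",
                evidence = sprintf("length %d < %d with %d AG motif(s)",
                                   arch$length, agp_max_length, nrow(motifs)),
                warnings = warnings))
  }
  bias <- compute_bias(arch$residues)
  cov <- compute_motif_coverage(arch$residues, arch$hyp_positions)
  cls <- classify_maab(arch$residues, bias, cov,
                       gpi = !is.na(arch$omega_site),
                       partial_c_terminus = arch$partial_c_terminus)
  if (!is.na(cls$class_id) && cls$class_id %in% c(1L, 4L)) {
    return(list(label = "classicalAGP",
                evidence = sprintf("MAAB class %d", cls$class_id),
                warnings = warnings))
  }
  list(label = "other", evidence = "no family rule matched",
       warnings = warnings)
}

#' Deterministic diagram layout for an architecture
#'
#' Emits every annotated feature exactly once as a row with a role and
#' 1-based coordinates, suitable for drawing protein schematics (signal
#' segment, omega diamond, domain boxes, TM rectangles, AG motif spans,
#' hydroxyproline ticks).
#'
#' @param arch an `agp_architecture`.
#' @return `data.frame` with columns `feature`, `start`, `end`, `role`.
#' @export
render_diagram <- function(arch) {
  rows <- list(data.frame(feature = "backbone", start = 1L,
                          end = arch$length, role = "backbone",
                          stringsAsFactors = FALSE))
  add <- function(feature, start, end, role) {
    rows[[length(rows) + 1L]] <<- data.frame(feature = feature,
                                             start = as.integer(start),
                                             end = as.integer(end),
                                             role = role,
                                             stringsAsFactors = FALSE)
  }
  if (!is.na(arch$nsp_end)) add("nsp", 1L, arch$nsp_end, "signal")
  if (!is.na(arch$omega_site)) add("omega", arch$omega_site,
                                   arch$omega_site, "omega")
  for (j in seq_len(nrow(arch$domains))) {
    add(arch$domains$accession[j], arch$domains$start[j],
        arch$domains$end[j], "domain")
  }
  for (j in seq_len(nrow(arch$tm_segments))) {
    add("tm", arch$tm_segments$start[j], arch$tm_segments$end[j], "tm")
  }
  for (cl in arch$ag_spans) add("ag_span", cl$span_start, cl$span_end,
                                "ag_span")
  for (p in arch$hyp_positions) add("hyp", p, p, "hyp")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.agp_architecture <- function(x, ...) {
  cat(sprintf("<agp_architecture> %s (%d aa)\n", x$id, x$length))
  cat(sprintf("  N-sp end: %s  omega: %s  TM: %d  domains: %d\n",
              ifelse(is.na(x$nsp_end), "-", x$nsp_end),
              ifelse(is.na(x$omega_site), "-", x$omega_site),
              nrow(x$tm_segments), nrow(x$domains)))
  cat(sprintf("  hydroxyprolines: %d  AG spans: %d\n",
              length(x$hyp_positions), length(x$ag_spans)))
  if (!is.null(x$mature)) {
    cat(sprintf("  mature peptide: %d-%d (%d aa, %d Hyp in motif context)\n",
                x$mature$start, x$mature$end, x$mature$length,
                x$mature$n_hyp_in_motif_context))
  }
  invisible(x)
}
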