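#' Read a protein FASTA file
#'
#' Reads a FASTA file into a proteome data frame with one row per record.
#' Residues are uppercased and validated against the 20 amino-acid letters
#' plus `X` and `O` (`O` marks a hydroxyproline known in advance).
#'
#' @param path path to a FASTA file.
#' @return a `data.frame` with columns `id`, `description`, `residues` and
#'   `length`, of class `c("proteome", "data.frame")`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MASTPAST"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # validate residues up front with line numbers; the library parser
  # below would silently drop unknown letter codes
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, ">")) next
    chars <- strsplit(toupper(ln), "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% VALID_RESIDUES)
    if (length(bad)) {
      stop(sprintf("illegal residue '%s' at line %d", chars[bad[1]], i),
           call. = FALSE)
    }
  }
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set) %||% character(0)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    stop("malformed FASTA header: empty id in record ",
         which(!nzchar(ids))[1], call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  residues <- as.character(set)
  residues <- vapply(seq_along(residues), function(i) {
    normalize_residues(residues[i], ids[i])
  }, character(1))
  out <- data.frame(id = ids, description = desc,
                    residues = unname(residues),
                    length = nchar(residues),
                    stringsAsFactors = FALSE)
  class(out) <- c("proteome", "data.frame")
  out
}

#' Write a proteome to FASTA
#'
#' Inverse of [read_fasta()]; `read_fasta(write_fasta(x, f))` reproduces
#' `x`. Pre-marked hydroxyprolines (`O`) are preserved verbatim.
#'
#' @param proteome a proteome data frame (columns `id`, `description`,
#'   `residues`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  set <- Biostrings::AAStringSet(proteome$residues %||% character(0))
  hdr <- proteome$id
  has_desc <- nzchar(proteome$description %||% rep("", nrow(proteome)))
  hdr[has_desc] <- paste(proteome$id[has_desc], proteome$description[has_desc])
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# column indices of the hmmscan 3.x domtblout dialect we consume
DOMTBL_COLS <- list(name = 1L, accession = 2L, protein_id = 4L,
                    i_evalue = 13L, env_from = 20L, env_to = 21L)

#' Read a protein domain hit table
#'
#' Accepts either the whitespace-delimited `hmmscan --domtblout` dialect
#' (comment lines starting with `#`) or a simplified 6-column TSV
#' (`protein_id accession name start end i_evalue`). Coordinates are taken
#' from the envelope columns and are 1-based inclusive. Hits whose
#' independent e-value exceeds `evalue_cutoff` are dropped at load time.
#'
#' @param path input file.
#' @param evalue_cutoff maximum independent e-value retained (default 0.01).
#' @return `data.frame` with columns `protein_id`, `accession`, `name`,
#'   `start`, `end`, `independent_evalue`.
#' @export
read_domain_table <- function(path, evalue_cutoff = 0.01) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  rows <- lapply(keep, function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    parsed <- if (length(fields) >= 22) {
      list(protein_id = fields[DOMTBL_COLS$protein_id],
           accession = fields[DOMTBL_COLS$accession],
           name = fields[DOMTBL_COLS$name],
           start = suppressWarnings(as.integer(fields[DOMTBL_COLS$env_from])),
           end = suppressWarnings(as.integer(fields[DOMTBL_COLS$env_to])),
           independent_evalue = suppressWarnings(as.numeric(fields[DOMTBL_COLS$i_evalue])))
    } else if (length(fields) == 6) {
      list(protein_id = fields[1], accession = fields[2], name = fields[3],
           start = suppressWarnings(as.integer(fields[4])),
           end = suppressWarnings(as.integer(fields[5])),
           independent_evalue = suppressWarnings(as.numeric(fields[6])))
    } else {
      NULL
    }
    if (is.null(parsed) || is.na(parsed$start) || is.na(parsed$end) ||
        is.na(parsed$independent_evalue)) {
      stop("unparseable domain-table row at line ", i, call. = FALSE)
    }
    if (parsed$start < 1L || parsed$start > parsed$end) {
      stop("invalid domain coordinates at line ", i, call. = FALSE)
    }
    parsed
  })
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), accession = character(0),
                      name = character(0), start = integer(0),
                      end = integer(0), independent_evalue = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out[out$independent_evalue <= evalue_cutoff, , drop = FALSE]
}

empty_bundle <- function() {
  list(nsp_votes = rep(FALSE, 3),
       nsp_cleavages = rep(NA_integer_, 3),
       tm_segments = data.frame(start = integer(0), end = integer(0)),
       omega_site = NA_integer_,
       hyp_probs = stats::setNames(numeric(0), character(0)),
       domain_hits = data.frame(protein_id = character(0),
                                accession = character(0),
                                name = character(0),
                                start = integer(0), end = integer(0),
                                independent_evalue = numeric(0),
                                stringsAsFactors = FALSE))
}

#' Read a per-protein prediction table
#'
#' Reads the three-column prediction TSV (`protein_id`, `field`, `value`)
#' that carries external predictor outputs. Recognized fields:
#' \describe{
#'   \item{`nsp_vote_1` .. `nsp_vote_3`}{secretory-signal vote, value
#'     `TRUE`/`FALSE`.}
#'   \item{`nsp_cleavage`}{value `i:pos` — predictor index and the last
#'     residue of the signal it reports.}
#'   \item{`tm`}{transmembrane segment, value `start-end`.}
#'   \item{`omega`}{GPI omega site, value a single position.}
#'   \item{`hyp`}{per-proline hydroxylation probability, value `pos:prob`.}
#'   \item{`domain`}{domain hit, value `accession:start-end`.}
#' }
#' Missing sections default to empty. TM segments are sorted and must not
#' overlap.
#'
#' @param path input TSV.
#' @param proteome optional proteome data frame; when given, positions are
#'   validated against sequence lengths.
#' @return named list of prediction bundles, one per protein id.
#' @export
read_prediction_table <- function(path, proteome = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("protein_id", "field", "value"),
                           colClasses = "character", comment.char = "")
  bundles <- list()
  for (i in seq_len(nrow(tab))) {
    id <- tab$protein_id[i]; field <- tab$field[i]; value <- tab$value[i]
    if (is.null(bundles[[id]])) bundles[[id]] <- empty_bundle()
    b <- bundles[[id]]
    if (grepl("^nsp_vote_[123]$", field)) {
      k <- as.integer(sub("nsp_vote_", "", field))
      b$nsp_votes[k] <- as.logical(value)
    } else if (field == "nsp_cleavage") {
      parts <- strsplit(value, ":", fixed = TRUE)[[1]]
      b$nsp_cleavages[as.integer(parts[1])] <- as.integer(parts[2])
    } else if (field == "tm") {
      parts <- as.integer(strsplit(value, "-", fixed = TRUE)[[1]])
      b$tm_segments <- rbind(b$tm_segments,
                             data.frame(start = parts[1], end = parts[2]))
    } else if (field == "omega") {
      b$omega_site <- as.integer(value)
    } else if (field == "hyp") {
      parts <- strsplit(value, ":", fixed = TRUE)[[1]]
      b$hyp_probs[parts[1]] <- as.numeric(parts[2])
    } else if (field == "domain") {
      parts <- strsplit(value, ":", fixed = TRUE)[[1]]
      span <- as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]])
      b$domain_hits <- rbind(b$domain_hits,
                             data.frame(protein_id = id, accession = parts[1],
                                        name = parts[1], start = span[1],
                                        end = span[2],
                                        independent_evalue = 0,
                                        stringsAsFactors = FALSE))
    } else {
      stop("unknown prediction field '", field, "' at row ", i,
           call. = FALSE)
    }
    bundles[[id]] <- b
  }
  for (id in names(bundles)) {
    tm <- bundles[[id]]$tm_segments
    if (nrow(tm) > 1) {
      tm <- tm[order(tm$start), , drop = FALSE]
      if (any(tm$start[-1] <= tm$end[-nrow(tm)])) {
        stop("overlapping TM segments for protein ", id, call. = FALSE)
      }
      rownames(tm) <- NULL
      bundles[[id]]$tm_segments <- tm
    }
  }
  if (!is.null(proteome)) {
    lens <- stats::setNames(proteome$length, proteome$id)
    for (id in intersect(names(bundles), names(lens))) {
      om <- bundles[[id]]$omega_site
      if (!is.na(om) && om > lens[[id]]) {
        stop("omega site ", om, " beyond sequence length for protein ", id,
             call. = FALSE)
      }
    }
  }
  bundles
}

#' Write a prediction table
#'
#' Inverse of [read_prediction_table()]; round-trips losslessly.
#'
#' @param bundles named list of prediction bundles.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(bundles, path) {
  lines <- character(0)
  emit <- function(id, field, value) {
    lines[[length(lines) + 1]] <<- paste(id, field, value, sep = "\t")
  }
  for (id in names(bundles)) {
    b <- bundles[[id]]
    for (k in 1:3) {
      emit(id, paste0("nsp_vote_", k), as.character(b$nsp_votes[k]))
      if (!is.na(b$nsp_cleavages[k])) {
        emit(id, "nsp_cleavage", paste0(k, ":", b$nsp_cleavages[k]))
      }
    }
    if (nrow(b$tm_segments)) {
      for (j in seq_len(nrow(b$tm_segments))) {
        emit(id, "tm", paste0(b$tm_segments$start[j], "-", b$tm_segments$end[j]))
      }
    }
    if (!is.na(b$omega_site)) emit(id, "omega", as.character(b$omega_site))
    if (length(b$hyp_probs)) {
      for (p in names(b$hyp_probs)) {
        emit(id, "hyp", paste0(p, ":", format(b$hyp_probs[[p]], digits = 15)))
      }
    }
    if (nrow(b$domain_hits)) {
      for (j in seq_len(nrow(b$domain_hits))) {
        emit(id, "domain", paste0(b$domain_hits$accession[j], ":",
                                  b$domain_hits$start[j], "-",
                                  b$domain_hits$end[j]))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Reads a long-format CSV with columns `gene,sample,replicate,ct` into a
#' Ct table object carrying the control sample and reference genes.
#'
#' @param path input CSV.
#' @param control_sample id of the calibrator sample (e.g. the 0-min or
#'   rosette-leaf sample).
#' @param reference_genes character vector of reference (housekeeping)
#'   gene ids; their per-replicate arithmetic mean Ct is the normalizer.
#' @return an object of class `ct_table`: a list with elements `data`
#'   (the long data frame), `genes`, `samples`, `control_sample` and
#'   `reference_genes`.
#' @export
read_ct_table <- function(path, control_sample, reference_genes) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  ct_table(dat, control_sample, reference_genes)
}

#' Construct a Ct table from a data frame
#'
#' @param data data frame with columns `gene`, `sample`, `replicate`, `ct`.
#' @inheritParams read_ct_table
#' @return an object of class `ct_table`.
#' @export
ct_table <- function(data, control_sample, reference_genes) {
  need <- c("gene", "sample", "replicate", "ct")
  if (!all(need %in% names(data))) {
    stop("Ct table must have columns gene, sample, replicate, ct",
         call. = FALSE)
  }
  if (!all(is.finite(data$ct))) stop("non-finite Ct value", call. = FALSE)
  genes <- unique(data$gene)
  samples <- unique(data$sample)
  if (!control_sample %in% samples) {
    stop("control sample '", control_sample, "' absent from Ct table",
         call. = FALSE)
  }
  missing_ref <- setdiff(reference_genes, genes)
  if (length(missing_ref)) {
    stop("reference gene '", missing_ref[1], "' absent from Ct table",
         call. = FALSE)
  }
  structure(list(data = data, genes = genes, samples = samples,
                 control_sample = control_sample,
                 reference_genes = reference_genes),
            class = "ct_table")
}

#' Write a Ct table to CSV
#'
#' @param ct a `ct_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.csv(ct$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
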