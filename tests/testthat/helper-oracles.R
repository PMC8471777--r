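# Independent brute-force oracles used to check the scanner, clusterer
# and tree builder against a second, deliberately naive implementation.

# every dipeptide window matching the AG alphabet with a hydroxylated,
# non-poly-run P member; checks each window from first principles
brute_force_motifs <- function(residues, hyp = NULL, extended = TRUE) {
  chars <- strsplit(toupper(residues), "")[[1]]
  if (is.null(hyp)) hyp <- which(chars == "O")
  alphabet <- if (extended) {
    c("PA", "PS", "PT", "AP", "SP", "TP", "VP", "PV", "GP", "PG")
  } else {
    c("PA", "PS", "PT", "AP", "SP", "TP")
  }
  in_run <- function(p) {
    lo <- p; hi <- p
    while (lo > 1 && chars[lo - 1] %in% c("P", "O")) lo <- lo - 1
    while (hi < length(chars) && chars[hi + 1] %in% c("P", "O")) hi <- hi + 1
    (hi - lo + 1) >= 3
  }
  starts <- integer(0)
  if (length(chars) >= 2) {
    for (i in 1:(length(chars) - 1)) {
      a <- chars[i]; b <- chars[i + 1]
      a <- if (a == "O") "P" else a
      b <- if (b == "O") "P" else b
      dip <- paste0(a, b)
      if (!dip %in% alphabet) next
      p_pos <- if (a == "P") i else i + 1
      if (!p_pos %in% hyp) next
      if (in_run(p_pos)) next
      starts <- c(starts, i)
    }
  }
  starts
}

# all maximal contiguous runs of sorted motif windows whose internal gaps
# are <= max_gap, kept if they hold >= min_motifs motifs; enumerated by
# testing every contiguous subsequence
brute_force_clusters <- function(starts, min_motifs, max_gap) {
  ends <- starts + 1L
  m <- length(starts)
  if (m == 0) return(list())
  valid <- function(i, j) {
    if (i == j) return(TRUE)
    all(starts[(i + 1):j] - ends[i:(j - 1)] - 1L <= max_gap)
  }
  out <- list()
  for (i in 1:m) for (j in i:m) {
    if (!valid(i, j)) next
    maximal <- (i == 1 || !valid(i - 1, j)) && (j == m || !valid(i, j + 1))
    if (!maximal || (j - i + 1) < min_motifs) next
    out[[length(out) + 1]] <- c(span_start = starts[i], span_end = ends[j],
                                motif_count = j - i + 1L)
  }
  out
}

# random test sequence rich in scanner-relevant structure
random_scan_sequence <- function(max_len = 60) {
  len <- sample(0:max_len, 1)
  pool <- c("A", "S", "T", "P", "O", "V", "G", "E", "K", "L", "F", "D")
  weights <- c(3, 3, 3, 4, 4, 2, 2, 1, 1, 1, 1, 1)
  paste(sample(pool, len, replace = TRUE, prob = weights), collapse = "")
}

# random additive distance matrix with known generating tree
random_additive_matrix <- function(n) {
  tree <- ape::rtree(n, rooted = FALSE)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.5, 3)
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}
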