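# Alignment-free k-mer phylogeny for short, highly divergent AG peptides:
# 3-mer count profiles, a fractional-common-k-mer distance, two-stage
# homolog selection, neighbor joining, nonparametric bootstrap over k-mer
# word types, and collapsing of weakly supported edges.

#' Count k-mer words in a protein sequence
#'
#' Sliding-window counts of k-length amino-acid words. `O` is mapped to
#' `P` first (hydroxylation marking is a prediction, not sequence), and
#' windows containing `X` are skipped.
#'
#' @param residues residue string.
#' @param k word length (default 3).
#' @return list with `counts` (named integer vector) and `total_windows`
#'   (number of counted windows). A sequence shorter than `k` yields an
#'   empty profile with a warning.
#' @export
kmer_counts <- function(residues, k = 3L) {
  residues <- o_to_p(toupper(residues))
  n <- nchar(residues)
  if (n < k) {
    warning("sequence shorter than k: empty k-mer profile")
    return(list(counts = stats::setNames(integer(0), character(0)),
                total_windows = 0L))
  }
  words <- substring(residues, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  words <- words[!grepl("X", words, fixed = TRUE)]
  counts <- table(words)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       total_windows = length(words))
}

# fraction of common k-mers between two profiles
kmer_fraction <- function(a, b) {
  denom <- min(a$total_windows, b$total_windows)
  if (denom == 0L) stop("empty k-mer profile", call. = FALSE)
  shared <- intersect(names(a$counts), names(b$counts))
  sum(pmin(a$counts[shared], b$counts[shared])) / denom
}

#' Alignment-free k-mer distance between two sequences
#'
#' Distance based on the fraction of common k-mers,
#' `F = sum_w min(count_a(w), count_b(w)) / (min(L_a, L_b) - k + 1)`,
#' transformed as `d = -ln(0.1 + 0.9 F)` (so identical profiles give 0
#' and fully disjoint profiles give `-ln(0.1) ~ 2.30`). The raw `1 - F`
#' variant is available via `transform = "raw"`. The formula is a pinned
#' reconstruction of the common fractional-k-mer distance, stated here
#' explicitly so results are reproducible.
#'
#' @param a,b residue strings or profiles from [kmer_counts()].
#' @param k word length (default 3).
#' @param transform `"log"` (default) or `"raw"`.
#' @return non-negative distance.
#' @export
kmer_distance <- function(a, b, k = 3L, transform = c("log", "raw")) {
  transform <- match.arg(transform)
  if (is.character(a)) a <- kmer_counts(a, k)
  if (is.character(b)) b <- kmer_counts(b, k)
  f <- kmer_fraction(a, b)
  if (transform == "log") max(0, -log(0.1 + 0.9 * f)) else 1 - f
}

#' Pairwise k-mer distance matrix
#'
#' @param sequences named character vector of residue strings.
#' @param k word length.
#' @param transform see [kmer_distance()].
#' @return symmetric matrix with zero diagonal, dimnames = sequence ids.
#' @export
kmer_dist_matrix <- function(sequences, k = 3L,
                             transform = c("log", "raw")) {
  transform <- match.arg(transform)
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named", call. = FALSE)
  profiles <- lapply(sequences, kmer_counts, k = k)
  n <- length(sequences)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- kmer_distance(profiles[[i]], profiles[[j]],
                                          k = k, transform = transform)
    }
  }
  d
}

#' Two-stage nearest-homolog selection
#'
#' For each query, stage 1 keeps the `per_species` nearest pool sequences
#' per species; stage 2 keeps the `final` nearest among the stage-1
#' survivors. A pool entry with the same id as the query is excluded.
#' Ties are broken by id order.
#'
#' @param queries named character vector of query sequences.
#' @param pool named character vector of candidate homolog sequences.
#' @param species named character vector mapping pool ids to species.
#' @param per_species stage-1 keep per species (default 5).
#' @param final stage-2 keep overall (default 5).
#' @param k k-mer length for distances.
#' @return named list: for each query id, the character vector of
#'   selected pool ids (nearest first).
#' @export
select_homologs <- function(queries, pool, species, per_species = 5L,
                            final = 5L, k = 3L) {
  stopifnot(!is.null(names(queries)), !is.null(names(pool)))
  qprof <- lapply(queries, kmer_counts, k = k)
  pprof <- lapply(pool, kmer_counts, k = k)
  out <- list()
  for (q in names(queries)) {
    cand <- setdiff(names(pool), q)
    d <- vapply(cand, function(p) kmer_distance(qprof[[q]], pprof[[p]], k = k),
                numeric(1))
    stage1 <- character(0)
    for (sp in sort(unique(species[cand]))) {
      ids <- cand[species[cand] == sp]
      ids <- ids[order(d[ids], ids)]
      stage1 <- c(stage1, utils::head(ids, per_species))
    }
    stage1 <- stage1[order(d[stage1], stage1)]
    out[[q]] <- utils::head(stage1, final)
  }
  out
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on a distance matrix; exactly
#' recovers additive matrices. Thin wrapper keeping the module surface;
#' accepts any user-supplied distance matrix, so alignment-derived
#' distances can be fed in as well.
#'
#' @param d symmetric distance matrix or `dist`, with at least 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa",
                         call. = FALSE)
  ape::nj(d)
}

# distance matrix from a seqs x words count matrix (columns may carry
# bootstrap multiplicity); totals are recomputed from the given columns
dist_from_counts <- function(counts, transform = "log") {
  n <- nrow(counts)
  totals <- rowSums(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    denom <- min(totals[i], totals[j])
    # a replicate may resample only word types absent from a sequence;
    # such a sequence shares nothing, F = 0
    f <- if (denom == 0) 0 else sum(pmin(counts[i, ], counts[j, ])) / denom
    d[i, j] <- d[j, i] <- if (transform == "log") {
      max(0, -log(0.1 + 0.9 * f))
    } else 1 - f
  }
  d
}

#' Bootstrap support for an alignment-free NJ tree
#'
#' Builds the NJ tree from the k-mer distance matrix and assesses cluster
#' stability with a nonparametric bootstrap: each replicate resamples the
#' k-mer word types (columns of the count table) with replacement — the
#' standard surrogate for site resampling in alignment-free data — then
#' rebuilds distances and the NJ tree. Support of an internal edge is the
#' number of replicates (out of `B`) whose tree contains the same
#' bipartition, stored in `node.label`.
#'
#' @param sequences named character vector (at least 3).
#' @param k k-mer length (default 3).
#' @param B bootstrap replicates (default 100).
#' @param seed RNG seed for reproducible resampling.
#' @return a `phylo` tree whose `node.label` holds bootstrap counts
#'   (the root label is empty).
#' @export
bootstrap_support <- function(sequences, k = 3L, B = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- names(sequences)
  profiles <- lapply(sequences, kmer_counts, k = k)
  words <- sort(unique(unlist(lapply(profiles, function(p) names(p$counts)))))
  counts <- matrix(0L, length(sequences), length(words),
                   dimnames = list(ids, words))
  for (i in seq_along(profiles)) {
    counts[i, names(profiles[[i]]$counts)] <- profiles[[i]]$counts
  }
  tree <- nj_tree(dist_from_counts(counts, transform = "log"))
  boot <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(counts), replace = TRUE)
    boot[[b]] <- nj_tree(dist_from_counts(counts[, cols, drop = FALSE]))
  }
  supports <- ape::prop.clades(tree, boot, rooted = FALSE)
  supports[is.na(supports)] <- 0L
  labels <- as.character(supports)
  labels[1] <- ""  # root pseudo-node carries no bipartition
  tree$node.label <- labels
  tree
}

#' Collapse weakly supported edges into multichotomies
#'
#' Contracts every internal edge whose bootstrap support is at or below
#' `threshold`, producing multichotomies; the leaf set is unchanged and
#' the operation is idempotent.
#'
#' @param tree a `phylo` with numeric `node.label` supports (non-numeric
#'   or empty labels, e.g. the root, are kept).
#' @param threshold support at or below which an edge is collapsed
#'   (default 50, of 100 replicates).
#' @return the collapsed `phylo`.
#' @export
collapse_low_support <- function(tree, threshold = 50) {
  repeat {
    ntip <- length(tree$tip.label)
    sup <- suppressWarnings(as.numeric(tree$node.label))
    root <- ntip + 1L
    nodes <- (ntip + 1L):(ntip + tree$Nnode)
    bad <- nodes[!is.na(sup) & sup <= threshold & nodes != root]
    if (!length(bad)) return(tree)
    node <- bad[1]
    edge_in <- which(tree$edge[, 2] == node)
    parent <- tree$edge[edge_in, 1]
    child_edges <- which(tree$edge[, 1] == node)
    tree$edge[child_edges, 1] <- parent
    tree$edge <- tree$edge[-edge_in, , drop = FALSE]
    if (!is.null(tree$edge.length)) {
      tree$edge.length <- tree$edge.length[-edge_in]
    }
    tree$edge[tree$edge > node] <- tree$edge[tree$edge > node] - 1L
    tree$node.label <- tree$node.label[-(node - ntip)]
    tree$Nnode <- tree$Nnode - 1L
    class(tree) <- "phylo"
  }
}

#' Write / read a Newick tree
#'
#' Round-trip preserving topology, branch lengths and internal-node
#' support labels.
#'
#' @param tree a `phylo`.
#' @param path file path.
#' @return `write_newick`: `path`, invisibly; `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
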