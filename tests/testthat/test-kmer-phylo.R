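test_that("k-mer counting slides windows, maps O to P and skips X", {
  p <- kmer_counts("AAAA", k = 3)
  expect_equal(p$counts, c(AAA = 2L))
  expect_equal(p$total_windows, 2L)
  # hydroxylation marking must not alter the profile
  expect_equal(kmer_counts("QAOAOAOAATSD")$counts,
               kmer_counts("QAPAPAPAATSD")$counts)
  # brute-force window recount
  s <- "QAPAPAPAATSD"
  want <- table(substring(s, 1:10, 3:12))
  got <- kmer_counts(s)$counts
  expect_equal(got[order(names(got))],
               stats::setNames(as.integer(want), names(want)))
  # windows containing X are not counted
  expect_equal(kmer_counts("AAXAA", k = 3)$total_windows, 0L)
  expect_warning(p2 <- kmer_counts("AB", k = 3), "shorter")
  expect_equal(p2$total_windows, 0L)
})

test_that("the k-mer distance has its closed-form anchors and symmetry", {
  expect_equal(kmer_distance("ASTGAVLIK", "ASTGAVLIK"), 0)
  # disjoint 3-mer sets: F = 0, d = -ln(0.1)
  expect_equal(kmer_distance("AAAAAA", "SSSSSS"), -log(0.1))
  expect_equal(kmer_distance("AAAAAA", "SSSSSS", transform = "raw"), 1)
  set.seed(31)
  for (i in 1:20) {
    a <- random_scan_sequence(40); b <- random_scan_sequence(40)
    if (nchar(a) < 3 || nchar(b) < 3) next
    expect_equal(kmer_distance(a, b), kmer_distance(b, a))
    expect_gte(kmer_distance(a, b), 0)
  }
  d <- kmer_dist_matrix(c(s1 = "APSAPSAPS", s2 = "APSAPSAPT",
                          s3 = "GGGVVVLLL"))
  expect_equal(d, t(d))
  expect_equal(diag(d), c(s1 = 0, s2 = 0, s3 = 0))
})

test_that("two-stage homolog selection matches a brute-force sort", {
  set.seed(17)
  pool <- character(0); species <- character(0)
  for (sp in c("spA", "spB", "spC")) {
    for (i in 1:10) {
      id <- paste0(sp, "_", i)
      pool[id] <- paste0(random_scan_sequence(30), "APSAPS")
      species[id] <- sp
    }
  }
  queries <- c(q1 = "APSAPSAPSAPS", q2 = "TPTPTPGEGEGE")
  sel <- select_homologs(queries, pool, species, per_species = 5, final = 5)
  for (q in names(queries)) {
    d <- vapply(pool, function(s) kmer_distance(queries[[q]], s), 0)
    stage1 <- unlist(lapply(split(names(pool), species), function(ids) {
      ids[order(d[ids], ids)][1:5]
    }), use.names = FALSE)
    want <- stage1[order(d[stage1], stage1)][1:5]
    expect_equal(sel[[q]], want)
    expect_length(sel[[q]], 5L)
  }
  # a pool smaller than `final` is returned whole; the query excludes itself
  small <- c(a = "APSAPSAPS", b = "TPTPTPTPT")
  sel2 <- select_homologs(c(a = "APSAPSAPS"), small,
                          c(a = "sp1", b = "sp1"), final = 5)
  expect_equal(sel2$a, "b")
})

test_that("neighbor joining exactly recovers additive matrices", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    gen <- random_additive_matrix(n)
    tree <- nj_tree(gen$d)
    # additivity: path distances on the NJ tree equal the input matrix
    got <- ape::cophenetic.phylo(tree)[rownames(gen$d), colnames(gen$d)]
    expect_equal(got, gen$d, tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(gen$tree)), 0,
                 ignore_attr = TRUE)
    # taxon order must not matter for the unrooted topology
    perm <- sample(n)
    tree2 <- nj_tree(gen$d[perm, perm])
    expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(tree2)), 0,
                 ignore_attr = TRUE)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("bootstrap support is deterministic, bounded and maximal for duplicates", {
  seqs <- c(dup1 = "APSAPSAPSAPSGEG", dup2 = "APSAPSAPSAPSGEG",
            far1 = "KLVKLVKLVKLVKLV", far2 = "GEGGEGGEGGEGGEG",
            far3 = "TYTYTYTYTYTYTYT", far4 = "DWDWDWDWDWDWDWD")
  tr <- bootstrap_support(seqs, B = 50, seed = 99)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 50))
  # the exact-duplicate cherry appears in every replicate
  cherry <- vapply((length(seqs) + 1):(length(seqs) + tr$Nnode), function(nd) {
    tips <- ape::extract.clade(tr, nd)$tip.label
    setequal(tips, c("dup1", "dup2"))
  }, logical(1))
  expect_true(any(cherry))
  expect_equal(as.numeric(tr$node.label[which(cherry)]), 50)
  tr2 <- bootstrap_support(seqs, B = 50, seed = 99)
  expect_equal(ape::write.tree(tr), ape::write.tree(tr2))
})

test_that("low-support collapsing contracts edges, is idempotent and keeps leaves", {
  tr <- ape::read.tree(text = "((a:1,b:1)90:1,(c:1,d:1)40:1,(e:1,f:1)50:1);")
  col <- collapse_low_support(tr, threshold = 50)
  expect_setequal(col$tip.label, tr$tip.label)
  # the 40 and 50 nodes collapse, the 90 cherry stays
  expect_equal(col$Nnode, 2L)
  expect_equal(ape::write.tree(collapse_low_support(col, 50)),
               ape::write.tree(col))
  # hand-contracted reference topology
  want <- ape::read.tree(text = "((a:1,b:1)90:1,c:1,d:1,e:1,f:1);")
  expect_equal(ape::dist.topo(col, want), 0, ignore_attr = TRUE)
  # all supports high: unchanged; all low: star
  hi <- ape::read.tree(text = "((a:1,b:1)99:1,(c:1,d:1)98:1,e:1);")
  expect_equal(ape::write.tree(collapse_low_support(hi, 50)),
               ape::write.tree(hi))
  lo <- ape::read.tree(text = "((a:1,b:1)10:1,(c:1,d:1)20:1,e:1);")
  star <- collapse_low_support(lo, 50)
  expect_equal(star$Nnode, 1L)
})

test_that("Newick round-trips preserve topology, lengths and supports", {
  set.seed(5)
  for (i in 1:10) {
    tr <- ape::rtree(sample(4:9, 1), rooted = FALSE)
    tr$node.label <- as.character(sample(0:100, tr$Nnode))
    f <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, f)
    back <- read_newick(f)
    expect_equal(back$tip.label, tr$tip.label)
    expect_equal(back$node.label, tr$node.label)
    expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-8)
  }
  star <- ape::read.tree(text = "(a:1,b:2,c:3,d:4);")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(star, f)
  expect_equal(read_newick(f)$Nnode, 1L)
})
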