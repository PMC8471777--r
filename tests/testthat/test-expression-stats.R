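noise_free_wounding <- function() {
  sc <- wounding_scenario()
  sc$sigma <- 0
  sc
}

test_that("delta-delta-Ct recovers planted fold changes exactly at zero noise", {
  gen <- make_wounding_ct(noise_free_wounding(), seed = 1)
  rel <- relative_expression(gen$ct)
  prof <- rel_expr_profiles(rel)
  traj <- wounding_scenario()$trajectories
  expect_equal(prof[rownames(traj), colnames(traj)], traj)
  # a 6.5-cycle Ct drop at the peak is a 6.5 log2 fold change
  expect_equal(prof["w1", "6h"], 6.5)
  expect_equal(prof["w1", "0min"], 0)
})

test_that("control-sample mean expression is exactly zero for every gene", {
  gen <- make_wounding_ct(seed = 42)   # noisy defaults
  rel <- relative_expression(gen$ct)
  ctrl <- rel[rel$sample == attr(rel, "control_sample"), ]
  means <- tapply(ctrl$log2_rel, ctrl$gene, mean)
  expect_equal(as.vector(means), rep(0, length(means)), tolerance = 1e-12)
})

test_that("amplification efficiency scales the log2 fold change", {
  gen <- make_wounding_ct(noise_free_wounding(), seed = 1)
  rel <- relative_expression(gen$ct, efficiency = 4)
  prof <- rel_expr_profiles(rel)
  expect_equal(prof["w1", "6h"], 13)   # -ddCt * log2(4)
})

test_that("t-tests against the control match a hand computation", {
  dat <- rbind(
    data.frame(gene = "g", sample = "ctrl", replicate = 1:3,
               ct = c(24.0, 24.2, 24.4)),
    data.frame(gene = "g", sample = "t1", replicate = 1:3,
               ct = c(22.0, 22.3, 22.1)),
    data.frame(gene = "ref", sample = "ctrl", replicate = 1:3, ct = 20),
    data.frame(gene = "ref", sample = "t1", replicate = 1:3, ct = 20))
  ct <- ct_table(dat, "ctrl", "ref")
  rel <- relative_expression(ct)
  tests <- test_vs_control(rel, method = "student")
  x <- rel$log2_rel[rel$gene == "g" & rel$sample == "t1"]
  y <- rel$log2_rel[rel$gene == "g" & rel$sample == "ctrl"]
  sp <- sqrt((2 * var(x) + 2 * var(y)) / 4)
  tstat <- (mean(x) - mean(y)) / (sp * sqrt(2 / 3))
  expect_equal(tests$p, 2 * stats::pt(-abs(tstat), df = 4))
  expect_equal(tests$mean_log2fc, mean(x))

  welch <- test_vs_control(rel, method = "welch")
  expect_equal(welch$mean_log2fc, tests$mean_log2fc)

  # single replicates cannot be tested
  one <- dat[dat$replicate == 1, ]
  expect_error(test_vs_control(relative_expression(ct_table(one, "ctrl", "ref"))),
               "2 replicates")
})

test_that("identical groups are non-significant", {
  dat <- rbind(
    data.frame(gene = "g", sample = "ctrl", replicate = 1:3,
               ct = c(24.0, 24.5, 25.0)),
    data.frame(gene = "g", sample = "t1", replicate = 1:3,
               ct = c(24.0, 24.5, 25.0)),
    data.frame(gene = "ref", sample = "ctrl", replicate = 1:3, ct = 20),
    data.frame(gene = "ref", sample = "t1", replicate = 1:3, ct = 20))
  tests <- test_vs_control(relative_expression(ct_table(dat, "ctrl", "ref")),
                           method = "student")
  expect_equal(tests$p, 1)
})

test_that("Benjamini-Hochberg step-up matches the hand computation", {
  expect_equal(adjust_bh(0.02), 0.02)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.003, 0.04, 0.2, 0.9)
  shuffled <- adjust_bh(p[c(3, 1, 4, 2)])
  expect_equal(shuffled[c(2, 4, 1, 3)], adjust_bh(p))
  expect_true(all(adjust_bh(p) >= p))
})

test_that("result flagging combines significance and a strict effect threshold", {
  tests <- data.frame(gene = c("a", "b", "c"), sample = "t1",
                      mean_log2fc = c(2.5, 0.5, 2.0),
                      p = c(0.001, 0.0001, 0.0005))
  flagged <- flag_results(tests)
  expect_true(flagged$sig05[1] && flagged$highlighted[1])
  expect_true(flagged$sig01[2] && !flagged$highlighted[2])
  # a fold change of exactly 2 is not a large effect
  expect_false(flagged$large_effect[3])
  expect_true(all(flagged$p_adj >= flagged$p))
})

test_that("Pearson clustering has exact anchors and a valid dendrogram", {
  prof <- rbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
                c = c(5, 4, 3, 2, 1), d = c(2, 1, 4, 3, 5))
  pc <- pearson_cluster(prof)
  expect_equal(pc$r["a", "b"], 1)
  expect_equal(pc$r["a", "c"], -1)
  expect_equal(as.matrix(pc$dist)["a", "b"], 0)
  expect_equal(as.matrix(pc$dist)["a", "c"], 2)
  expect_true(all(diff(pc$hclust$height) >= -1e-12))
  expect_true(is.na(pc$p["a", "a"]))
})

test_that("BCMI vanishes for independent pairs and ranks dependence", {
  set.seed(77)
  x <- rnorm(500); y <- rnorm(500)
  expect_lt(abs(bcmi(x, y)), 0.1)
  # deterministic monotone dependence beats independence
  z <- rnorm(100)
  expect_gt(bcmi(z, z^3), bcmi(rnorm(100), rnorm(100)))
  # self-BCMI is the maximal entry of a gene's row
  prof <- matrix(rnorm(4 * 30), 4, 30,
                 dimnames = list(paste0("g", 1:4), NULL))
  m <- bcmi_matrix(prof)
  expect_equal(m, t(m))
  for (i in 1:4) expect_equal(which.max(m[i, ]), i, ignore_attr = TRUE)
})

test_that("top-pair selection takes the floor of the requested fraction", {
  set.seed(3)
  genes <- sprintf("g%02d", 1:18)
  m <- matrix(runif(18 * 18), 18, 18, dimnames = list(genes, genes))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  top <- top_pairs(m, fraction = 0.05)
  expect_equal(nrow(top), 7L)              # floor(0.05 * 153)
  expect_true(all(diff(top$value) <= 0))
  expect_equal(nrow(top_pairs(m, fraction = 1)), 153L)
  two <- m[1:2, 1:2]
  expect_equal(nrow(top_pairs(two, fraction = 0.05)), 0L)
})
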