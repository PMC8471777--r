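test_that("amino-acid bias fractions count O as P", {
  b <- compute_bias("PAST")
  expect_equal(b$past_fraction, 1)
  expect_equal(compute_bias("AOAOAOAOAG")$past_fraction, 0.9)
  expect_equal(compute_bias("PSKYPSKY")$psky_fraction, 1)
  expect_equal(compute_bias("OVKC")$pvkc_fraction, 1)
  expect_error(compute_bias(""), "empty")
})

test_that("motif coverage covers the three HRGP families and unions overlaps", {
  # one SP3 extensin motif covering the whole sequence
  cov <- compute_motif_coverage("SPPP")
  expect_equal(cov$ext$fraction, 1)
  expect_equal(cov$ext_motif_count, 1L)
  expect_equal(cov$agp$fraction, 0)
  # hydroxyproline-aware AG dipeptide repeat
  cov2 <- compute_motif_coverage("AOAOAOAOAO")
  expect_gte(cov2$agp$fraction, 0.45)
  expect_equal(cov2$union_fraction, cov2$agp$fraction)
  # PRP motifs
  cov3 <- compute_motif_coverage("GGPPVAKGGKKPCPPGG")
  expect_equal(cov3$prp$count, 11L)
  # motif-free sequence
  cov4 <- compute_motif_coverage("GGLLVVIIFF")
  expect_equal(cov4$union_fraction, 0)
  # union never exceeds the sum of family fractions
  expect_lte(cov3$union_fraction,
             cov3$agp$fraction + cov3$ext$fraction + cov3$prp$fraction)
})

test_that("classification separates classes 1, 4, 24 and none", {
  thresholds <- maab_thresholds()
  seqs <- list(
    agp = "AOAOAOAOAOAOASTSAST",          # biased, covered
    lowcov = "ATAPPPPTAATAPPPPTAAT",      # biased, Hyp only in runs
    unbiased = "GGLLVVKKEEDDRRNNQQWW")
  hyp <- lapply(seqs, function(s) hyp_positions(gsub("P", "O", s)))
  cls <- function(s, h, gpi) {
    classify_maab(s, compute_bias(s), compute_motif_coverage(s, h), gpi,
                  thresholds)
  }
  with_gpi <- cls(seqs$agp, hyp$agp, TRUE)
  expect_equal(with_gpi$class_id, 1L)
  expect_equal(with_gpi$family, "AGP")
  no_gpi <- cls(seqs$agp, hyp$agp, FALSE)
  expect_equal(no_gpi$class_id, 4L)
  lowcov <- cls(seqs$lowcov, hyp$lowcov, FALSE)
  expect_equal(lowcov$class_id, 24L)
  none <- cls(seqs$unbiased, integer(0), FALSE)
  expect_true(is.na(none$class_id))
  expect_equal(none$family, "none")
  # a partial sequence is never called GPI-anchored
  partial <- classify_maab(seqs$agp, compute_bias(seqs$agp),
                           compute_motif_coverage(seqs$agp, hyp$agp),
                           gpi = TRUE, partial_c_terminus = TRUE)
  expect_equal(partial$class_id, 4L)
  expect_true(partial$partial)
})

test_that("planted MAAB anchors classify to their classes", {
  gen <- make_proteome(proteome_scenario(c(classicalAGP_gpi = 8L,
                                           classicalAGP_nogpi = 8L,
                                           biased_lowcoverage = 8L,
                                           extensin_like = 8L,
                                           background = 20L)), seed = 21)
  tab <- maab_classify_proteome(gen$proteome, gen$bundles)
  merged <- merge(tab, gen$truth, by = "id")
  expect_equal(merged$class_id, merged$expected_class)
  # removing the omega site moves class 1 to class 4 and nothing else
  gpi_ids <- gen$truth$id[gen$truth$category == "classicalAGP_gpi"]
  stripped <- gen$bundles
  for (id in gpi_ids) stripped[[id]]$omega_site <- NA_integer_
  tab2 <- maab_classify_proteome(gen$proteome, stripped)
  expect_true(all(tab2$class_id[tab2$id %in% gpi_ids] == 4L))
  others <- !(tab$id %in% gpi_ids)
  expect_equal(tab2$class_id[others], tab$class_id[others])
})

test_that("classification is permutation-invariant and coverage-monotone", {
  gen <- make_proteome(proteome_scenario(c(classicalAGP_gpi = 5L,
                                           extensin_like = 5L,
                                           biased_lowcoverage = 5L)),
                       seed = 8)
  tab <- maab_classify_proteome(gen$proteome, gen$bundles)
  perm <- sample(nrow(gen$proteome))
  tab_perm <- maab_classify_proteome(gen$proteome[perm, ], gen$bundles)
  expect_equal(tab_perm[order(tab_perm$id), ], tab[order(tab$id), ],
               ignore_attr = TRUE)
  # raising coverage_min can only move sequences into class 24
  strict <- maab_classify_proteome(gen$proteome, gen$bundles,
                                   thresholds = maab_thresholds(coverage_min = 0.6))
  changed <- which(strict$class_id != tab$class_id)
  expect_true(all(strict$class_id[changed] == 24L))
})
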