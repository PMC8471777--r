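# Two wound-induced AG peptides are reconstructed with synthetic
# flanks around their printed mature spans: the signal and C-terminal
# regions are stand-ins, the mature residues are the published ones.
synthetic_ag_peptide_64aa <- function() {
  nsp <- paste0("M", strrep("L", 25))                       # 1..26
  mature <- "AOFEAFAOAOAOTAES"                              # 27..42
  tail <- strrep("V", 21)                                   # 44..64
  list(residues = paste0(nsp, mature, "S", tail),
       nsp_end = 26L, omega = 43L)
}

synthetic_ag_peptide_74aa <- function() {
  nsp <- paste0("M", strrep("L", 31))                       # 1..32
  mature <- "QAOAOAOAATSD"                                  # 33..44
  tail <- strrep("V", 29)                                   # 46..74
  list(residues = paste0(nsp, mature, "S", tail),
       nsp_end = 32L, omega = 45L)
}

test_that("mature peptides of the worked AG peptide examples are recovered", {
  p6 <- synthetic_ag_peptide_64aa()
  expect_equal(nchar(p6$residues), 64L)
  m6 <- derive_mature_peptide(p6$residues, p6$nsp_end, p6$omega)
  expect_equal(c(m6$start, m6$end), c(27L, 42L))
  expect_equal(m6$length, 16L)
  expect_equal(m6$residues, "AOFEAFAOAOAOTAES")
  expect_equal(m6$n_hyp_in_motif_context, 4L)

  p7 <- synthetic_ag_peptide_74aa()
  expect_equal(nchar(p7$residues), 74L)
  m7 <- derive_mature_peptide(p7$residues, p7$nsp_end, p7$omega)
  expect_equal(c(m7$start, m7$end), c(33L, 44L))
  expect_equal(m7$length, 12L)
  expect_equal(m7$n_hyp_in_motif_context, 3L)

  # trim-only: no omega
  m <- derive_mature_peptide(strrep("A", 100), nsp_end = 20L)
  expect_equal(c(m$start, m$end, m$length), c(21L, 100L, 80L))
  expect_true(is.na(m$omega_residue))
  expect_error(derive_mature_peptide("MAAAA", nsp_end = 4L, omega_site = 3L),
               "precede")
})

test_that("topology alternates across transmembrane segments and tiles", {
  one_tm <- assign_topology(100L, nsp_end = 25L,
                            tm_segments = data.frame(start = 50L, end = 70L))
  expect_equal(one_tm$side, c("extracellular", "membrane", "intracellular"))
  expect_equal(one_tm$start, c(1L, 50L, 71L))
  expect_equal(one_tm$end, c(49L, 70L, 100L))

  none <- assign_topology(60L)
  expect_equal(none, data.frame(start = 1L, end = 60L,
                                side = "extracellular"))

  two_tm <- assign_topology(200L, tm_segments = data.frame(
    start = c(40L, 120L), end = c(60L, 140L)))
  expect_equal(two_tm$side, c("extracellular", "membrane", "intracellular",
                              "membrane", "extracellular"))
  # regions partition [1, L]
  expect_equal(two_tm$start[1], 1L)
  expect_equal(two_tm$end[nrow(two_tm)], 200L)
  expect_true(all(two_tm$start[-1] == two_tm$end[-nrow(two_tm)] + 1L))
})

test_that("family assignment follows FLA > KLA > AGp priority on planted truth", {
  gen <- make_proteome(proteome_scenario(c(FLA = 6L, KLA = 6L,
                                           AG_peptide = 6L,
                                           classicalAGP_gpi = 6L)), seed = 13)
  for (i in seq_len(nrow(gen$proteome))) {
    id <- gen$proteome$id[i]
    arch <- build_architecture(id, gen$proteome$residues[i],
                               gen$bundles[[id]])
    fam <- assign_family(arch)
    expect_equal(fam$label,
                 gen$truth$expected_family[gen$truth$id == id],
                 info = id)
  }
})

test_that("family assignment ignores hit order and duplicates; KLA warns on intracellular spans", {
  gen <- make_proteome(proteome_scenario(c(FLA = 1L)), seed = 2)
  id <- gen$proteome$id[1]
  b <- gen$bundles[[id]]
  arch1 <- build_architecture(id, gen$proteome$residues[1], b)
  b2 <- b
  b2$domain_hits <- rbind(b$domain_hits, b$domain_hits)[c(2, 1), ]
  arch2 <- build_architecture(id, gen$proteome$residues[1], b2)
  expect_equal(assign_family(arch1)$label, assign_family(arch2)$label)

  # kinase-like protein whose only AG span lies after the TM: flagged
  span <- "APSAPSAPAPAST"
  residues <- paste0("M", strrep("L", 24), strrep("G", 20),
                     strrep("V", 21), strrep("G", 5), span,
                     strrep("G", 80))
  tm_start <- 46L
  b3 <- agpminer:::empty_bundle()
  b3$nsp_votes <- rep(TRUE, 3); b3$nsp_cleavages <- rep(25L, 3)
  b3$tm_segments <- data.frame(start = tm_start, end = tm_start + 20L)
  hyp_pos <- which(strsplit(residues, "")[[1]] == "P")
  b3$hyp_probs <- stats::setNames(rep(1, length(hyp_pos)), hyp_pos)
  b3$domain_hits <- data.frame(protein_id = "kla_x", accession = "PF07714",
                               name = "kinase", start = 100L, end = 160L,
                               independent_evalue = 1e-10)
  arch3 <- build_architecture("kla_x", residues, b3)
  fam3 <- assign_family(arch3)
  expect_equal(fam3$label, "KLA")
  expect_true("intracellular-AG-span" %in% fam3$warnings)
})

test_that("diagram layouts are complete and deterministic", {
  gen <- make_proteome(proteome_scenario(c(FLA = 1L)), seed = 4)
  id <- gen$proteome$id[1]
  arch <- build_architecture(id, gen$proteome$residues[1],
                             gen$bundles[[id]])
  lay <- render_diagram(arch)
  expect_equal(sum(lay$role == "signal"), 1L)
  expect_equal(sum(lay$role == "omega"), 1L)
  expect_equal(sum(lay$role == "domain"), 1L)
  expect_equal(sum(lay$role == "ag_span"), length(arch$ag_spans))
  expect_equal(sum(lay$role == "hyp"), length(arch$hyp_positions))
  expect_identical(lay, render_diagram(arch))

  bare <- build_architecture("bare", "GAVLIKGAVLIK",
                             agpminer:::empty_bundle())
  expect_equal(render_diagram(bare)$role, "backbone")
})
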