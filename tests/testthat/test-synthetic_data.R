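test_that("ligand panel schemes follow the truth labelling rules", {
  ala <- generate_ligand_panel("VRSRRCLRL", "alanine_scan")
  expect_equal(nrow(ala), 9L)   # no alanine in the seed -> 9 variants
  # substituting away a TCR contact (P5 R, P8 R) is non-stimulatory
  expect_equal(ala$label[ala$sequence == "VRSRACLRL"], "non_stimulatory")
  expect_equal(ala$label[ala$sequence == "VRSRRCLAL"], "non_stimulatory")
  # a non-special position stays stimulatory
  expect_equal(ala$label[ala$sequence == "VRARRCLRL"], "stimulatory")
  # seed positions already holding alanine are skipped with a note
  ala2 <- generate_ligand_panel("VARRRCLRL", "alanine_scan")
  expect_equal(nrow(ala2), 8L)
  ex <- generate_ligand_panel("VRSRRCLRL", "anchor_exchange",
                              exchange_positions = 2L)
  expect_equal(nrow(ex), 2L)    # truth P2 set {A,K,R} minus the seed residue
  expect_true(all(ex$label == "stimulatory"))
  lib1 <- generate_ligand_panel("VRSRRCLRL", "library", n = 25, seed = 99)
  lib2 <- generate_ligand_panel("VRSRRCLRL", "library", n = 25, seed = 99)
  expect_identical(lib1, lib2)  # same seed, same panel
  truth <- default_motif_truth()
  expect_true(all(vapply(lib1$sequence, truth_accepts_for_test, logical(1),
                         truth = truth)))
})

test_that("the suite is byte-identical under a fixed seed", {
  s1 <- generate_peptidome_suite(small_cfg(seed = 31))
  s2 <- generate_peptidome_suite(small_cfg(seed = 31))
  expect_identical(lapply(s1$peptidomes, function(p) p$records),
                   lapply(s2$peptidomes, function(p) p$records))
  expect_identical(s1$gold$planted, s2$gold$planted)
  expect_identical(as.character(s1$proteome), as.character(s2$proteome))
  s3 <- generate_peptidome_suite(small_cfg(seed = 32))
  expect_false(identical(s1$peptidomes[[1]]$records,
                         s3$peptidomes[[1]]$records))
})

test_that("depths, gold accounting and infeasible configs behave", {
  cfg <- small_cfg(seed = 11)
  suite <- generate_peptidome_suite(cfg)
  for (j in seq_along(cfg$depths))
    expect_length(deduplicate(suite$peptidomes[[j]]), cfg$depths[j])
  expect_equal(nrow(suite$gold$planted),
               cfg$n_planted * length(cfg$depths) + 1L)  # + non-binder ligand
  expect_equal(sum(suite$gold$planted$kind == "non_binder_ligand"), 1L)
  expect_error(simulation_config(depths = c(15L, 15L), n_planted = 10L),
               "infeasible")
})

test_that("length spectrum of a 10,000-peptide draw is within 2% per length", {
  cfg <- simulation_config(seed = 77, depths = c(5000L, 5000L),
                           n_planted = 0L, n_duplicates = 0L)
  suite <- generate_peptidome_suite(cfg)
  seqs <- unique(unlist(lapply(suite$peptidomes, deduplicate)))
  emp <- table(factor(nchar(seqs), levels = 8:11)) / length(seqs)
  for (L in names(cfg$length_probs))
    expect_lt(abs(emp[[L]] - cfg$length_probs[[L]]), 0.02)
})

test_that("forced sharing probability 1 gives 100% overlap", {
  sharing <- matrix(0, 2, 2)
  sharing[1, 2] <- 1
  cfg <- simulation_config(seed = 13, depths = c(200L, 250L),
                           sharing = sharing, n_planted = 5L,
                           n_duplicates = 0L)
  suite <- generate_peptidome_suite(cfg)
  a <- deduplicate(suite$peptidomes[[1]])
  b <- deduplicate(suite$peptidomes[[2]])
  # planted peptides are excluded from the sharing pool by design
  background_a <- setdiff(as.character(a), suite$gold$planted$sequence)
  expect_equal(overlap_fraction(background_a, as.character(b))$percent, 100L)
})

test_that("q-value mixture straddles the 1%/10% boundary as configured", {
  cfg <- simulation_config(seed = 5, depths = c(4000L, 4000L),
                           n_planted = 0L, n_duplicates = 0L)
  suite <- generate_peptidome_suite(cfg)
  q <- unlist(lapply(suite$peptidomes, function(p) p$records$q_value))
  frac_mid <- mean(q > 0.01 & q <= 0.10)
  expect_lt(abs(frac_mid - cfg$q_probs[2]), 0.01)
  expect_gt(mean(q <= 0.01), 0.9)
})

test_that("strong-binder fraction for the shared allele matches the rank model", {
  cfg <- simulation_config(seed = 9, depths = c(4000L, 4000L),
                           n_planted = 0L, n_duplicates = 0L)
  suite <- generate_peptidome_suite(cfg)
  for (p in suite$peptidomes) {
    ranks <- p$records[[cfg$shared_allele]]
    frac_strong <- mean(ranks <= 0.5)
    target <- cfg$strata_probs[["strong"]]
    expect_lt(abs(frac_strong - target),
              4 * sqrt(target * (1 - target) / length(ranks)))
  }
})

test_that("write_suite emits the documented file set and round-trips", {
  dir <- withr::local_tempdir()
  suite <- generate_peptidome_suite(small_cfg(seed = 2))
  write_suite(suite, dir)
  files <- list.files(dir)
  expect_true(all(c("BCL1.tsv", "BCL4.tsv", "gold_planted.tsv",
                    "proteome.fasta", "config.json") %in% files))
  p <- read_peptide_table(file.path(dir, "BCL1.tsv"), name = "BCL1")
  expect_equal(p$records$sequence, suite$peptidomes[["BCL1"]]$records$sequence)
  expect_equal(p$records[["HLA-C*06:02"]],
               suite$peptidomes[["BCL1"]]$records[["HLA-C*06:02"]])
})
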