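test_that("build_motif count arithmetic matches closed forms", {
  # degenerate: identical peptides, zero pseudocount -> probability 1
  panel <- ligand_panel(data.frame(sequence = rep("VRSRRCLRL", 4),
                                   label = "stimulatory",
                                   provenance = "library"))
  m0 <- build_motif(panel, pseudocount = 0)
  ppm <- m0$lengths[["9"]]$ppm
  expect_equal(unname(ppm[1, "V"]), 1)
  expect_equal(unname(ppm[5, "R"]), 1)
  expect_equal(sum(ppm[1, ] > 0), 1L)
  # single peptide, pseudocount 1 -> (1+1)/(1+20) at the observed residue
  m1 <- build_motif(panel[1, ], pseudocount = 1)
  expect_equal(unname(m1$lengths[["9"]]$ppm[1, "V"]), 2 / 21)
  expect_equal(unname(m1$lengths[["9"]]$ppm[1, "A"]), 1 / 21)
  # rows sum to 1
  expect_true(all(abs(rowSums(m1$lengths[["9"]]$ppm) - 1) < 1e-9))
  # log-odds vs uniform background
  expect_equal(unname(m1$lengths[["9"]]$lod[1, "V"]), log2((2 / 21) / 0.05))
})

test_that("build_motif recovers generating probabilities from a large panel", {
  set.seed(77)
  truth <- default_motif_truth()
  panel <- generate_ligand_panel("VRSRRCLRL", "library", truth, n = 500)
  m <- build_motif(panel, pseudocount = 1)
  ppm <- m$lengths[["9"]]$ppm
  # non-anchor, non-contact positions are uniform in the generator
  for (pos in c(1, 3, 4, 6))
    expect_true(all(abs(ppm[pos, ] - 0.05) < 0.03))
  # anchor positions concentrate on the truth-allowed residues
  for (p in names(truth$anchors[["9"]])) {
    allowed <- truth$anchors[["9"]][[p]]
    expect_gt(sum(ppm[as.integer(p), allowed]), 0.95)
  }
})

test_that("motif build is order-independent and warns on missing lengths", {
  panel <- default_ligand_panel(seed = 5)
  m1 <- build_motif(panel)
  m2 <- build_motif(panel[rev(seq_len(nrow(panel))), ])
  expect_equal(m1$lengths, m2$lengths)
  only9 <- panel[nchar(panel$sequence) == 9, ]
  m9 <- build_motif(only9)
  expect_null(m9$lengths[["8"]])
  non_stim8 <- rbind(only9, data.frame(sequence = "AAAAAAAA",
                                       label = "non_stimulatory",
                                       provenance = "library"))
  expect_warning(build_motif(non_stim8), "length 8")
})

test_that("information content follows entropy arithmetic", {
  panel <- ligand_panel(data.frame(sequence = rep("VRSRRCLRL", 4),
                                   label = "stimulatory",
                                   provenance = "library"))
  m0 <- build_motif(panel, pseudocount = 0)
  ic <- position_information_content(m0)
  expect_equal(unname(ic), rep(log2(20), 9), tolerance = 1e-12)
  # two equiprobable residues -> log2(20) - 1
  panel2 <- ligand_panel(data.frame(sequence = c("VRSRRCLRL", "IRSRRCLRL"),
                                    label = "stimulatory",
                                    provenance = "library"))
  ic2 <- position_information_content(build_motif(panel2, pseudocount = 0))
  expect_equal(unname(ic2[["P1"]]), log2(20) - 1, tolerance = 1e-12)
  # pseudocount shrinks IC toward 0 and bounds hold
  icp <- position_information_content(build_motif(panel2, pseudocount = 1))
  expect_true(all(icp < ic2[1] + 1e-9))
  expect_true(all(icp >= 0 & icp <= log2(20)))
})

test_that("match_peptide agrees with the brute-force oracle on random peptides", {
  set.seed(123)
  m <- build_motif(default_ligand_panel(seed = 5))
  peps <- c(
    vapply(1:500, function(i)
      paste(sample(AA_ALPHABET, 9, replace = TRUE), collapse = ""), ""),
    vapply(1:300, function(i)
      paste(sample(AA_ALPHABET, 8, replace = TRUE), collapse = ""), ""),
    sample_truth_peptides_for_test(200, 9),
    "VRSRRCLRL", "VRHDGGNVL", "RRLPCRKR")
  for (p in peps) {
    got <- match_peptide(m, p)
    want <- oracle_match(m, p)
    expect_equal(got$passed, want$passed, info = p)
    expect_equal(got$score, want$score, info = p)
    expect_equal(got$anchor_ok, want$anchor_ok, info = p)
    expect_equal(got$contact_ok, want$contact_ok, info = p)
  }
  # wrong length / invalid alphabet
  expect_false(match_peptide(m, "AAAAAAA")$length_ok)
  expect_false(match_peptide(m, "AAAAAAA")$passed)
  expect_error(match_peptide(m, "AAAAAAAAB"), "invalid")
})

test_that("printed control peptides behave per the default rules", {
  m <- build_motif(default_ligand_panel())
  adam <- match_peptide(m, "VRSRRCLRL")   # basic residues at P5/P8
  expect_true(adam$contact_ok && adam$anchor_ok && adam$passed)
  falk <- match_peptide(m, "VRHDGGNVL")   # G at P5, V at P8
  expect_false(falk$contact_ok)
  expect_false(falk$passed)
  rnf <- match_peptide(m, "RRLPCRKR")     # K at octamer contact P7
  expect_true(rnf$contact_ok && rnf$passed)
})

test_that("screening is order-invariant, monotone and matches brute force", {
  set.seed(9)
  m <- build_motif(default_ligand_panel(seed = 5))
  peps <- c(sample_truth_peptides_for_test(30, 9),
            vapply(1:800, function(i)
              paste(sample(AA_ALPHABET, sample(8:9, 1), replace = TRUE),
                    collapse = ""), ""))
  res <- screen_peptidome(m, peps)
  expect_equal(res, screen_peptidome(m, sample(peps)))   # order-invariant
  expect_equal(sort(res$sequence), oracle_screen(m, peps))
  expect_true(all(diff(res$score) <= 0))                 # ranked by score
  expect_equal(res$rank, seq_len(nrow(res)))
  # raising the threshold never adds a candidate
  for (thr in c(2, 5, 10)) {
    sub <- screen_peptidome(m, peps, threshold = thr)
    expect_true(all(sub$sequence %in% res$sequence))
  }
  expect_equal(nrow(screen_peptidome(m, peps, threshold = Inf)), 0L)
  expect_equal(nrow(screen_peptidome(m, peps, top_k = 5)), 5L)
  # enlarging an anchor allowed set never removes a candidate
  cfg2 <- motif_config(anchor_allowed = list(`9` = list(`2` = AA_ALPHABET)))
  m2 <- build_motif(default_ligand_panel(seed = 5), config = cfg2)
  res2 <- screen_peptidome(m2, peps)
  expect_true(all(res$sequence[nchar(res$sequence) == 9] %in% res2$sequence))
})

test_that("peptidome screening separates binder-only from include_nonbinders", {
  suite <- generate_peptidome_suite(small_cfg(seed = 4))
  m <- build_motif(default_ligand_panel())
  nb <- suite$gold$planted[suite$gold$planted$kind == "non_binder_ligand", ]
  p <- suite$peptidomes[[nb$cell_line]]
  with_nb <- screen_peptidome(m, p, include_nonbinders = TRUE)
  binders_only <- screen_peptidome(m, p, include_nonbinders = FALSE)
  expect_true(nb$sequence %in% with_nb$sequence)
  expect_false(nb$sequence %in% binders_only$sequence)
})

test_that("motif JSON serialization round-trips", {
  m <- build_motif(default_ligand_panel(seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_motif(m, path)
  m2 <- read_motif(path)
  expect_equal(m2$lengths[["9"]]$ppm, m$lengths[["9"]]$ppm,
               ignore_attr = TRUE)
  expect_equal(m2$lengths[["8"]]$anchors, m$lengths[["8"]]$anchors)
  # same screening behaviour after round trip
  peps <- sample_truth_peptides_for_test(50, 9)
  expect_equal(screen_peptidome(m2, peps)$sequence,
               screen_peptidome(m, peps)$sequence)
})
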