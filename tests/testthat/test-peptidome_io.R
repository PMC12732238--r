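test_that("read_peptide_table round-trips a well-formed table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(demo_records(), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  p <- read_peptide_table(path, name = "demo")
  expect_s3_class(p, "Immunopeptidome")
  expect_equal(nrow(p$records), 3L)
  expect_setequal(p$alleles, c("HLA-C*06:02", "HLA-A*01:01"))
  # printed-case peptide: 8-mer with q 0.0106
  rnf <- p$records[p$records$sequence == "RRLPCRKR", ]
  expect_equal(rnf$length, 8L)
  expect_equal(rnf$q_value, 0.0106)
  # lossless write/read round trip
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(p, path2)
  p2 <- read_peptide_table(path2, name = "demo")
  expect_equal(p2$records, p$records)
})

test_that("invalid rows are rejected with diagnostics, others loaded", {
  rec <- demo_records()
  rec$sequence[2] <- "RRLBCRKR"      # B not in alphabet
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(p <- read_peptide_table(path), "rejected 1")
  expect_equal(nrow(p$records), 2L)
  expect_false("RRLBCRKR" %in% p$records$sequence)
})

test_that("dialect remaps headers; missing mandatory column errors; empty file warns", {
  rec <- demo_records()
  names(rec)[names(rec) == "sequence"] <- "Peptide"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rec[, c("Peptide", "q_value")], path, row.names = FALSE)
  p <- read_peptide_table(path, dialect = c(sequence = "Peptide"))
  expect_equal(nrow(p$records), 3L)
  expect_error(read_peptide_table(path), "mandatory")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sequence\tq_value", empty)
  expect_warning(p0 <- read_peptide_table(empty), "empty")
  expect_equal(nrow(p0$records), 0L)
})

test_that("filter_by_fdr keeps q <= t inclusively and is idempotent/monotone", {
  p <- Immunopeptidome("x", demo_records())
  expect_true("RRLPCRKR" %in% filter_by_fdr(p, 0.10)$records$sequence)
  expect_false("RRLPCRKR" %in% filter_by_fdr(p, 0.01)$records$sequence)
  # inclusive boundary
  expect_true("RRLPCRKR" %in% filter_by_fdr(p, 0.0106)$records$sequence)
  expect_equal(nrow(filter_by_fdr(p, 1.0)$records), nrow(p$records))
  expect_error(filter_by_fdr(p, 0), "threshold")
  # idempotence and monotonicity over a random q grid
  set.seed(5)
  big <- Immunopeptidome("y", data.frame(
    sequence = make_peps(500, 9), q_value = runif(500)))
  for (t in c(0.01, 0.1, 0.5)) {
    f1 <- filter_by_fdr(big, t)
    expect_equal(filter_by_fdr(f1, t)$records, f1$records)
  }
  thresholds <- sort(runif(5))
  surv <- lapply(thresholds, function(t) filter_by_fdr(big, t)$records$sequence)
  for (i in seq_len(length(surv) - 1))
    expect_true(all(surv[[i]] %in% surv[[i + 1]]))
})

test_that("per-category filtering reports per-category counts", {
  p <- Immunopeptidome("x", demo_records())
  f <- filter_by_fdr(p, 0.05, per_category = TRUE)
  cc <- attr(f, "category_counts")
  expect_setequal(cc$category, c("CDS", "UTR5"))
  expect_equal(cc$kept[cc$category == "CDS"], 1L)   # 0.2 fails
  expect_equal(cc$kept[cc$category == "UTR5"], 1L)
})

test_that("deduplicate keeps the minimum-q record and is idempotent", {
  rec <- data.frame(sequence = c("AAAAAAAAA", "AAAAAAAAA", "CCCCCCCCC"),
                    q_value = c(0.05, 0.01, 0.2))
  p <- Immunopeptidome("x", rec)
  u <- deduplicate(p)
  expect_setequal(as.character(u), c("AAAAAAAAA", "CCCCCCCCC"))
  reps <- attr(u, "records")
  expect_equal(reps$q_value[reps$sequence == "AAAAAAAAA"], 0.01)
  expect_equal(deduplicate(as.character(u)), as.character(u))
  expect_length(deduplicate(Immunopeptidome("e", data.frame(
    sequence = character(), q_value = numeric()))), 0L)
})

test_that("deduplicate recovers the generator's planted duplicate count", {
  # 83 unique peptides + 17 planted duplicate records = 100 records
  cfg <- simulation_config(seed = 3, depths = c(83L, 83L),
                           n_planted = 5L, n_duplicates = 17L)
  suite <- generate_peptidome_suite(cfg)
  p <- suite$peptidomes[[1]]
  expect_equal(nrow(p$records), 100L)
  expect_length(deduplicate(p), 83L)
  expect_equal(unname(suite$gold$duplicates[1]), 17L)
})

test_that("map_to_proteome agrees with a brute-force all-offsets scan", {
  set.seed(42)
  proteins <- setNames(
    vapply(1:5, function(i)
      paste(sample(AA_ALPHABET, 60, replace = TRUE), collapse = ""), ""),
    paste0("P", 1:5))
  # plant one peptide twice (two proteins) and once (known offset)
  pep1 <- "WWHKYMFDN"
  proteins[["P2"]] <- paste0(substr(proteins[["P2"]], 1, 10), pep1,
                             substr(proteins[["P2"]], 20, 60))
  proteins[["P4"]] <- paste0(pep1, substr(proteins[["P4"]], 10, 60))
  peps <- c(pep1, "AAAAAAAA", substr(proteins[["P1"]], 31, 39))
  hits <- map_to_proteome(peps, proteins)
  oracle <- oracle_proteome_scan(peps, as.list(proteins))
  hits_o <- hits[order(hits$peptide, hits$protein_id, hits$start), ]
  oracle <- oracle[order(oracle$peptide, oracle$protein_id, oracle$start), ]
  rownames(hits_o) <- rownames(oracle) <- NULL
  expect_equal(hits_o, oracle)
  h1 <- hits[hits$peptide == pep1, ]
  expect_equal(h1$protein_id, c("P2", "P4"))   # ordered by protein id
  expect_equal(h1$start, c(10L, 0L))
  expect_equal(nrow(hits[hits$peptide == "AAAAAAAA", ]), 0L)
  # substring invariant
  for (i in seq_len(nrow(hits)))
    expect_equal(substr(proteins[[hits$protein_id[i]]],
                        hits$start[i] + 1, hits$end[i]), hits$peptide[i])
})

test_that("map_to_proteome reads FASTA and finds generator plant positions", {
  suite <- generate_peptidome_suite(small_cfg())
  fa <- withr::local_tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(suite$proteome, fa)
  planted <- suite$gold$planted$sequence[1:5]
  hits <- map_to_proteome(planted, fa)
  pos <- suite$gold$plant_positions
  for (pep in planted) {
    want <- pos[pos$peptide == pep, ]
    got <- hits[hits$peptide == pep & hits$protein_id == want$protein_id &
                  hits$start == want$start, ]
    expect_equal(nrow(got), 1L)
  }
})
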