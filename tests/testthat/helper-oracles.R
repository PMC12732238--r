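# Independent brute-force oracles. These deliberately re-derive results with
# straight-line code so the implementation under test is checked against a
# second, structurally different route.

# straight-line motif matcher: loops, no vectorization, no shared helpers
oracle_match <- function(m, pep, threshold = 0) {
  L <- nchar(pep)
  ent <- m$lengths[[as.character(L)]]
  if (is.null(ent))
    return(list(passed = FALSE, score = NA_real_, anchor_ok = FALSE,
                contact_ok = FALSE))
  aa <- strsplit(pep, "")[[1]]
  score <- 0
  for (i in 1:L)
    score <- score + unname(ent$lod[i, match(aa[i], pepscreen::AA_ALPHABET)])
  anchor_ok <- TRUE
  for (a in names(ent$anchors))
    if (!(aa[as.integer(a)] %in% ent$anchors[[a]])) anchor_ok <- FALSE
  hits <- logical(0)
  for (cpos in names(ent$contacts))
    hits <- c(hits, aa[as.integer(cpos)] %in% ent$contacts[[cpos]])
  contact_ok <- if (ent$contact_mode == "all") all(hits) else any(hits)
  list(passed = anchor_ok && contact_ok && score >= threshold,
       score = score, anchor_ok = anchor_ok, contact_ok = contact_ok)
}

oracle_screen <- function(m, peptides, threshold = 0) {
  peptides <- unique(toupper(peptides))
  peptides <- peptides[nchar(peptides) %in% c(8, 9)]
  keep <- character(0)
  for (p in peptides)
    if (isTRUE(oracle_match(m, p, threshold)$passed)) keep <- c(keep, p)
  sort(keep)
}

# all-offsets scan, 0-based half-open
oracle_proteome_scan <- function(peptides, proteins) {
  out <- data.frame(peptide = character(), protein_id = character(),
                    start = integer(), end = integer())
  for (pep in unique(toupper(peptides))) {
    for (pid in sort(names(proteins))) {
      s <- proteins[[pid]]
      for (off in seq_len(nchar(s) - nchar(pep) + 1)) {
        if (substr(s, off, off + nchar(pep) - 1) == pep)
          out <- rbind(out, data.frame(peptide = pep, protein_id = pid,
                                       start = off - 1L,
                                       end = off - 1L + nchar(pep)))
      }
    }
  }
  out
}

# membership tabulation by per-peptide loops
oracle_upset <- function(sets) {
  universe <- unique(unlist(sets))
  counts <- list()
  for (pep in universe) {
    pat <- paste(names(sets)[vapply(sets, function(s) pep %in% s,
                                    logical(1))], collapse = "&")
    counts[[pat]] <- (counts[[pat]] %||% 0L) + 1L
  }
  counts
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic distinct peptides: index written in base 20 over the alphabet
make_peps <- function(n, L) {
  vapply(seq_len(n) - 1L, function(i) {
    digs <- integer(L)
    for (j in seq_len(L)) {
      digs[j] <- i %% 20L
      i <- i %/% 20L
    }
    paste(pepscreen::AA_ALPHABET[digs + 1L], collapse = "")
  }, "")
}

# small record table for IO tests
demo_records <- function() {
  data.frame(
    sequence = c("VRSRRCLRL", "RRLPCRKR", "AAAAAAAAK"),
    q_value = c(0.001, 0.0106, 0.2),
    category = c("CDS", "UTR5", "CDS"),
    `HLA-C*06:02` = c(0.2, 5.0, 1.1),
    `HLA-A*01:01` = c(12, 30, 0.3),
    check.names = FALSE)
}

# straight-line re-statement of the generator's truth acceptance rule
truth_accepts_for_test <- function(pep, truth) {
  L <- nchar(pep)
  key <- as.character(L)
  aa <- strsplit(pep, "")[[1]]
  for (p in names(truth$anchors[[key]]))
    if (!(aa[as.integer(p)] %in% truth$anchors[[key]][[p]])) return(FALSE)
  for (p in truth$contacts[[key]]) {
    req <- truth$contact_residues
    if (truth$allow_q_p5 && p == 5) req <- c(req, "Q")
    if (aa[p] %in% req) return(TRUE)
  }
  FALSE
}

# motif-conforming peptides via the library scheme (truth defaults)
sample_truth_peptides_for_test <- function(n, L) {
  seedpep <- if (L == 9) "VRSRRCLRL" else "RRLPCRKR"
  generate_ligand_panel(seedpep, "library", n = n)$sequence
}

small_cfg <- function(seed = 11)
  simulation_config(seed = seed, depths = c(400L, 300L, 900L, 800L),
                    n_duplicates = 8L)
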