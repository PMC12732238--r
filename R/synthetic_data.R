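#' Default truth rules for the synthetic TCR recognition motif
#'
#' The generating model used by the simulator and by [generate_ligand_panel()]:
#' HLA-anchor allowed sets, TCR-contact required residues and the positional
#' conventions for 8- and 9-mers. These are the ground truth against which
#' planted-peptide recovery is measured; the analysis side never reads them —
#' it re-derives its motif from a generated ligand panel.
#'
#' @return List with `anchors`/`contacts` per length, `contact_residues`,
#'   `allow_q_p5`.
#' @export
default_motif_truth <- function() {
  list(
    anchors = list(
      `9` = list(`2` = c("A", "K", "R"), `7` = c("L", "R", "V"),
                 `9` = c("I", "L", "V")),
      `8` = list(`2` = c("A", "K", "R"), `8` = c("L", "R", "V"))),
    contacts = list(`9` = c(5L, 8L), `8` = c(5L, 7L)),
    contact_residues = c("R", "K"),
    allow_q_p5 = TRUE)
}

truth_contact_set <- function(truth, pos) {
  req <- truth$contact_residues
  if (isTRUE(truth$allow_q_p5) && pos == 5L) req <- union(req, "Q")
  req
}

# does a peptide satisfy the truth rules (anchors + any-contact)?
truth_accepts <- function(peptide, truth) {
  L <- nchar(peptide)
  key <- as.character(L)
  if (!key %in% names(truth$anchors)) return(FALSE)
  aa <- strsplit(peptide, "")[[1]]
  anchors_ok <- all(vapply(names(truth$anchors[[key]]), function(p)
    aa[as.integer(p)] %in% truth$anchors[[key]][[p]], logical(1)))
  contact_ok <- any(vapply(truth$contacts[[key]], function(p)
    aa[p] %in% truth_contact_set(truth, p), logical(1)))
  anchors_ok && contact_ok
}

# sample n peptides of length L satisfying the truth rules
sample_truth_peptides <- function(n, L, truth) {
  if (n == 0L) return(character())
  key <- as.character(L)
  m <- matrix(sample(AA_ALPHABET, n * L, replace = TRUE), nrow = n)
  for (p in names(truth$anchors[[key]]))
    m[, as.integer(p)] <- sample(truth$anchors[[key]][[p]], n, replace = TRUE)
  contacts <- truth$contacts[[key]]
  for (p in contacts) {
    basic <- stats::runif(n) < 0.7
    m[basic, p] <- sample(truth$contact_residues, sum(basic), replace = TRUE)
  }
  # guarantee the any-contact rule
  has_contact <- rowSums(matrix(vapply(contacts, function(p)
    m[, p] %in% truth_contact_set(truth, p), logical(n)), nrow = n)) > 0
  fix <- which(!has_contact)
  if (length(fix)) {
    pos <- sample(contacts, length(fix), replace = TRUE)
    m[cbind(fix, pos)] <- sample(truth$contact_residues, length(fix),
                                 replace = TRUE)
  }
  apply(m, 1, paste, collapse = "")
}

#' Generate a stimulatory-ligand panel by a mutagenesis or library scheme
#'
#' Emulates how a TCR recognition motif panel is assembled experimentally:
#' `alanine_scan` substitutes alanine at each position of the seed peptide
#' (no-op positions where the seed already carries A are skipped with a
#' note); `anchor_exchange` substitutes each anchor-exchange position against
#' the truth-allowed HLA anchor residues; `library` draws random peptides
#' accepted by the truth motif. Labels follow the truth rule: a variant is
#' `non_stimulatory` when it loses a required TCR-contact residue (the seed's
#' basic residue at a contact position is substituted away) or breaks an
#' anchor; everything else (and every library draw) is `stimulatory`.
#'
#' @param seed_peptide 8- or 9-mer seed sequence.
#' @param scheme One of `"alanine_scan"`, `"anchor_exchange"`, `"library"`.
#' @param truth Truth rules, see [default_motif_truth()].
#' @param n Library size (library scheme only).
#' @param exchange_positions Anchor positions to exchange (anchor_exchange
#'   scheme); defaults to P2 and the C-terminus.
#' @param seed Optional RNG seed (library scheme); the same seed reproduces
#'   the same panel.
#' @return A [ligand_panel()] data frame.
#' @export
generate_ligand_panel <- function(seed_peptide,
                                  scheme = c("alanine_scan", "anchor_exchange",
                                             "library"),
                                  truth = default_motif_truth(), n = 50,
                                  exchange_positions = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  seed_peptide <- toupper(seed_peptide)
  L <- nchar(seed_peptide)
  if (!L %in% c(8L, 9L)) stop("seed peptide must be an 8- or 9-mer",
                              call. = FALSE)
  key <- as.character(L)
  aa <- strsplit(seed_peptide, "")[[1]]
  label_variant <- function(variant, pos) {
    vaa <- strsplit(variant, "")[[1]]
    anchors <- truth$anchors[[key]]
    anchors_ok <- all(vapply(names(anchors), function(p)
      vaa[as.integer(p)] %in% anchors[[p]], logical(1)))
    lost_contact <- pos %in% truth$contacts[[key]] &&
      aa[pos] %in% truth_contact_set(truth, pos) &&
      !vaa[pos] %in% truth_contact_set(truth, pos)
    if (!anchors_ok || lost_contact) "non_stimulatory" else "stimulatory"
  }
  run <- function() {
    if (scheme == "alanine_scan") {
      skipped <- which(aa == "A")
      pos <- setdiff(seq_len(L), skipped)
      variants <- vapply(pos, function(p) {
        v <- aa; v[p] <- "A"; paste(v, collapse = "")
      }, "")
      out <- data.frame(sequence = variants,
                        label = vapply(seq_along(pos), function(i)
                          label_variant(variants[i], pos[i]), ""),
                        provenance = "alanine_scan")
      if (length(skipped))
        attr(out, "note") <- paste("skipped no-op alanine substitution at",
                                   paste0("P", skipped, collapse = ", "))
      out
    } else if (scheme == "anchor_exchange") {
      if (is.null(exchange_positions)) exchange_positions <- c(2L, L)
      rows <- list()
      for (p in exchange_positions) {
        allowed <- truth$anchors[[key]][[as.character(p)]]
        if (is.null(allowed))
          stop("position ", p, " is not an anchor in the truth rules",
               call. = FALSE)
        for (res in setdiff(allowed, aa[p])) {
          v <- aa; v[p] <- res
          variant <- paste(v, collapse = "")
          rows[[length(rows) + 1L]] <- data.frame(
            sequence = variant, label = label_variant(variant, p),
            provenance = "anchor_exchange")
        }
      }
      do.call(rbind, rows)
    } else {
      data.frame(sequence = sample_truth_peptides(n, L, truth),
                 label = "stimulatory", provenance = "library")
    }
  }
  out <- if (is.null(seed)) run() else with_local_seed(seed, run())
  ligand_panel(out)
}

#' Assemble the default ligand panel
#'
#' Combines alanine scans, anchor exchanges and library draws around a
#' nonamer and an octamer seed into a 133-peptide panel — the scale of panel
#' from which the recognition motif is defined. Deterministic for a given
#' seed.
#'
#' @param seed RNG seed.
#' @param truth Truth rules.
#' @param nonamer_seed,octamer_seed Seed peptides.
#' @return A [ligand_panel()] data frame.
#' @export
default_ligand_panel <- function(seed = 1903, truth = default_motif_truth(),
                                 nonamer_seed = "VRSRRCLRL",
                                 octamer_seed = "RRLPCRKR") {
  with_local_seed(seed, {
    rbind(
      generate_ligand_panel(nonamer_seed, "alanine_scan", truth),
      generate_ligand_panel(nonamer_seed, "anchor_exchange", truth),
      generate_ligand_panel(nonamer_seed, "library", truth, n = 70),
      generate_ligand_panel(octamer_seed, "alanine_scan", truth),
      generate_ligand_panel(octamer_seed, "anchor_exchange", truth),
      generate_ligand_panel(octamer_seed, "library", truth, n = 38))
  })
}

#' Simulation configuration for synthetic immunopeptidome suites
#'
#' The stated world of the simulator: four B-cell-line peptidomes of unequal
#' depth, a 9-mer-dominant length spectrum, per-allele percent-rank strata
#' (strong / weak / other-allele / non-binder), a q-value mixture straddling
#' the 1% and 10% FDR boundaries, pairwise sharing between lines, and a small
#' planted set of motif-conforming stimulatory peptides including one
#' non-binder-stratum octamer (exercising the screen-the-non-binders path).
#'
#' @param seed Integer seed; fully determines every output.
#' @param depths Unique-peptide depth per cell line.
#' @param line_names Cell-line names.
#' @param length_probs Named probabilities over lengths 8..11.
#' @param shared_allele Allele carried by every line.
#' @param allele_panels List of per-line allele vectors (must contain
#'   `shared_allele`); two lines share an A-allele pair, mirroring the
#'   greater overlap of high-yield lines.
#' @param strata_probs Probabilities of the shared-allele strata
#'   `strong`/`weak`/`other`/`non_binder`.
#' @param q_probs Probabilities that a q-value falls in `(0, 0.01]`,
#'   `(0.01, 0.1]`, `(0.1, 0.5]`.
#' @param sharing Pairwise retention probability matrix (row = source line,
#'   column = destination line).
#' @param n_planted Motif-conforming stimulatory peptides planted per line.
#' @param n_duplicates Duplicate records planted per line.
#' @param truth Motif truth rules, see [default_motif_truth()].
#' @return Validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L,
                              depths = c(3200L, 2100L, 8600L, 8500L),
                              line_names = paste0("BCL", seq_along(depths)),
                              length_probs = c(`8` = 0.03, `9` = 0.95,
                                               `10` = 0.015, `11` = 0.005),
                              shared_allele = "HLA-C*06:02",
                              allele_panels = NULL,
                              strata_probs = c(strong = 0.030, weak = 0.020,
                                               other = 0.840,
                                               non_binder = 0.110),
                              q_probs = c(0.95, 0.03, 0.02),
                              sharing = NULL,
                              n_planted = 10L,
                              n_duplicates = 25L,
                              truth = default_motif_truth()) {
  n <- length(depths)
  if (is.null(allele_panels)) {
    others <- list(
      c("HLA-A*24:02", "HLA-A*68:01", "HLA-B*07:02", "HLA-B*44:02"),
      c("HLA-A*02:01", "HLA-A*11:01", "HLA-B*08:01", "HLA-B*35:01"),
      c("HLA-A*01:01", "HLA-A*03:01", "HLA-B*07:02", "HLA-B*57:01"),
      c("HLA-A*01:01", "HLA-A*03:01", "HLA-B*18:01", "HLA-B*44:03"))
    allele_panels <- lapply(seq_len(n), function(i)
      c(shared_allele, others[[((i - 1L) %% 4L) + 1L]]))
  }
  if (is.null(sharing)) {
    sharing <- matrix(0.08, n, n)
    if (n >= 4L) sharing[3, 4] <- sharing[4, 3] <- 0.30
    diag(sharing) <- 0
  }
  stopifnot(length(line_names) == n, length(allele_panels) == n,
            all(vapply(allele_panels, function(a) shared_allele %in% a,
                       logical(1))),
            abs(sum(length_probs) - 1) < 1e-9,
            abs(sum(strata_probs) - 1) < 1e-9,
            sum(q_probs) <= 1 + 1e-9,
            all(dim(sharing) == c(n, n)))
  if (any(n_planted + 10L > depths))
    stop("infeasible config: planted count exceeds depth", call. = FALSE)
  structure(list(seed = as.integer(seed), depths = as.integer(depths),
                 line_names = line_names, length_probs = length_probs,
                 shared_allele = shared_allele,
                 allele_panels = allele_panels,
                 strata_probs = strata_probs, q_probs = q_probs,
                 sharing = sharing, n_planted = as.integer(n_planted),
                 n_duplicates = as.integer(n_duplicates), truth = truth),
            class = "SimulationConfig")
}

# draw from a lognormal truncated to (lo, hi]
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  u <- stats::runif(n, stats::plnorm(lo, meanlog, sdlog),
                    stats::plnorm(hi, meanlog, sdlog))
  pmin(pmax(stats::qlnorm(u, meanlog, sdlog), lo + 1e-9), hi)
}

rank_band <- function(n, band) {
  switch(band,
         strong = rlnorm_trunc(n, log(0.20), 0.8, 0, 0.5),
         weak = rlnorm_trunc(n, log(1.00), 0.5, 0.5, 2),
         binder = rlnorm_trunc(n, log(0.50), 1.0, 0, 2),
         background = rlnorm_trunc(n, log(12), 1.0, 2, 100))
}

draw_q <- function(n, q_probs) {
  band <- sample.int(3L, n, replace = TRUE, prob = q_probs)
  q <- numeric(n)
  q[band == 1L] <- stats::runif(sum(band == 1L), 1e-5, 0.01)
  q[band == 2L] <- stats::runif(sum(band == 2L), 0.01 + 1e-6, 0.10)
  q[band == 3L] <- stats::runif(sum(band == 3L), 0.10 + 1e-6, 0.50)
  q
}

sample_background_peptides <- function(n, length_probs) {
  lens <- as.integer(sample(names(length_probs), n, replace = TRUE,
                            prob = length_probs))
  vapply(lens, function(L)
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""), "")
}

#' Generate a synthetic immunopeptidome suite
#'
#' Produces the full fixture set the pipeline consumes: one
#' [Immunopeptidome] per cell line honouring the configured depths, length
#' spectrum, rank strata, q-value mixture and pairwise sharing; gold labels
#' for every planted stimulatory peptide (including one forced into the
#' non-binder stratum with a q-value in the 1–10% FDR window); and a
#' synthetic proteome FASTA embedding every emitted peptide, with recorded
#' planting positions. A peptide shared between lines keeps its per-allele
#' ranks (the peptide–allele pair is a property of the peptide, not the
#' experiment) while q-values are re-drawn per line. Identical seeds give
#' byte-identical outputs.
#'
#' @param cfg A [simulation_config()].
#' @return List with `peptidomes` (named list of [Immunopeptidome]),
#'   `gold` (list: `planted` data frame, `pattern_counts`, `duplicates`,
#'   `plant_positions`, `strata` per-line tallies, `truth`, `config`) and
#'   `proteome` (a [Biostrings::AAStringSet]).
#' @export
generate_peptidome_suite <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  with_local_seed(cfg$seed, generate_suite_impl(cfg))
}

generate_suite_impl <- function(cfg) {
  n_lines <- length(cfg$depths)
  all_alleles <- unique(unlist(cfg$allele_panels))
  rank_env <- new.env(parent = emptyenv())   # (sequence|allele) -> rank
  stratum_env <- new.env(parent = emptyenv())  # sequence -> stratum/pref allele
  get_rank <- function(seqs, allele) {
    vapply(seqs, function(s) {
      k <- paste0(s, "|", allele)
      if (is.null(rank_env[[k]])) {
        meta <- stratum_env[[s]]
        rank_env[[k]] <-
          if (allele == cfg$shared_allele && meta$stratum == "strong")
            rank_band(1L, "strong")
          else if (allele == cfg$shared_allele && meta$stratum == "weak")
            rank_band(1L, "weak")
          else if (identical(allele, meta$pref_allele))
            rank_band(1L, "binder")
          else rank_band(1L, "background")
      }
      rank_env[[k]]
    }, numeric(1))
  }
  register <- function(seqs, strata, pref_alleles) {
    for (i in seq_along(seqs))
      stratum_env[[seqs[i]]] <- list(stratum = strata[i],
                                     pref_allele = pref_alleles[i])
  }
  line_seqs <- vector("list", n_lines)
  planted_rows <- list()
  # RNF111-like: one motif-conforming octamer forced into the non-binder
  # stratum of the deepest line, q in the 1-10% FDR window
  rnf_line <- which.max(cfg$depths)
  for (j in seq_len(n_lines)) {
    panel <- cfg$allele_panels[[j]]
    shared_in <- character()
    for (i in seq_len(j - 1L)) {
      src <- line_seqs[[i]]
      src <- src[!src %in% shared_in]
      take <- src[stats::runif(length(src)) < cfg$sharing[i, j]]
      shared_in <- c(shared_in, take)
    }
    shared_in <- utils::head(shared_in, cfg$depths[j] - cfg$n_planted - 1L)
    n_planted_j <- cfg$n_planted + (j == rnf_line)
    n_fresh <- cfg$depths[j] - length(shared_in) - n_planted_j
    fresh <- unique(sample_background_peptides(ceiling(n_fresh * 1.02),
                                               cfg$length_probs))
    fresh <- setdiff(fresh, shared_in)
    while (length(fresh) < n_fresh)
      fresh <- setdiff(unique(c(fresh,
        sample_background_peptides(n_fresh, cfg$length_probs))), shared_in)
    fresh <- fresh[seq_len(n_fresh)]
    strata <- sample(names(cfg$strata_probs), n_fresh, replace = TRUE,
                     prob = cfg$strata_probs)
    pref <- sample(setdiff(panel, cfg$shared_allele), n_fresh, replace = TRUE)
    pref[strata != "other"] <- NA_character_
    register(fresh, strata, pref)
    # planted stimulatory peptides: motif-conforming, strong binders of the
    # shared allele (70% nonamers, rest octamers)
    n9 <- stats::rbinom(1L, cfg$n_planted, 0.7)
    planted <- c(sample_truth_peptides(n9, 9L, cfg$truth),
                 sample_truth_peptides(cfg$n_planted - n9, 8L, cfg$truth))
    planted <- setdiff(unique(planted), c(fresh, shared_in))
    while (length(planted) < cfg$n_planted)
      planted <- setdiff(unique(c(planted,
        sample_truth_peptides(2L, 9L, cfg$truth))), c(fresh, shared_in))
    planted <- planted[seq_len(cfg$n_planted)]
    register(planted, rep("strong", cfg$n_planted),
             rep(NA_character_, cfg$n_planted))
    kind <- rep("stimulatory", cfg$n_planted)
    stratum <- rep("strong", cfg$n_planted)
    if (j == rnf_line) {
      repeat {
        rnf <- sample_truth_peptides(1L, 8L, cfg$truth)
        if (!rnf %in% c(fresh, shared_in, planted)) break
      }
      register(rnf, "non_binder", NA_character_)
      planted <- c(planted, rnf)
      kind <- c(kind, "non_binder_ligand")
      stratum <- c(stratum, "non_binder")
    }
    planted_rows[[j]] <- if (length(planted))
      data.frame(sequence = planted, cell_line = cfg$line_names[j],
                 kind = kind, stratum = stratum)
    else NULL
    line_seqs[[j]] <- c(shared_in, fresh, planted)
  }
  gold_planted <- do.call(rbind, planted_rows)
  # assemble record tables
  categories <- c("CDS", "UTR5", "UTR3", "OffFrame", "Intronic", "Intergenic")
  cat_probs <- c(0.62, 0.12, 0.10, 0.08, 0.05, 0.03)
  peptidomes <- list()
  dup_counts <- integer(n_lines)
  for (j in seq_len(n_lines)) {
    panel <- cfg$allele_panels[[j]]
    seqs <- line_seqs[[j]]
    nrec <- length(seqs)
    rec <- data.frame(sequence = seqs,
                      q_value = draw_q(nrec, cfg$q_probs),
                      category = sample(categories, nrec, replace = TRUE,
                                        prob = cat_probs),
                      cell_line = cfg$line_names[j],
                      stringsAsFactors = FALSE)
    for (a in panel) rec[[a]] <- get_rank(seqs, a)
    # planted peptides are confident identifications; the non-binder-stratum
    # ligand sits in the (1%, 10%] FDR window by construction
    pl <- gold_planted[gold_planted$cell_line == cfg$line_names[j], ]
    idx <- match(pl$sequence, rec$sequence)
    rec$q_value[idx[pl$kind == "stimulatory"]] <-
      stats::runif(sum(pl$kind == "stimulatory"), 1e-4, 0.009)
    nb <- idx[pl$kind == "non_binder_ligand"]
    if (length(nb)) rec$q_value[nb] <- stats::runif(length(nb), 0.0102, 0.0999)
    # planted duplicate records: same sequence, weaker q
    ndup <- min(cfg$n_duplicates, nrec)
    dup_counts[j] <- ndup
    if (ndup > 0L) {
      di <- sample.int(nrec, ndup)
      dup <- rec[di, , drop = FALSE]
      dup$q_value <- pmin(dup$q_value * 1.5 + 0.001, 1)
      rec <- rbind(rec, dup)
      rec <- rec[sample.int(nrow(rec)), , drop = FALSE]
      rownames(rec) <- NULL
    }
    peptidomes[[cfg$line_names[j]]] <-
      Immunopeptidome(cfg$line_names[j], rec, alleles = panel)
  }
  names(dup_counts) <- cfg$line_names
  # generator bookkeeping: exclusive membership pattern counts
  universe <- unique(unlist(line_seqs))
  member <- vapply(line_seqs, function(s) universe %in% s,
                   logical(length(universe)))
  colnames(member) <- cfg$line_names
  patterns <- apply(member, 1, function(row)
    paste(cfg$line_names[row], collapse = "&"))
  pattern_counts <- table(patterns)
  # synthetic proteome embedding every emitted peptide
  shuffled <- sample(universe)
  per_protein <- 40L
  splits <- split(shuffled, (seq_along(shuffled) - 1L) %/% per_protein)
  prot_seqs <- vapply(splits, paste, "", collapse = "")
  names(prot_seqs) <- sprintf("SYNP%05d", seq_along(prot_seqs))
  plant_positions <- do.call(rbind, lapply(seq_along(splits), function(k) {
    lens <- nchar(splits[[k]])
    starts <- cumsum(c(0L, lens[-length(lens)]))
    data.frame(peptide = splits[[k]], protein_id = names(prot_seqs)[k],
               start = starts, end = starts + lens)
  }))
  rownames(plant_positions) <- NULL
  proteome <- Biostrings::AAStringSet(prot_seqs)
  list(peptidomes = peptidomes,
       gold = list(planted = gold_planted,
                   pattern_counts = pattern_counts,
                   duplicates = dup_counts,
                   plant_positions = plant_positions,
                   truth = cfg$truth,
                   config = cfg),
       proteome = proteome)
}

#' Write a synthetic suite to disk
#'
#' Emits one module-standard peptide TSV per line, the gold-label TSV, the
#' proteome FASTA and a JSON echo of the configuration.
#'
#' @param suite Output of [generate_peptidome_suite()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_suite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(suite$peptidomes))
    write_peptide_table(suite$peptidomes[[nm]],
                        file.path(dir, paste0(nm, ".tsv")))
  utils::write.table(suite$gold$planted, file.path(dir, "gold_planted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(suite$proteome,
                              file.path(dir, "proteome.fasta"))
  cfg <- suite$gold$config
  jsonlite::write_json(
    list(seed = cfg$seed, depths = cfg$depths, line_names = cfg$line_names,
         length_probs = as.list(cfg$length_probs),
         shared_allele = cfg$shared_allele,
         strata_probs = as.list(cfg$strata_probs),
         n_planted = cfg$n_planted, n_duplicates = cfg$n_duplicates),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
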