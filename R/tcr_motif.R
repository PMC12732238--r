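#' Default motif configuration
#'
#' Position conventions for the TCR recognition motif, 1-based peptide
#' positions. For nonamers the HLA anchor positions are P2/P7/P9 and the
#' TCR contact positions P5/P8; for octamers the anchors are P2/P8 and the
#' contacts P5/P7 (C-terminally aligned scaling of the nonamer scheme). The
#' contact requirement is satisfied when at least one contact position
#' carries a basic residue (R or K); glutamine is additionally admitted at
#' position 5 (a stimulatory mimotope carried Q5), controllable via
#' `allow_q_p5`. Anchor allowed-residue sets default to `NULL`, meaning
#' "derive empirically from the stimulatory panel" at motif-build time; a
#' config can pin explicit sets instead.
#'
#' @param contact_residues Residues accepted at contact positions.
#' @param contact_mode `"any"` (default: one contact position suffices) or
#'   `"all"` (every contact position must carry an accepted residue).
#' @param allow_q_p5 Also accept `Q` at peptide position 5.
#' @param anchor_allowed Optional list mapping length (as character `"8"`,
#'   `"9"`) to a named list position -> character vector of allowed residues;
#'   `NULL` entries are filled from the panel.
#' @return A list of class `motif_config`.
#' @export
motif_config <- function(contact_residues = c("R", "K"),
                         contact_mode = c("any", "all"),
                         allow_q_p5 = TRUE,
                         anchor_allowed = NULL) {
  contact_mode <- match.arg(contact_mode)
  structure(list(
    positions = list(
      `9` = list(anchors = c(2L, 7L, 9L), contacts = c(5L, 8L)),
      `8` = list(anchors = c(2L, 8L), contacts = c(5L, 7L))),
    contact_residues = contact_residues,
    contact_mode = contact_mode,
    allow_q_p5 = allow_q_p5,
    anchor_allowed = anchor_allowed), class = "motif_config")
}

#' Validate a stimulatory-ligand panel
#'
#' A panel is a data frame with columns `sequence`, `label`
#' (`stimulatory` / `non_stimulatory`) and `provenance`
#' (`library`, `anchor_exchange`, `alanine_scan`, `proteome_match`). Only
#' peptides of length 8 or 9 are admitted and each length group used must
#' contain at least one stimulatory peptide.
#'
#' @param panel Data frame as above.
#' @return The validated panel (sequences upper-cased).
#' @export
ligand_panel <- function(panel) {
  panel <- as.data.frame(panel)
  need <- c("sequence", "label", "provenance")
  if (!all(need %in% names(panel)))
    stop("panel needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  panel$sequence <- toupper(panel$sequence)
  if (!all(is_valid_peptide(panel$sequence)))
    stop("panel contains invalid sequences", call. = FALSE)
  if (!all(nchar(panel$sequence) %in% c(8L, 9L)))
    stop("panel peptides must be 8- or 9-mers", call. = FALSE)
  if (!all(panel$label %in% c("stimulatory", "non_stimulatory")))
    stop("labels must be stimulatory/non_stimulatory", call. = FALSE)
  panel
}

#' Read a ligand panel from a delimited file
#' @param path TSV/CSV with columns `sequence`, `label`, `provenance`.
#' @return Validated panel data frame.
#' @export
read_ligand_panel <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (!grepl("\t", header) && grepl(",", header)) "," else "\t"
  ligand_panel(utils::read.table(path, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE))
}

count_matrix <- function(peptides) {
  m <- peptide_matrix(peptides)
  t(vapply(seq_len(ncol(m)), function(j)
    table(factor(m[, j], levels = AA_ALPHABET)),
    integer(length(AA_ALPHABET))))
}

#' Build a TCR peptide recognition motif from a ligand panel
#'
#' For each peptide length (8 and 9) with at least one stimulatory panel
#' member, estimates a position-probability matrix from the stimulatory
#' peptides with a pseudocount — `p(pos, a) = (count + pc) / (n + 20*pc)` —
#' and a log-odds matrix `log2(p / background)`. Anchor positions keep
#' allowed-residue sets (by default the residues observed among stimulatory
#' peptides at that position, the empirical HLA-binding motif of the panel);
#' contact positions keep the required basic-residue rule from the config.
#' With `discriminative = TRUE` the log-odds contrasts stimulatory against
#' non-stimulatory panel members instead of against the background.
#'
#' @param panel A [ligand_panel()] data frame.
#' @param pseudocount Non-negative pseudocount (default 1).
#' @param background Length-20 residue-frequency vector named by
#'   [AA_ALPHABET], or `NULL` for uniform 1/20.
#' @param config A [motif_config()].
#' @param discriminative Use stimulatory-vs-non-stimulatory log-odds.
#' @return Object of class `RecognitionMotif`: a list with one entry per
#'   length holding `ppm`, `lod`, `anchors`, `contacts`, `n_stim`, plus the
#'   shared `background` and `config`.
#' @export
build_motif <- function(panel, pseudocount = 1, background = NULL,
                        config = motif_config(), discriminative = FALSE) {
  panel <- ligand_panel(panel)
  stopifnot(pseudocount >= 0)
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  background <- background[AA_ALPHABET]
  stopifnot(abs(sum(background) - 1) < 1e-6)
  out <- list(lengths = list(), background = background, config = config)
  for (L in c(8L, 9L)) {
    key <- as.character(L)
    stim <- panel$sequence[panel$label == "stimulatory" &
                             nchar(panel$sequence) == L]
    if (!length(stim)) {
      if (any(nchar(panel$sequence) == L))
        warning("no stimulatory ", L, "-mers in panel; motif for length ",
                L, " absent", call. = FALSE)
      next
    }
    counts <- count_matrix(stim)
    ppm <- (counts + pseudocount) / (length(stim) + 20 * pseudocount)
    if (discriminative) {
      non <- panel$sequence[panel$label == "non_stimulatory" &
                              nchar(panel$sequence) == L]
      pc <- max(pseudocount, 0.5)  # avoid log(0) against empty negatives
      nc <- if (length(non)) count_matrix(non) else
        matrix(0L, nrow = L, ncol = 20, dimnames = dimnames(counts))
      pn <- (nc + pc) / (length(non) + 20 * pc)
      lod <- log2(((counts + pc) / (length(stim) + 20 * pc)) / pn)
    } else {
      lod <- log2(ppm / matrix(background, nrow = L, ncol = 20, byrow = TRUE))
    }
    pos <- config$positions[[key]]
    allowed <- config$anchor_allowed[[key]]
    anchors <- lapply(pos$anchors, function(a) {
      pinned <- allowed[[as.character(a)]]
      if (!is.null(pinned)) sort(unique(toupper(pinned)))
      else sort(unique(substr(stim, a, a)))
    })
    names(anchors) <- as.character(pos$anchors)
    contacts <- lapply(pos$contacts, function(cpos) {
      req <- config$contact_residues
      if (config$allow_q_p5 && cpos == 5L) req <- union(req, "Q")
      sort(unique(req))
    })
    names(contacts) <- as.character(pos$contacts)
    out$lengths[[key]] <- list(
      length = L, n_stim = length(stim), ppm = ppm, lod = lod,
      anchors = anchors, contacts = contacts,
      contact_mode = config$contact_mode)
  }
  if (!length(out$lengths))
    stop("panel yielded no motif (no stimulatory peptides)", call. = FALSE)
  class(out) <- "RecognitionMotif"
  out
}

#' @export
print.RecognitionMotif <- function(x, ...) {
  for (key in names(x$lengths)) {
    m <- x$lengths[[key]]
    cat(sprintf("%s-mer motif from %d stimulatory peptides\n",
                key, m$n_stim))
    cat("  anchors:",
        paste(sprintf("P%s{%s}", names(m$anchors),
                      vapply(m$anchors, paste, "", collapse = "")),
              collapse = " "), "\n")
    cat("  contacts:",
        paste(sprintf("P%s{%s}", names(m$contacts),
                      vapply(m$contacts, paste, "", collapse = "")),
              collapse = " "), sprintf("(mode %s)\n", m$contact_mode))
  }
  invisible(x)
}

#' Per-position information content of a motif
#'
#' Sequence-logo information content in bits:
#' `IC(pos) = log2(20) + sum_a p(pos,a) * log2 p(pos,a)`, bounded in
#' `[0, log2 20]`; a uniform position scores 0 and a single-residue position
#' scores `log2(20) ~ 4.32` bits.
#'
#' @param m A `RecognitionMotif`.
#' @param length Peptide length (8 or 9) selecting the matrix.
#' @return Named numeric vector of per-position bits.
#' @export
position_information_content <- function(m, length = 9L) {
  key <- as.character(length)
  ent <- m$lengths[[key]]
  if (is.null(ent)) stop("no motif for length ", length, call. = FALSE)
  p <- ent$ppm
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ic <- log2(20) + rowSums(plogp)
  stats::setNames(pmax(ic, 0), paste0("P", seq_len(nrow(p))))
}

match_one <- function(m, peptide, threshold) {
  L <- nchar(peptide)
  key <- as.character(L)
  res <- list(sequence = peptide, length_ok = FALSE, anchor_ok = FALSE,
              contact_ok = FALSE, score = NA_real_, passed = FALSE)
  ent <- m$lengths[[key]]
  if (is.null(ent)) return(res)
  res$length_ok <- TRUE
  aa <- strsplit(peptide, "")[[1]]
  res$anchor_ok <- all(vapply(names(ent$anchors), function(a)
    aa[as.integer(a)] %in% ent$anchors[[a]], logical(1)))
  hit <- vapply(names(ent$contacts), function(cpos)
    aa[as.integer(cpos)] %in% ent$contacts[[cpos]], logical(1))
  res$contact_ok <- if (ent$contact_mode == "all") all(hit) else any(hit)
  idx <- match(aa, AA_ALPHABET)
  res$score <- sum(ent$lod[cbind(seq_len(L), idx)])
  res$passed <- res$length_ok && res$anchor_ok && res$contact_ok &&
    res$score >= threshold
  res
}

#' Match a single peptide against a recognition motif
#'
#' Applies the combined rule set: the peptide length must have a motif; every
#' anchor position must carry an allowed residue; the contact requirement
#' (basic residue at a contact position) must hold; and the summed log-odds
#' score must reach `threshold`. All four conditions are reported separately.
#'
#' @param m A `RecognitionMotif`.
#' @param peptide Peptide sequence.
#' @param threshold Score threshold in bits (default 0: better than
#'   background).
#' @return One-row data frame: `sequence`, `length_ok`, `anchor_ok`,
#'   `contact_ok`, `score`, `passed`.
#' @export
match_peptide <- function(m, peptide, threshold = 0) {
  peptide <- toupper(peptide)
  if (!is_valid_peptide(peptide))
    stop("invalid peptide: ", peptide, call. = FALSE)
  as.data.frame(match_one(m, peptide, threshold))
}

#' Screen a peptidome for candidate TCR ligands
#'
#' Evaluates [match_peptide()] on every unique 8-/9-mer of the input and
#' returns the passing candidates ranked by descending log-odds score (ties
#' broken lexicographically by sequence), so the candidate list is
#' reproducible bit-for-bit across runs and input orderings.
#'
#' When `peptides` is an [Immunopeptidome], the unique sequences are first
#' restricted to assigned HLA binders of `allele` unless
#' `include_nonbinders = TRUE` (the non-binder fraction has yielded true TCR
#' ligands, so screening it is supported explicitly).
#'
#' @param m A `RecognitionMotif`.
#' @param peptides Character vector of sequences or an [Immunopeptidome].
#' @param threshold Score threshold in bits.
#' @param top_k Optional truncation after ranking.
#' @param include_nonbinders Peptidome input only: keep peptides not assigned
#'   to any allele.
#' @param allele Peptidome input only: allele whose binder set is screened
#'   when `include_nonbinders = FALSE`.
#' @return Data frame of passing candidates: `sequence`, `length_ok`,
#'   `anchor_ok`, `contact_ok`, `score`, `passed`, `rank`; attribute
#'   `"n_evaluated"` records how many 8-/9-mers were scored.
#' @export
screen_peptidome <- function(m, peptides, threshold = 0, top_k = NULL,
                             include_nonbinders = FALSE,
                             allele = "HLA-C*06:02") {
  if (inherits(peptides, "Immunopeptidome")) {
    peptides <- if (include_nonbinders) deduplicate(peptides)
                else c0602_binder_set(peptides, allele = allele)
  }
  peptides <- sort(unique(toupper(peptides)))
  peptides <- peptides[nchar(peptides) %in% c(8L, 9L)]
  n_eval <- length(peptides)
  if (!n_eval) {
    out <- data.frame(sequence = character(), length_ok = logical(),
                      anchor_ok = logical(), contact_ok = logical(),
                      score = numeric(), passed = logical(), rank = integer())
    attr(out, "n_evaluated") <- 0L
    return(out)
  }
  res <- do.call(rbind, lapply(peptides, function(p)
    as.data.frame(match_one(m, p, threshold))))
  cand <- res[res$passed, , drop = FALSE]
  cand <- cand[order(-cand$score, cand$sequence), , drop = FALSE]
  if (!is.null(top_k)) cand <- utils::head(cand, top_k)
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  attr(cand, "n_evaluated") <- n_eval
  cand
}

#' Serialize a recognition motif to JSON
#'
#' Canonical representation (stable key order, matrices as row-major lists of
#' named rows) so two builds of the same motif diff cleanly.
#'
#' @param m A `RecognitionMotif`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif <- function(m, path) {
  ser_len <- function(ent) list(
    length = ent$length, n_stim = ent$n_stim,
    ppm = apply(ent$ppm, 1, function(r) as.list(stats::setNames(r, AA_ALPHABET)),
                simplify = FALSE),
    lod = apply(ent$lod, 1, function(r) as.list(stats::setNames(r, AA_ALPHABET)),
                simplify = FALSE),
    anchors = ent$anchors, contacts = ent$contacts,
    contact_mode = ent$contact_mode)
  doc <- list(
    format = "pepscreen-motif/1",
    background = as.list(m$background),
    lengths = lapply(m$lengths[order(names(m$lengths))], ser_len),
    config = list(contact_residues = m$config$contact_residues,
                  contact_mode = m$config$contact_mode,
                  allow_q_p5 = m$config$allow_q_p5))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a recognition motif from JSON written by [write_motif()]
#' @param path JSON path.
#' @return A `RecognitionMotif`.
#' @export
read_motif <- function(path) {
  doc <- jsonlite::read_json(path)
  bg <- unlist(doc$background)[AA_ALPHABET]
  de_len <- function(e) {
    L <- e$length
    mat <- function(rows) {
      mm <- do.call(rbind, lapply(rows, function(r) unlist(r)[AA_ALPHABET]))
      rownames(mm) <- NULL
      mm
    }
    list(length = L, n_stim = e$n_stim, ppm = mat(e$ppm), lod = mat(e$lod),
         anchors = lapply(e$anchors, function(a) unlist(a)),
         contacts = lapply(e$contacts, function(a) unlist(a)),
         contact_mode = e$contact_mode)
  }
  cfg <- motif_config(contact_residues = unlist(doc$config$contact_residues),
                      contact_mode = doc$config$contact_mode,
                      allow_q_p5 = isTRUE(doc$config$allow_q_p5))
  structure(list(lengths = lapply(doc$lengths, de_len), background = bg,
                 config = cfg), class = "RecognitionMotif")
}
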