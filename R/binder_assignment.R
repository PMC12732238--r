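#' Classify a percent rank into binder categories
#'
#' NetMHCpan-style classification: a peptide is a strong binder at
#' `rank <= strong_cut`, a weak binder at `strong_cut < rank <= weak_cut`, and
#' a non-binder above `weak_cut`. Cutoffs are inclusive on the binder side,
#' matching NetMHCpan convention. Defaults are the conventional 0.5% / 2%.
#'
#' @param rank Numeric vector of percent ranks (non-negative; lower is
#'   stronger).
#' @param strong_cut Strong-binder cutoff in percent rank.
#' @param weak_cut Weak-binder cutoff in percent rank.
#' @return Character vector in `{"strong","weak","non_binder"}`.
#' @examples
#' classify_rank(c(0.4, 1.5, 2.5))
#' @export
classify_rank <- function(rank, strong_cut = 0.5, weak_cut = 2.0) {
  if (!is.numeric(rank) || any(rank < 0, na.rm = TRUE))
    stop("`rank` must be non-negative", call. = FALSE)
  stopifnot(strong_cut > 0, strong_cut < weak_cut)
  out <- rep(NA_character_, length(rank))
  out[!is.na(rank) & rank <= strong_cut] <- "strong"
  out[!is.na(rank) & rank > strong_cut & rank <= weak_cut] <- "weak"
  out[!is.na(rank) & rank > weak_cut] <- "non_binder"
  out
}

#' Best-binder call for one record
#'
#' Assigns a peptide to the allele with the minimal percent rank among the
#' cell line's alleles ("best binder analysis") and classifies that minimal
#' rank. Ties are broken by allele-list order (first wins). A record with no
#' rank, or whose minimal rank exceeds the weak cutoff, is a non-binder with
#' allele `NA`.
#'
#' @param ranks Named numeric vector of percent ranks (names are alleles);
#'   `NA` entries are ignored.
#' @param alleles Allele list defining eligibility and tie order; defaults to
#'   `names(ranks)`.
#' @inheritParams classify_rank
#' @return List with elements `allele` (or `NA`), `category`, `rank`.
#' @export
best_binder <- function(ranks, alleles = names(ranks),
                        strong_cut = 0.5, weak_cut = 2.0) {
  ranks <- ranks[intersect(alleles, names(ranks))]
  ranks <- ranks[!is.na(ranks)]
  if (!length(ranks))
    return(list(allele = NA_character_, category = "non_binder",
                rank = NA_real_))
  ord <- match(names(ranks), alleles)
  best <- order(ranks, ord)[1L]
  cat <- classify_rank(ranks[[best]], strong_cut, weak_cut)
  list(allele = if (cat == "non_binder") NA_character_ else names(ranks)[best],
       category = cat, rank = unname(ranks[[best]]))
}

#' Assign binder calls across a peptidome
#'
#' Vectorized best-binder assignment: adds `assigned_allele`,
#' `binder_category` and `assigned_rank` columns to the record table.
#'
#' @param p An [Immunopeptidome].
#' @inheritParams classify_rank
#' @return Data frame: the records with the three assignment columns added.
#' @export
assign_binders <- function(p, strong_cut = 0.5, weak_cut = 2.0) {
  stopifnot(inherits(p, "Immunopeptidome"))
  rec <- p$records
  cols <- intersect(p$alleles, names(rec))
  n <- nrow(rec)
  if (!length(cols) || n == 0L) {
    rec$assigned_allele <- rep(NA_character_, n)
    rec$binder_category <- rep("non_binder", n)
    rec$assigned_rank <- rep(NA_real_, n)
    return(rec)
  }
  m <- as.matrix(rec[, cols, drop = FALSE])
  # allele order = p$alleles order; max.col on negated ranks with ties.method
  # "first" implements argmin with first-allele tie-breaking
  m_order <- m[, intersect(p$alleles, cols), drop = FALSE]
  filled <- m_order
  filled[is.na(filled)] <- Inf
  idx <- max.col(-filled, ties.method = "first")
  best_rank <- filled[cbind(seq_len(n), idx)]
  best_rank[!is.finite(best_rank)] <- NA_real_
  category <- ifelse(is.na(best_rank), "non_binder",
                     classify_rank(pmin(best_rank, Inf), strong_cut, weak_cut))
  category[is.na(category)] <- "non_binder"
  allele <- colnames(m_order)[idx]
  allele[category == "non_binder"] <- NA_character_
  rec$assigned_allele <- allele
  rec$binder_category <- category
  rec$assigned_rank <- best_rank
  rec
}

#' Unique binder set for a given allele
#'
#' Unique peptide sequences whose best-binder allele is `allele` with a
#' strong or weak classification — the per-allele immunopeptidome (by default
#' HLA-C*06:02, the shared allele of the study design this package serves).
#'
#' @param p An [Immunopeptidome].
#' @param allele Allele of interest; must be in the peptidome's panel and
#'   carried as a rank column.
#' @inheritParams classify_rank
#' @return Character vector of unique sequences.
#' @export
c0602_binder_set <- function(p, allele = "HLA-C*06:02",
                             strong_cut = 0.5, weak_cut = 2.0) {
  stopifnot(inherits(p, "Immunopeptidome"))
  if (!(allele %in% p$alleles) || !(allele %in% names(p$records)))
    stop("allele ", allele, " absent from peptidome ", p$name, call. = FALSE)
  rec <- assign_binders(p, strong_cut, weak_cut)
  keep <- !is.na(rec$assigned_allele) & rec$assigned_allele == allele &
    rec$binder_category %in% c("strong", "weak")
  unique(rec$sequence[keep])
}

#' Peptide length distribution
#'
#' Counts peptides per length over the listed lengths and converts to
#' percentages of the listed-length total, rounded half-up to two decimals
#' (the convention of printed immunopeptidome summary tables). Lengths
#' outside `lengths` are tallied separately in the `"other"` attribute.
#'
#' @param s Character vector of peptide sequences (a unique set).
#' @param lengths Integer lengths to report on; default 8–11.
#' @return List of class `LengthDistribution` with `counts` and `percents`
#'   (both named by length) and `total`.
#' @examples
#' length_distribution(c("ABCDEFGH", replicate(3, paste(sample(LETTERS[1:20], 9,
#'   TRUE), collapse = ""))))
#' @export
length_distribution <- function(s, lengths = 8:11) {
  len <- nchar(s)
  counts <- vapply(lengths, function(L) sum(len == L), integer(1))
  names(counts) <- as.character(lengths)
  total <- sum(counts)
  percents <- if (total > 0) round_half_up(100 * counts / total, 2)
              else stats::setNames(rep(0, length(counts)), names(counts))
  structure(list(counts = counts, percents = percents, total = total),
            other = sum(!len %in% lengths),
            class = "LengthDistribution")
}

#' @export
print.LengthDistribution <- function(x, ...) {
  for (L in names(x$counts))
    cat(sprintf("%s-mers: %d (%.2f%%)\n", L, x$counts[[L]], x$percents[[L]]))
  invisible(x)
}

#' Non-binder fraction of a peptidome
#'
#' Percent of unique peptides whose best rank across the cell line's alleles
#' exceeds the weak cutoff (peptides that cannot be mapped to any allele).
#'
#' @param p An [Immunopeptidome].
#' @inheritParams classify_rank
#' @return Percent of total unique peptides, rounded half-up to 2 decimals.
#' @export
non_binder_fraction <- function(p, strong_cut = 0.5, weak_cut = 2.0) {
  rec <- assign_binders(p, strong_cut, weak_cut)
  ord <- order(match(rec$sequence, rec$sequence), rec$assigned_rank)
  rec <- rec[ord, , drop = FALSE]
  uniq <- rec[!duplicated(rec$sequence), , drop = FALSE]
  if (!nrow(uniq)) return(0)
  round_half_up(100 * mean(uniq$binder_category == "non_binder"), 2)
}
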