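#' Construct an immunopeptidome
#'
#' An immunopeptidome is a named collection of identified HLA class I ligands
#' for one cell line, together with the cell line's HLA allele panel and
#' (optionally) its ERAP1 diplotype. Records are held in a data frame with one
#' row per identification: columns `sequence`, `length`, `q_value`, `category`,
#' `cell_line`, plus one numeric column per allele holding the NetMHCpan-style
#' percent rank (`NA` where no prediction is available).
#'
#' @param name Cell-line / peptidome identifier (non-empty string).
#' @param records Data frame of peptide records. Must contain `sequence` and
#'   `q_value`; `category` and `cell_line` are filled with defaults when
#'   absent. Any additional numeric column whose name is listed in `alleles`
#'   is treated as a percent-rank column.
#' @param alleles Character vector of HLA allele names carried by the cell
#'   line. Defaults to the record columns that are not core fields.
#' @param erap1 Optional ERAP1 diplotype label (e.g. `"Hap2/Hap10"`).
#' @return An object of class `Immunopeptidome`.
#' @examples
#' rec <- data.frame(sequence = c("VRSRRCLRL", "RRLPCRKR"),
#'                   q_value = c(0.001, 0.0106),
#'                   `HLA-C*06:02` = c(0.2, 5.0), check.names = FALSE)
#' Immunopeptidome("demo", rec, alleles = "HLA-C*06:02")
#' @export
Immunopeptidome <- function(name, records, alleles = NULL, erap1 = NA_character_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string", call. = FALSE)
  records <- as.data.frame(records, check.names = FALSE)
  core <- c("sequence", "length", "q_value", "category", "cell_line")
  if (!all(c("sequence", "q_value") %in% names(records)))
    stop("records must contain `sequence` and `q_value` columns", call. = FALSE)
  if (is.null(alleles)) alleles <- setdiff(names(records), core)
  records$sequence <- toupper(as.character(records$sequence))
  records$length <- nchar(records$sequence)
  if (is.null(records$category))
    records$category <- rep("unknown", nrow(records))
  if (is.null(records$cell_line))
    records$cell_line <- rep(name, nrow(records))
  bad <- !is_valid_peptide(records$sequence) |
    is.na(records$q_value) | records$q_value < 0 | records$q_value > 1
  for (a in alleles) if (a %in% names(records)) {
    records[[a]] <- as.numeric(records[[a]])
    bad <- bad | (!is.na(records[[a]]) & records[[a]] < 0)
  }
  if (any(bad))
    stop("invalid records at rows: ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  extra_rank <- setdiff(names(records), c(core, alleles))
  if (length(extra_rank))
    stop("rank columns not declared in `alleles`: ",
         paste(extra_rank, collapse = ", "), call. = FALSE)
  records <- records[, c(intersect(core, names(records)),
                         intersect(alleles, names(records))), drop = FALSE]
  structure(list(name = name, alleles = alleles, erap1 = erap1,
                 records = records),
            class = "Immunopeptidome")
}

#' @export
print.Immunopeptidome <- function(x, ...) {
  cat(sprintf("Immunopeptidome '%s': %d records, %d unique peptides\n",
              x$name, nrow(x$records), length(unique(x$records$sequence))))
  cat("  alleles:", paste(x$alleles, collapse = ", "), "\n")
  if (!is.na(x$erap1)) cat("  ERAP1:", x$erap1, "\n")
  invisible(x)
}

#' @export
length.Immunopeptidome <- function(x) nrow(x$records)

#' Read a peptide identification table
#'
#' Reads a delimited peptide table (TSV by default; comma-separated files are
#' detected automatically) into an [Immunopeptidome]. Mandatory columns are
#' `sequence` and `q_value`; `category` and `cell_line` are optional, and any
#' further numeric column is interpreted as a per-allele percent-rank column
#' named exactly by the allele (e.g. `HLA-C*06:02`). Rows violating the
#' sequence alphabet or the `q_value`/rank range invariants are dropped with a
#' row-indexed warning; input order of the surviving rows is preserved.
#'
#' @param path Path to the delimited file.
#' @param dialect Optional named character vector remapping nonstandard
#'   headers, e.g. `c(sequence = "Peptide", q_value = "qval")`: names are the
#'   standard column names, values the headers found in the file.
#' @param name Peptidome name; defaults to the file name without extension.
#' @param alleles Optional explicit allele list; defaults to all non-core
#'   columns.
#' @param erap1 Optional ERAP1 diplotype label.
#' @param sep Field separator; `NULL` (default) sniffs tab vs comma.
#' @return An [Immunopeptidome]. An empty file yields an empty peptidome with
#'   a warning.
#' @export
read_peptide_table <- function(path, dialect = NULL, name = NULL,
                               alleles = NULL, erap1 = NA_character_,
                               sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (length(header) && !grepl("\t", header) && grepl(",", header))
      "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      hit <- match(dialect[[std]], names(df))
      if (!is.na(hit)) names(df)[hit] <- std
    }
  }
  if (nrow(df) == 0L) {
    warning("empty peptide table: ", path, call. = FALSE)
    empty <- data.frame(sequence = character(), q_value = numeric())
    return(Immunopeptidome(name, empty, alleles = alleles %||% character(),
                           erap1 = erap1))
  }
  missing <- setdiff(c("sequence", "q_value"), names(df))
  if (length(missing))
    stop("mandatory column(s) missing (dialect unresolved): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$sequence <- toupper(as.character(df$sequence))
  df$q_value <- suppressWarnings(as.numeric(df$q_value))
  core <- c("sequence", "length", "q_value", "category", "cell_line")
  if (is.null(alleles)) alleles <- setdiff(names(df), core)
  bad <- !is_valid_peptide(df$sequence) |
    is.na(df$q_value) | df$q_value < 0 | df$q_value > 1
  for (a in intersect(alleles, names(df))) {
    df[[a]] <- suppressWarnings(as.numeric(df[[a]]))
    bad <- bad | (!is.na(df[[a]]) & df[[a]] < 0)
  }
  if (any(bad)) {
    warning(sprintf("rejected %d invalid row(s): %s", sum(bad),
                    paste(which(bad), collapse = ", ")), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  Immunopeptidome(name, df, alleles = alleles, erap1 = erap1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a peptide table
#'
#' Serializes an [Immunopeptidome]'s records as TSV (the module-standard
#' on-disk format); [read_peptide_table()] round-trips the result losslessly.
#'
#' @param p An [Immunopeptidome].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(p, path) {
  stopifnot(inherits(p, "Immunopeptidome"))
  utils::write.table(p$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter a peptidome by false discovery rate
#'
#' Keeps records whose identification q-value does not exceed `threshold`
#' (inclusive comparison, so a peptide with q = 0.0106 survives a 1.06%
#' threshold). With `per_category = TRUE` the same per-record rule applies,
#' and kept/total counts per identification category are attached as the
#' `"category_counts"` attribute for reporting; category-wise q-value
#' recomputation is an upstream (Peptide-PRISM) concern and is not redone
#' here.
#'
#' @param p An [Immunopeptidome].
#' @param threshold FDR threshold as a fraction in (0, 1].
#' @param per_category Report per-category kept/total counts.
#' @return A new filtered [Immunopeptidome]; the input is not modified.
#' @export
filter_by_fdr <- function(p, threshold, per_category = FALSE) {
  stopifnot(inherits(p, "Immunopeptidome"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("`threshold` must be a fraction in (0, 1]", call. = FALSE)
  keep <- p$records$q_value <= threshold
  out <- p
  out$records <- p$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  if (per_category) {
    tot <- table(p$records$category)
    kept <- table(factor(p$records$category[keep], levels = names(tot)))
    attr(out, "category_counts") <- data.frame(
      category = names(tot), total = as.integer(tot), kept = as.integer(kept))
  }
  out
}

#' Unique peptide sequences of a peptidome
#'
#' Case-normalized exact-string deduplication. Where a sequence occurs in
#' several records the minimum-q_value record is kept as its provenance
#' representative (attached as attribute `"records"`).
#'
#' @param p An [Immunopeptidome] or a character vector of sequences.
#' @return Character vector of unique sequences (first-occurrence order) with
#'   attribute `"records"` (representative rows) when `p` is a peptidome.
#' @export
deduplicate <- function(p) {
  if (is.character(p)) return(unique(toupper(p)))
  stopifnot(inherits(p, "Immunopeptidome"))
  rec <- p$records
  if (nrow(rec) == 0L) return(character())
  ord <- order(match(rec$sequence, rec$sequence), rec$q_value)
  rec <- rec[ord, , drop = FALSE]
  rep_rows <- rec[!duplicated(rec$sequence), , drop = FALSE]
  # restore first-occurrence order of the original table
  first <- rep_rows[order(match(rep_rows$sequence,
                                unique(p$records$sequence))), , drop = FALSE]
  rownames(first) <- NULL
  structure(first$sequence, records = first)
}

#' Map peptides to a proteome by exact substring search
#'
#' Finds every exact occurrence of each peptide in a protein FASTA and reports
#' 0-based, half-open coordinates, deterministically ordered by peptide, then
#' protein id, then offset.
#'
#' @param peptides Character vector of peptide sequences (alphabet-valid).
#' @param proteome Path to a FASTA file, a [Biostrings::AAStringSet], or a
#'   named character vector of protein sequences.
#' @return Data frame with columns `peptide`, `protein_id`, `start`, `end`
#'   (`end` exclusive).
#' @export
map_to_proteome <- function(peptides, proteome) {
  peptides <- unique(toupper(peptides))
  if (!all(is_valid_peptide(peptides)))
    stop("invalid peptide sequence(s)", call. = FALSE)
  if (is.character(proteome) && length(proteome) == 1L && file.exists(proteome))
    proteome <- Biostrings::readAAStringSet(proteome)
  if (inherits(proteome, "AAStringSet"))
    proteome <- stats::setNames(as.character(proteome), names(proteome))
  if (is.null(names(proteome)) || any(!nzchar(names(proteome))))
    stop("proteome sequences must be named", call. = FALSE)
  # strip FASTA description lines down to the identifier token
  names(proteome) <- sub("\\s.*$", "", names(proteome))
  hits <- vector("list", length(peptides))
  pids <- sort(names(proteome))
  for (i in seq_along(peptides)) {
    pep <- peptides[i]
    rows <- list()
    for (pid in pids) {
      m <- gregexpr(pep, proteome[[pid]], fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      # gregexpr reports non-overlapping matches; rescan inside each match
      # tail to recover overlapping occurrences
      starts <- integer()
      seqc <- proteome[[pid]]
      from <- 1L
      while (TRUE) {
        pos <- regexpr(pep, substr(seqc, from, nchar(seqc)), fixed = TRUE)
        if (pos == -1L) break
        starts <- c(starts, from + pos - 1L)
        from <- from + pos  # allow overlaps
      }
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, protein_id = pid,
        start = starts - 1L, end = starts - 1L + nchar(pep))
    }
    hits[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(peptide = character(), protein_id = character(),
                      start = integer(), end = integer())
  rownames(out) <- NULL
  out
}
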