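#' Exclusive intersection counts across peptidomes (upset table)
#'
#' Counts each unique peptide exactly once under its full membership pattern
#' across the named sets — the numbers behind an upset plot. Patterns are
#' ordered by descending count, then by pattern label.
#'
#' @param sets Named list of character vectors (unique peptide sets); at
#'   least two, with distinct names. [Immunopeptidome] elements are
#'   deduplicated automatically.
#' @return Object of class `UpsetTable`: data frame with `pattern`
#'   (ampersand-joined sorted set names), `sets` (list column of name
#'   vectors), `count`; attribute `universe` holds the union size.
#' @examples
#' intersection_counts(list(A = c("x", "y"), B = c("y", "z")))
#' @export
intersection_counts <- function(sets) {
  if (length(sets) < 2L) stop("need >= 2 named sets", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))) ||
      anyDuplicated(names(sets)))
    stop("sets must carry unique non-empty names", call. = FALSE)
  sets <- lapply(sets, function(s)
    if (inherits(s, "Immunopeptidome")) as.character(deduplicate(s))
    else unique(toupper(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  pat <- apply(member, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  tab <- table(pat)
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$pattern), , drop = FALSE]
  out$sets <- strsplit(out$pattern, "&", fixed = TRUE)
  out <- out[, c("pattern", "sets", "count")]
  rownames(out) <- NULL
  structure(out, universe = length(universe),
            class = c("UpsetTable", "data.frame"))
}

#' Pairwise overlap of two peptide sets
#'
#' Shared unique-peptide count and the percent of the *first* set that is
#' shared (the denominator is `a`, so the percent is directional even though
#' the count is symmetric). The integer-rounded percent matches how such
#' overlaps are quoted in summaries (e.g. 245/388 -> 63%); a two-decimal
#' version is also returned.
#'
#' @param a,b Character vectors of peptide sequences (or [Immunopeptidome]s).
#' @return List: `shared`, `percent` (integer-rounded), `percent2` (two
#'   decimals). An empty `a` yields percent 0 with a warning.
#' @export
overlap_fraction <- function(a, b) {
  dedup <- function(s)
    if (inherits(s, "Immunopeptidome")) as.character(deduplicate(s))
    else unique(toupper(s))
  a <- dedup(a); b <- dedup(b)
  shared <- length(intersect(a, b))
  if (!length(a)) {
    warning("empty first set; percent reported as 0", call. = FALSE)
    return(list(shared = shared, percent = 0, percent2 = 0))
  }
  frac <- 100 * shared / length(a)
  list(shared = shared,
       percent = as.integer(round_half_up(frac, 0)),
       percent2 = round_half_up(frac, 2))
}

#' Write an upset table as JSON
#'
#' Patterns are encoded as sorted name lists for machine consumption.
#' @param x An `UpsetTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_upset_json <- function(x, path) {
  doc <- list(universe = attr(x, "universe"),
              patterns = lapply(seq_len(nrow(x)), function(i)
                list(sets = sort(x$sets[[i]]), count = x$count[i])))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
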