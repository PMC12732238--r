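#' Load an ERAP1 haplotype key
#'
#' The key defines, for each of the nine ERAP1 coding SNPs
#' (rs3734016, rs26653, rs26618, rs27895, rs2287987, rs30187, rs10050860,
#' rs17482078, rs27044), the translation from nucleotide allele to the
#' residue state of the canonical ERAP1 isoform, plus the mapping from
#' 9-residue-state strings to haplotype labels (Hap1..Hap10). The key is an
#' editable JSON config rather than hard-coded biology; the bundled default
#' (`erap1_key_synthetic.json`) is a synthetic, non-authoritative placeholder
#' and should be replaced with a transcription of the published haplotype
#' definitions for real analyses.
#'
#' @param path JSON key path; default is the bundled synthetic placeholder.
#' @return Object of class `Erap1HaplotypeKey`: list with `snps` (data frame:
#'   `rsid`, `ref`, `alt`, `ref_residue`, `alt_residue`) and `haplotypes`
#'   (named character vector label -> 9-state string).
#' @export
read_erap1_key <- function(path = system.file("extdata",
                                              "erap1_key_synthetic.json",
                                              package = "pepscreen")) {
  doc <- jsonlite::read_json(path)
  snps <- do.call(rbind, lapply(doc$snps, function(s)
    data.frame(rsid = s$rsid, ref = s$ref, alt = s$alt,
               ref_residue = s$ref_residue, alt_residue = s$alt_residue)))
  haps <- unlist(doc$haplotypes)
  validate_erap1_key(snps, haps)
  structure(list(snps = snps, haplotypes = haps,
                 authoritative = isTRUE(doc$authoritative)),
            class = "Erap1HaplotypeKey")
}

validate_erap1_key <- function(snps, haps) {
  if (nrow(snps) != 9L) stop("key must define exactly 9 SNPs", call. = FALSE)
  if (anyDuplicated(snps$rsid)) stop("duplicate rsIDs in key", call. = FALSE)
  if (any(nchar(haps) != 9L))
    stop("haplotype state strings must have 9 residue states", call. = FALSE)
  if (anyDuplicated(haps))
    stop("haplotype state strings must be unique", call. = FALSE)
  for (i in seq_len(9L)) {
    states <- unique(substr(haps, i, i))
    ok <- c(snps$ref_residue[i], snps$alt_residue[i])
    if (!all(states %in% ok))
      stop("haplotype states at position ", i,
           " outside declared residues for ", snps$rsid[i], call. = FALSE)
  }
  invisible(TRUE)
}

#' Translate a phased genotype into two residue-state strings
#'
#' Each haplotype's nucleotide alleles at the nine SNPs (in key order) are
#' mapped to ERAP1 residue states, giving one 9-character string per
#' chromosome. Unphased genotypes with heterozygous sites are ambiguous: the
#' error lists the `2^h` consistent phasings.
#'
#' @param g An ERAP1 genotype: list with `sample`, `alleles` (named list
#'   rsid -> character(2) nucleotide alleles) and `phased` flag, as produced
#'   by [read_erap1_genotypes()].
#' @param key An [read_erap1_key()] object.
#' @return Character vector of two 9-state strings.
#' @export
genotype_to_residue_strings <- function(g, key) {
  stopifnot(inherits(key, "Erap1HaplotypeKey"))
  missing <- setdiff(key$snps$rsid, names(g$alleles))
  if (length(missing))
    stop("genotype lacks SNP(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  translate <- function(rsid, nt) {
    row <- key$snps[key$snps$rsid == rsid, ]
    if (nt == row$ref) row$ref_residue
    else if (nt == row$alt) row$alt_residue
    else stop("allele ", nt, " not declared for ", rsid, call. = FALSE)
  }
  het <- vapply(key$snps$rsid, function(r)
    g$alleles[[r]][1] != g$alleles[[r]][2], logical(1))
  if (!isTRUE(g$phased) && any(het)) {
    combos <- expand.grid(rep(list(c(1L, 2L)), sum(het)))
    phasings <- apply(combos, 1, function(pick) {
      k <- 0L
      s1 <- s2 <- character(9)
      for (i in seq_len(9L)) {
        r <- key$snps$rsid[i]
        if (het[i]) {
          k <- k + 1L
          a1 <- g$alleles[[r]][pick[k]]
          a2 <- g$alleles[[r]][3L - pick[k]]
        } else a1 <- a2 <- g$alleles[[r]][1]
        s1[i] <- translate(r, a1); s2[i] <- translate(r, a2)
      }
      paste(paste(s1, collapse = ""), paste(s2, collapse = ""), sep = "/")
    })
    stop("unphased genotype with ", sum(het), " heterozygous site(s); ",
         "consistent phasings: ", paste(unique(phasings), collapse = "; "),
         call. = FALSE)
  }
  s1 <- vapply(key$snps$rsid, function(r) translate(r, g$alleles[[r]][1]), "")
  s2 <- vapply(key$snps$rsid, function(r) translate(r, g$alleles[[r]][2]), "")
  c(paste(s1, collapse = ""), paste(s2, collapse = ""))
}

hap_ordinal <- function(label) {
  n <- suppressWarnings(as.integer(sub("^Hap", "", label)))
  ifelse(is.na(n), .Machine$integer.max, n)  # unassigned sorts last
}

#' Call an ERAP1 diplotype from two residue-state strings
#'
#' Looks each string up in the key; an unmatched string contributes an
#' `"unassigned"` component (with a diagnostic attribute). The label is
#' canonically ordered (`Hap2/Hap10`, never `Hap10/Hap2`).
#'
#' @param states Character vector of two 9-state strings.
#' @param key An [read_erap1_key()] object.
#' @return Diplotype label `"HapX/HapY"`; attribute `"unmatched"` lists any
#'   state string absent from the key.
#' @export
call_diplotype <- function(states, key) {
  stopifnot(length(states) == 2L, inherits(key, "Erap1HaplotypeKey"))
  lab <- vapply(states, function(s) {
    hit <- names(key$haplotypes)[key$haplotypes == s]
    if (length(hit)) hit[1] else "unassigned"
  }, "", USE.NAMES = FALSE)
  ord <- order(hap_ordinal(lab), lab)
  out <- paste(lab[ord], collapse = "/")
  un <- states[lab == "unassigned"]
  if (length(un)) attr(out, "unmatched") <- un
  out
}

#' Compose a phased genotype from two key haplotypes
#'
#' Inverse of the calling path, used for round-trip validation and synthetic
#' genotype generation: the residue states of the two named haplotypes are
#' mapped back to nucleotide alleles.
#'
#' @param hap1,hap2 Haplotype labels present in the key.
#' @param key An [read_erap1_key()] object.
#' @param sample Sample name for the composed genotype.
#' @return A phased genotype list as consumed by
#'   [genotype_to_residue_strings()].
#' @export
compose_genotype <- function(hap1, hap2, key, sample = "synthetic") {
  stopifnot(inherits(key, "Erap1HaplotypeKey"))
  for (h in c(hap1, hap2))
    if (!h %in% names(key$haplotypes))
      stop("haplotype not in key: ", h, call. = FALSE)
  back <- function(i, residue) {
    row <- key$snps[i, ]
    if (residue == row$ref_residue) row$ref
    else if (residue == row$alt_residue) row$alt
    else stop("residue ", residue, " undeclared for ", row$rsid, call. = FALSE)
  }
  s1 <- key$haplotypes[[hap1]]; s2 <- key$haplotypes[[hap2]]
  alleles <- lapply(seq_len(9L), function(i)
    c(back(i, substr(s1, i, i)), back(i, substr(s2, i, i))))
  names(alleles) <- key$snps$rsid
  list(sample = sample, alleles = alleles, phased = TRUE)
}

#' Read phased ERAP1 genotypes
#'
#' Accepts either a delimited table (`sample` column plus one column per
#' rsID holding `"A|G"`-style allele pairs; `/` marks unphased) or a minimal
#' VCF (records identified by rsID; only CHROM/POS/ID/REF/ALT and the GT
#' field are consumed).
#'
#' @param path Input path (`.vcf` or header sniffing selects the parser).
#' @param key An [read_erap1_key()] object (used for rsID order and, for
#'   VCF, allele decoding).
#' @return List of genotype objects (one per sample).
#' @export
read_erap1_genotypes <- function(path, key) {
  first <- readLines(path, n = 1L)
  if (grepl("^##fileformat=VCF", first) || grepl("\\.vcf$", path))
    return(read_erap1_vcf(path, key))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(key$snps$rsid, names(df))
  if (length(missing))
    stop("genotype table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(key$snps$rsid, function(r) df[i, r], "")
    phased <- all(grepl("|", cells, fixed = TRUE))
    alleles <- lapply(strsplit(cells, "[|/]"), function(x) x[1:2])
    names(alleles) <- key$snps$rsid
    list(sample = as.character(df$sample[i]), alleles = alleles,
         phased = phased)
  })
}

read_erap1_vcf <- function(path, key) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- do.call(rbind, strsplit(lines[-1], "\t"))
  colnames(body) <- header
  samples <- setdiff(header, c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                               "FILTER", "INFO", "FORMAT"))
  idx <- match(key$snps$rsid, body[, "ID"])
  if (anyNA(idx))
    stop("VCF lacks record(s) for: ",
         paste(key$snps$rsid[is.na(idx)], collapse = ", "), call. = FALSE)
  lapply(samples, function(sm) {
    alleles <- lapply(idx, function(i) {
      gt <- strsplit(body[i, sm], ":")[[1]][1]
      codes <- strsplit(gt, "[|/]")[[1]]
      opts <- c(body[i, "REF"], strsplit(body[i, "ALT"], ",")[[1]])
      opts[as.integer(codes) + 1L]
    })
    names(alleles) <- key$snps$rsid
    phased <- all(vapply(idx, function(i)
      grepl("|", strsplit(body[i, sm], ":")[[1]][1], fixed = TRUE),
      logical(1)))
    list(sample = sm, alleles = alleles, phased = phased)
  })
}

#' Call ERAP1 diplotypes for a set of genotypes
#'
#' @param genotypes Output of [read_erap1_genotypes()] (or a single genotype
#'   list).
#' @param key An [read_erap1_key()] object.
#' @return Data frame with columns `sample`, `diplotype`.
#' @export
call_erap1 <- function(genotypes, key) {
  if (!is.null(genotypes$alleles)) genotypes <- list(genotypes)
  do.call(rbind, lapply(genotypes, function(g) {
    states <- genotype_to_residue_strings(g, key)
    data.frame(sample = g$sample,
               diplotype = as.character(call_diplotype(states, key)))
  }))
}
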