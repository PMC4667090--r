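#' IUPAC nucleotide ambiguity handling and amplicon observation
#'
#' A Sanger read of a PCR product that amplifies several near-identical
#' templates (the two subgenome copies of an allotetraploid locus, or two
#' paralogs within one genome) reports, at each position, the superposition of
#' all template bases as a single IUPAC ambiguity letter ("double peaks" in the
#' trace). These helpers convert between base sets and IUPAC letters and build
#' the observed consensus for a set of copies.
#'
#' @name iupac
NULL

# base-set <-> letter tables built once from Biostrings' canonical map
.iupac_code_of <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  keys <- vapply(strsplit(unname(m), ""), function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(m), keys)
})
.iupac_bases_of <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  stats::setNames(strsplit(unname(m), ""), names(m))
})

#' Superpose a set of canonical bases into one IUPAC letter
#'
#' @param bases character vector of canonical bases (subset of A, C, G, T);
#'   duplicates allowed and ignored.
#' @return single IUPAC letter encoding exactly that set; a singleton set
#'   returns the base itself.
#' @examples
#' iupac_superpose(c("A", "G"))  # "R"
#' @export
iupac_superpose <- function(bases) {
  bases <- unique(toupper(bases))
  if (length(bases) == 0L) stop("empty base set")
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("non-canonical base in set: ", paste(setdiff(bases, c("A","C","G","T")), collapse = ","))
  }
  unname(.iupac_code_of[[paste(sort(bases), collapse = "")]])
}

#' Decompose an IUPAC letter into its set of canonical bases
#'
#' Inverse of [iupac_superpose()]: round-trips on all 15 letters.
#'
#' @param letter single IUPAC nucleotide letter.
#' @return character vector of canonical bases, sorted.
#' @export
iupac_decompose <- function(letter) {
  letter <- toupper(letter)
  if (length(letter) != 1L || is.na(letter) || !letter %in% names(.iupac_bases_of)) {
    stop("invalid IUPAC letter: ", letter)
  }
  sort(.iupac_bases_of[[letter]])
}

# vectorised decomposition of a sequence string into a list of base sets
.decompose_seq <- function(seq) {
  lapply(strsplit(seq, "")[[1]], iupac_decompose)
}

#' Observe an amplicon: superpose all copies into an IUPAC consensus
#'
#' Models noiseless Sanger sequencing of a PCR product amplifying every
#' retained copy of a locus: each position reports the IUPAC code of the union
#' of the copies' bases. One or two identical copies give a plain homozygous
#' sequence; any within- or between-copy difference appears as an ambiguity
#' code and flags the amplicon heterozygous.
#'
#' @param copies character vector of equal-length DNA sequences (IUPAC letters
#'   allowed, so observations themselves can be re-observed).
#' @param locus_id,genotype_id identifiers carried into the result.
#' @return an `amplicon_obs` object: list with `locus_id`, `genotype_id`,
#'   `sequence`, `ambiguity_positions` (0-based, sorted) and `zygosity`
#'   (`"homozygous"` or `"heterozygous"`).
#' @export
observe_amplicon <- function(copies, locus_id = NA_character_, genotype_id = NA_character_) {
  if (length(copies) == 0L) stop("empty copy list")
  n <- nchar(copies)
  if (length(unique(n)) != 1L) stop("copies must have equal length (substitution-only model)")
  mat <- do.call(rbind, strsplit(toupper(copies), ""))
  seq <- vapply(seq_len(ncol(mat)), function(j) {
    bases <- unique(unlist(lapply(unique(mat[, j]), iupac_decompose)))
    iupac_superpose(bases)
  }, "")
  amb <- which(!seq %in% c("A", "C", "G", "T")) - 1L
  structure(list(
    locus_id = locus_id,
    genotype_id = genotype_id,
    sequence = paste(seq, collapse = ""),
    ambiguity_positions = amb,
    zygosity = if (length(amb)) "heterozygous" else "homozygous"
  ), class = "amplicon_obs")
}

#' @export
print.amplicon_obs <- function(x, ...) {
  cat(sprintf("<amplicon_obs> locus=%s genotype=%s length=%d %s (%d ambiguity positions)\n",
              x$locus_id, x$genotype_id, nchar(x$sequence), x$zygosity,
              length(x$ambiguity_positions)))
  invisible(x)
}

#' Zygosity rates of a set of amplicon observations
#'
#' Fraction of heterozygous and homozygous amplicons, optionally per group
#' (e.g. EST- vs genomic-survey-derived amplicons).
#'
#' @param observations list of `amplicon_obs`.
#' @param group_by optional character vector, one label per observation.
#' @return data.frame with columns `group`, `n`, `heterozygous`, `homozygous`;
#'   the two fractions sum to 1 per group.
#' @export
zygosity_rates <- function(observations, group_by = NULL) {
  if (length(observations) == 0L) stop("no observations")
  het <- vapply(observations, function(o) identical(o$zygosity, "heterozygous"), TRUE)
  grp <- if (is.null(group_by)) rep("all", length(het)) else as.character(group_by)
  stopifnot(length(grp) == length(het))
  out <- do.call(rbind, lapply(split(het, grp), function(h) {
    data.frame(n = length(h), heterozygous = mean(h), homozygous = mean(!h))
  }))
  data.frame(group = rownames(out), out, row.names = NULL)
}

# complement of canonical bases (used for strand-collapsed variant classes)
.complement <- c(A = "T", C = "G", G = "C", T = "A")
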