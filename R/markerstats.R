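#' Marker panel statistics
#'
#' Allele counts over a variety panel, polymorphism information content
#' (PIC), variant densities, strand-collapsed variant-class spectra, pairwise
#' linkage-disequilibrium r-squared, and 1:1 segregation tests for
#' recombinant inbred lines.
#'
#' @name markerstats
NULL

#' Polymorphism information content of a marker
#'
#' PIC = 1 - sum(p_i^2) with p_i = count_i / panel_size. The denominator is
#' the *full panel size* (default 96), not the number of successfully
#' genotyped varieties: markers with failed calls therefore have allele
#' frequencies summing below 1, which is the convention that reproduces
#' published allele-count tables where counts do not sum to the panel size.
#' Set `denominator = "genotyped"` for the alternative convention.
#'
#' For a biallelic marker PIC is at most 0.5, attained at equal counts.
#'
#' @param counts non-negative per-allele variety counts (any k >= 1).
#' @param panel_size panel denominator; must be >= sum(counts).
#' @param denominator `"panel"` (default) or `"genotyped"`.
#' @return list with `k`, `p` (frequencies), `pic` (unrounded), and
#'   `pic_3dp` (rounded to 3 decimals, the reporting precision).
#' @export
pic <- function(counts, panel_size = 96L, denominator = c("panel", "genotyped")) {
  denominator <- match.arg(denominator)
  if (panel_size <= 0) stop("panel_size must be positive")
  if (any(counts < 0)) stop("negative allele counts")
  if (sum(counts) > panel_size) stop("allele counts exceed panel_size")
  denom <- if (denominator == "panel") panel_size else sum(counts)
  if (denom == 0) stop("no genotyped varieties")
  p <- counts / denom
  val <- 1 - sum(p^2)
  list(k = length(counts), p = p, pic = val, pic_3dp = round(val, 3))
}

#' Summarize a set of markers: per-marker PIC and per-group means
#'
#' @param markers data.frame with columns `marker_id`, `count1`, `count2`,
#'   optionally `group` (e.g. EST/GSS, inferred from the id prefix when
#'   absent) and `variant_class`.
#' @param panel_size panel denominator (default 96).
#' @return list with `table` (one row per marker: counts, PIC to 3 decimals)
#'   and `summary` (per group: n, min, max, mean PIC; the mean is taken over
#'   the unrounded per-marker values and reported to 3 decimals).
#' @export
summarize_markers <- function(markers, panel_size = 96L) {
  stopifnot(nrow(markers) >= 1L)
  if (is.null(markers$group)) {
    markers$group <- ifelse(grepl("^EST", markers$marker_id), "EST",
                            ifelse(grepl("^GSS", markers$marker_id), "GSS", "other"))
  }
  pics <- vapply(seq_len(nrow(markers)), function(i) {
    pic(c(markers$count1[i], markers$count2[i]), panel_size)$pic
  }, 0)
  tab <- data.frame(marker_id = markers$marker_id, group = markers$group,
                    variant_class = markers$variant_class %||% NA_character_,
                    count1 = markers$count1, count2 = markers$count2,
                    pic = round(pics, 3), stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(pics, markers$group), function(v) {
    data.frame(n = length(v), min_pic = round(min(v), 3),
               max_pic = round(max(v), 3), mean_pic = round(mean(v), 3))
  }))
  list(table = tab,
       summary = data.frame(group = rownames(summ), summ, row.names = NULL))
}

#' Variant density as base pairs per variant
#'
#' @param n_variants number of variants found.
#' @param total_bp total sequence surveyed.
#' @param digits rounding for the report: 0 for the sparse SNP densities
#'   ("one SNP per N bp"), 1 decimal for the dense HSV/PSV densities.
#' @return list with `bp_per_variant` (unrounded), `reported` (rounded), or
#'   `reported = "no variants"` when `n_variants` is zero.
#' @export
variant_density <- function(n_variants, total_bp, digits = 1L) {
  if (total_bp <= 0) stop("total_bp must be positive")
  if (n_variants < 0) stop("n_variants must be non-negative")
  if (n_variants == 0) {
    return(list(bp_per_variant = NA_real_, reported = "no variants"))
  }
  d <- total_bp / n_variants
  list(bp_per_variant = d, reported = round(d, digits))
}

#' Spectrum over the four strand-collapsed variant classes
#'
#' @param sites variant table with a `collapsed_class` column, or a character
#'   vector of class labels.
#' @return data.frame with `class`, `count`, `proportion` (summing to 1) over
#'   the classes `C/T(G/A)`, `A/C(T/G)`, `A/T(T/A)`, `C/G(G/C)`.
#' @export
class_spectrum <- function(sites) {
  cls <- if (is.data.frame(sites)) sites$collapsed_class else sites
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0L) stop("no classified sites")
  lev <- c("C/T(G/A)", "A/C(T/G)", "A/T(T/A)", "C/G(G/C)")
  tb <- table(factor(cls, levels = lev))
  data.frame(class = lev, count = as.integer(tb),
             proportion = as.numeric(tb) / length(cls))
}

#' Linkage-disequilibrium r-squared between two biallelic markers
#'
#' Squared Pearson correlation of 0/1-coded calls over varieties with both
#' calls present. For phase-known inbred lines this equals the classical
#' D^2 / (p1 p2 q1 q2) from the 2x2 haplotype table. r2 = 1 means the two
#' markers partition the panel identically and are redundant for genotyping.
#'
#' @param calls_x,calls_y vectors of calls coercible to two levels; `NA` for
#'   missing.
#' @return list with `r2`, `n_complete`, and `defined` (FALSE when a marker
#'   is monomorphic among the complete pairs, which leaves r2 undefined).
#' @export
ld_r2 <- function(calls_x, calls_y) {
  if (length(calls_x) != length(calls_y)) stop("call vectors differ in length")
  ok <- !is.na(calls_x) & !is.na(calls_y)
  if (sum(ok) < 2L) stop("need at least two complete variety pairs")
  x <- as.integer(factor(calls_x[ok])) - 1L
  y <- as.integer(factor(calls_y[ok])) - 1L
  if (length(unique(x)) > 2L || length(unique(y)) > 2L) stop("markers must be biallelic")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(r2 = NA_real_, n_complete = sum(ok), defined = FALSE))
  }
  list(r2 = stats::cor(x, y)^2, n_complete = sum(ok), defined = TRUE)
}

#' Reduce a multi-SNP fragment to the markers needed for genotyping
#'
#' Within one amplified fragment, SNPs with pairwise r2 = 1 carry identical
#' information, so one per fully linked group suffices; fragments whose SNPs
#' have r2 < 1 keep one representative per r2 = 1 equivalence class. The
#' representative is the first SNP by position.
#'
#' @param fragment list of SNPs, each a list with `id`, `position`, `calls`.
#' @param tol numerical tolerance for r2 == 1.
#' @return character vector of selected SNP ids.
#' @export
marker_selection <- function(fragment, tol = 1e-9) {
  if (length(fragment) == 0L) stop("fragment contains no SNPs")
  ord <- order(vapply(fragment, `[[`, 0, "position"))
  fragment <- fragment[ord]
  n <- length(fragment)
  if (n == 1L) return(fragment[[1]]$id)
  # union-find over r2 == 1 pairs (identical partitions are transitive)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      r <- ld_r2(fragment[[i]]$calls, fragment[[j]]$calls)
      if (isTRUE(r$defined) && r$r2 >= 1 - tol) {
        parent[find(j)] <- find(i)
      }
    }
  }
  reps <- !duplicated(vapply(seq_len(n), find, 0L))
  vapply(fragment[reps], `[[`, "", "id")
}

#' Chi-squared test of 1:1 segregation
#'
#' Goodness-of-fit of two observed class counts against equal expectation
#' (E = total/2), df = 1. The standard check for segregation distortion of a
#' marker in a recombinant inbred population.
#'
#' @param counts two non-negative observed counts (heterozygous or missing
#'   lines are excluded upstream).
#' @param alpha significance level for the `distorted` flag (default 0.05).
#' @return list with `observed`, `chi2`, `df`, `p`, `distorted`.
#' @export
chi_square_1to1 <- function(counts, alpha = 0.05) {
  if (length(counts) != 2L || any(counts < 0)) stop("need two non-negative counts")
  total <- sum(counts)
  if (total == 0) stop("zero total count")
  e <- total / 2
  chi2 <- sum((counts - e)^2 / e)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(observed = counts, chi2 = chi2, df = 1L, p = p, distorted = p < alpha)
}

#' Segregation tests for a RIL genotype matrix
#'
#' @param ril matrix from [simulate_ril()] (lines x markers); heterozygous
#'   (`"H"`) and missing calls are dropped per marker.
#' @param alpha significance level.
#' @return data.frame, one row per segregating marker: counts, chi2, p,
#'   distorted.
#' @export
segregation_tests <- function(ril, alpha = 0.05) {
  out <- lapply(colnames(ril), function(m) {
    calls <- ril[, m]
    calls <- calls[!is.na(calls) & calls != "H"]
    lev <- sort(unique(calls))
    if (length(lev) != 2L) return(NULL)
    ct <- as.integer(table(factor(calls, levels = lev)))
    tst <- chi_square_1to1(ct, alpha)
    data.frame(marker_id = m, allele1 = lev[1], allele2 = lev[2],
               n1 = ct[1], n2 = ct[2], chi2 = tst$chi2, p = tst$p,
               distorted = tst$distorted, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out)) do.call(rbind, out) else
    data.frame(marker_id = character(), allele1 = character(),
               allele2 = character(), n1 = integer(), n2 = integer(),
               chi2 = numeric(), p = numeric(), distorted = logical())
}
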