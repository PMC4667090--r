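#' Simplified high-resolution melting (HRM) engine
#'
#' HRM genotypes a short (80-250 bp) nested PCR product by the shape and
#' position of its fluorescent melt curve on a dense temperature grid
#' (72-90 degrees C in 0.1 degree steps, 181 points). A heterozygote forms
#' two homoduplexes and two mismatch-destabilised heteroduplexes, giving an
#' early-melting shoulder that separates it from either homozygote after
#' curve normalization and difference plotting. The signal model here is a
#' two-state logistic melt per duplex species with additive superposition;
#' real instrument chemistry (dye saturation, exponential background) is not
#' modeled.
#'
#' @name hrm
NULL

#' The melt protocol temperature grid: 72.0-90.0 C inclusive, step 0.1
#' @return numeric vector of 181 temperatures.
#' @export
hrm_grid <- function() seq(72, 90, by = 0.1)

#' Predict duplex melting temperature from GC content and length
#'
#' Tm = 81.5 + 0.41 * GC% - 675 / length - salt_offset (degrees C), the
#' standard empirical formula for PCR-scale products. The configurable
#' `salt_offset` stands in for buffer/dye effects; its default of 12 places
#' typical 100-200 bp amplicons inside the 72-90 melt window.
#'
#' @param seq DNA sequence of canonical bases, length >= 20; ambiguity
#'   letters are rejected -- expand a genotype into its per-allele duplexes
#'   first.
#' @param salt_offset constant subtracted from the formula value.
#' @return melting temperature in degrees C.
#' @export
predict_tm <- function(seq, salt_offset = 12) {
  ch <- strsplit(toupper(seq), "")[[1]]
  if (!all(ch %in% .BASES)) stop("ambiguity letters rejected: expand per allele first")
  n <- length(ch)
  if (n < 20L) stop("sequence shorter than 20 bp")
  gc_pct <- 100 * mean(ch %in% c("G", "C"))
  81.5 + 0.41 * gc_pct - 675 / n - salt_offset
}

#' Duplex species formed by a genotype at a biallelic marker
#'
#' A homozygote yields one homoduplex (weight 1). A heterozygote denatures
#' and reanneals into four species at weight 1/4 each: two homoduplexes and
#' two heteroduplexes whose Tm is lowered by `delta` per mismatched position
#' between the two allele amplicons.
#'
#' @param alleles one (homozygote) or two (heterozygote) allele names.
#' @param amplicon_seqs named character vector of per-allele amplicon
#'   sequences (equal length).
#' @param delta Tm penalty per mismatch in a heteroduplex (default 1.0 C).
#' @param salt_offset passed to [predict_tm()].
#' @param width transition width of each species (default 0.8 C).
#' @return data.frame of species: `kind`, `tm` (clamped to the melt grid),
#'   `weight` (sums to 1), `width`.
#' @export
sample_duplexes <- function(alleles, amplicon_seqs, delta = 1.0,
                            salt_offset = 12, width = 0.8) {
  alleles <- unique(alleles)
  if (length(alleles) > 2L) stop("more than two alleles at a biallelic marker")
  if (!all(alleles %in% names(amplicon_seqs))) stop("missing amplicon sequence for an allele")
  grid <- hrm_grid()
  clamp <- function(x) pmin(max(grid), pmax(min(grid), x))
  tms <- vapply(amplicon_seqs[alleles], predict_tm, 0, salt_offset = salt_offset)
  if (length(alleles) == 1L) {
    return(data.frame(kind = "homoduplex", tm = clamp(unname(tms)), weight = 1,
                      width = width, stringsAsFactors = FALSE))
  }
  s1 <- strsplit(toupper(amplicon_seqs[[alleles[1]]]), "")[[1]]
  s2 <- strsplit(toupper(amplicon_seqs[[alleles[2]]]), "")[[1]]
  if (length(s1) != length(s2)) stop("allele amplicons differ in length")
  n_mm <- sum(s1 != s2)
  data.frame(
    kind = c("homoduplex", "homoduplex", "heteroduplex", "heteroduplex"),
    tm = clamp(c(tms[1], tms[2], tms[1] - delta * n_mm, tms[2] - delta * n_mm)),
    weight = rep(0.25, 4), width = width, stringsAsFactors = FALSE)
}

#' Synthesize a melt curve from duplex species
#'
#' F(T) = sum_d w_d * logistic((tm_d - T) / width_d), plus optional Gaussian
#' noise. Noiseless curves are monotone non-increasing in temperature and
#' pass 0.5 at the Tm of a single species.
#'
#' @param species data.frame from [sample_duplexes()].
#' @param noise_sd Gaussian noise standard deviation (0 = noiseless).
#' @param seed optional integer for reproducible noise.
#' @param sample_id identifier carried on the curve.
#' @return a `melt_curve`: list with `sample_id`, `temperature`,
#'   `fluorescence`.
#' @export
simulate_melt_curve <- function(species, noise_sd = 0, seed = NULL,
                                sample_id = NA_character_) {
  if (nrow(species) == 0L) stop("empty species list")
  if (abs(sum(species$weight) - 1) > 1e-8) stop("species weights must sum to 1")
  grid <- hrm_grid()
  f <- rowSums(vapply(seq_len(nrow(species)), function(d) {
    species$weight[d] * stats::plogis((species$tm[d] - grid) / species$width[d])
  }, numeric(length(grid))))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + stats::rnorm(length(grid), 0, noise_sd)
  }
  structure(list(sample_id = sample_id, temperature = grid, fluorescence = f),
            class = "melt_curve")
}

#' Normalize melt curves and subtract a reference
#'
#' Standard HRM post-processing: fit a linear baseline to the pre-melt and
#' post-melt temperature windows of each curve, rescale the signal between
#' the baselines to 100% -> 0%, and subtract the reference sample's
#' normalized curve. The reference maps to the zero difference curve;
#' swapping the reference negates all differences.
#'
#' With `baseline = "linear"` (the classic instrument procedure) a sloped
#' baseline is fitted per window; under heavy per-point noise the fitted
#' slope extrapolates poorly across the 18 C grid, so `baseline = "constant"`
#' (window means; exact for the two-state model, whose plateaus are flat) is
#' the robust choice and is what the genotyping driver uses. `smooth_span`
#' optionally lowess-smooths the difference curves over temperature.
#'
#' @param curves named list of `melt_curve` objects on the common grid.
#' @param pre_window,post_window temperature intervals (default 73-75 C and
#'   88-90 C) inside the grid, non-overlapping.
#' @param reference sample id of the reference curve (default: first).
#' @param baseline `"linear"` or `"constant"` (see above).
#' @param smooth_span lowess span fraction for the difference curves
#'   (0 = no smoothing).
#' @return list with `normalized` and `difference` (samples x temperatures
#'   matrices), `temperature`, `reference`.
#' @export
normalize_and_difference <- function(curves, pre_window = c(73, 75),
                                     post_window = c(88, 90),
                                     reference = NULL,
                                     baseline = c("linear", "constant"),
                                     smooth_span = 0) {
  baseline <- match.arg(baseline)
  grid <- hrm_grid()
  if (pre_window[2] >= post_window[1]) stop("windows must not overlap")
  if (pre_window[1] < min(grid) || post_window[2] > max(grid)) {
    stop("windows must lie inside the melt grid")
  }
  ids <- names(curves) %||% vapply(curves, `[[`, "", "sample_id")
  reference <- reference %||% ids[1]
  if (!reference %in% ids) stop("unknown reference sample: ", reference)
  pre_idx <- which(grid >= pre_window[1] & grid <= pre_window[2])
  post_idx <- which(grid >= post_window[1] & grid <= post_window[2])
  norm <- t(vapply(curves, function(cv) {
    f <- cv$fluorescence
    if (baseline == "linear") {
      up <- stats::lm.fit(cbind(1, grid[pre_idx]), f[pre_idx])$coefficients
      lo <- stats::lm.fit(cbind(1, grid[post_idx]), f[post_idx])$coefficients
      upper <- up[1] + up[2] * grid
      lower <- lo[1] + lo[2] * grid
    } else {
      upper <- rep(mean(f[pre_idx]), length(grid))
      lower <- rep(mean(f[post_idx]), length(grid))
    }
    rng <- upper - lower
    if (any(abs(rng) < 1e-12)) stop("degenerate baseline window (constant signal)")
    100 * (f - lower) / rng
  }, numeric(length(grid))))
  rownames(norm) <- ids
  diff <- sweep(norm, 2L, norm[reference, ])
  if (smooth_span > 0) {
    diff <- t(apply(diff, 1L, function(y) stats::lowess(grid, y, f = smooth_span)$y))
  }
  list(normalized = norm, difference = diff, temperature = grid,
       reference = reference)
}

#' Cluster difference curves into genotype groups
#'
#' Agglomerative (complete-linkage) clustering under the maximum-absolute
#' curve distance, cut at `threshold` (in normalized-fluorescence units) or
#' into a known number of groups `k` (for a validated biallelic marker in an
#' inbred panel, two homozygote groups are expected a priori). With
#' `refine = TRUE` the cut is polished by centroid reassignment (Lloyd
#' iterations on the curves): pairwise distances between noisy curves
#' overlap long before the cluster mean curves do, so the polish recovers
#' assignments that single-linkage decisions get wrong. Cluster ids are
#' ordered by size, largest first, so cluster 1 is the majority genotype;
#' the result is invariant to sample order.
#'
#' @param difference samples x temperatures matrix from
#'   [normalize_and_difference()].
#' @param threshold cut height (default 5, i.e. 5% of normalized signal);
#'   ignored when `k` is given.
#' @param k optional fixed number of clusters.
#' @param refine polish the cut by centroid reassignment (default TRUE).
#' @return data.frame with `sample_id`, `cluster`, `reference_distance`
#'   (max-abs deviation from the reference curve).
#' @export
cluster_genotypes <- function(difference, threshold = 5, k = NULL,
                              refine = TRUE) {
  n <- nrow(difference)
  if (n < 2L) stop("need at least two samples")
  hc <- stats::hclust(stats::dist(difference, method = "maximum"),
                      method = "complete")
  raw <- if (is.null(k)) stats::cutree(hc, h = threshold) else
    stats::cutree(hc, k = min(k, n))
  nk <- length(unique(raw))
  if (refine && nk > 1L) {
    for (it in seq_len(50L)) {
      cent <- do.call(rbind, lapply(seq_len(nk), function(g) {
        colMeans(difference[raw == g, , drop = FALSE])
      }))
      new <- apply(difference, 1L, function(x) {
        which.min(colSums((t(cent) - x)^2))
      })
      if (length(unique(new)) < nk) break  # would empty a cluster: keep previous
      if (all(new == raw)) break
      raw <- new
    }
  }
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  data.frame(sample_id = rownames(difference),
             cluster = unname(relabel[as.character(raw)]),
             reference_distance = apply(abs(difference), 1L, max),
             stringsAsFactors = FALSE)
}

#' Filter samples with aberrant amplification before HRM
#'
#' Samples whose amplification crossing cycle (cycle at which the trace first
#' reaches half of its own plateau, linearly interpolated) deviates from the
#' panel median by more than `window` cycles are excluded -- significantly
#' early or late amplifications produce aberrant melt curves and are reported
#' as missing calls downstream.
#'
#' @param traces samples x cycles matrix of amplification signal on a common
#'   cycle grid.
#' @param window maximum allowed |crossing cycle - panel median| (default 5).
#' @return list with `retained`, `excluded` (sample id vectors) and
#'   `crossing_cycle` (named numeric).
#' @export
hrm_qc_filter <- function(traces, window = 5) {
  cycles <- seq_len(ncol(traces))
  ct <- apply(traces, 1L, function(y) {
    half <- max(y) / 2
    i <- which(y >= half)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1L) return(cycles[1])
    cycles[i - 1L] + (half - y[i - 1L]) / (y[i] - y[i - 1L])
  })
  med <- stats::median(ct, na.rm = TRUE)
  keep <- !is.na(ct) & abs(ct - med) <= window
  ids <- rownames(traces) %||% as.character(seq_len(nrow(traces)))
  list(retained = ids[keep], excluded = ids[!keep],
       crossing_cycle = stats::setNames(ct, ids))
}

#' Genotype a sample panel at one marker through the full HRM channel
#'
#' Convenience driver used by the pipeline and the melt-channel fidelity
#' checks: build duplex species per sample, synthesize curves, normalize,
#' difference against the first sample, and cluster.
#'
#' Uses the noise-robust settings: constant-plateau baselines, lowess
#' smoothing of the difference curves (span 0.15), and centroid-refined
#' clustering. At zero noise these coincide with the classic procedure.
#'
#' @param genotypes named list of allele vectors (length 1 or 2) per sample.
#' @param amplicon_seqs named per-allele amplicon sequences.
#' @param noise_sd curve noise (0 = noiseless).
#' @param threshold clustering cut height; ignored when `k` given.
#' @param k optional known number of genotype groups.
#' @param seed RNG seed for noise.
#' @param delta,salt_offset,width passed to [sample_duplexes()].
#' @param smooth_span passed to [normalize_and_difference()].
#' @return the [cluster_genotypes()] data.frame.
#' @export
hrm_genotype_panel <- function(genotypes, amplicon_seqs, noise_sd = 0,
                               threshold = 5, k = NULL, seed = 1L,
                               delta = 1.0, salt_offset = 12, width = 0.8,
                               smooth_span = 0.15) {
  if (!is.null(seed)) set.seed(seed)
  curves <- lapply(names(genotypes), function(s) {
    sp <- sample_duplexes(genotypes[[s]], amplicon_seqs, delta = delta,
                          salt_offset = salt_offset, width = width)
    simulate_melt_curve(sp, noise_sd = noise_sd, sample_id = s)
  })
  names(curves) <- names(genotypes)
  nd <- normalize_and_difference(curves, baseline = "constant",
                                 smooth_span = smooth_span)
  cluster_genotypes(nd$difference, threshold = threshold, k = k)
}

#' Random SNP amplicon pair for HRM simulation
#'
#' Generates a nested-PCR-sized amplicon and its alternate-allele version
#' differing at the central position. The default length of 80 bp is the
#' short end of the nested-product range: HRM discrimination improves as the
#' amplicon shrinks, because one substitution changes a larger fraction of
#' the GC content, so assays are designed as short as primers allow.
#'
#' @param length_bp amplicon length (default 80, inside the 80-250 bp
#'   nested-product range).
#' @param seed RNG seed.
#' @return named character vector of two allele sequences (`"1"`, `"2"`).
#' @export
snp_amplicon_pair <- function(length_bp = 80L, seed = 1L) {
  set.seed(seed)
  s1 <- .random_seq(length_bp)
  mid <- as.integer(ceiling(length_bp / 2))
  ref <- substring(s1, mid, mid)
  s2 <- s1
  # transition partner: the most common variant class, and always GC-changing
  # (a GC-neutral A/T or C/G swap has no Tm shift in the GC/length model)
  substring(s2, mid, mid) <- c(A = "G", G = "A", C = "T", T = "C")[[ref]]
  c("1" = s1, "2" = s2)
}
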