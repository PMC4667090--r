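#' Progenitor-guided variant classification in an allotetraploid
#'
#' The central inference: given the amplicon consensus of each tetraploid
#' variety and of the two diploid progenitors at the same locus, decide which
#' subgenome copies survive in the tetraploid (copy composition) and sort
#' every variable alignment column into homologous SNP, homoeologous sequence
#' variant (HSV, fixed A-vs-B difference) or paralogous sequence variant (PSV,
#' within-genome duplicate difference). Only SNPs are usable as genetic
#' markers; misclassified HSVs/PSVs are the dominant false-positive source in
#' polyploid SNP discovery.
#'
#' @name classify
NULL

# ---------------------------------------------------------------- alignment

#' Ambiguity-aware global alignment (Needleman-Wunsch / Gotoh)
#'
#' Global alignment over the IUPAC alphabet in which two letters match
#' whenever their decomposed base sets intersect (so Y aligns to T as a
#' match). Gap of length L costs `gap_open + L * gap_extend`, matching the
#' convention of Biostrings' `pairwiseAlignment`. Traceback ties are broken
#' deterministically: diagonal, then up (gap in `b`), then left.
#'
#' Real amplicon data can contain indels; the simulator is substitution-only,
#' where columns map 1:1 to reference coordinates and this function reduces
#' to a positional check. It exists for FASTA inputs from other sources.
#'
#' @param a,b sequences over the IUPAC alphabet.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return list with `aligned_a`, `aligned_b` (gap character `-`), `score`,
#'   and `identity` (matching columns / alignment length).
#' @export
align_global <- function(a, b, match = 1, mismatch = -1,
                         gap_open = 2, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty input sequence")
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  aset <- lapply(av, iupac_decompose)
  bset <- lapply(bv, iupac_decompose)
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  sub <- function(i, j) if (length(intersect(aset[[i]], bset[[j]]))) match else mismatch
  # Gotoh: M diagonal state, X gap in b (consumes a, "up"), Y gap in a ("left")
  M <- matrix(NEG, n + 1L, m + 1L); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1L, 1] <- -(gap_open + i * gap_extend)
  for (j in seq_len(m)) Y[1, j + 1L] <- -(gap_open + j * gap_extend)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub(i, j)
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_extend,
                               X[i, j + 1L] - gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_extend,
                               Y[i + 1L, j] - gap_extend)
    }
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  # traceback, preferring diagonal > up > left at every tie
  i <- n; j <- m
  state <- c("M", "X", "Y")[which.max(c(M[n + 1L, m + 1L], X[n + 1L, m + 1L],
                                        Y[n + 1L, m + 1L]))]
  ra <- character(); rb <- character()
  while (i > 0L || j > 0L) {
    if (state == "M" && i > 0L && j > 0L) {
      s <- sub(i, j)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      ra <- c(av[i], ra); rb <- c(bv[j], rb)
      i <- i - 1L; j <- j - 1L
      state <- c("M", "X", "Y")[which.max(prev)]
    } else if (state == "X" || (j == 0L && i > 0L)) {
      from_m <- M[i, j + 1L] - gap_open - gap_extend
      from_x <- X[i, j + 1L] - gap_extend
      ra <- c(av[i], ra); rb <- c("-", rb)
      i <- i - 1L
      state <- if (i == 0L && j == 0L) "M" else if (from_m >= from_x) "M" else "X"
      if (i > 0L && j == 0L) state <- "X"
    } else {
      from_m <- M[i + 1L, j] - gap_open - gap_extend
      from_y <- Y[i + 1L, j] - gap_extend
      ra <- c("-", ra); rb <- c(bv[j], rb)
      j <- j - 1L
      state <- if (i == 0L && j == 0L) "M" else if (from_m >= from_y) "M" else "Y"
      if (j > 0L && i == 0L) state <- "Y"
    }
  }
  is_match <- mapply(function(x, y) {
    x != "-" && y != "-" &&
      length(intersect(iupac_decompose(x), iupac_decompose(y))) > 0L
  }, ra, rb)
  list(aligned_a = paste(ra, collapse = ""), aligned_b = paste(rb, collapse = ""),
       score = score, identity = mean(is_match))
}

# ------------------------------------------------------- copy composition

.HYPOTHESES <- c("AB", "A_only", "B_only", "A_paralogs", "B_paralogs", "AB_paralogs")

# predicted consensus when both genomes' observations superpose
.superpose_obs <- function(sa, sb) {
  va <- .decompose_seq(sa); vb <- .decompose_seq(sb)
  paste(mapply(function(x, y) iupac_superpose(union(x, y)), va, vb), collapse = "")
}

#' Infer which subgenome copies of a locus survive in the tetraploid
#'
#' Enumerates candidate copy sets expressible from the three observations --
#' both genomes ({A,B}), one genome only, a within-genome paralog pair
#' ({A1,A2} or {B1,B2}; available only when that progenitor's amplicon is
#' heterozygous), or both genomes including a paralog pair -- predicts the
#' tetraploid consensus for each by per-position IUPAC superposition, and
#' returns the hypothesis with the fewest mismatching positions. Ties break
#' by precedence AB, A_only, B_only, A_paralogs, B_paralogs, AB_paralogs
#' (most loci retain both genomes).
#'
#' @param tetra,progA,progB `amplicon_obs` for the same locus, equal lengths.
#' @param mask optional logical vector of columns to score; the panel driver
#'   masks out segregating columns, which belong to the SNP-calling step and
#'   would otherwise let a high-frequency SNP veto the correct composition.
#' @return a `copy_composition`: `locus_id`, `hypothesis`, `mismatch_count`,
#'   `explained` (zero mismatches), `predicted` consensus, and per-genome
#'   progenitor heterozygosity flags.
#' @export
.composition_candidates <- function(progA, progB) {
  hetA <- identical(progA$zygosity, "heterozygous")
  hetB <- identical(progB$zygosity, "heterozygous")
  predAB <- .superpose_obs(progA$sequence, progB$sequence)
  cand <- list()
  if (!hetA && !hetB) cand$AB <- predAB
  if (!hetA) cand$A_only <- progA$sequence
  if (!hetB) cand$B_only <- progB$sequence
  if (hetA) cand$A_paralogs <- progA$sequence
  if (hetB) cand$B_paralogs <- progB$sequence
  if (hetA || hetB) cand$AB_paralogs <- predAB
  attr(cand, "hetA") <- hetA
  attr(cand, "hetB") <- hetB
  cand
}

infer_copy_composition <- function(tetra, progA, progB, mask = NULL) {
  lens <- c(nchar(tetra$sequence), nchar(progA$sequence), nchar(progB$sequence))
  if (length(unique(lens)) != 1L) stop("length-incompatible observations")
  cand <- .composition_candidates(progA, progB)
  tv <- strsplit(tetra$sequence, "")[[1]]
  use <- if (is.null(mask)) rep(TRUE, length(tv)) else mask
  mism <- vapply(cand, function(p) sum(strsplit(p, "")[[1]][use] != tv[use]), 0L)
  ord <- order(mism, match(names(cand), .HYPOTHESES))
  best <- names(cand)[ord[1]]
  structure(list(
    locus_id = tetra$locus_id, hypothesis = best,
    mismatch_count = unname(mism[best]), explained = mism[[best]] == 0L,
    predicted = cand[[best]], progA_het = attr(cand, "hetA"),
    progB_het = attr(cand, "hetB")
  ), class = "copy_composition")
}

#' @export
print.copy_composition <- function(x, ...) {
  cat(sprintf("<copy_composition> locus=%s hypothesis=%s mismatches=%d%s\n",
              x$locus_id, x$hypothesis, x$mismatch_count,
              if (x$explained) " (explained)" else ""))
  invisible(x)
}

# ------------------------------------------------------------ PSV detection

#' PSVs visible in a single progenitor amplicon
#'
#' A heterozygous position in a *diploid inbred* progenitor amplicon can only
#' come from co-amplified paralogs, so each ambiguity position yields one PSV.
#' Positions decomposing to more than two bases are flagged complex and
#' excluded with a warning.
#'
#' @param prog an `amplicon_obs` of a progenitor.
#' @param subgenome `"A"` or `"B"` (for the `within-A`/`within-B` label).
#' @return data.frame of PSV sites (1-based `pos_1based`), zero rows for a
#'   homozygous amplicon.
#' @export
detect_psv <- function(prog, subgenome = c("A", "B")) {
  subgenome <- match.arg(subgenome)
  out <- list()
  for (p0 in prog$ambiguity_positions) {
    bases <- iupac_decompose(substring(prog$sequence, p0 + 1L, p0 + 1L))
    if (length(bases) > 2L) {
      warning(sprintf("locus %s pos %d: complex ambiguity (%s), excluded",
                      prog$locus_id, p0 + 1L, paste(bases, collapse = "")))
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      locus_id = prog$locus_id, pos_1based = p0 + 1L, category = "PSV",
      subgenome = paste0("within-", subgenome),
      allele1 = bases[1], allele2 = bases[2],
      collapsed_class = collapse_variant_class(bases[1], bases[2]),
      hsv_coincident = FALSE, n_varieties_minor = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else .empty_variant_table()
}

.empty_variant_table <- function() {
  data.frame(locus_id = character(), pos_1based = integer(), category = character(),
             subgenome = character(), allele1 = character(), allele2 = character(),
             collapsed_class = character(), hsv_coincident = logical(),
             n_varieties_minor = integer(), stringsAsFactors = FALSE)
}

# ------------------------------------------------------- site classification

#' Classify every variable column of a locus
#'
#' Works positionally on equal-length observations (substitution-only data;
#' align first for indel-containing inputs). Per variable column:
#' \itemize{
#'   \item \strong{HSV}: progenitors carry different single bases, both
#'     genomes are retained, and every variety shows the same superposed
#'     letter.
#'   \item \strong{PSV}: a within-genome paralog difference (heterozygous
#'     progenitor column) whose paralog pair is retained, uniform across
#'     varieties.
#'   \item \strong{SNP}: varieties differ among themselves and the varying
#'     base is attributable to exactly one subgenome copy while the other
#'     copies' contribution stays fixed. A SNP sitting on an HSV column (its
#'     minor allele hidden by the homoeologous base) gets
#'     `hsv_coincident = TRUE` -- such markers cannot give clean allelic
#'     segregation in crosses.
#'   \item \strong{fixed_diff}: all varieties identical but differing from
#'     the progenitor prediction -- a fixed difference versus the progenitor
#'     accessions, not a marker segregating in the panel.
#'   \item \strong{unresolvable}: anything else (e.g. three alleles).
#' }
#'
#' @param panel_obs named list of variety `amplicon_obs` (>= 2).
#' @param progA,progB progenitor `amplicon_obs`.
#' @param composition the locus's [infer_copy_composition()] result; must be
#'   `explained`, otherwise classification refuses (model misfit).
#' @return a variant table (see [detect_psv()] columns) with one row per
#'   variable column, plus an attribute `"calls"`: named list (by
#'   `locus:pos`) of per-variety allele calls (1/2) for SNP rows.
#' @export
classify_sites <- function(panel_obs, progA, progB, composition) {
  if (length(panel_obs) < 2L) stop("need at least two varieties")
  if (!composition$explained) {
    stop(sprintf("locus %s: composition %s leaves %d mismatches; refusing to classify",
                 composition$locus_id, composition$hypothesis, composition$mismatch_count))
  }
  hyp <- composition$hypothesis
  has_a <- hyp %in% c("AB", "A_only", "A_paralogs", "AB_paralogs")
  has_b <- hyp %in% c("AB", "B_only", "B_paralogs", "AB_paralogs")
  L <- nchar(progA$sequence)
  vseq <- do.call(rbind, lapply(panel_obs, function(o) strsplit(o$sequence, "")[[1]]))
  aS <- .decompose_seq(progA$sequence)
  bS <- .decompose_seq(progB$sequence)
  locus <- composition$locus_id
  rows <- list(); calls <- list()

  for (p in seq_len(L)) {
    aset <- aS[[p]]; bset <- bS[[p]]
    E <- union(if (has_a) aset else character(), if (has_b) bset else character())
    pred <- iupac_superpose(E)
    col <- vseq[, p]
    uniform <- length(unique(col)) == 1L
    if (uniform && col[1] == pred && length(E) == 1L) next  # invariant column

    rec <- function(category, subgenome, a1, a2, coincident = FALSE, n_minor = NA_integer_) {
      cc <- if (!is.na(a1) && !is.na(a2) && a1 != a2 &&
                all(c(a1, a2) %in% .BASES)) collapse_variant_class(a1, a2) else NA_character_
      data.frame(locus_id = locus, pos_1based = p, category = category,
                 subgenome = subgenome, allele1 = a1, allele2 = a2,
                 collapsed_class = cc, hsv_coincident = coincident,
                 n_varieties_minor = n_minor, stringsAsFactors = FALSE)
    }

    if (uniform) {
      if (col[1] == pred) {
        # invariant in the panel but ambiguous: progenitor-level variation
        if (length(aset) == 2L && has_a && hyp %in% c("A_paralogs", "AB_paralogs")) {
          rows[[length(rows) + 1L]] <- rec("PSV", "within-A", aset[1], aset[2])
        } else if (length(bset) == 2L && has_b && hyp %in% c("B_paralogs", "AB_paralogs")) {
          rows[[length(rows) + 1L]] <- rec("PSV", "within-B", bset[1], bset[2])
        } else if (has_a && has_b && length(aset) == 1L && length(bset) == 1L &&
                   aset != bset) {
          rows[[length(rows) + 1L]] <- rec("HSV", "between", aset, bset)
        } else {
          rows[[length(rows) + 1L]] <- rec("unresolvable", NA_character_,
                                           NA_character_, NA_character_)
        }
      } else {
        rows[[length(rows) + 1L]] <- rec("fixed_diff", NA_character_,
                                         strsplit(pred, "")[[1]][1], col[1])
      }
      next
    }

    # varieties differ among themselves: candidate SNP
    U <- lapply(unique(col), iupac_decompose)
    names(U) <- unique(col)
    Uv <- U[col]
    F0 <- Reduce(intersect, Uv)
    Dv <- lapply(Uv, function(u) setdiff(u, F0))
    if (any(lengths(Dv) > 1L)) {
      rows[[length(rows) + 1L]] <- rec("unresolvable", NA_character_,
                                       NA_character_, NA_character_)
      next
    }
    ds <- unique(unlist(Dv))
    allele_of <- NULL
    if (length(ds) == 2L && all(lengths(Dv) == 1L)) {
      alleles <- ds
      allele_of <- unlist(Dv)
    } else if (length(ds) == 1L && length(F0) == 1L) {
      # second allele hidden inside the fixed contribution (HSV-coincident case)
      alleles <- c(ds, F0)
      allele_of <- ifelse(lengths(Dv) == 1L, ds, F0)
    } else {
      rows[[length(rows) + 1L]] <- rec("unresolvable", NA_character_,
                                       NA_character_, NA_character_)
      next
    }
    candA <- has_a && (!has_b || all(bset %in% F0)) && any(alleles %in% aset)
    candB <- has_b && (!has_a || all(aset %in% F0)) && any(alleles %in% bset)
    if (candA && candB) {
      onlyA <- any(alleles %in% aset) && !any(alleles %in% bset)
      onlyB <- any(alleles %in% bset) && !any(alleles %in% aset)
      if (onlyA) candB <- FALSE else if (onlyB) candA <- FALSE
    }
    if (candA || candB) {
      # both attributions viable happens whenever the progenitors share the
      # column base: the SNP is real but its subgenome is not identifiable
      # from this column alone
      sg <- if (candA && candB) NA_character_ else if (candA) "A" else "B"
      coincident <- has_a && has_b && length(aset) == 1L && length(bset) == 1L &&
        !identical(aset, bset)
      tab <- table(factor(allele_of, levels = alleles))
      n_minor <- as.integer(min(tab))
      # order alleles ref-first: a progenitor-matching base is the reference
      pg <- union(aset, bset)
      if (alleles[2] %in% pg && !(alleles[1] %in% pg)) alleles <- rev(alleles)
      rows[[length(rows) + 1L]] <- rec("SNP", sg, alleles[1], alleles[2],
                                       coincident, n_minor)
      cl <- match(allele_of, alleles)
      names(cl) <- names(panel_obs)
      calls[[sprintf("%s:%d", locus, p)]] <- cl
    } else {
      rows[[length(rows) + 1L]] <- rec("unresolvable", NA_character_,
                                       NA_character_, NA_character_)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_variant_table()
  attr(out, "calls") <- calls
  out
}

# ----------------------------------------------------- strand-collapsed class

#' Collapse a base pair to its strand-symmetric variant class
#'
#' The 12 ordered base pairs fall into 4 classes under complementation:
#' `C/T(G/A)`, `A/C(T/G)`, `A/T(T/A)`, `C/G(G/C)`. Transitions (the first
#' class) cover 4 of the 12 ordered pairs.
#'
#' @param a,b two distinct canonical bases.
#' @return class label, one of the four above.
#' @export
collapse_variant_class <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (!all(c(a, b) %in% .BASES)) stop("canonical bases required")
  if (a == b) stop("identical bases have no variant class")
  key <- paste(sort(c(a, b)), collapse = "")
  switch(key,
         "CT" = , "AG" = "C/T(G/A)",
         "AC" = , "GT" = "A/C(T/G)",
         "AT" = "A/T(T/A)",
         "CG" = "C/G(G/C)")
}

# per-column modal variety letter: majority pattern, ties broken toward the
# smaller base set (homozygous-like), then alphabetically -- a robust stand-in
# for "a typical variety" when inferring composition on a segregating panel
.modal_observation <- function(panel_obs) {
  mat <- do.call(rbind, lapply(panel_obs, function(o) strsplit(o$sequence, "")[[1]]))
  seq <- vapply(seq_len(ncol(mat)), function(j) {
    tb <- table(mat[, j])
    cand <- names(tb)[tb == max(tb)]
    if (length(cand) > 1L) {
      sz <- vapply(cand, function(l) length(iupac_decompose(l)), 0L)
      cand <- sort(cand[sz == min(sz)])
    }
    cand[1]
  }, "")
  obs <- observe_amplicon(paste(seq, collapse = ""),
                          panel_obs[[1]]$locus_id, "panel-modal")
  attr(obs, "uniform") <- vapply(seq_len(ncol(mat)), function(j) {
    length(unique(mat[, j])) == 1L
  }, TRUE)
  obs
}

#' Classify a whole simulated panel and compare against truth
#'
#' Convenience driver: for every sequenceable locus of a `panel_truth`, build
#' the observations, infer copy composition, classify all sites, and (if
#' requested) join against the generator's truth table.
#'
#' @param panel a `panel_truth`.
#' @param compare_truth add per-site truth category and a recovery summary.
#' @return list with `variants` (all classified sites), `compositions`
#'   (per-locus table), `calls` (SNP call list) and, when `compare_truth`,
#'   `recovery`: fraction of observable truth sites recovered with the
#'   correct category, plus the false-category count among resolved sites.
#' @export
classify_panel <- function(panel, compare_truth = TRUE) {
  stopifnot(inherits(panel, "panel_truth"))
  vts <- list(); comps <- list(); calls <- list()
  for (lm in panel$loci) {
    if (!lm$sequenceable) next
    obs <- locus_observations(panel, lm$locus_id)
    tetra_ref <- .modal_observation(obs$varieties)
    comp <- infer_copy_composition(tetra_ref, obs$progA, obs$progB,
                                   mask = attr(tetra_ref, "uniform"))
    comps[[lm$locus_id]] <- data.frame(
      locus_id = lm$locus_id, hypothesis = comp$hypothesis,
      mismatch_count = comp$mismatch_count, explained = comp$explained,
      stringsAsFactors = FALSE)
    if (!comp$explained) next
    vt <- classify_sites(obs$varieties, obs$progA, obs$progB, comp)
    calls <- c(calls, attr(vt, "calls"))
    vts[[lm$locus_id]] <- vt
  }
  variants <- if (length(vts)) do.call(rbind, c(vts, make.row.names = FALSE)) else .empty_variant_table()
  out <- list(variants = variants,
              compositions = do.call(rbind, c(comps, make.row.names = FALSE)),
              calls = calls)
  if (compare_truth) {
    ts <- truth_sites(panel)
    seqable <- vapply(panel$loci, function(l) l$sequenceable, TRUE)
    ok_loci <- vapply(panel$loci, `[[`, "", "locus_id")[seqable]
    ts <- ts[ts$observable & ts$locus_id %in% ok_loci, , drop = FALSE]
    key_t <- sprintf("%s:%d:%s", ts$locus_id, ts$position + 1L, ts$category)
    key_c <- sprintf("%s:%d:%s", variants$locus_id, variants$pos_1based,
                     variants$category)
    recovered <- key_t %in% key_c
    resolved <- variants[!variants$category %in% c("unresolvable", "fixed_diff"), ]
    key_r <- sprintf("%s:%d:%s", resolved$locus_id, resolved$pos_1based,
                     resolved$category)
    out$recovery <- list(
      n_truth = nrow(ts), n_recovered = sum(recovered),
      recovery_rate = if (nrow(ts)) mean(recovered) else NA_real_,
      n_false_category = sum(!key_r %in% key_t))
  }
  out
}

#' Write a classified variant table as TSV
#'
#' @param variants variant table from [classify_sites()]/[classify_panel()].
#' @param file output path.
#' @export
write_variant_tsv <- function(variants, file) {
  utils::write.table(variants, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
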