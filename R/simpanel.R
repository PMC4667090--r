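#' Synthetic progenitor / tetraploid amplicon panels with known truth
#'
#' The real data regime this emulates: ~600 bp Sanger amplicons sequenced in
#' two diploid progenitor genomes (A and B) and a panel of allotetraploid
#' (AABB) varieties. Between the subgenomes, fixed homoeologous sequence
#' variants (HSVs) accumulate at roughly one per 32-77 bp; within a genome,
#' duplicated loci carry paralogous sequence variants (PSVs) at one per
#' 27-87 bp; true homologous SNPs segregating among varieties are far rarer
#' (one per 1000-2600 bp). After polyploidisation some copies are lost
#' ("sequence elimination"), multi-copy loci more readily than single-copy
#' ones. Every planted variant is recorded so downstream classification can be
#' scored against truth.
#'
#' @name simpanel
NULL

.BASES <- c("A", "C", "G", "T")

.random_seq <- function(len) paste(sample(.BASES, len, replace = TRUE), collapse = "")

# substitute a random different base at the given 1-based positions
.mutate_at <- function(seq, pos1) {
  if (length(pos1) == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos1) ch[p] <- sample(setdiff(.BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

.char_at <- function(seq, pos1) substring(seq, pos1, pos1)

#' Simulation configuration
#'
#' Defaults place the generator in the regime described above: 600 bp loci,
#' HSV rate 1/50 bp, PSV rate 1/50 bp on the ~20% of loci that carry a
#' within-genome duplicate, SNP rate 1/1500 bp, a 96-variety panel, and
#' elimination probabilities 0.05 (single-copy) / 0.15 (multi-copy).
#'
#' @param n_loci number of amplified loci.
#' @param locus_length_bp amplicon length (default 600).
#' @param hsv_rate per-bp probability of a fixed A-vs-B difference.
#' @param psv_dup_prob probability that a genome carries a paralog pair at a
#'   locus (applied independently to A and B).
#' @param psv_rate per-bp divergence between paralogs.
#' @param snp_rate per-bp probability of a SNP segregating in the panel.
#' @param elimination_prob_single,elimination_prob_multi per-copy loss
#'   probability in the tetraploid for single-copy / multi-copy loci;
#'   `elimination_prob_multi >= elimination_prob_single` is enforced.
#' @param n_varieties tetraploid panel size (default 96).
#' @param minor_allele_freq_range interval in (0, 0.5] from which each SNP's
#'   minor-allele frequency is drawn uniformly.
#' @param hsv_coincident_frac fraction of SNPs deliberately planted on HSV
#'   columns with the minor allele equal to the other subgenome's base -- the
#'   pathological case in which a subgenome SNP hides inside a homoeologous
#'   difference.
#' @param unsequenceable_prob probability a locus yields no readable sequence
#'   (multi-fragment amplicons, indel mixtures); such loci are flagged and
#'   skipped downstream, mirroring the ~80% sequencing success of real panels.
#' @param est_frac fraction of loci labelled EST-derived (rest GSS).
#' @param seed integer RNG seed; all outputs are reproducible given the seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_loci,
                       locus_length_bp = 600L,
                       hsv_rate = 1 / 50,
                       psv_dup_prob = 0.2,
                       psv_rate = 1 / 50,
                       snp_rate = 1 / 1500,
                       elimination_prob_single = 0.05,
                       elimination_prob_multi = 0.15,
                       n_varieties = 96L,
                       minor_allele_freq_range = c(0.01, 0.5),
                       hsv_coincident_frac = 0,
                       unsequenceable_prob = 0.2,
                       est_frac = 0.5,
                       seed = 1L) {
  rates <- c(hsv_rate, psv_dup_prob, psv_rate, snp_rate,
             elimination_prob_single, elimination_prob_multi,
             hsv_coincident_frac, unsequenceable_prob, est_frac)
  if (any(rates < 0 | rates > 1)) stop("all rates/probabilities must lie in [0, 1]")
  if (elimination_prob_multi < elimination_prob_single) {
    stop("elimination_prob_multi must be >= elimination_prob_single")
  }
  if (locus_length_bp <= 0) stop("locus_length_bp must be positive")
  if (n_loci <= 0) stop("n_loci must be positive")
  if (length(minor_allele_freq_range) != 2L ||
      minor_allele_freq_range[1] <= 0 || minor_allele_freq_range[2] > 0.5 ||
      diff(minor_allele_freq_range) < 0) {
    stop("minor_allele_freq_range must be an interval within (0, 0.5]")
  }
  structure(list(
    n_loci = as.integer(n_loci), locus_length_bp = as.integer(locus_length_bp),
    hsv_rate = hsv_rate, psv_dup_prob = psv_dup_prob, psv_rate = psv_rate,
    snp_rate = snp_rate,
    elimination_prob_single = elimination_prob_single,
    elimination_prob_multi = elimination_prob_multi,
    n_varieties = as.integer(n_varieties),
    minor_allele_freq_range = minor_allele_freq_range,
    hsv_coincident_frac = hsv_coincident_frac,
    unsequenceable_prob = unsequenceable_prob,
    est_frac = est_frac, seed = as.integer(seed)
  ), class = "sim_config")
}

.empty_truth <- function() {
  data.frame(locus_id = character(), position = integer(), category = character(),
             subgenome = character(), allele1 = character(), allele2 = character(),
             n_minor = integer(), n_major = integer(), hsv_coincident = logical(),
             observable = logical(), stringsAsFactors = FALSE)
}

#' Simulate the two diploid progenitor genomes
#'
#' Each locus starts from a random ancestral sequence; the B copy diverges
#' from the A copy by per-bp Bernoulli substitutions at `hsv_rate` (these are
#' the future HSV columns). Independently, each genome gains a paralog with
#' probability `psv_dup_prob`, diverged at `psv_rate` on columns not already
#' used by an HSV so that every variable column has exactly one truth record.
#'
#' @param cfg a [sim_config()].
#' @return list of `locus_model` objects with fields `locus_id`,
#'   `source_class` (EST/GSS), `a_copies`, `b_copies` (named character
#'   vectors), `sequenceable`, and `truth_sites` (0-based positions).
#' @export
simulate_progenitors <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$locus_length_bp
  lapply(seq_len(cfg$n_loci), function(i) {
    locus_id <- sprintf("L%04d", i)
    source_class <- if (stats::runif(1) < cfg$est_frac) "EST" else "GSS"
    a1 <- .random_seq(L)
    hsv_pos <- which(stats::runif(L) < cfg$hsv_rate)   # 1-based
    b1 <- .mutate_at(a1, hsv_pos)
    truth <- .empty_truth()
    if (length(hsv_pos)) {
      truth <- rbind(truth, data.frame(
        locus_id = locus_id, position = hsv_pos - 1L, category = "HSV",
        subgenome = "between", allele1 = .char_at(a1, hsv_pos),
        allele2 = .char_at(b1, hsv_pos), n_minor = NA_integer_,
        n_major = NA_integer_, hsv_coincident = FALSE, observable = NA,
        stringsAsFactors = FALSE))
    }
    a_copies <- c(A1 = a1)
    b_copies <- c(B1 = b1)
    free <- setdiff(seq_len(L), hsv_pos)
    for (g in c("A", "B")) {
      if (stats::runif(1) >= cfg$psv_dup_prob) next
      base_seq <- if (g == "A") a1 else b1
      psv_pos <- free[stats::runif(length(free)) < cfg$psv_rate]
      dup <- .mutate_at(base_seq, psv_pos)
      if (g == "A") a_copies <- c(a_copies, A2 = dup) else b_copies <- c(b_copies, B2 = dup)
      if (length(psv_pos)) {
        truth <- rbind(truth, data.frame(
          locus_id = locus_id, position = psv_pos - 1L, category = "PSV",
          subgenome = paste0("within-", g), allele1 = .char_at(base_seq, psv_pos),
          allele2 = .char_at(dup, psv_pos), n_minor = NA_integer_,
          n_major = NA_integer_, hsv_coincident = FALSE, observable = NA,
          stringsAsFactors = FALSE))
      }
      free <- setdiff(free, psv_pos)  # keep PSV columns distinct across genomes
    }
    structure(list(
      locus_id = locus_id, source_class = source_class,
      a_copies = a_copies, b_copies = b_copies,
      sequenceable = stats::runif(1) >= cfg$unsequenceable_prob,
      truth_sites = truth[order(truth$position), , drop = FALSE]
    ), class = "locus_model")
  })
}

#' Simulate the tetraploid panel: sequence elimination plus segregating SNPs
#'
#' Each subgenome's sequence unit (a single copy, or a paralog pair lost or
#' kept together) is dropped independently with the class-appropriate
#' elimination probability -- loci carrying a paralog pair use the multi-copy
#' probability -- and at least one unit is always retained.
#' SNPs are then planted on retained copies at `snp_rate` per bp, each with a
#' minor-allele count drawn from `minor_allele_freq_range`, and a fraction
#' `hsv_coincident_frac` of them is placed on HSV columns with the minor
#' allele equal to the homoeologous base.
#'
#' @param loci output of [simulate_progenitors()].
#' @param cfg the same [sim_config()].
#' @return a `panel_truth` object: `loci` (each gaining `retained`,
#'   `snp_table`, completed `truth_sites` with observability), `varieties`,
#'   and `cfg`.
#' @export
simulate_tetraploid_panel <- function(loci, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(loci) == 0L) stop("empty locus list")
  set.seed(cfg$seed + 1L)
  varieties <- sprintf("V%03d", seq_len(cfg$n_varieties))
  maf_lo <- cfg$minor_allele_freq_range[1]
  maf_hi <- cfg$minor_allele_freq_range[2]
  loci <- lapply(loci, function(lm) {
    all_copies <- c(lm$a_copies, lm$b_copies)
    # elimination acts on whole subgenome sequence units: a paralog pair is one
    # multi-copy unit and is lost or kept together (a half-lost pair would be
    # observationally indistinguishable from other compositions)
    multi <- length(all_copies) > 2L
    p_drop <- if (multi) cfg$elimination_prob_multi else cfg$elimination_prob_single
    keepA <- stats::runif(1) >= p_drop
    keepB <- stats::runif(1) >= p_drop
    if (!keepA && !keepB) {
      if (stats::runif(1) < 0.5) keepA <- TRUE else keepB <- TRUE
    }
    retained <- c(if (keepA) names(lm$a_copies), if (keepB) names(lm$b_copies))

    # observability of progenitor-planted variants given what survived
    ts <- lm$truth_sites
    has_a <- any(startsWith(retained, "A"))
    has_b <- any(startsWith(retained, "B"))
    if (nrow(ts)) {
      ts$observable <- ifelse(
        ts$category == "HSV", has_a && has_b,
        ifelse(ts$subgenome == "within-A", all(c("A1", "A2") %in% retained),
               all(c("B1", "B2") %in% retained)))
    }

    # SNP planting on retained copies
    L <- cfg$locus_length_bp
    taken <- ts$position + 1L
    n_snp <- stats::rbinom(1L, L, cfg$snp_rate)
    snp_table <- data.frame(position = integer(), copy = character(),
                            ref = character(), alt = character(),
                            carriers = I(list()), stringsAsFactors = FALSE)
    if (n_snp > 0L) {
      hsv_cols <- ts$position[ts$category == "HSV" & ts$observable] + 1L
      for (k in seq_len(n_snp)) {
        coincident <- stats::runif(1) < cfg$hsv_coincident_frac && length(hsv_cols) > 0L
        if (coincident) {
          pos <- if (length(hsv_cols) == 1L) hsv_cols else sample(hsv_cols, 1L)
          hsv_cols <- setdiff(hsv_cols, pos)
        } else {
          avail <- setdiff(seq_len(L), c(taken, snp_table$position + 1L))
          if (length(avail) == 0L) next
          pos <- if (length(avail) == 1L) avail else sample(avail, 1L)
        }
        copy <- if (length(retained) == 1L) retained else sample(retained, 1L)
        ref <- .char_at(all_copies[[copy]], pos)
        alt <- if (coincident) {
          # minor allele equals the homoeologous base: the classic failure case
          other <- if (startsWith(copy, "A")) "B1" else "A1"
          .char_at(all_copies[[other]], pos)
        } else sample(setdiff(.BASES, ref), 1L)
        if (alt == ref) next
        maf <- stats::runif(1, maf_lo, maf_hi)
        n_minor <- max(1L, min(as.integer(round(maf * cfg$n_varieties)),
                               cfg$n_varieties %/% 2L))
        carriers <- sort(sample(cfg$n_varieties, n_minor))
        snp_table <- rbind(snp_table, data.frame(
          position = pos - 1L, copy = copy, ref = ref, alt = alt,
          carriers = I(list(carriers)), stringsAsFactors = FALSE))
        ts <- rbind(ts, data.frame(
          locus_id = lm$locus_id, position = pos - 1L, category = "SNP",
          subgenome = substr(copy, 1L, 1L), allele1 = ref, allele2 = alt,
          n_minor = n_minor, n_major = cfg$n_varieties - n_minor,
          hsv_coincident = coincident, observable = TRUE,
          stringsAsFactors = FALSE))
      }
    }
    lm$retained <- retained
    lm$snp_table <- snp_table
    lm$truth_sites <- ts[order(ts$position), , drop = FALSE]
    lm
  })
  structure(list(loci = loci, varieties = varieties, cfg = cfg),
            class = "panel_truth")
}

#' @export
print.panel_truth <- function(x, ...) {
  ts <- truth_sites(x)
  cat(sprintf("<panel_truth> %d loci x %d varieties; truth: %d SNP, %d HSV, %d PSV\n",
              length(x$loci), length(x$varieties),
              sum(ts$category == "SNP"), sum(ts$category == "HSV"),
              sum(ts$category == "PSV")))
  invisible(x)
}

#' Collected truth table of a panel
#'
#' @param panel a `panel_truth`.
#' @return one data.frame of all planted variants (0-based `position`).
#' @export
truth_sites <- function(panel) {
  stopifnot(inherits(panel, "panel_truth"))
  do.call(rbind, lapply(panel$loci, function(lm) lm$truth_sites))
}

# sequences of the retained copies for one variety (SNP alleles substituted)
.variety_copy_seqs <- function(lm, variety_index) {
  seqs <- c(lm$a_copies, lm$b_copies)[lm$retained]
  st <- lm$snp_table
  if (!is.null(st) && nrow(st)) {
    for (k in seq_len(nrow(st))) {
      if (variety_index %in% st$carriers[[k]] && st$copy[k] %in% lm$retained) {
        s <- seqs[[st$copy[k]]]
        substring(s, st$position[k] + 1L, st$position[k] + 1L) <- st$alt[k]
        seqs[[st$copy[k]]] <- s
      }
    }
  }
  seqs
}

#' Amplicon observations for one locus of a simulated panel
#'
#' Returns what Sanger sequencing would read: the progenitor A and B amplicons
#' (superposing each genome's 1-2 copies) and one consensus per tetraploid
#' variety (superposing all retained copies, with that variety's SNP alleles).
#'
#' @param panel a `panel_truth`.
#' @param locus_id locus identifier.
#' @return list with `progA`, `progB` (`amplicon_obs`) and `varieties`
#'   (named list of `amplicon_obs`).
#' @export
locus_observations <- function(panel, locus_id) {
  stopifnot(inherits(panel, "panel_truth"))
  idx <- match(locus_id, vapply(panel$loci, `[[`, "", "locus_id"))
  if (is.na(idx)) stop("unknown locus: ", locus_id)
  lm <- panel$loci[[idx]]
  progA <- observe_amplicon(unname(lm$a_copies), lm$locus_id, "progA")
  progB <- observe_amplicon(unname(lm$b_copies), lm$locus_id, "progB")
  vars <- lapply(seq_along(panel$varieties), function(v) {
    observe_amplicon(unname(.variety_copy_seqs(lm, v)), lm$locus_id,
                     panel$varieties[v])
  })
  names(vars) <- panel$varieties
  list(progA = progA, progB = progB, varieties = vars)
}

#' RIL simulation configuration
#'
#' @param n_lines population size (default 142).
#' @param n_markers number of unlinked markers.
#' @param selfing_generations generations of selfing after the F1; residual
#'   heterozygosity per marker is (1/2)^selfing_generations in expectation.
#' @param missing_rate per-call missing probability.
#' @param seed RNG seed.
#' @export
ril_config <- function(n_lines = 142L, n_markers, selfing_generations = 6L,
                       missing_rate = 0, seed = 1L) {
  if (n_lines <= 0) stop("n_lines must be positive")
  if (selfing_generations < 1) stop("selfing_generations must be >= 1")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate in [0,1]")
  structure(list(n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
                 selfing_generations = as.integer(selfing_generations),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "ril_config")
}

#' Simulate a recombinant inbred line (RIL) genotype matrix
#'
#' Markers are unlinked; each line inherits one parental allele per marker
#' with equal probability, remains heterozygous (call `"H"`) with probability
#' (1/2)^selfing_generations, and calls are masked at `missing_rate`.
#'
#' @param parent_calls_1,parent_calls_2 character vectors of parental alleles,
#'   one per marker; markers where the parents agree are monomorphic and
#'   inherited as-is.
#' @param cfg a [ril_config()].
#' @return character matrix, lines x markers, values in the parental alleles,
#'   `"H"`, or `NA`.
#' @export
simulate_ril <- function(parent_calls_1, parent_calls_2, cfg) {
  stopifnot(inherits(cfg, "ril_config"))
  if (length(parent_calls_1) != length(parent_calls_2)) stop("parent vectors differ in length")
  if (all(parent_calls_1 == parent_calls_2)) stop("parents identical at all markers: nothing segregates")
  set.seed(cfg$seed)
  n <- cfg$n_lines
  m <- length(parent_calls_1)
  h <- (1 / 2)^cfg$selfing_generations
  out <- matrix(NA_character_, n, m,
                dimnames = list(sprintf("RIL%03d", seq_len(n)),
                                names(parent_calls_1) %||% sprintf("M%03d", seq_len(m))))
  for (j in seq_len(m)) {
    if (parent_calls_1[j] == parent_calls_2[j]) {
      out[, j] <- parent_calls_1[j]
      next
    }
    het <- stats::runif(n) < h
    from1 <- stats::runif(n) < 0.5
    out[, j] <- ifelse(het, "H", ifelse(from1, parent_calls_1[j], parent_calls_2[j]))
  }
  if (cfg$missing_rate > 0) {
    out[matrix(stats::runif(length(out)) < cfg$missing_rate, n, m)] <- NA_character_
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write panel sequences as multi-FASTA
#'
#' Record ids follow `<locus>|<genotype>|<copy>` for per-copy truth sequences
#' and `<locus>|<genotype>|consensus` for IUPAC observations.
#'
#' @param panel a `panel_truth`.
#' @param file output path.
#' @param what `"observations"` (IUPAC consensus per genotype, the realistic
#'   view) or `"copies"` (phased truth sequences).
#' @return the file path, invisibly.
#' @export
write_panel_fasta <- function(panel, file, what = c("observations", "copies")) {
  what <- match.arg(what)
  stopifnot(inherits(panel, "panel_truth"))
  recs <- character()
  for (lm in panel$loci) {
    if (what == "copies") {
      for (g in c("progA", "progB")) {
        copies <- if (g == "progA") lm$a_copies else lm$b_copies
        for (nm in names(copies)) {
          recs[sprintf("%s|%s|%s", lm$locus_id, g, nm)] <- copies[[nm]]
        }
      }
    } else {
      obs <- locus_observations(panel, lm$locus_id)
      recs[sprintf("%s|progA|consensus", lm$locus_id)] <- obs$progA$sequence
      recs[sprintf("%s|progB|consensus", lm$locus_id)] <- obs$progB$sequence
      for (v in names(obs$varieties)) {
        recs[sprintf("%s|%s|consensus", lm$locus_id, v)] <- obs$varieties[[v]]$sequence
      }
    }
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(recs), file)
  invisible(file)
}

#' Write the truth table as TSV (1-based positions in reports)
#'
#' @param panel a `panel_truth`.
#' @param file output path.
#' @export
write_truth_tsv <- function(panel, file) {
  ts <- truth_sites(panel)
  ts$pos_1based <- ts$position + 1L
  ts$alleles <- paste0(ts$allele1, "/", ts$allele2)
  utils::write.table(
    ts[, c("locus_id", "pos_1based", "category", "subgenome", "alleles",
           "n_minor", "n_major", "hsv_coincident", "observable")],
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
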