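test_that("align_global handles identity, ambiguity matching, and errors", {
  al <- align_global("ACGT", "ACGT")
  expect_equal(al$score, 4)
  expect_equal(al$identity, 1)
  # Y decomposes to {C,T}, which intersects T: counted as a match
  expect_equal(align_global("ACTT", "ACYT")$identity, 1)
  expect_error(align_global("", "ACGT"), "empty")
})

test_that("align_global scores equal an independent DP oracle on random 12-mers", {
  # oracle: Biostrings pairwiseAlignment under the same scoring convention
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                 mismatch = -1,
                                                 baseOnly = TRUE)
  set.seed(99)
  for (i in 1:40) {
    la <- sample(4:12, 1); lb <- sample(4:12, 1)
    a <- paste(sample(c("A", "C", "G", "T"), la, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), lb, TRUE), collapse = "")
    mine <- align_global(a, b, match = 1, mismatch = -1,
                         gap_open = 2, gap_extend = 1)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = sm,
                                         gapOpening = 2, gapExtension = 1,
                                         scoreOnly = TRUE)
    expect_equal(mine$score, ref, label = paste(a, b))
    # ungapping each aligned row reproduces the input
    expect_identical(gsub("-", "", mine$aligned_a), a)
    expect_identical(gsub("-", "", mine$aligned_b), b)
  }
})

test_that("copy composition reproduces the three archetype retention patterns", {
  a <- observe_amplicon("ACGTACGTAC", "L1", "progA")
  b <- observe_amplicon("ACGTTCGTAG", "L1", "progB")   # differs at 5, 10

  # both copies retained: tetraploid superposes A and B
  tetra_ab <- observe_amplicon(c("ACGTACGTAC", "ACGTTCGTAG"), "L1", "tet")
  cab <- infer_copy_composition(tetra_ab, a, b)
  expect_identical(cab$hypothesis, "AB")
  expect_identical(cab$mismatch_count, 0L)
  expect_true(cab$explained)
  # consistency: the predicted consensus reproduces the observation
  expect_identical(cab$predicted, tetra_ab$sequence)

  # B copy eliminated: tetraploid identical to progenitor A
  ca <- infer_copy_composition(observe_amplicon("ACGTACGTAC", "L1", "tet"), a, b)
  expect_identical(ca$hypothesis, "A_only")
  expect_true(ca$explained)

  # heterozygous progenitor A, tetraploid reproducing its paralog superposition
  a2 <- observe_amplicon(c("ACGTACGTAC", "ACCTACGTAC"), "L1", "progA")
  tetra_pa <- observe_amplicon(c("ACGTACGTAC", "ACCTACGTAC"), "L1", "tet")
  cpa <- infer_copy_composition(tetra_pa, a2, b)
  expect_identical(cpa$hypothesis, "A_paralogs")
  expect_true(cpa$explained)

  expect_error(infer_copy_composition(observe_amplicon("ACG"), a, b),
               "length-incompatible")
})

test_that("detect_psv lists one PSV per ambiguity position and flags complex codes", {
  expect_identical(nrow(detect_psv(observe_amplicon("ACGTACGT"))), 0L)
  prog <- observe_amplicon(c("ACGTACGTACG", "ACGTACGTACG"))
  het <- observe_amplicon(c("ACGTACGTACG", "ACGTACGTGCG"))  # R at offset 8
  ps <- detect_psv(het, "A")
  expect_identical(ps$pos_1based, 9L)
  expect_setequal(c(ps$allele1, ps$allele2), c("A", "G"))
  expect_identical(ps$subgenome, "within-A")

  seq_v <- paste0("ACGT", "V", "CGT")  # V = {A,C,G}: triallelic
  expect_warning(res <- detect_psv(observe_amplicon(seq_v)), "complex")
  expect_identical(nrow(res), 0L)
})

test_that("classify_sites sorts columns into HSV / SNP / PSV as constructed", {
  progA <- observe_amplicon("ACGTACGTAC", "L1", "progA")
  progB <- observe_amplicon("ACGTTCGTAC", "L1", "progB")  # HSV at position 5
  # 12 varieties, all superposing A+B; 3 carry a SNP on the A copy at pos 8
  mk <- function(snp) {
    acopy <- "ACGTACGTAC"
    if (snp) substring(acopy, 8, 8) <- "A"
    observe_amplicon(c(acopy, "ACGTTCGTAC"), "L1", "v")
  }
  vars <- c(lapply(1:9, function(i) mk(FALSE)), lapply(1:3, function(i) mk(TRUE)))
  names(vars) <- sprintf("V%02d", 1:12)
  comp <- infer_copy_composition(tetrasnp:::.modal_observation(vars), progA, progB)
  expect_true(comp$explained)
  vt <- classify_sites(vars, progA, progB, comp)

  hsv <- vt[vt$category == "HSV", ]
  expect_identical(hsv$pos_1based, 5L)
  expect_identical(hsv$subgenome, "between")
  expect_setequal(c(hsv$allele1, hsv$allele2), c("A", "T"))

  snp <- vt[vt$category == "SNP", ]
  expect_identical(snp$pos_1based, 8L)
  expect_identical(snp$n_varieties_minor, 3L)
  calls <- attr(vt, "calls")[["L1:8"]]
  expect_identical(sum(calls == 2L), 3L)

  # refuse to classify on a misfitting composition
  bad <- comp; bad$explained <- FALSE; bad$mismatch_count <- 3L
  expect_error(classify_sites(vars, progA, progB, bad), "refusing")
})

test_that("collapse_variant_class maps all 12 ordered pairs onto 4 classes, strand-symmetrically", {
  expect_identical(collapse_variant_class("G", "A"), "C/T(G/A)")
  expect_identical(collapse_variant_class("G", "T"), "A/C(T/G)")
  expect_identical(collapse_variant_class("T", "A"), "A/T(T/A)")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pairs <- expand.grid(a = names(comp), b = names(comp),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  cls <- mapply(collapse_variant_class, pairs$a, pairs$b)
  expect_setequal(unique(cls), c("C/T(G/A)", "A/C(T/G)", "A/T(T/A)", "C/G(G/C)"))
  # 4 of the 12 ordered pairs are transitions
  expect_identical(sum(cls == "C/T(G/A)"), 4L)
  expect_identical(cls, mapply(collapse_variant_class, comp[pairs$a], comp[pairs$b]))
  expect_error(collapse_variant_class("A", "A"), "identical")
})

test_that("panel classification partitions variable columns and recovers truth exactly", {
  panel <- small_panel(seed = 21, n_loci = 60)
  cls <- classify_panel(panel)
  # partition property: every variant row has exactly one category
  expect_true(all(cls$variants$category %in%
                    c("SNP", "HSV", "PSV", "fixed_diff", "unresolvable")))
  expect_false(any(duplicated(
    cls$variants[, c("locus_id", "pos_1based")])))
  # zero-noise oracle equivalence
  expect_identical(cls$recovery$n_recovered, cls$recovery$n_truth)
  expect_identical(cls$recovery$n_false_category, 0L)
  # composition must be explained on every sequenceable locus
  expect_true(all(cls$compositions$explained))
})

test_that("the HSV-coincident SNP failure case is detected and flagged", {
  cfg <- sim_config(n_loci = 30, hsv_rate = 1 / 40, psv_dup_prob = 0,
                    snp_rate = 1 / 300, hsv_coincident_frac = 1,
                    elimination_prob_single = 0, elimination_prob_multi = 0,
                    unsequenceable_prob = 0, n_varieties = 12,
                    minor_allele_freq_range = c(0.1, 0.4), seed = 23)
  panel <- simulate_tetraploid_panel(simulate_progenitors(cfg), cfg)
  ts <- truth_sites(panel)
  expect_gt(sum(ts$hsv_coincident), 0)
  cls <- classify_panel(panel)
  got <- cls$variants[cls$variants$category == "SNP" & cls$variants$hsv_coincident, ]
  want <- ts[ts$category == "SNP" & ts$hsv_coincident, ]
  expect_identical(
    sort(sprintf("%s:%d", got$locus_id, got$pos_1based)),
    sort(sprintf("%s:%d", want$locus_id, want$position + 1L)))
  # coincident SNPs are attributable to the subgenome they sit on
  expect_true(all(got$subgenome %in% c("A", "B")))
})
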