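test_that("sim_config validates rates and intervals", {
  expect_error(sim_config(n_loci = 5, hsv_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_loci = 5, elimination_prob_single = 0.5,
                          elimination_prob_multi = 0.1), "elimination_prob_multi")
  expect_error(sim_config(n_loci = 5, locus_length_bp = 0), "positive")
  expect_error(sim_config(n_loci = 5, minor_allele_freq_range = c(0, 0.6)),
               "minor_allele_freq_range")
})

test_that("zero-rate progenitors are identical and truth-free; fixed seed reproduces", {
  cfg <- sim_config(n_loci = 10, hsv_rate = 0, psv_dup_prob = 0, seed = 2)
  loci <- simulate_progenitors(cfg)
  for (lm in loci) {
    expect_identical(unname(lm$a_copies["A1"]), unname(lm$b_copies["B1"]))
    expect_identical(nrow(lm$truth_sites), 0L)
  }
  loci2 <- simulate_progenitors(cfg)
  expect_identical(loci, loci2)

  cfg2 <- sim_config(n_loci = 6, seed = 9)
  p1 <- simulate_tetraploid_panel(simulate_progenitors(cfg2), cfg2)
  p2 <- simulate_tetraploid_panel(simulate_progenitors(cfg2), cfg2)
  expect_identical(p1, p2)
})

test_that("HSV planting follows its Poisson/binomial law (3-sigma oracle)", {
  cfg <- sim_config(n_loci = 50, locus_length_bp = 600, hsv_rate = 1 / 32,
                    psv_dup_prob = 0, seed = 4)
  loci <- simulate_progenitors(cfg)
  n_hsv <- sum(vapply(loci, function(l) sum(l$truth_sites$category == "HSV"), 0L))
  lambda <- 50 * 600 / 32
  expect_lt(abs(n_hsv - lambda), 3 * sqrt(lambda))
})

test_that("multi-copy sequences are eliminated more often than single-copy", {
  cfg <- sim_config(n_loci = 500, locus_length_bp = 80, psv_dup_prob = 0.5,
                    elimination_prob_single = 0.1, elimination_prob_multi = 0.5,
                    snp_rate = 0, unsequenceable_prob = 0, n_varieties = 2,
                    seed = 6)
  panel <- simulate_tetraploid_panel(simulate_progenitors(cfg), cfg)
  loss <- vapply(panel$loci, function(lm) {
    total <- length(lm$a_copies) + length(lm$b_copies)
    c(multi = total > 2L, lost = (total - length(lm$retained)) / total)
  }, c(multi = 0, lost = 0))
  lost_multi <- mean(loss["lost", loss["multi", ] == 1])
  lost_single <- mean(loss["lost", loss["multi", ] == 0])
  expect_gt(lost_multi, lost_single)
})

test_that("no elimination retains the full AB composition everywhere", {
  cfg <- sim_config(n_loci = 30, elimination_prob_single = 0,
                    elimination_prob_multi = 0, psv_dup_prob = 0, seed = 8)
  panel <- simulate_tetraploid_panel(simulate_progenitors(cfg), cfg)
  for (lm in panel$loci) expect_setequal(lm$retained, c("A1", "B1"))
  expect_error(simulate_tetraploid_panel(list(), cfg), "empty")
})

test_that("realized SNP density matches the target rate within 3 sigma", {
  rate <- 1 / 1011
  cfg <- sim_config(n_loci = 400, locus_length_bp = 600, snp_rate = rate,
                    psv_dup_prob = 0, unsequenceable_prob = 0,
                    elimination_prob_single = 0, elimination_prob_multi = 0,
                    n_varieties = 12, seed = 10)
  panel <- simulate_tetraploid_panel(simulate_progenitors(cfg), cfg)
  ts <- truth_sites(panel)
  n_snp <- sum(ts$category == "SNP")
  lambda <- 400 * 600 * rate
  expect_lt(abs(n_snp - lambda), 3 * sqrt(lambda))
  d <- variant_density(n_snp, 400 * 600, digits = 0)
  expect_lt(abs(d$bp_per_variant - 1011), 3 * sqrt(lambda) / n_snp * 1011)
})

test_that("truth completeness: a brute-force column scan of retained copies equals truth_sites", {
  panel <- small_panel(seed = 12, n_loci = 25)
  for (lm in panel$loci) {
    obs_var <- lapply(seq_along(panel$varieties),
                      function(v) tetrasnp:::.variety_copy_seqs(lm, v))
    L <- panel$cfg$locus_length_bp
    variable <- vapply(seq_len(L), function(p) {
      letters <- unlist(lapply(obs_var, function(cp) substring(cp, p, p)))
      length(unique(letters)) > 1L
    }, TRUE)
    ts <- lm$truth_sites
    expected <- sort(unique(ts$position[ts$observable])) + 1L
    expect_identical(which(variable), as.integer(expected), label = lm$locus_id)
    # and each variable position has exactly one observable truth record
    expect_false(any(duplicated(ts$position[ts$observable])))
  }
})

test_that("RIL simulation obeys its closed forms", {
  p1 <- stats::setNames(rep("A", 20), sprintf("M%02d", 1:20))
  p2 <- stats::setNames(rep("B", 20), sprintf("M%02d", 1:20))
  cfg <- ril_config(n_lines = 2000, n_markers = 20, selfing_generations = 6,
                    missing_rate = 0, seed = 1)
  ril <- simulate_ril(p1, p2, cfg)
  expect_false(anyNA(ril))
  het <- mean(ril == "H")
  expect_lt(abs(het - 1 / 64), 3 * sqrt((1 / 64) * (63 / 64) / length(ril)))

  # fair segregation accepted by the chi-square test in >= 94% of markers
  cfg2 <- ril_config(n_lines = 142, n_markers = 300, selfing_generations = 6,
                     missing_rate = 0, seed = 2)
  seg <- segregation_tests(simulate_ril(
    stats::setNames(rep("A", 300), sprintf("M%03d", 1:300)),
    stats::setNames(rep("B", 300), sprintf("M%03d", 1:300)), cfg2))
  expect_gte(mean(!seg$distorted), 0.94)

  expect_error(simulate_ril(p1, p1, cfg), "identical")
  cfg3 <- ril_config(n_lines = 50, n_markers = 20, missing_rate = 0.2, seed = 3)
  expect_gt(sum(is.na(simulate_ril(p1, p2, cfg3))), 0)
})

test_that("panel FASTA and truth TSV round-trip through standard readers", {
  panel <- small_panel(seed = 14, n_loci = 4, n_varieties = 3)
  fa <- tempfile(fileext = ".fasta")
  write_panel_fasta(panel, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_true(all(grepl("\\|consensus$", names(seqs))))
  expect_identical(unique(Biostrings::width(seqs)), panel$cfg$locus_length_bp)

  tsv <- tempfile(fileext = ".tsv")
  write_truth_tsv(panel, tsv)
  ts <- utils::read.delim(tsv)
  expect_identical(nrow(ts), nrow(truth_sites(panel)))
  expect_true(all(ts$pos_1based >= 1))
})
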