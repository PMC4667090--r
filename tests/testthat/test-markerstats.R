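test_that("pic reproduces published marker values and the closed-form bounds", {
  expect_equal(pic(c(28, 68), 96)$pic_3dp, 0.413)
  expect_equal(pic(c(71, 15), 96)$pic_3dp, 0.429)  # counts sum to 86: /96 convention
  expect_equal(pic(c(96, 0), 96)$pic, 0)
  expect_equal(pic(c(48, 48), 96)$pic, 0.5)
  # the alternative genotyped-denominator convention gives a different value
  expect_equal(round(pic(c(71, 15), 96, denominator = "genotyped")$pic, 3), 0.288)
  expect_error(pic(c(50, 50), 96), "exceed")
  expect_error(pic(c(-1, 5), 96), "negative")
  expect_error(pic(c(1, 2), 0), "positive")
})

test_that("pic is label-symmetric, maximized at equifrequency, and monotone past N/2", {
  for (a in c(0, 10, 30, 48)) {
    expect_equal(pic(c(a, 96 - a), 96)$pic, pic(c(96 - a, a), 96)$pic)
  }
  sweep <- vapply(48:96, function(a) pic(c(a, 96 - a), 96)$pic, 0)
  expect_true(all(diff(sweep) < 0))
  expect_equal(max(sweep), 0.5)
})

test_that("summarize_markers reproduces the published EST group mean", {
  t1 <- utils::read.delim(table1_path())
  res <- summarize_markers(t1[, c("marker_id", "variant_class", "count1", "count2")],
                           panel_size = 96)
  est <- res$summary[res$summary$group == "EST", ]
  expect_equal(est$mean_pic, 0.172)
  expect_equal(est$n, 12L)
  expect_equal(est$min_pic, 0.021)
  expect_equal(est$max_pic, 0.413)
  single <- summarize_markers(data.frame(marker_id = "EST-x", count1 = 28,
                                         count2 = 68), 96)
  expect_equal(single$summary$mean_pic, 0.413)
  mono <- summarize_markers(data.frame(marker_id = c("a", "b"),
                                       count1 = c(96, 0), count2 = c(0, 96),
                                       group = "g"), 96)
  expect_equal(mono$summary$mean_pic, 0)
})

test_that("variant_density inverts counts and handles the zero case", {
  expect_equal(variant_density(10, 1000)$bp_per_variant, 100)
  expect_equal(variant_density(306, 23531)$reported, 76.9)
  expect_identical(variant_density(0, 1000)$reported, "no variants")
  expect_error(variant_density(5, 0), "positive")
})

test_that("class_spectrum matches hand arithmetic and the uniform-mutation law", {
  cls <- rep(c("C/T(G/A)", "A/C(T/G)", "A/T(T/A)", "C/G(G/C)"), c(7, 7, 3, 1))
  sp <- class_spectrum(cls)
  expect_equal(round(100 * sp$proportion, 1), c(38.9, 38.9, 16.7, 5.6))
  expect_equal(sum(sp$proportion), 1)
  one <- class_spectrum("A/T(T/A)")
  expect_equal(one$proportion[one$class == "A/T(T/A)"], 1)

  # under uniform substitution, 4 of the 12 ordered pairs are transitions
  set.seed(31)
  pairs <- t(replicate(4000, sample(c("A", "C", "G", "T"), 2)))
  cls2 <- apply(pairs, 1, function(p) collapse_variant_class(p[1], p[2]))
  frac <- mean(cls2 == "C/T(G/A)")
  expect_lt(abs(frac - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 4000))
})

test_that("ld_r2 matches the contingency-table oracle and flags degenerate input", {
  expect_equal(ld_r2(c(0, 0, 1, 1), c(0, 0, 1, 1))$r2, 1)
  expect_equal(ld_r2(c(0, 0, 1, 1), c(0, 1, 0, 1))$r2, 0)

  x <- c(0, 0, 1, 1, 1, 1); y <- c(0, 1, 1, 1, 1, 0)
  # oracle: D^2 / (p1 p2 q1 q2) from the 2x2 haplotype table
  pAB <- mean(x == 1 & y == 1); pA <- mean(x == 1); pB <- mean(y == 1)
  D <- pAB - pA * pB
  oracle <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  expect_equal(ld_r2(x, y)$r2, oracle)

  # symmetry and relabeling invariance
  expect_equal(ld_r2(y, x)$r2, ld_r2(x, y)$r2)
  expect_equal(ld_r2(1 - x, y)$r2, ld_r2(x, y)$r2)

  # missing data restricts to complete pairs
  r <- ld_r2(c(0, 1, NA, 1, 0), c(0, 1, 0, 1, NA))
  expect_identical(r$n_complete, 3L)
  # monomorphic among complete pairs: undefined, not an error
  expect_false(ld_r2(c(0, 0, 0, NA), c(0, 1, 0, 1))$defined)
  expect_error(ld_r2(c(0, 1), c(0, 1, 1)), "length")
})

test_that("marker_selection keeps one SNP per fully linked class", {
  calls_a <- c(0, 0, 1, 1, 0, 1)
  calls_b <- 1 - calls_a          # same partition, relabeled: r2 = 1
  calls_c <- c(0, 1, 1, 0, 0, 1)  # different partition
  frag3 <- list(list(id = "s1", position = 10, calls = calls_a),
                list(id = "s2", position = 40, calls = calls_b),
                list(id = "s3", position = 90, calls = calls_a))
  expect_identical(marker_selection(frag3), "s1")
  frag2 <- list(list(id = "s1", position = 10, calls = calls_a),
                list(id = "s2", position = 40, calls = calls_c))
  expect_identical(marker_selection(frag2), c("s1", "s2"))
  expect_identical(marker_selection(list(list(id = "only", position = 5,
                                              calls = calls_a))), "only")
  expect_error(marker_selection(list()), "no SNPs")
})

test_that("chi_square_1to1 gives the closed-form statistic and flags", {
  even <- chi_square_1to1(c(50, 50))
  expect_equal(even$chi2, 0)
  expect_false(even$distorted)
  skew <- chi_square_1to1(c(60, 40))
  expect_equal(skew$chi2, 4)
  expect_equal(round(skew$p, 4), 0.0455)
  expect_true(skew$distorted)
  expect_error(chi_square_1to1(c(0, 0)), "zero total")
})
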