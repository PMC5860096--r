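test_that("score_word evaluates the log-likelihood ratio", {
  unif_pfm <- motifclump:::new_pfm(matrix(0.25, 4, 3), name = "flat")
  for (w in c("AAA", "ACG", "TGT"))
    expect_equal(score_word(unif_pfm, uniform_bg, w), 0, tolerance = 1e-14)

  m1 <- motifclump:::new_pfm(matrix(c(0.5, 0.25, 0.125, 0.125), 4, 1))
  expect_equal(score_word(m1, uniform_bg, "A"), log(2), tolerance = 1e-14)

  expect_equal(score_word(fix$aaa, uniform_bg, "AAA"),
               3 * log(0.97 / 0.25), tolerance = 1e-14)

  expect_error(score_word(fix$aaa, bg_order1, "AAAA"), "length")
  bg4 <- estimate_background("ACGTACGTACGT", 4, 1)
  expect_error(score_word(fix$aaa, bg4, "AAA"), "order exceeds")
})

test_that("the score DP equals exhaustive enumeration", {
  # flat motif on a flat background collapses to a point mass at 0
  unif_pfm <- motifclump:::new_pfm(matrix(0.25, 4, 3))
  sd0 <- score_distribution(unif_pfm, uniform_bg, 0.01)
  expect_equal(sd0$index, 0L)
  expect_equal(sd0$prob, 1)

  for (d in 0:2) {
    bg <- if (d == 0) skew_bg else
      estimate_background(sample_sequences(skew_bg, 1, 4000, seed = 30 + d),
                          d, 1)
    p <- random_pfm(4, seed = 40 + d)
    got <- score_distribution(p, bg, 0.01)
    want <- oracle_score_dist(p, bg, 0.01)
    expect_identical(got$index, want$index)
    expect_equal(got$prob, want$prob, tolerance = 1e-12)
    expect_equal(sum(got$prob), 1, tolerance = 1e-12)
  }
})

test_that("score distributions are strand-symmetric under symmetric bg", {
  # exact grid equality for order 0: per-position rounding commutes with
  # reverse complementation when the background factor is a single pi
  for (p in list(fix$nonself, fix$palindrome, random_pfm(4, seed = 45))) {
    a <- score_distribution(p, skew_bg, 0.01)
    b <- score_distribution(reverse_complement_pfm(p), skew_bg, 0.01)
    expect_identical(a$index, b$index)
    expect_equal(a$prob, b$prob, tolerance = 1e-12)
  }
  # for d >= 1 the grids differ by per-position rounding, but the hit
  # probability of a well-separated motif is identical on both strands
  # (alpha anchored just above the exact-word probability)
  for (nm in c("nonself", "palindrome")) {
    p <- fix[[nm]]
    a <- 1.2 * exp(word_logprob(bg_order1, attr(p, "name")))
    ta <- choose_threshold(score_distribution(p, bg_order1, 0.01), a)
    tb <- choose_threshold(
      score_distribution(reverse_complement_pfm(p), bg_order1, 0.01), a)
    expect_gt(ta$attained_alpha, 0)
    expect_equal(ta$attained_alpha, tb$attained_alpha, tolerance = 1e-12)
  }
})

test_that("choose_threshold picks the smallest grid score within alpha", {
  dist <- score_distribution(fix$aaa, uniform_bg, 0.01)
  t1 <- choose_threshold(dist, 1)
  expect_equal(t1$t_index, min(dist$index))
  expect_equal(t1$attained_alpha, 1, tolerance = 1e-12)

  # alpha just above P(AAA): only the exact word scores at or above t
  thr <- choose_threshold(dist, 0.02)
  expect_equal(thr$attained_alpha, 1 / 64, tolerance = 1e-14)
  words <- motifclump:::all_words(3)
  idx <- apply(words, 1, oracle_window_index, pfm = fix$aaa,
               bg = uniform_bg, g = 0.01)
  expect_identical(which(idx >= thr$t_index), 1L)  # word index 1 = AAA

  # monotone in alpha
  alphas <- c(0.9, 0.5, 0.1, 0.02, 0.015625)
  ts <- vapply(alphas, function(a) choose_threshold(dist, a)$t_alpha, 0)
  expect_true(all(diff(ts) >= 0))
  for (a in alphas)
    expect_lte(choose_threshold(dist, a)$attained_alpha, a)

  expect_warning(tsm <- choose_threshold(dist, 1e-9), "smallest positive")
  expect_equal(tsm$attained_alpha, 0)
  expect_gt(tsm$t_index, max(dist$index))
})

test_that("attained alpha converges under grid refinement", {
  # for the sharply separated fixture the hit set is the exact word at
  # any reasonable granularity, so the attained level is grid-free
  for (g in c(0.05, 0.01, 0.002)) {
    a <- choose_threshold(score_distribution(fix$aaa, uniform_bg, g),
                          0.02)$attained_alpha
    expect_equal(a, 1 / 64, tolerance = 1e-12)
  }
  # fixed real threshold: rounding moves a word score by at most M*g/2,
  # so the tail at t can change by at most the mass near t
  coarse <- score_distribution(fix$nonself, bg_order1, 0.01)
  thr <- choose_threshold(coarse,
                          1.2 * exp(word_logprob(bg_order1, "ACGGT")))
  fine <- score_distribution(fix$nonself, bg_order1, 0.001)
  band <- 5 / 2 * (0.01 + 0.001)
  tail_fine <- sum(fine$prob[fine$index * 0.001 >= thr$t_alpha])
  near <- sum(fine$prob[abs(fine$index * 0.001 - thr$t_alpha) <= band])
  expect_lte(abs(tail_fine - thr$attained_alpha), near + 1e-12)
})

test_that("joint distributions have consistent marginals", {
  p <- random_pfm(4, seed = 50)
  sd_f <- score_distribution(p, bg_order1, 0.01)
  sd_r <- score_distribution(reverse_complement_pfm(p), bg_order1, 0.01)
  # each marginal must equal the 1-D distribution of the matrix that
  # scored that window (forward or reverse complement per orientation)
  expect_marg <- function(j, wh, want) {
    m <- joint_marginal(j, wh)
    expect_identical(m$index, want$index)
    expect_equal(m$prob, want$prob, tolerance = 1e-9)
  }
  for (k in c(1L, 3L)) {
    jff <- joint_score_distribution(p, bg_order1, k, "ff", 0.01)
    expect_marg(jff, 1, sd_f); expect_marg(jff, 2, sd_f)
    jfr <- joint_score_distribution(p, bg_order1, k, "fr", 0.01)
    expect_marg(jfr, 1, sd_f); expect_marg(jfr, 2, sd_r)
    jrf <- joint_score_distribution(p, bg_order1, k, "rf", 0.01)
    expect_marg(jrf, 1, sd_r); expect_marg(jrf, 2, sd_f)
    expect_equal(sum(jff$table$p), 1, tolerance = 1e-12)
  }
  expect_error(joint_score_distribution(p, bg_order1, 0, "ff"), "shift")
  expect_error(joint_score_distribution(p, bg_order1, 4, "fr"), "shift")
})

test_that("fr at shift 0 is exchangeable for the palindromic fixture", {
  j <- joint_score_distribution(fix$palindrome, uniform_bg, 0, "fr", 0.01)
  tab <- j$table
  key <- paste(tab$ia, tab$ib)
  swap <- paste(tab$ib, tab$ia)
  expect_setequal(key, swap)
  expect_equal(tab$p[match(swap, key)], tab$p, tolerance = 1e-12)
})

test_that("joint DP equals exhaustive enumeration at maximal shift", {
  p <- random_pfm(3, seed = 51)
  thr <- choose_threshold(score_distribution(p, skew_bg, 0.01), 0.05)
  j <- joint_score_distribution(p, skew_bg, 2L, "ff", 0.01)
  got <- joint_tail_prob(j, thr$t_index) / thr$attained_alpha
  expect_equal(got, oracle_gamma(p, skew_bg, thr, 2L, "ff"),
               tolerance = 1e-12)
})
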