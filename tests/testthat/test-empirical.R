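aaa_thr2 <- choose_threshold(score_distribution(fix$aaa, uniform_bg, 0.01),
                             0.02)

test_that("the scanner finds hits on both strands at exact coordinates", {
  expect_equal(nrow(scan_sequence(fix$aaa, uniform_bg, aaa_thr2, "AC")), 0)

  h <- scan_sequence(fix$aaa, uniform_bg, aaa_thr2, "TTTAAATTT")
  # AAA at start 3 on +; the TTT windows at 0 and 6 are reverse hits
  expect_equal(h$start, c(0L, 3L, 6L))
  expect_equal(h$strand, c("-", "+", "-"))
  expect_equal(h$score[2], 3 * log(0.97 / 0.25), tolerance = 0.02)

  # masked windows are skipped
  hN <- scan_sequence(fix$aaa, uniform_bg, aaa_thr2, "AANAAA")
  expect_equal(hN$start, 3L)

  # + before - at the same start
  hp <- scan_sequence(fix$palindrome, uniform_bg,
                      choose_threshold(score_distribution(fix$palindrome,
                                                          uniform_bg, 0.01),
                                       1e-3),
                      "ACGCGT")
  expect_equal(hp$start, c(0L, 0L))
  expect_equal(hp$strand, c("+", "-"))
})

test_that("scanning the reverse complement mirrors the hit list", {
  set.seed(90)
  s <- sample_sequences(uniform_bg, 1, 3000, seed = 90)
  thr <- choose_threshold(score_distribution(fix$repeatlike, uniform_bg,
                                             0.01), 1e-2)
  h1 <- scan_sequence(fix$repeatlike, uniform_bg, thr, s)
  h2 <- scan_sequence(fix$repeatlike, uniform_bg, thr, rc_word(s))
  n <- nchar(s); M <- 5L
  mirrored <- data.frame(start = rev(n - M - h2$start),
                         strand = rev(ifelse(h2$strand == "+", "-", "+")))
  expect_equal(h1$start, mirrored$start)
  expect_equal(h1$strand, mirrored$strand)
})

test_that("clump grouping joins hits whose windows overlap", {
  mk <- function(start, strand) {
    structure(data.frame(start = start, strand = strand,
                         score = numeric(length(start))),
              class = c("hit_list", "data.frame"), M = 5L)
  }
  expect_equal(clump_sizes(mk(integer(0), character(0))), integer(0))
  # same start +/-: one clump of 2; gap of M breaks the clump
  expect_equal(clump_sizes(mk(c(0, 0, 4, 9), c("+", "-", "+", "+"))),
               c(3L, 1L))
})

test_that("distances follow the L1 definitions", {
  p <- c(0.2, 0.5, 0.3)
  expect_equal(distribution_distance(p, p), 0)
  expect_equal(distribution_distance(c(1), c(0, 1)), 2)
  set.seed(91)
  a <- runif(6); a <- a / sum(a)
  b <- runif(9); b <- b / sum(b)
  expect_equal(distribution_distance(a, b),
               sum(abs(c(a, 0, 0, 0) - b)), tolerance = 1e-15)
  # tail distance only counts x at or above the 95th percentile of P
  P <- c(0.5, 0.3, 0.15, 0.04, 0.01)
  Q <- c(0.5, 0.3, 0.15, 0.05, 0.00)
  expect_equal(tail_distance(P, Q), abs(0.04 - 0.05) + 0.01)
  expect_equal(tail_distance(P, P), 0)
})

test_that("empirical count distributions are reproducible and calibrated", {
  thr <- choose_threshold(score_distribution(fix$nonself, uniform_bg, 0.01),
                          1e-3)
  e1 <- empirical_count_distribution(fix$nonself, uniform_bg, thr,
                                     n_seqs = 400, length = 5000,
                                     batches = 20, seed = 17)
  e2 <- empirical_count_distribution(fix$nonself, uniform_bg, thr,
                                     n_seqs = 400, length = 5000,
                                     batches = 20, seed = 17)
  expect_identical(e1$prob, e2$prob)
  expect_true(all(e1$q25 <= e1$q75))
  expect_equal(sum(e1$prob), 1, tolerance = 1e-12)

  m <- expected_hits(thr$attained_alpha, 5000, 5)
  se <- stats::sd(e1$counts) / sqrt(e1$n_samples)
  expect_lt(abs(mean(e1$counts) - m), 3 * se + 1e-9)

  # per-position hit frequency matches alpha'
  phat <- sum(e1$counts) / (2 * 400 * (5000 - 5 + 1))
  se_p <- sqrt(thr$attained_alpha / (2 * 400 * 4996))
  expect_lt(abs(phat - thr$attained_alpha), 3 * se_p * sqrt(2))
})

test_that("the repeat-like fixture is overdispersed in simulation", {
  thr <- choose_threshold(score_distribution(fix$repeatlike, uniform_bg,
                                             0.01), 1e-3)
  e <- empirical_count_distribution(fix$repeatlike, uniform_bg, thr,
                                    n_seqs = 500, length = 5000,
                                    batches = 20, seed = 19)
  a <- thr$attained_alpha
  binom_var <- 2 * a * (5000 - 5 + 1) * (1 - a)
  expect_gt(stats::var(e$counts) / binom_var, 1.2)
})

test_that("empirical palindrome clumps come in pairs", {
  thr <- choose_threshold(score_distribution(fix$palindrome, uniform_bg,
                                             0.01), 1e-3)
  ec <- empirical_clump_distribution(fix$palindrome, uniform_bg, thr,
                                     total_length = 1e6, seed = 23)
  expect_gt(ec$n_clumps, 50)
  odd <- ec$sizes[seq(1, length(ec$sizes), by = 2)]
  expect_equal(sum(odd), 0)
})

test_that("compare_models orders the models as expected (scaled down)", {
  cmp <- compare_models(fix$repeatlike, uniform_bg, alpha = 1e-3,
                        length = 5000, n_seqs = 500, batches = 20,
                        seed = 29)
  tab <- cmp$table
  expect_named(tab, c("model", "distance", "tail_distance"))
  d_new <- tab$distance[tab$model == "compound_poisson_new"]
  expect_lt(d_new, tab$distance[tab$model == "compound_poisson_marginal"])
  expect_lt(d_new, tab$distance[tab$model == "binomial"])
  expect_equal(cmp$delta_new_vs_marginal,
               tab$distance[1] - tab$distance[2])
})
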