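# Independent oracles: exhaustive enumeration over all words, computing
# probabilities and rounded score indices by direct formulas (no reuse of
# the package's DP or conditional tables).

# stationary-start probability of an integer word under bg, by direct
# product of mu and transition lookups
oracle_word_prob <- function(bg, w) {
  d <- bg$order
  if (d == 0L) return(prod(bg$trans[1L, w]))
  p <- bg$stationary[motifclump:::word_to_index(w[seq_len(d)])]
  for (i in seq_along(w)[-seq_len(d)])
    p <- p * bg$trans[motifclump:::word_to_index(w[(i - d):(i - 1L)]), w[i]]
  p
}

# marginal probability of a prefix under mu, by explicit summation
oracle_prefix_prob <- function(bg, w) {
  d <- bg$order
  if (length(w) == 0L) return(1)
  words <- motifclump:::all_words(d)
  keep <- rep(TRUE, nrow(words))
  for (j in seq_along(w)) keep <- keep & words[, j] == w[j]
  sum(bg$stationary[keep])
}

# rounded score index of one window, using the stationary-start scoring
# convention: mu-conditionals (computed by explicit marginal sums) for
# positions <= d, transitions afterwards
oracle_window_index <- function(w, pfm, bg, g) {
  d <- bg$order
  m <- unclass(pfm)
  total <- 0L
  for (j in seq_along(w)) {
    if (j <= d) {
      b <- oracle_prefix_prob(bg, w[seq_len(j)]) /
        oracle_prefix_prob(bg, w[seq_len(j - 1L)])
    } else if (d == 0L) {
      b <- bg$trans[1L, w[j]]
    } else {
      b <- bg$trans[motifclump:::word_to_index(w[(j - d):(j - 1L)]), w[j]]
    }
    total <- total + round((log(m[w[j], j]) - log(b)) / g)
  }
  as.integer(total)
}

# exhaustive score distribution: index -> probability, all 4^M words
oracle_score_dist <- function(pfm, bg, g) {
  M <- ncol(pfm)
  words <- motifclump:::all_words(M)
  idx <- apply(words, 1L, oracle_window_index, pfm = pfm, bg = bg, g = g)
  pw <- apply(words, 1L, oracle_word_prob, bg = bg)
  agg <- tapply(pw, idx, sum)
  list(index = as.integer(names(agg))[order(as.integer(names(agg)))],
       prob = as.numeric(agg[order(as.integer(names(agg)))]))
}

# exhaustive gamma for one shift/orientation: enumerate all 4^(M+k) words
oracle_gamma <- function(pfm, bg, thr, k, orientation) {
  M <- ncol(pfm)
  g <- thr$granularity
  rc <- reverse_complement_pfm(pfm)
  pfmA <- if (orientation == "rf") rc else pfm
  pfmB <- if (orientation == "fr") rc else pfm
  words <- motifclump:::all_words(M + k)
  pw <- apply(words, 1L, oracle_word_prob, bg = bg)
  sA <- apply(words[, seq_len(M), drop = FALSE], 1L,
              oracle_window_index, pfm = pfmA, bg = bg, g = g)
  sB <- apply(words[, k + seq_len(M), drop = FALSE], 1L,
              oracle_window_index, pfm = pfmB, bg = bg, g = g)
  sum(pw[sA >= thr$t_index & sB >= thr$t_index]) / thr$attained_alpha
}

# empirical conditional frequencies of the principal-overlap events from
# forward/reverse hit indicator vectors (TRUE at hit window starts)
oracle_beta_frequencies <- function(Yf, Yr, M) {
  n <- length(Yf)
  tot <- cumsum(Yf + Yr)
  none_between <- function(i, k) {
    # no hit on either strand at positions i+1 .. i+k-1
    if (k <= 1L) return(rep(TRUE, length(i)))
    tot[i + k - 1L] - tot[i] == 0L
  }
  fhits <- which(Yf); rhits <- which(Yr)
  beta <- beta5p <- numeric(M - 1L)
  beta3p <- numeric(M)
  i <- fhits[fhits <= n - 0L]
  beta3p[1L] <- mean(Yr[i])
  for (k in seq_len(M - 1L)) {
    i <- fhits[fhits + k <= n]
    # forward -> forward: no reverse partner at i, nothing in between
    beta[k] <- mean(!Yr[i] & none_between(i, k) & Yf[i + k])
    # forward -> reverse: no reverse at i..i+k-1, no forward at i+1..i+k
    rfree <- vapply(seq_along(i), function(t)
      sum(Yr[i[t]:(i[t] + k - 1L)]) == 0L, logical(1L))
    ffree <- vapply(seq_along(i), function(t)
      sum(Yf[(i[t] + 1L):(i[t] + k)]) == 0L, logical(1L))
    beta3p[k + 1L] <- mean(rfree & ffree & Yr[i + k])
    # reverse -> forward: nothing in between
    ir <- rhits[rhits + k <= n]
    beta5p[k] <- if (length(ir)) mean(none_between(ir, k) & Yf[ir + k]) else 0
  }
  list(beta = beta, beta3p = beta3p, beta5p = beta5p,
       n_f = length(fhits), n_r = length(rhits))
}

# hit indicator vectors for a long integer-encoded sequence
oracle_hit_indicators <- function(v, pfm, bg, thr) {
  g <- thr$granularity
  incF <- motifclump:::score_increments(pfm, bg, g)
  incR <- motifclump:::score_increments(reverse_complement_pfm(pfm), bg, g)
  sf <- motifclump:::.window_scores(v, incF, bg$order)
  sr <- motifclump:::.window_scores(v, incR, bg$order)
  list(Yf = !is.na(sf) & sf >= thr$t_index,
       Yr = !is.na(sr) & sr >= thr$t_index)
}
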