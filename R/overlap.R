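#' Overlapping hit probabilities
#'
#' Given a hit at a reference position, the marginal overlapping hit
#' probability gamma_k is the conditional probability of a second hit k
#' positions downstream, averaging over whatever happens in between.
#' Three strand cases arise on a double-stranded sequence: same strand
#' (gamma_k, shifts 1..M-1), forward hit followed by reverse hit
#' (gamma3'_k, 3'-end overlap, shifts 0..M-1; shift 0 is the palindromic
#' pairing of a forward and reverse hit at the same position) and
#' reverse hit followed by forward hit (gamma5'_k, 5'-end overlap,
#' shifts 1..M-1).
#'
#' The principal overlapping hit probabilities beta exclude intermediate
#' hits: beta_k is the probability of a hit at shift k with no hit at
#' any earlier shift on either strand. Events are ordered
#' Y_1 Y'_1 Y_2 Y'_2 ... (forward before reverse at equal shift), so each
#' event is counted exactly once. beta is approximated from gamma by a
#' renewal-style chain subtraction: from gamma_k, subtract every chain
#' "first principal overlap at shift j, then a marginal overlap from
#' shift j to shift k", including the palindromic pairing at shift 0.
#'
#' @name overlap
NULL

#' Marginal overlapping hit probabilities
#'
#' Computes gamma_k = P(S_0 >= t, S_k >= t) / alpha' from the joint
#' score distribution for every shift and strand case, where alpha' is
#' the attained false-positive level of the threshold.
#'
#' @param pfm a \code{pfm}.
#' @param bg a \code{background_model}.
#' @param thr a \code{score_threshold} with \code{attained_alpha > 0}.
#' @return an \code{overlap_probabilities} object with fields
#'   \code{gamma} (k = 1..M-1), \code{gamma3p} (k = 0..M-1),
#'   \code{gamma5p} (k = 1..M-1), \code{alpha} and \code{M}. The beta
#'   fields are filled in by \code{\link{principal_overlaps}}.
#' @export
marginal_overlaps <- function(pfm, bg, thr) {
  if (thr$attained_alpha <= 0)
    stop("threshold admits no hits (attained alpha is 0)")
  M <- pfm_length(pfm)
  a <- thr$attained_alpha
  tp <- function(k, ori) {
    j <- joint_score_distribution(pfm, bg, k, ori, thr$granularity)
    joint_tail_prob(j, thr$t_index)
  }
  clip01 <- function(x) pmin(1, pmax(0, x))
  gamma <- gamma5p <- numeric(max(M - 1L, 0L))
  gamma3p <- numeric(M)
  for (k in seq_len(M - 1L)) {
    gamma[k] <- tp(k, "ff") / a
    gamma5p[k] <- tp(k, "rf") / a
  }
  for (k in 0:(M - 1L)) gamma3p[k + 1L] <- tp(k, "fr") / a
  structure(list(gamma = clip01(gamma), gamma3p = clip01(gamma3p),
                 gamma5p = clip01(gamma5p), alpha = a, M = M),
            class = "overlap_probabilities")
}

#' Principal overlapping hit probabilities
#'
#' Approximates beta from gamma by chain subtraction, processing shifts
#' in increasing order and, within a shift, forward before reverse.
#' With G(k), G3(k), G5(k) denoting the marginal probabilities (zero
#' outside their index ranges), the recursion is
#' \deqn{beta_k   = G(k) - beta3'_0 G5(k)
#'       - \sum_{j=1}^{k-1} [beta_j G(k-j) + beta3'_j G5(k-j)]}
#' \deqn{beta3'_k = G3(k) - \sum_{j=1}^{k} beta_j G3(k-j)
#'       - \sum_{j=0}^{k-1} beta3'_j G(k-j)}
#' \deqn{beta5'_k = G5(k)
#'       - \sum_{j=1}^{k-1} [beta5'_j G(k-j) + beta_j G5(k-j)]}
#' with beta3'_0 = gamma3'_0 (no intermediate events exist at shift 0).
#' Reverse-to-reverse overlaps equal forward-to-forward ones by the
#' background symmetry, which is why G and beta appear in the reverse
#' chains. Each value is clipped into [0, gamma_k]; the aggregates
#' B = sum(beta), B3 = sum(beta3'), B5 = sum(beta5') are clipped so that
#' B + B3 <= 1 and B + B5 <= 1.
#'
#' @param overlaps an \code{overlap_probabilities} from
#'   \code{\link{marginal_overlaps}}.
#' @return the same object with fields \code{beta}, \code{beta3p},
#'   \code{beta5p}, \code{B}, \code{B3}, \code{B5} added.
#' @export
principal_overlaps <- function(overlaps) {
  M <- overlaps$M
  G  <- function(k) if (k >= 1 && k <= M - 1) overlaps$gamma[k] else 0
  G3 <- function(k) if (k >= 0 && k <= M - 1) overlaps$gamma3p[k + 1L] else 0
  G5 <- function(k) if (k >= 1 && k <= M - 1) overlaps$gamma5p[k] else 0
  beta <- beta5p <- numeric(max(M - 1L, 0L))
  beta3p <- numeric(M)
  beta3p[1L] <- G3(0)
  clipped <- FALSE
  clip <- function(x, up) {
    if (x < -1e-12 || x > up + 1e-12) clipped <<- TRUE
    min(up, max(0, x))
  }
  for (k in seq_len(M - 1L)) {
    s <- beta3p[1L] * G5(k)
    if (k > 1L) for (j in 1:(k - 1L))
      s <- s + beta[j] * G(k - j) + beta3p[j + 1L] * G5(k - j)
    beta[k] <- clip(G(k) - s, G(k))

    s <- 0
    for (j in 1:k) s <- s + beta[j] * G3(k - j)
    for (j in 0:(k - 1L)) s <- s + beta3p[j + 1L] * G(k - j)
    beta3p[k + 1L] <- clip(G3(k) - s, G3(k))

    s <- 0
    if (k > 1L) for (j in 1:(k - 1L))
      s <- s + beta5p[j] * G(k - j) + beta[j] * G5(k - j)
    beta5p[k] <- clip(G5(k) - s, G5(k))
  }
  if (clipped)
    message("principal overlap recursion produced values outside [0, gamma]; ",
            "clipped")
  B <- sum(beta); B3 <- sum(beta3p); B5 <- sum(beta5p)
  if (B + B3 > 1) { B3 <- 1 - B }
  if (B + B5 > 1) { B5 <- 1 - B }
  overlaps$beta <- beta
  overlaps$beta3p <- beta3p
  overlaps$beta5p <- beta5p
  overlaps$B <- B; overlaps$B3 <- B3; overlaps$B5 <- B5
  overlaps
}

#' Overlap structure of a motif at a threshold
#'
#' Convenience wrapper returning the sets of shifts with non-negligible
#' marginal (periods) and principal (principal periods) overlap
#' probability on the same strand.
#'
#' @inheritParams marginal_overlaps
#' @param tol values above \code{tol} count as nonzero; strictly
#'   positive PFMs make every gamma mathematically positive, so
#'   membership is necessarily threshold-relative.
#' @return list with \code{periods}, \code{principal_periods} and the
#'   underlying \code{overlap_probabilities}.
#' @export
overlap_structure <- function(pfm, bg, thr, tol = 1e-9) {
  ov <- principal_overlaps(marginal_overlaps(pfm, bg, thr))
  list(periods = which(ov$gamma > tol),
       principal_periods = which(ov$beta > tol),
       overlaps = ov)
}

#' @export
print.overlap_probabilities <- function(x, ...) {
  cat(sprintf(
    "Overlap probabilities (M = %d, attained alpha = %g)\n", x$M, x$alpha))
  df <- data.frame(k = 0:(x$M - 1L),
                   gamma = c(NA, x$gamma), gamma3p = x$gamma3p,
                   gamma5p = c(NA, x$gamma5p))
  if (!is.null(x$beta)) {
    df$beta <- c(NA, x$beta); df$beta3p <- x$beta3p
    df$beta5p <- c(NA, x$beta5p)
    cat(sprintf("  B = %.4g, B3' = %.4g, B5' = %.4g\n", x$B, x$B3, x$B5))
  }
  print(df, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write an overlap table as TSV
#' @param overlaps an \code{overlap_probabilities} (after
#'   \code{\link{principal_overlaps}}).
#' @param path output path.
#' @export
write_overlaps <- function(overlaps, path) {
  x <- overlaps
  df <- data.frame(k = 0:(x$M - 1L),
                   gamma = c(0, x$gamma), gamma3p = x$gamma3p,
                   gamma5p = c(0, x$gamma5p),
                   beta = c(0, x$beta %||% rep(NA, x$M - 1L)),
                   beta3p = x$beta3p %||% rep(NA, x$M),
                   beta5p = c(0, x$beta5p %||% rep(NA, x$M - 1L)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
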