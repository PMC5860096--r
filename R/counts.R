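#' Hit-count distributions
#'
#' The number of motif hits X on both strands of a sequence of length N
#' is modeled as a compound Poisson variable: a Poisson number of clumps
#' with rate lambda = 2 alpha' (N - M + 1) / E[C], each contributing an
#' i.i.d. clump size with law theta. The probability mass function
#' follows the standard compound-Poisson (Panjer) recursion
#' \deqn{P(X=0) = e^{-lambda}, \quad
#'       P(X=x) = (lambda/x) \sum_{x'<x} (x-x') theta_{x-x'} P(X=x'),}
#' which preserves the mean identity E[X] = lambda E[C] =
#' 2 alpha' (N - M + 1). The binomial reference model treats the
#' 2 (N - M + 1) scan positions as independent Bernoulli trials.
#'
#' @name counts
NULL

new_hit_count_dist <- function(prob, model, params) {
  structure(list(prob = prob, x = seq_along(prob) - 1L, model = model,
                 params = params),
            class = "hit_count_distribution")
}

#' Expected number of hits on both strands
#'
#' @param alpha_attained attained false-positive level alpha'.
#' @param N sequence length.
#' @param M motif length.
#' @return 2 * alpha' * (N - M + 1).
#' @export
expected_hits <- function(alpha_attained, N, M) {
  stopifnot(N >= M)
  2 * alpha_attained * (N - M + 1)
}

#' Compound Poisson hit-count distribution
#'
#' @param clump a \code{clump_size_distribution}.
#' @param alpha_attained attained false-positive level alpha'.
#' @param N sequence length (total scannable length).
#' @param M motif length.
#' @param tail_tol recursion is extended until the cumulative mass
#'   reaches 1 - tail_tol (or the hard maximum 2 (N - M + 1) hits).
#' @return a \code{hit_count_distribution} with model
#'   \code{"compound_poisson"}.
#' @export
compound_poisson_counts <- function(clump, alpha_attained, N, M,
                                    tail_tol = 1e-10) {
  stopifnot(N >= M)
  theta <- clump$theta
  if (!length(theta)) stop("empty clump-size distribution")
  EC <- sum(seq_along(theta) * theta)
  lambda <- expected_hits(alpha_attained, N, M) / EC
  xmax <- 2L * (N - M + 1L)
  p <- numeric(xmax + 1L)
  p[1L] <- exp(-lambda)
  acc <- p[1L]
  cth <- seq_along(theta) * theta
  x <- 0L
  while (acc < 1 - tail_tol && x < xmax) {
    x <- x + 1L
    cs <- seq_len(min(x, length(theta)))
    p[x + 1L] <- (lambda / x) * sum(cth[cs] * p[x - cs + 1L])
    acc <- acc + p[x + 1L]
  }
  new_hit_count_dist(p[seq_len(x + 1L)], "compound_poisson",
                     list(alpha = alpha_attained, N = N, M = M,
                          lambda = lambda, tail_tol = tail_tol))
}

#' Binomial hit-count distribution
#'
#' P(X = x) = C(2(N-M+1), x) alpha'^x (1-alpha')^(2(N-M+1)-x), evaluated
#' on the log scale for numerical stability.
#'
#' @inheritParams expected_hits
#' @return a \code{hit_count_distribution} with model \code{"binomial"}.
#' @export
binomial_counts <- function(alpha_attained, N, M) {
  stopifnot(N >= M)
  n <- 2L * (N - M + 1L)
  x <- 0:n
  if (alpha_attained == 0) {
    p <- c(1, numeric(n))
  } else if (alpha_attained == 1) {
    p <- c(numeric(n), 1)
  } else {
    p <- exp(lchoose(n, x) + x * log(alpha_attained) +
               (n - x) * log1p(-alpha_attained))
  }
  new_hit_count_dist(p, "binomial",
                     list(alpha = alpha_attained, N = N, M = M))
}

#' Enrichment p-value for an observed hit count
#'
#' Returns P(X >= observed) under the model, with any truncated tail
#' mass included as an upper-bound correction.
#'
#' @param dist a \code{hit_count_distribution}.
#' @param observed non-negative integer hit count.
#' @return upper-tail probability.
#' @export
enrichment_pvalue <- function(dist, observed) {
  stopifnot(observed >= 0)
  if (observed == 0) return(1)
  below <- dist$prob[dist$x < observed]
  max(0, 1 - sum(below))
}

#' Mean of a hit-count distribution
#' @param dist a \code{hit_count_distribution}.
#' @export
count_mean <- function(dist) sum(dist$x * dist$prob)

#' @export
print.hit_count_distribution <- function(x, ...) {
  cat(sprintf("Hit-count distribution (%s): mean %.4g over x = 0..%d\n",
              x$model, count_mean(x), max(x$x)))
  invisible(x)
}

#' Write a hit-count distribution as TSV (+ JSON metadata)
#' @param dist a \code{hit_count_distribution}.
#' @param path output TSV path; metadata goes to \code{paste0(path, ".json")}.
#' @export
write_count_distribution <- function(dist, path) {
  write.table(data.frame(x = dist$x, probability = dist$prob),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(list(model = dist$model), dist$params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
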