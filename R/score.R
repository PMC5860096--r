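#' Motif score distributions under the background
#'
#' The motif score of a length-M window is the log-likelihood ratio
#' \eqn{s(w) = \log P_M(w) - \log P_B(w)} between the PFM and the
#' background model, with the background started in its stationary
#' distribution. Its distribution under the background is computed
#' exactly on a discretized grid: per-position score increments are
#' rounded to the nearest multiple of the granularity g and accumulated
#' by a dynamic program over motif positions whose state is the Markov
#' context. Probabilities of a hit (score >= threshold) and all overlap
#' probabilities downstream are defined on this grid.
#'
#' @name score_model
NULL

#' Log-odds score of a single word
#'
#' @param pfm a \code{pfm}.
#' @param bg a \code{background_model}; its order must not exceed the
#'   motif length.
#' @param word DNA string of length \code{ncol(pfm)}.
#' @return the exact (un-discretized) natural-log score.
#' @export
score_word <- function(pfm, bg, word) {
  M <- pfm_length(pfm)
  if (bg$order > M) stop("background order exceeds motif length")
  v <- encode_seq(word)
  if (anyNA(v)) stop("word contains letters outside ACGT")
  if (length(v) != M) stop("word length must equal the motif length")
  sum(log(unclass(pfm)[cbind(v, seq_len(M))])) - word_logprob(bg, word)
}

# Per-position score increment tables.
#
# For motif position j the background factor is the stationary-chain
# conditional: for j <= d the chain factorization of mu into successive
# conditionals (telescopes to exactly mu), for j > d the transition
# probability pi. Increments are rounded to the nearest grid index.
# Returns a list over j with elements ctxlen, inc (4^ctxlen x 4 integer),
# bprob (the background conditional, same shape).
score_increments <- function(pfm, bg, granularity) {
  stopifnot(granularity > 0)
  M <- pfm_length(pfm)
  d <- bg$order
  if (d > M) stop("background order exceeds motif length")
  lapply(seq_len(M), function(j) {
    if (j <= d) {
      bp <- bg$mu_cond[[j]]
    } else {
      bp <- bg$trans
    }
    lp <- matrix(log(unclass(pfm)[, j]), nrow = nrow(bp), ncol = 4L,
                 byrow = TRUE)
    list(ctxlen = if (j <= d) j - 1L else d,
         inc = matrix(as.integer(round((lp - log(bp)) / granularity)),
                      nrow = nrow(bp)),
         bprob = bp)
  })
}

new_score_distribution <- function(index, prob, granularity) {
  keep <- prob > 0
  structure(list(index = index[keep], prob = prob[keep],
                 granularity = granularity),
            class = "score_distribution")
}

#' Exact discretized score distribution
#'
#' Dynamic program over motif positions j = 1..M with state (Markov
#' context, accumulated rounded score index). For positions j <= d the
#' background contribution uses the chain factorization of the
#' stationary distribution, so the total background probability of a
#' word is exactly its stationary-start probability. The result matches
#' brute-force enumeration of all 4^M words under identical rounding.
#'
#' @param pfm a \code{pfm}.
#' @param bg a \code{background_model}.
#' @param granularity grid width g in natural-log score units; scores
#'   are index * g.
#' @return a \code{score_distribution} with fields \code{index}
#'   (ascending integer grid indices), \code{prob} and
#'   \code{granularity}.
#' @export
score_distribution <- function(pfm, bg, granularity = 0.01) {
  incs <- score_increments(pfm, bg, granularity)
  M <- length(incs)
  d <- bg$order
  lo <- sum(vapply(incs, function(z) min(z$inc), 0L))
  hi <- sum(vapply(incs, function(z) max(z$inc), 0L))
  width <- hi - lo + 1L
  P <- matrix(0, nrow = 1L, ncol = width)
  off <- 0L  # accumulated index of column 1 relative to score index 0
  # column of index v is v - off + 1 once off = lo; track running offsets
  cur_lo <- 0L
  P[1L, 1L] <- 1
  for (j in seq_len(M)) {
    z <- incs[[j]]
    nctx_new <- 4^min(j, d)
    newP <- matrix(0, nrow = nctx_new, ncol = width)
    new_lo <- cur_lo + min(z$inc)
    for (ctx in seq_len(nrow(z$inc))) {
      row <- P[ctx, ]
      nz <- which(row > 0)
      if (!length(nz)) next
      for (x in 1:4) {
        ctx2 <- .next_ctx(ctx, x, j, d)
        sh <- z$inc[ctx, x] + cur_lo - new_lo
        newP[ctx2, nz + sh] <- newP[ctx2, nz + sh] + row[nz] * z$bprob[ctx, x]
      }
    }
    P <- newP
    cur_lo <- new_lo
  }
  prob <- colSums(P)
  new_score_distribution(cur_lo + seq_len(width) - 1L, prob, granularity)
}

# Context update when appending letter x at motif/sequence position j:
# contexts grow letter by letter until length d, then slide.
.next_ctx <- function(ctx, x, j, d) {
  if (d == 0L) return(1L)
  if (j < d) return((ctx - 1L) * 4L + x)
  if (j == d) return(if (d == 1L) x else (ctx - 1L) * 4L + x)
  ((ctx - 1L) %% 4^(d - 1L)) * 4L + x
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf(
    "Score distribution: %d atoms, granularity %g, score range [%g, %g]\n",
    length(x$index), x$granularity,
    min(x$index) * x$granularity, max(x$index) * x$granularity))
  invisible(x)
}

#' Score threshold for a nominal false-positive level
#'
#' Returns the smallest grid score t with tail probability
#' \eqn{P(S \ge t) \le \alpha}, together with the attained level
#' \eqn{\alpha' = P(S \ge t)}. All downstream overlap and count formulas
#' use the attained level, because on a discrete grid the nominal level
#' is generally not achievable exactly.
#'
#' @param dist a \code{score_distribution}.
#' @param alpha nominal false-positive level, 0 < alpha <= 1.
#' @return a \code{score_threshold} with fields \code{t_alpha} (grid
#'   score), \code{t_index}, \code{nominal_alpha}, \code{attained_alpha}
#'   and \code{granularity}.
#' @export
choose_threshold <- function(dist, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  tailp <- rev(cumsum(rev(dist$prob)))
  ok <- which(tailp <= alpha + 1e-15)
  if (!length(ok)) {
    warning("alpha smaller than the smallest positive tail atom; ",
            "threshold lies above the maximum support score")
    t_index <- max(dist$index) + 1L
    attained <- 0
  } else {
    i <- ok[1L]
    # any grid score just above the previous atom attains the same tail
    t_index <- if (i == 1L) dist$index[1L] else dist$index[i - 1L] + 1L
    attained <- min(tailp[i], alpha)  # clamp float noise at exact ties
  }
  structure(list(t_alpha = t_index * dist$granularity, t_index = t_index,
                 nominal_alpha = alpha, attained_alpha = attained,
                 granularity = dist$granularity),
            class = "score_threshold")
}

#' @export
print.score_threshold <- function(x, ...) {
  cat(sprintf("Score threshold t = %g (nominal alpha %g, attained %g)\n",
              x$t_alpha, x$nominal_alpha, x$attained_alpha))
  invisible(x)
}

#' Write a score distribution as two-column TSV
#' @param dist a \code{score_distribution}.
#' @param path output path.
#' @export
write_score_distribution <- function(dist, path) {
  write.table(
    data.frame(score = dist$index * dist$granularity, probability = dist$prob),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a score threshold as JSON
#' @param thr a \code{score_threshold}.
#' @param path output path.
#' @export
write_threshold <- function(thr, path) {
  jsonlite::write_json(
    list(t_alpha = thr$t_alpha, nominal_alpha = thr$nominal_alpha,
         attained_alpha = thr$attained_alpha, granularity = thr$granularity),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
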