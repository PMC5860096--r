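#' Two-dimensional score distributions of shifted window pairs
#'
#' Joint distribution of the scores of two motif windows whose starts
#' differ by a shift k, under the background chain started in its
#' stationary distribution. The three orientations mirror the three
#' overlapping-hit scenarios on a double-stranded sequence:
#' \describe{
#'   \item{ff}{both windows scored with the motif (same strand),
#'     1 <= k <= M-1;}
#'   \item{fr}{window 0 with the motif, window k with its reverse
#'     complement (forward hit followed by reverse hit, 3'-end overlap),
#'     0 <= k <= M-1;}
#'   \item{rf}{window 0 with the reverse complement, window k with the
#'     motif (reverse hit followed by forward hit, 5'-end overlap),
#'     1 <= k <= M-1.}
#' }
#' Each window is scored with its own stationary-start convention: the
#' same deterministic function of the letters that
#' \code{\link{score_distribution}} and the sequence scanner use, on the
#' identical rounding grid. The state of the dynamic program is the
#' Markov context plus the pair of accumulated score indices;
#' zero-probability states are pruned at every step.
#'
#' @param pfm a \code{pfm}.
#' @param bg a \code{background_model}.
#' @param shift integer shift k between the two window starts.
#' @param orientation one of "ff", "fr", "rf".
#' @param granularity score grid width g.
#' @return a \code{joint_score_distribution}: a list with
#'   \code{granularity}, \code{shift}, \code{orientation} and
#'   \code{table}, a \code{data.table} with columns \code{ia}, \code{ib}
#'   (grid indices of the two scores) and \code{p}.
#' @export
joint_score_distribution <- function(pfm, bg, shift,
                                     orientation = c("ff", "fr", "rf"),
                                     granularity = 0.01) {
  orientation <- match.arg(orientation)
  M <- pfm_length(pfm)
  d <- bg$order
  k <- as.integer(shift)
  kmin <- if (orientation == "fr") 0L else 1L
  if (k < kmin || k > M - 1L)
    stop("shift out of range for orientation ", orientation)
  rc <- reverse_complement_pfm(pfm)
  pfmA <- if (orientation == "rf") rc else pfm
  pfmB <- if (orientation == "fr") rc else pfm
  incA <- score_increments(pfmA, bg, granularity)
  incB <- score_increments(pfmB, bg, granularity)
  L <- M + k

  dt <- data.table::data.table(ctx = 1L, ia = 0L, ib = 0L, p = 1)
  for (i in seq_len(L)) {
    l <- min(i - 1L, d)
    nctx <- 4^l
    # generative background factor at sequence position i
    bp <- if (i <= d) bg$mu_cond[[i]] else bg$trans
    # per-(context, letter) lookup tables over the full sequence context
    CT <- outer(seq_len(nctx), 1:4, function(c, x)
      mapply(.next_ctx, c, x, MoreArgs = list(j = i, d = d)))
    BP <- bp[seq_len(nctx), , drop = FALSE]
    IA <- matrix(0L, nctx, 4L)
    if (i <= M) {
      zA <- incA[[i]]  # scoring ctxlen equals sequence ctxlen here
      IA <- zA$inc[seq_len(nctx), , drop = FALSE]
    }
    IB <- matrix(0L, nctx, 4L)
    if (i > k) {
      zB <- incB[[i - k]]
      lB <- zB$ctxlen
      projected <- (seq_len(nctx) - 1L) %% 4^lB + 1L  # last lB letters
      IB <- zB$inc[projected, , drop = FALSE]
    }
    pieces <- vector("list", 4L)
    for (x in 1:4) {
      ij <- cbind(dt$ctx, x)
      pieces[[x]] <- data.table::data.table(
        ctx = as.integer(CT[ij]), ia = dt$ia + IA[ij], ib = dt$ib + IB[ij],
        p = dt$p * BP[ij])
    }
    dt <- data.table::rbindlist(pieces)
    dt <- dt[, list(p = sum(p)), by = c("ctx", "ia", "ib")]
    dt <- dt[dt$p > 0]
  }
  tab <- dt[, list(p = sum(p)), by = c("ia", "ib")]
  data.table::setorderv(tab, c("ia", "ib"))
  structure(list(granularity = granularity, shift = k,
                 orientation = orientation, table = tab),
            class = "joint_score_distribution")
}

#' Marginal of a joint score distribution
#'
#' @param joint a \code{joint_score_distribution}.
#' @param which 1 for the window-0 score, 2 for the window-k score.
#' @return a \code{score_distribution}.
#' @export
joint_marginal <- function(joint, which = 1L) {
  v <- if (which == 1L) "ia" else "ib"
  m <- joint$table[, list(p = sum(p)), by = v]
  data.table::setorderv(m, v)
  new_score_distribution(m[[v]], m$p, joint$granularity)
}

# P(S_A >= tA, S_B >= tB) on the grid.
joint_tail_prob <- function(joint, tA_index, tB_index = tA_index) {
  tab <- joint$table
  sum(tab$p[tab$ia >= tA_index & tab$ib >= tB_index])
}

#' @export
print.joint_score_distribution <- function(x, ...) {
  cat(sprintf(
    "Joint score distribution (%s, shift %d): %d atoms, granularity %g\n",
    x$orientation, x$shift, nrow(x$table), x$granularity))
  invisible(x)
}
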