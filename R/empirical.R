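#' Empirical reference distributions and model comparison
#'
#' Simulation harness: sample sequences from the background, scan them
#' on both strands, and summarize hit counts and clump sizes into
#' empirical distributions. These are the reference against which the
#' compound Poisson and binomial models are judged, using the L1
#' discrepancy (twice the conventional total variation distance) on the
#' whole distribution or on its upper 5\% tail.
#'
#' @name empirical
NULL

.pmf_vec <- function(x) {
  if (inherits(x, "hit_count_distribution")) return(x$prob)
  if (inherits(x, "empirical_distribution")) return(x$prob)
  if (is.list(x) && !is.null(x$prob)) return(x$prob)
  as.numeric(x)
}

#' L1 distance between two count distributions
#'
#' \eqn{d(P, Q) = \sum_x |P(x) - Q(x)|}, both distributions read as PMFs
#' over the non-negative integers (shorter supports are zero-padded).
#' Note this is twice the conventional total variation distance.
#'
#' @param P,Q \code{hit_count_distribution}, empirical distribution or
#'   bare PMF vectors indexed from x = 0.
#' @return the distance, in [0, 2].
#' @export
distribution_distance <- function(P, Q) {
  p <- .pmf_vec(P); q <- .pmf_vec(Q)
  n <- max(length(p), length(q))
  sum(abs(c(p, numeric(n - length(p))) - c(q, numeric(n - length(q)))))
}

#' Tail L1 distance on the 5\% significance region
#'
#' Sums |P(x) - Q(x)| only over x at or above the 95th percentile of P
#' (the empirical reference).
#'
#' @inheritParams distribution_distance
#' @param q quantile defining the tail (default 0.95).
#' @return the tail distance.
#' @export
tail_distance <- function(P, Q, q = 0.95) {
  p <- .pmf_vec(P); qq <- .pmf_vec(Q)
  n <- max(length(p), length(qq))
  p <- c(p, numeric(n - length(p))); qq <- c(qq, numeric(n - length(qq)))
  q95 <- which(cumsum(p) >= q)[1L]      # x = q95 - 1
  if (is.na(q95)) q95 <- n
  sum(abs(p[q95:n] - qq[q95:n]))
}

#' Empirical hit-count distribution
#'
#' Samples sequences from the background, counts motif hits on both
#' strands per sequence and returns the pooled PMF together with per-x
#' 25\%/75\% quantiles over batch PMFs (sampling-noise band).
#'
#' @param pfm a \code{pfm}.
#' @param bg a \code{background_model}.
#' @param thr a \code{score_threshold}.
#' @param n_seqs number of sequences; must be divisible by
#'   \code{batches}.
#' @param length length of each sequence.
#' @param batches number of batches for the quantile band.
#' @param seed integer seed.
#' @return an \code{empirical_distribution} with fields \code{x},
#'   \code{prob}, \code{q25}, \code{q75}, \code{counts},
#'   \code{n_samples}, \code{seed}.
#' @export
empirical_count_distribution <- function(pfm, bg, thr, n_seqs = 2000L,
                                         length = 10000L, batches = 20L,
                                         seed = 1L) {
  stopifnot(n_seqs %% batches == 0L)
  g <- thr$granularity
  incF <- score_increments(pfm, bg, g)
  incR <- score_increments(reverse_complement_pfm(pfm), bg, g)
  d <- bg$order
  set.seed(seed)
  counts <- integer(n_seqs)
  chunk <- max(1L, min(n_seqs, floor(2e7 / length)))
  done <- 0L
  while (done < n_seqs) {
    nb <- min(chunk, n_seqs - done)
    v <- cpp_sample_markov(nb, as.integer(length), d, bg$stationary, bg$trans)
    for (i in seq_len(nb)) {
      s <- v[((i - 1L) * length + 1L):(i * length)]
      sf <- .window_scores(s, incF, d)
      sr <- .window_scores(s, incR, d)
      counts[done + i] <- sum(sf >= thr$t_index, na.rm = TRUE) +
        sum(sr >= thr$t_index, na.rm = TRUE)
    }
    done <- done + nb
  }
  xmax <- max(counts)
  pooled <- tabulate(counts + 1L, nbins = xmax + 1L) / n_seqs
  bm <- matrix(counts, ncol = batches)
  bp <- apply(bm, 2L, function(cc) tabulate(cc + 1L, nbins = xmax + 1L) /
                nrow(bm))
  qs <- apply(bp, 1L, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  structure(list(x = 0:xmax, prob = pooled, q25 = qs[1L, ], q75 = qs[2L, ],
                 counts = counts, n_samples = n_seqs, seed = seed),
            class = "empirical_distribution")
}

#' @export
print.empirical_distribution <- function(x, ...) {
  cat(sprintf(
    "Empirical hit-count distribution: %d sequences, mean %.4g hits\n",
    x$n_samples, sum(x$x * x$prob)))
  invisible(x)
}

#' Group hits into clumps
#'
#' Two consecutive hits in (start, strand) order belong to the same
#' clump if their window starts differ by at most M - 1 (their windows
#' overlap); a forward and a reverse hit at the same start form one
#' clump of size 2.
#'
#' @param hits a \code{hit_list}.
#' @return integer vector of clump sizes in sequence order.
#' @export
clump_sizes <- function(hits) {
  M <- attr(hits, "M")
  if (nrow(hits) == 0L) return(integer(0))
  brk <- c(TRUE, diff(hits$start) > M - 1L)
  as.integer(table(cumsum(brk)))
}

#' Empirical clump-size distribution
#'
#' Samples one long sequence from the background, scans both strands,
#' groups hits into clumps and returns the clump-size PMF.
#'
#' @inheritParams empirical_count_distribution
#' @param total_length length of the sampled sequence.
#' @return list with \code{sizes} (PMF over clump sizes 1..cmax),
#'   \code{n_clumps} and \code{seed}.
#' @export
empirical_clump_distribution <- function(pfm, bg, thr, total_length = 1e7,
                                         seed = 1L) {
  M <- pfm_length(pfm)
  stopifnot(total_length >= 10 * M)
  set.seed(seed)
  v <- cpp_sample_markov(1L, as.integer(total_length), bg$order,
                         bg$stationary, bg$trans)
  g <- thr$granularity
  incF <- score_increments(pfm, bg, g)
  incR <- score_increments(reverse_complement_pfm(pfm), bg, g)
  hits <- .scan_encoded(v, incF, incR, bg$order, thr$t_index, g,
                        attr(pfm, "name") %||% "motif")
  cs <- clump_sizes(hits)
  if (!length(cs)) {
    warning("no hits found; empty clump-size distribution")
    return(list(sizes = numeric(0), n_clumps = 0L, seed = seed))
  }
  list(sizes = tabulate(cs) / length(cs), n_clumps = length(cs), seed = seed)
}

#' Compare analytic hit-count models to the empirical reference
#'
#' Runs the full pipeline at a given nominal alpha: exact score
#' distribution and threshold, overlap probabilities, clump-size
#' distributions in principal and marginal mode, the two compound
#' Poisson models and the binomial model, and an empirical reference
#' from simulation. Reports the L1 and 5\%-tail distances of each model
#' to the reference and the pairwise differences of the new model
#' against the other two.
#'
#' @param pfm a \code{pfm}.
#' @param bg a \code{background_model}.
#' @param alpha nominal false-positive level.
#' @param length sequence length N.
#' @param n_seqs number of simulated sequences.
#' @param batches batches for the empirical quantile band.
#' @param seed integer seed.
#' @param granularity score grid width.
#' @return a \code{model_comparison}: list with the distributions, a
#'   results table (model, distance, tail_distance) and the deltas
#'   \code{delta_new_vs_marginal}, \code{delta_new_vs_binomial}.
#' @export
compare_models <- function(pfm, bg, alpha = 1e-3, length = 10000L,
                           n_seqs = 2000L, batches = 20L, seed = 1L,
                           granularity = 0.01) {
  M <- pfm_length(pfm)
  sd_ <- score_distribution(pfm, bg, granularity)
  thr <- choose_threshold(sd_, alpha)
  ov <- principal_overlaps(marginal_overlaps(pfm, bg, thr))
  a <- thr$attained_alpha
  cp_new <- compound_poisson_counts(
    clump_distribution(ov, "double", "principal"), a, length, M)
  cp_marg <- compound_poisson_counts(
    clump_distribution(ov, "double", "marginal"), a, length, M)
  bin <- binomial_counts(a, length, M)
  emp <- empirical_count_distribution(pfm, bg, thr, n_seqs, length,
                                      batches, seed)
  models <- list(compound_poisson_new = cp_new,
                 compound_poisson_marginal = cp_marg,
                 binomial = bin)
  tab <- data.frame(
    model = names(models),
    distance = vapply(models, function(m) distribution_distance(emp, m), 0),
    tail_distance = vapply(models, function(m) tail_distance(emp, m), 0),
    row.names = NULL)
  structure(list(
    empirical = emp, models = models, threshold = thr, overlaps = ov,
    table = tab,
    delta_new_vs_marginal = tab$distance[1L] - tab$distance[2L],
    delta_new_vs_binomial = tab$distance[1L] - tab$distance[3L]),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (attained alpha = %g)\n",
              x$threshold$attained_alpha))
  print(x$table, digits = 4, row.names = FALSE)
  cat(sprintf("delta(new - marginal) = %.4g; delta(new - binomial) = %.4g\n",
              x$delta_new_vs_marginal, x$delta_new_vs_binomial))
  invisible(x)
}

#' Write a model-comparison table as TSV
#' @param comparison a \code{model_comparison}.
#' @param path output path.
#' @export
write_comparison <- function(comparison, path) {
  write.table(comparison$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
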