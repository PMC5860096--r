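#' Clump-size distributions
#'
#' A clump is a maximal run of mutually overlapping motif hits; theta_c
#' is the probability that a clump contains exactly c hits. On a single
#' strand the clump size is geometric in the aggregate principal overlap
#' probability B. On both strands, clumps are tracked by the strand of
#' their last hit: a forward-ending clump is extended by a same-strand
#' overlap (rate B) or by a forward-to-reverse overlap (rate B3'), a
#' reverse-ending clump by a reverse-to-reverse overlap (B again, by
#' strand symmetry) or a reverse-to-forward overlap (B5'). A clump ends
#' on a forward hit with probability 1 - B - B3' and on a reverse hit
#' with probability 1 - B - B5'. A clump starts with a forward hit, or
#' with a reverse hit not paired to a forward hit at the same position:
#' start weights proportional to (1, 1 - pair0), where pair0 is the
#' palindromic pairing probability at shift 0. For palindromic motifs
#' pair0 = 1, which forces every forward hit to be followed by its
#' reverse partner and places all mass on even clump sizes.
#'
#' In \code{overlap_mode = "marginal"} the aggregated marginal overlap
#' probabilities take the place of B, B3', B5' throughout; this serves
#' as the surrogate for the earlier, redundancy-prone model.
#'
#' @name clump
NULL

new_clump_dist <- function(theta, mode, overlap_mode, params) {
  theta <- theta / sum(theta)
  structure(list(theta = theta, cmax = length(theta), mode = mode,
                 overlap_mode = overlap_mode, params = params),
            class = "clump_size_distribution")
}

#' Single-strand clump-size distribution
#'
#' Geometric: theta_c proportional to (1 - B) B^(c-1), truncated when
#' the remaining tail mass drops below \code{cmax_tol} and renormalized.
#'
#' @param B aggregate principal overlap probability, 0 <= B < 1.
#' @param cmax_tol truncation tolerance for the tail mass.
#' @param overlap_mode label recorded in the result ("principal" when B
#'   aggregates beta, "marginal" when it aggregates gamma).
#' @return a \code{clump_size_distribution}.
#' @export
clump_single <- function(B, cmax_tol = 1e-10, overlap_mode = "principal") {
  if (B >= 1) stop("overlap mass >= 1")
  if (B < 0) stop("negative overlap mass")
  cmax <- if (B == 0) 1L else min(1000L, max(1L, ceiling(log(cmax_tol) / log(B))))
  theta <- (1 - B) * B^(seq_len(cmax) - 1L)
  new_clump_dist(theta, "single", overlap_mode, list(B = B))
}

#' Double-strand clump-size distribution
#'
#' Two-channel recursion over the strand of the last hit, with clump
#' start weights (1, 1 - pair0) and end factors (1 - B - B3, 1 - B - B5)
#' as described in \link{clump}. Truncated when the remaining mass drops
#' below \code{cmax_tol} (hard cap 1000) and renormalized.
#'
#' @param B,B3,B5 aggregate overlap probabilities (principal, or
#'   marginal in marginal mode); B + B3 <= 1 and B + B5 <= 1 after
#'   upstream clipping.
#' @param pair0 probability that a hit is palindromically paired with a
#'   hit on the other strand at the same position (beta3'_0, or
#'   gamma3'_0 in marginal mode).
#' @param overlap_mode label, "principal" or "marginal".
#' @param cmax_tol truncation tolerance.
#' @return a \code{clump_size_distribution}.
#' @export
clump_double <- function(B, B3, B5, pair0 = 0,
                         overlap_mode = c("principal", "marginal"),
                         cmax_tol = 1e-10) {
  overlap_mode <- match.arg(overlap_mode)
  stopifnot(B >= 0, B3 >= 0, B5 >= 0, pair0 >= 0, pair0 <= 1)
  if (B + B3 > 1 + 1e-9 || B + B5 > 1 + 1e-9)
    stop("overlap aggregates exceed 1; clip upstream")
  ef <- 1 - B - B3
  er <- 1 - B - B5
  if (ef < 0) {
    warning("degenerate palindrome: 1 - B - B3 < 0 clipped to 0")
    ef <- 0
  }
  if (er < 0) {
    warning("degenerate palindrome: 1 - B - B5 < 0 clipped to 0")
    er <- 0
  }
  v <- c(1, 1 - pair0)   # start weights (forward-first, reverse-only-first)
  theta <- numeric(0)
  for (cc in seq_len(1000L)) {
    theta[cc] <- v[1L] * ef + v[2L] * er
    v <- c(B * v[1L] + B5 * v[2L], B3 * v[1L] + B * v[2L])
    if (sum(v) < cmax_tol * max(sum(theta), cmax_tol)) break
  }
  if (sum(theta) <= 0) stop("clump-size distribution degenerated to zero mass")
  new_clump_dist(theta, "double", overlap_mode,
                 list(B = B, B3 = B3, B5 = B5, pair0 = pair0))
}

#' Clump-size distribution from overlap probabilities
#'
#' Dispatches to \code{\link{clump_single}} or \code{\link{clump_double}}
#' with either the principal (beta) or marginal (gamma) aggregates of an
#' \code{overlap_probabilities} object.
#'
#' @param overlaps an \code{overlap_probabilities}; for principal mode it
#'   must have been through \code{\link{principal_overlaps}}.
#' @param mode "double" (both strands) or "single".
#' @param overlap_mode "principal" (the refined model) or "marginal"
#'   (the previous-model surrogate).
#' @param cmax_tol truncation tolerance.
#' @return a \code{clump_size_distribution}.
#' @export
clump_distribution <- function(overlaps, mode = c("double", "single"),
                               overlap_mode = c("principal", "marginal"),
                               cmax_tol = 1e-10) {
  mode <- match.arg(mode)
  overlap_mode <- match.arg(overlap_mode)
  if (overlap_mode == "principal") {
    if (is.null(overlaps$beta)) overlaps <- principal_overlaps(overlaps)
    B <- overlaps$B; B3 <- overlaps$B3; B5 <- overlaps$B5
    pair0 <- overlaps$beta3p[1L]
  } else {
    B <- min(sum(overlaps$gamma), 1)
    B3 <- min(sum(overlaps$gamma3p), max(0, 1 - B))
    B5 <- min(sum(overlaps$gamma5p), max(0, 1 - B))
    pair0 <- overlaps$gamma3p[1L]
  }
  if (mode == "single") clump_single(B, cmax_tol, overlap_mode)
  else clump_double(B, B3, B5, pair0, overlap_mode, cmax_tol)
}

#' Expected clump size
#' @param clump a \code{clump_size_distribution}.
#' @return E[C] = sum over c of c * theta_c.
#' @export
expected_clump_size <- function(clump) {
  sum(seq_along(clump$theta) * clump$theta)
}

#' @export
print.clump_size_distribution <- function(x, ...) {
  cat(sprintf("Clump-size distribution (%s strand, %s overlaps): E[C] = %.4g\n",
              x$mode, x$overlap_mode, expected_clump_size(x)))
  show <- head(x$theta, 8L)
  names(show) <- seq_along(show)
  print(round(show, 5))
  invisible(x)
}

#' Write a clump-size distribution as TSV (+ JSON metadata)
#' @param clump a \code{clump_size_distribution}.
#' @param path output TSV path; metadata goes to \code{paste0(path, ".json")}.
#' @export
write_clump_distribution <- function(clump, path) {
  write.table(data.frame(c = seq_along(clump$theta), theta = clump$theta),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(list(mode = clump$mode, overlap_mode = clump$overlap_mode,
           cmax = clump$cmax), clump$params),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
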