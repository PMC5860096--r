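# Vectorized window scoring on the discretized grid.
#
# The scanner uses the identical per-position rounded increments as the
# score-distribution DP, so "score >= threshold" agrees exactly between
# the analytic distribution and scanned sequences.

# Context codes of length l ending just before each position:
# A[i] encodes v[i-l..i-1]; NA where letters are missing or non-ACGT.
.ctx_codes <- function(v, l) {
  n <- length(v)
  if (l == 0L) return(rep(1L, n + 1L))
  a <- rep(NA_integer_, n + 1L)
  idx <- rep(0, n + 1L - l)
  for (u in seq_len(l)) {
    # letter at offset u within the context window i-l..i-1
    idx <- idx + (v[seq_len(n + 1L - l) + (u - 1L)] - 1L) * 4^(l - u)
  }
  a[(l + 1L):(n + 1L)] <- as.integer(idx) + 1L
  a
}

# Summed rounded score index of every window; NA for masked windows.
.window_scores <- function(v, incs, d) {
  M <- length(incs)
  n <- length(v)
  if (n < M) return(integer(0))
  nwin <- n - M + 1L
  ctx <- lapply(0:d, function(l) .ctx_codes(v, l))
  total <- rep(0L, nwin)
  for (j in seq_len(M)) {
    z <- incs[[j]]
    l <- z$ctxlen
    pos <- seq_len(nwin) + (j - 1L)
    total <- total + z$inc[ctx[[l + 1L]][pos] + (v[pos] - 1L) * 4^l]
  }
  total
}

#' Scan a sequence for motif hits on both strands
#'
#' Position i (0-based) is a forward hit if the window score index is at
#' least the threshold index; reverse hits are found by scoring the same
#' forward-coordinate windows with the reverse-complement PFM. Windows
#' containing non-ACGT letters are skipped.
#'
#' @param pfm a \code{pfm}.
#' @param bg a \code{background_model}.
#' @param thr a \code{score_threshold}.
#' @param sequence DNA string.
#' @return a data.frame of class \code{hit_list} with columns
#'   \code{start} (0-based window start), \code{strand} ("+"/"-") and
#'   \code{score} (grid score), sorted by (start, strand) with "+"
#'   before "-" at equal start.
#' @export
scan_sequence <- function(pfm, bg, thr, sequence) {
  v <- if (is.integer(sequence)) sequence else encode_seq(sequence)
  g <- thr$granularity
  incF <- score_increments(pfm, bg, g)
  incR <- score_increments(reverse_complement_pfm(pfm), bg, g)
  .scan_encoded(v, incF, incR, bg$order, thr$t_index, g,
                attr(pfm, "name") %||% "motif")
}

.scan_encoded <- function(v, incF, incR, d, t_index, granularity, name) {
  sf <- .window_scores(v, incF, d)
  sr <- .window_scores(v, incR, d)
  hf <- which(!is.na(sf) & sf >= t_index)
  hr <- which(!is.na(sr) & sr >= t_index)
  df <- data.frame(
    start = c(hf, hr) - 1L,
    strand = rep(c("+", "-"), c(length(hf), length(hr))),
    score = c(sf[hf], sr[hr]) * granularity)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("hit_list", "data.frame"),
            M = length(incF), motif = name)
}

#' Write motif hits as BED6
#'
#' Coordinates are 0-based, half-open windows of the motif length;
#' reverse-strand hits are reported at their forward-strand window
#' start.
#'
#' @param hits a \code{hit_list}.
#' @param path output path.
#' @param chrom record name placed in the first column.
#' @export
write_bed <- function(hits, path, chrom = "seq") {
  M <- attr(hits, "M")
  df <- data.frame(chrom = chrom, start = hits$start,
                   end = hits$start + M,
                   name = attr(hits, "motif") %||% "motif",
                   score = hits$score, strand = hits$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
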