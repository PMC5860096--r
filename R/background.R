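#' Order-d Markov background models of unbound DNA
#'
#' A background model holds the transition probabilities \eqn{\pi} of a
#' homogeneous order-d Markov chain over {A,C,G,T} together with its
#' stationary distribution \eqn{\mu}, under the strand/reversal symmetry
#' constraint: every word of length d+1 has the same stationary
#' probability as its reverse complement and as its reversal. The
#' symmetry is what makes both-strand motif scanning consistent, because
#' a match on the reverse strand is then exactly as likely as the
#' corresponding forward-strand match.
#'
#' @name background
NULL

new_background <- function(order, trans, stationary, pseudocount) {
  d <- as.integer(order)
  trans <- matrix(as.numeric(trans), nrow = 4^d, ncol = 4L)
  stationary <- as.numeric(stationary)
  if (d == 0L) stationary <- as.numeric(trans)
  stopifnot(length(stationary) == if (d == 0L) 4L else 4^d)
  bg <- structure(
    list(order = d, trans = trans, stationary = stationary,
         pseudocount = pseudocount),
    class = "background_model"
  )
  bg$log_trans <- log(trans)
  bg$mu_cond <- .mu_conditionals(bg)
  .validate_background(bg)
  bg
}

# Chain factorization of mu into positionwise conditionals:
# mu_cond[[j]] is a 4^(j-1) x 4 matrix with P(letter | first j-1 letters)
# under the marginals of mu. The product over j = 1..d telescopes to mu.
.mu_conditionals <- function(bg) {
  d <- bg$order
  if (d == 0L) return(list())
  pref <- vector("list", d + 1L)       # pref[[l+1]]: marginal over first l letters
  pref[[d + 1L]] <- bg$stationary
  for (l in d:1) {
    # big-endian indexing: dropping the last (least significant) letter
    # groups blocks of 4 consecutive indices
    pref[[l]] <- rowSums(matrix(pref[[l + 1L]], ncol = 4L, byrow = TRUE))
  }
  lapply(seq_len(d), function(j) {
    matrix(pref[[j + 1L]], ncol = 4L, byrow = TRUE) / pref[[j]]
  })
}

.validate_background <- function(bg) {
  d <- bg$order
  if (any(abs(rowSums(bg$trans) - 1) > 1e-12))
    stop("transition rows do not sum to 1")
  if (abs(sum(bg$stationary) - 1) > 1e-12 * 4^max(d, 1L))
    stop("stationary distribution does not sum to 1")
  # stationarity: mu must be a left fixed point of the context chain
  mu2 <- .advance_stationary(bg)
  if (max(abs(mu2 - bg$stationary)) > 1e-8)
    stop("internal consistency error: stationary distribution is not a ",
         "fixed point of the transition probabilities")
  # strand/reversal symmetry of stationary (d+1)-word probabilities
  p <- .word_probs_d1(bg)
  for (op in c("reverse", "complement", "revcomp")) {
    if (max(abs(p - p[index_permutation(d + 1L, op)])) > 1e-12)
      stop("internal consistency error: stationary word probabilities are ",
           "not ", op, "-symmetric")
  }
  invisible(bg)
}

# One step of the stationary distribution under the context chain.
.advance_stationary <- function(bg) {
  d <- bg$order
  if (d == 0L) return(as.numeric(bg$trans))
  p <- .word_probs_d1(bg)                      # over (d+1)-words
  # suffix marginal: sum over the first (most significant) letter
  colSums(matrix(p, nrow = 4L, byrow = TRUE))
}

# Stationary probabilities of all (d+1)-words: mu(prefix) * pi(prefix; x).
.word_probs_d1 <- function(bg) {
  d <- bg$order
  if (d == 0L) return(as.numeric(bg$trans))
  as.numeric(t(bg$trans * bg$stationary))      # big-endian order
}

#' Estimate a symmetric order-d Markov background model
#'
#' Tallies (d+1)-mer counts over the input sequences, symmetrizes them by
#' averaging over the closure \{identity, reverse, complement, reverse
#' complement\}, adds a pseudocount to every (d+1)-mer, and derives the
#' transition probabilities by row normalization and the stationary
#' distribution from the symmetrized d-mer marginals. Counting is done
#' circularly within each contiguous run of A/C/G/T letters so that
#' prefix and suffix marginals of the count table coincide, which makes
#' the stationary distribution an exact fixed point of the transitions.
#' Windows containing non-ACGT letters are skipped.
#'
#' @param sequences character vector of DNA sequences (case-insensitive;
#'   letters outside ACGT are treated as masked).
#' @param order non-negative integer, the Markov order d.
#' @param pseudocount non-negative real added to every symmetrized
#'   (d+1)-mer count. The default 1 guarantees strictly positive
#'   transition probabilities, which the log-odds score requires.
#' @return an object of class \code{background_model} with elements
#'   \code{order}, \code{trans} (4^d x 4 matrix of \eqn{\pi}),
#'   \code{stationary} (\eqn{\mu}; for d = 0 equal to \eqn{\pi}) and
#'   \code{pseudocount}.
#' @examples
#' bg <- estimate_background("ACGTACGTACGT", order = 0)
#' bg$stationary
#' @export
estimate_background <- function(sequences, order = 1L, pseudocount = 1) {
  d <- as.integer(order)
  stopifnot(d >= 0L, pseudocount >= 0)
  if (inherits(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  stopifnot(is.character(sequences), length(sequences) >= 1L)

  counts <- numeric(4^(d + 1L))
  for (s in sequences) {
    v <- encode_seq(s)
    # contiguous clean segments of length >= d+1, counted circularly
    ok <- !is.na(v)
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths >= d + 1L)) {
      seg <- v[starts[i]:ends[i]]
      L <- length(seg)
      ext <- if (d > 0L) c(seg, seg[seq_len(d)]) else seg
      idx <- 0
      for (t in 0:d) idx <- idx * 4 + (ext[seq_len(L) + t] - 1L)
      counts <- counts + tabulate(as.integer(idx) + 1L, nbins = 4^(d + 1L))
    }
  }
  if (sum(counts) == 0)
    stop("insufficient data: no window of length ", d + 1L,
         " free of non-ACGT letters")

  k <- counts
  for (op in c("reverse", "complement", "revcomp"))
    k <- k + counts[index_permutation(d + 1L, op)]
  k <- k / 4 + pseudocount
  if (any(k == 0))
    stop("zero-probability transition: a symmetrized (d+1)-mer count is 0 ",
         "and pseudocount is 0; the score definition requires strictly ",
         "positive background probabilities")

  km <- matrix(k, nrow = 4^d, ncol = 4L, byrow = TRUE)  # rows = contexts
  trans <- km / rowSums(km)
  stationary <- if (d == 0L) as.numeric(trans) else rowSums(km) / sum(km)
  new_background(d, trans, stationary, pseudocount)
}

#' Log-probability of a DNA word under the background
#'
#' Returns \eqn{\log \mu(w_1..w_d) + \sum_{i>d} \log \pi(w_{i-d}..w_{i-1};
#' w_i)} in natural log units, i.e. the probability of the word for a
#' chain started in the stationary distribution.
#'
#' @param bg a \code{background_model}.
#' @param word DNA string of length >= d, letters in ACGT.
#' @return the natural-log probability.
#' @export
word_logprob <- function(bg, word) {
  v <- encode_seq(word)
  if (anyNA(v)) stop("word contains letters outside ACGT")
  d <- bg$order
  if (length(v) < d) stop("word shorter than the background order")
  if (d == 0L) return(sum(bg$log_trans[1L, v]))
  lp <- log(bg$stationary[word_to_index(v[seq_len(d)])])
  if (length(v) > d) {
    for (i in (d + 1L):length(v)) {
      ctx <- word_to_index(v[(i - d):(i - 1L)])
      lp <- lp + bg$log_trans[ctx, v[i]]
    }
  }
  lp
}

#' Sample random DNA sequences from a background model
#'
#' Draws the first d letters from the stationary distribution and extends
#' with the transition probabilities. Uses R's RNG, so results are
#' reproducible under \code{set.seed} or via the \code{seed} argument.
#'
#' @param bg a \code{background_model}.
#' @param count number of sequences.
#' @param length length of each sequence; must be >= max(d, 1).
#' @param seed optional integer seed applied before sampling.
#' @return character vector of \code{count} DNA strings.
#' @export
sample_sequences <- function(bg, count, length, seed = NULL) {
  stopifnot(count >= 1L)
  if (length < max(bg$order, 1L))
    stop("length must be at least max(order, 1)")
  if (!is.null(seed)) set.seed(seed)
  v <- cpp_sample_markov(as.integer(count), as.integer(length), bg$order,
                         bg$stationary, bg$trans)
  vapply(seq_len(count),
         function(i) decode_seq(v[((i - 1L) * length + 1L):(i * length)]),
         character(1L))
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("Order-%d Markov background model (pseudocount %g)\n",
              x$order, x$pseudocount))
  if (x$order == 0L) {
    p <- as.numeric(x$trans); names(p) <- .dna
    print(round(p, 4))
  } else {
    cat(sprintf("  %d contexts; stationary distribution over %d-mers\n",
                4^x$order, x$order))
  }
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper around \code{Biostrings::readDNAStringSet} returning a
#' plain named character vector.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Serialize a background model to JSON
#'
#' The JSON object holds \code{order}, \code{pseudocount} and flat tables
#' of \eqn{\pi} (keyed by (d+1)-words) and \eqn{\mu} (keyed by d-words;
#' for d = 0 keyed by single letters).
#'
#' @param bg a \code{background_model}.
#' @param path output file path.
#' @export
write_background <- function(bg, path) {
  d <- bg$order
  w1 <- apply(all_words(d + 1L), 1L, decode_seq)
  pi_tab <- as.numeric(t(bg$trans))
  names(pi_tab) <- w1
  if (d == 0L) {
    mu_tab <- bg$stationary
    names(mu_tab) <- .dna
  } else {
    mu_tab <- bg$stationary
    names(mu_tab) <- apply(all_words(d), 1L, decode_seq)
  }
  jsonlite::write_json(
    list(order = d, pseudocount = bg$pseudocount,
         pi = as.list(pi_tab), mu = as.list(mu_tab)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a background model from JSON
#'
#' @param path path written by \code{\link{write_background}}.
#' @return a \code{background_model}.
#' @export
read_background <- function(path) {
  x <- jsonlite::read_json(path)
  d <- as.integer(x$order)
  w1 <- apply(all_words(d + 1L), 1L, decode_seq)
  pi_flat <- unlist(x$pi)[w1]
  trans <- matrix(pi_flat, nrow = 4^d, ncol = 4L, byrow = TRUE)
  if (d == 0L) {
    stationary <- as.numeric(trans)
  } else {
    wmu <- apply(all_words(d), 1L, decode_seq)
    stationary <- as.numeric(unlist(x$mu)[wmu])
  }
  new_background(d, trans, stationary, as.numeric(x$pseudocount))
}
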