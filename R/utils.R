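# Internal helpers: DNA encoding and word-index arithmetic.
#
# Letters are encoded A=1, C=2, G=3, T=4; anything else becomes NA.
# Words of length L are encoded as 1 + sum_i (l_i - 1) * 4^(L - i),
# i.e. base-4 with the first letter most significant.

.char_lut <- local({
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut
})

encode_seq <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  codes <- utf8ToInt(x)
  codes[codes > 127L | codes < 1L] <- 1L
  .char_lut[codes]
}

decode_seq <- function(v) {
  intToUtf8(c(65L, 67L, 71L, 84L)[v])
}

complement_int <- function(v) 5L - v

# All words of length L as an integer matrix (4^L rows, L columns),
# row r encodes the word with index r.
all_words <- function(L) {
  if (L == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  idx <- 0:(4^L - 1)
  m <- matrix(0L, nrow = 4^L, ncol = L)
  for (j in L:1) {
    m[, j] <- as.integer(idx %% 4L) + 1L
    idx <- idx %/% 4L
  }
  m
}

# Index of each row-word of an integer matrix.
word_index <- function(m) {
  if (ncol(m) == 0L) return(rep(1L, nrow(m)))
  idx <- 0
  for (j in seq_len(ncol(m))) idx <- idx * 4 + (m[, j] - 1L)
  as.integer(idx) + 1L
}

word_to_index <- function(v) {
  if (length(v) == 0L) return(1L)
  as.integer(sum((v - 1L) * 4^(rev(seq_along(v)) - 1L))) + 1L
}

index_to_word <- function(i, L) {
  if (L == 0L) return(integer(0))
  i <- i - 1L
  out <- integer(L)
  for (j in L:1) {
    out[j] <- (i %% 4L) + 1L
    i <- i %/% 4L
  }
  out
}

# Permutations of word indices of length L under reversal, complementation
# and reverse complementation: perm[i] is the index of op(word_i).
index_permutation <- function(L, op = c("reverse", "complement", "revcomp")) {
  op <- match.arg(op)
  w <- all_words(L)
  w <- switch(op,
    reverse    = w[, rev(seq_len(ncol(w))), drop = FALSE],
    complement = 5L - w,
    revcomp    = (5L - w)[, rev(seq_len(ncol(w))), drop = FALSE]
  )
  word_index(w)
}

reverse_complement <- function(word) {
  decode_seq(rev(complement_int(encode_seq(word))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
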