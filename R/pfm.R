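#' Position frequency matrices
#'
#' A PFM is a 4 x M column-stochastic matrix with strictly positive
#' entries giving per-position nucleotide probabilities of a motif.
#' Rows are in A, C, G, T order.
#'
#' @name pfm
NULL

new_pfm <- function(m, name = "motif") {
  m <- as.matrix(m)
  if (nrow(m) != 4L) stop("a PFM must have 4 rows (A, C, G, T)")
  if (!is.numeric(m)) stop("non-numeric PFM entries")
  if (any(m <= 0)) stop("all PFM entries must be strictly positive")
  if (any(abs(colSums(m) - 1) > 1e-9)) stop("PFM columns must sum to 1")
  rownames(m) <- .dna
  structure(m, name = name, class = c("pfm", "matrix"))
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM '%s' (%d positions)\n", attr(x, "name"), ncol(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

pfm_length <- function(pfm) ncol(pfm)

#' Read a PFM from a motif file
#'
#' Supports JASPAR count matrices (bare 4-row matrices or the
#' ">header" + "A [ ... ]" bracket style), TRANSFAC matrix blocks (the
#' column order is taken from the P0/PO header line) and plain TSV
#' (4 rows x M columns, optional header line and optional leading
#' letter column). Counts are converted to probabilities per column
#' after adding \code{pseudocount} to every cell.
#'
#' @param path motif file.
#' @param format one of "jaspar", "transfac", "tsv".
#' @param pseudocount non-negative real added to every cell.
#' @param name motif name; defaults to a name found in the file, else
#'   the file name.
#' @return a \code{pfm} object.
#' @export
read_pfm <- function(path, format = c("jaspar", "transfac", "tsv"),
                     pseudocount = 1, name = NULL) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  parsed <- switch(format,
    jaspar   = .parse_jaspar(lines),
    transfac = .parse_transfac(lines),
    tsv      = .parse_tsv(lines)
  )
  counts <- parsed$counts
  if (any(is.na(counts))) stop("non-numeric cell in motif file")
  counts <- counts + pseudocount
  tot <- colSums(counts)
  if (any(tot == 0)) stop("zero column total in motif file")
  new_pfm(sweep(counts, 2L, tot, "/"),
          name = name %||% parsed$name %||% basename(path))
}

.parse_jaspar <- function(lines) {
  lines <- trimws(lines)
  name <- NULL
  hdr <- grepl("^>", lines)
  if (any(hdr)) name <- sub("^>\\s*", "", lines[which(hdr)[1L]])
  lines <- lines[!hdr & nzchar(lines)]
  if (length(lines) != 4L) stop("wrong row count: expected 4 matrix rows")
  rows <- lapply(lines, function(l) {
    l <- sub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("\\[|\\]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("ragged matrix rows in JASPAR file")
  list(counts = do.call(rbind, rows), name = name)
}

.parse_transfac <- function(lines) {
  lines <- trimws(lines)
  name <- NULL
  id <- grep("^(ID|NA|AC)\\s+", lines, value = TRUE)
  if (length(id)) name <- sub("^\\S+\\s+", "", id[1L])
  p0 <- grep("^P[0O]\\b", lines)
  if (!length(p0)) stop("no P0 header line in TRANSFAC file")
  colorder <- toupper(strsplit(trimws(sub("^P[0O]", "", lines[p0[1L]])),
                               "\\s+")[[1L]])
  if (!setequal(colorder, .dna))
    stop("TRANSFAC P0 line must name the four nucleotides")
  rows <- list()
  for (l in lines[-seq_len(p0[1L])]) {
    if (grepl("^(XX|//)", l)) break
    if (!grepl("^\\d+\\s", l)) next
    f <- strsplit(l, "\\s+")[[1L]][-1L]
    rows[[length(rows) + 1L]] <- suppressWarnings(as.numeric(f[seq_len(4L)]))
  }
  if (!length(rows)) stop("no matrix rows in TRANSFAC block")
  m <- t(do.call(rbind, rows))           # 4 x M in file column order
  m <- m[match(.dna, colorder), , drop = FALSE]
  list(counts = m, name = name)
}

.parse_tsv <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  fields <- strsplit(lines, "[\t ]+")
  # optional header line: first line with any non-numeric field beyond a
  # possible leading nucleotide letter
  is_num_row <- vapply(fields, function(f) {
    if (toupper(f[1L]) %in% .dna) f <- f[-1L]
    length(f) > 0L && !anyNA(suppressWarnings(as.numeric(f)))
  }, logical(1L))
  fields <- fields[is_num_row]
  if (length(fields) != 4L) stop("wrong row count: expected 4 matrix rows")
  letters_lead <- vapply(fields, function(f) toupper(f[1L]) %in% .dna,
                         logical(1L))
  rowlab <- NULL
  if (all(letters_lead)) {
    rowlab <- toupper(vapply(fields, `[`, character(1L), 1L))
    fields <- lapply(fields, `[`, -1L)
  }
  m <- do.call(rbind, lapply(fields, as.numeric))
  if (!is.null(rowlab)) {
    if (!setequal(rowlab, .dna)) stop("row letters must be A, C, G, T")
    m <- m[match(.dna, rowlab), , drop = FALSE]
  }
  list(counts = m, name = NULL)
}

#' Write a PFM as TSV
#'
#' Writes 4 rows (A, C, G, T, with a leading letter column) of
#' probabilities; \code{read_pfm(..., format = "tsv", pseudocount = 0)}
#' round-trips exactly up to numerical print precision.
#'
#' @param pfm a \code{pfm}.
#' @param path output path.
#' @export
write_pfm <- function(pfm, path) {
  m <- format(unclass(pfm), digits = 17, scientific = FALSE, trim = TRUE)
  writeLines(paste(.dna, apply(m, 1L, paste, collapse = "\t"), sep = "\t"),
             path)
  invisible(path)
}

#' Reverse complement of a PFM
#'
#' Reverses the column order and swaps rows A with T and C with G, giving
#' the motif as read on the opposite strand.
#'
#' @param pfm a \code{pfm}.
#' @return a \code{pfm}.
#' @export
reverse_complement_pfm <- function(pfm) {
  m <- unclass(pfm)[4:1, rev(seq_len(ncol(pfm))), drop = FALSE]
  new_pfm(m, name = paste0(attr(pfm, "name"), "_rc"))
}

#' Near-point-mass PFM for a DNA word
#'
#' Each column puts mass 1 - 3*epsilon on the corresponding word letter
#' and epsilon on every other letter. At stringent thresholds the hit set
#' of such a motif is exactly the word, which makes brute-force oracles
#' tractable.
#'
#' @param word DNA string.
#' @param epsilon off-letter probability, 0 < epsilon < 0.25.
#' @return a \code{pfm}.
#' @export
word_motif <- function(word, epsilon = 0.01) {
  stopifnot(epsilon > 0, epsilon < 0.25)
  v <- encode_seq(word)
  if (anyNA(v)) stop("word contains letters outside ACGT")
  m <- matrix(epsilon, nrow = 4L, ncol = length(v))
  m[cbind(v, seq_along(v))] <- 1 - 3 * epsilon
  new_pfm(m, name = word)
}

#' Built-in toy motif fixtures
#'
#' Returns the named motifs used throughout the package's tests:
#' \code{nonself} (word ACGGT, no self-overlap), \code{palindrome}
#' (ACGCGT, equal to its reverse complement), \code{repeatlike} (AAAAA)
#' and \code{aaa} (AAA, the classic periodicity example with periods
#' \{1, 2\} and principal period \{1\}).
#'
#' @param epsilon off-letter probability passed to \code{\link{word_motif}}.
#' @return named list of \code{pfm} objects.
#' @export
fixture_motifs <- function(epsilon = 0.01) {
  list(nonself    = word_motif("ACGGT", epsilon),
       palindrome = word_motif("ACGCGT", epsilon),
       repeatlike = word_motif("AAAAA", epsilon),
       aaa        = word_motif("AAA", epsilon))
}
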