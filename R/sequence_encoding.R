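#' Fixed-length window from the 5' end of an intron
#'
#' Returns the first `min(L, k)` bases, right-padded with 'N' to length `k`
#' when the intron is shorter than the window.
#'
#' @param sequence Character vector of sequences.
#' @param k Window length in bp (default 1000).
#' @return Character vector of strings of length exactly `k`.
#' @export
first_window <- function(sequence, k = 1000L) {
  check_nonempty(sequence)
  n <- nchar(sequence)
  out <- substr(sequence, 1L, k)
  short <- n < k
  if (any(short)) {
    out[short] <- paste0(out[short],
                         strrep("N", k - n[short]))
  }
  out
}

#' Fixed-length window from the 3' end of an intron
#'
#' Returns the last `min(L, k)` bases, left-padded with 'N' to length `k`.
#'
#' @inheritParams first_window
#' @return Character vector of strings of length exactly `k`.
#' @export
last_window <- function(sequence, k = 1000L) {
  check_nonempty(sequence)
  n <- nchar(sequence)
  out <- substr(sequence, pmax(1L, n - k + 1L), n)
  short <- n < k
  if (any(short)) {
    out[short] <- paste0(strrep("N", k - n[short]), out[short])
  }
  out
}

# IUPAC codes mapped to integer codes: A=1, C=2, G=3, T=4, anything
# ambiguous (incl. the 'N' padding) = 5, which one-hot encodes as a
# uniform 0.25 row.
.base_codes <- local({
  codes <- rep(NA_integer_, 256)
  amb <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  codes[utf8ToInt("A")] <- 1L
  codes[utf8ToInt("C")] <- 2L
  codes[utf8ToInt("G")] <- 3L
  codes[utf8ToInt("T")] <- 4L
  for (a in amb) codes[utf8ToInt(a)] <- 5L
  codes
})

# 5x4 emission matrix: rows A,C,G,T unit vectors, row 5 uniform.
.onehot_rows <- rbind(diag(4), rep(0.25, 4))

#' Encode sequences as integer base codes
#'
#' Internal dense representation used by the convolutional classifier:
#' A/C/G/T map to 1..4 and every IUPAC ambiguity code (including 'N' padding)
#' to 5.
#'
#' @param sequence Character vector of equal-length window strings.
#' @return An integer matrix, one row per sequence.
#' @export
encode_codes <- function(sequence) {
  check_nonempty(sequence)
  n <- nchar(sequence)
  if (length(unique(n)) != 1L) {
    stop("all window sequences must have equal length")
  }
  raw <- utf8ToInt(paste(sequence, collapse = ""))
  codes <- .base_codes[raw]
  if (anyNA(codes)) {
    pos <- which(is.na(codes))[1]
    seq_i <- (pos - 1L) %/% n[1] + 1L
    seq_p <- (pos - 1L) %% n[1] + 1L
    stop("unexpected character '", intToUtf8(raw[pos]), "' at position ",
         seq_p, " of sequence ", seq_i)
  }
  matrix(codes, nrow = length(sequence), ncol = n[1], byrow = TRUE)
}

#' One-hot encode a DNA sequence
#'
#' Produces the L x 4 matrix (columns A, C, G, T) with unit indicator rows
#' for unambiguous bases and uniform 0.25 rows for N/ambiguity/padding
#' positions, so every row sums to 1.
#'
#' @param sequence A single window string.
#' @return A list of class `one_hot_sequence` with elements `matrix` (L x 4),
#'   `pad_len` (number of trailing/leading N positions) and `sequence`.
#' @export
one_hot <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  codes <- encode_codes(sequence)[1, ]
  m <- .onehot_rows[codes, , drop = FALSE]
  colnames(m) <- c("A", "C", "G", "T")
  structure(list(matrix = m,
                 pad_len = sum(codes == 5L &
                                 strsplit(sequence, "")[[1]] == "N"),
                 sequence = sequence),
            class = "one_hot_sequence")
}

#' Decode a one-hot matrix back to sequence text
#'
#' Unit rows decode to their base; uniform rows decode to 'N'.
#'
#' @param x A `one_hot_sequence` or plain L x 4 matrix.
#' @return A character scalar.
#' @export
decode_one_hot <- function(x) {
  m <- if (inherits(x, "one_hot_sequence")) x$matrix else x
  stopifnot(is.matrix(m), ncol(m) == 4L)
  bases <- c("A", "C", "G", "T")
  chars <- apply(m, 1, function(r) {
    if (max(r) > 0.5) bases[which.max(r)] else "N"
  })
  paste(chars, collapse = "")
}
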