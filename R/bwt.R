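#' Burrows-Wheeler transform of a string over its cyclic rotations
#'
#' Forms the `n` cyclic rotations of `s`, sorts them lexicographically (by
#' byte code, locale-independent), and reads the last character of each sorted
#' rotation. No end-of-string sentinel is appended: the transform is the pure
#' cyclic-rotation variant, so the rank of the original rotation among the
#' sorted rotations must be kept alongside the transformed string to make the
#' transform reversible. For periodic inputs the rotations are duplicated; the
#' rank is then the smallest sorted index holding the original rotation.
#'
#' The rotation sort runs on a prefix-doubling suffix ranking in compiled
#' code and scales to multi-megabase inputs.
#'
#' @param s a single non-empty character string.
#' @return An object of class `bwt` with elements
#'   \describe{
#'     \item{transform}{the transformed string `F`, same length as `s`}
#'     \item{rank}{0-based index of the original rotation among the sorted
#'       rotations}
#'   }
#' @examples
#' b <- bwt_forward("BANANA")
#' b$transform   # "NNBAAA"
#' b$rank        # 3
#' bwt_inverse(b)
#' @seealso [bwt_inverse()], [rle_encode()], [compressed_length()]
#' @export
bwt_forward <- function(s) {
  codes <- string_codes(s)
  n <- length(codes)
  ord <- cyclic_order_cpp(codes)
  f <- codes[(ord + n - 1L) %% n + 1L]
  structure(
    list(transform = intToUtf8(f), rank = which(ord == 0L) - 1L),
    class = "bwt"
  )
}

#' Invert a Burrows-Wheeler transform
#'
#' Reconstructs the original string from the transformed string and the rank
#' of the original rotation, by LF-mapping with stable ordering of equal
#' characters. `bwt_inverse(bwt_forward(s))` is the identity for every
#' non-empty `s`.
#'
#' @param b a `bwt` object, or a list with elements `transform` and `rank`.
#' @return The original character string.
#' @export
bwt_inverse <- function(b) {
  stopifnot(is.list(b), !is.null(b$transform), !is.null(b$rank))
  codes <- string_codes(b$transform)
  rank <- as.integer(b$rank)
  if (is.na(rank) || rank < 0L || rank >= length(codes)) {
    stop("rank ", b$rank, " out of range [0, ", length(codes) - 1L, "]")
  }
  intToUtf8(bwt_inverse_cpp(codes, rank))
}

#' Run-length encode a Burrows-Wheeler transform
#'
#' Serializes a `bwt` object as the decimal rank followed by one
#' `<count><character>` pair per maximal run of the transformed string. Every
#' run carries an explicit decimal count, including runs of length one. The
#' character count of this serialization (its octet length) is the
#' compression cost used by [ncd_pair()].
#'
#' @param b a `bwt` object.
#' @return An object of class `bwt_rle` with elements `lengths` and `values`
#'   (the runs), `rank`, `serialized`, and `octet_length`.
#' @examples
#' e <- rle_encode(bwt_forward("BANANA"))
#' e$serialized    # "32N1B3A"
#' e$octet_length  # 7
#' @export
rle_encode <- function(b) {
  stopifnot(inherits(b, "bwt") || (is.list(b) && !is.null(b$transform)))
  chars <- strsplit(b$transform, "", fixed = TRUE)[[1]]
  r <- rle(chars)
  serialized <- paste0(b$rank, paste0(r$lengths, r$values, collapse = ""))
  structure(
    list(
      lengths = as.integer(r$lengths), values = r$values,
      rank = as.integer(b$rank), serialized = serialized,
      octet_length = nchar(serialized)
    ),
    class = "bwt_rle"
  )
}

#' Decode a run-length encoded Burrows-Wheeler transform
#'
#' Reconstitutes the `bwt` object from its runs and rank, validating the run
#' structure (positive counts, no two adjacent runs with the same character)
#' and, when present, the consistency of the `serialized` field. The
#' concatenated `<rank><count><char>...` text is a cost model rather than a
#' self-delimiting wire format (the rank digits and the first count digits
#' are not separable), so decoding operates on the structured runs.
#'
#' @param e a `bwt_rle` object.
#' @return A `bwt` object.
#' @export
rle_decode <- function(e) {
  stopifnot(is.list(e), !is.null(e$lengths), !is.null(e$values),
            !is.null(e$rank))
  lens <- as.integer(e$lengths)
  if (length(lens) != length(e$values)) {
    stop("malformed runs: ", length(lens), " counts vs ",
         length(e$values), " characters")
  }
  if (any(is.na(lens)) || any(lens < 1L)) stop("malformed runs: counts must be positive integers")
  if (any(nchar(e$values) != 1L)) stop("malformed runs: run values must be single characters")
  if (length(e$values) > 1L &&
      any(e$values[-1] == e$values[-length(e$values)])) {
    stop("malformed runs: adjacent runs repeat the same character")
  }
  if (!is.null(e$serialized)) {
    expect <- paste0(e$rank, paste0(lens, e$values, collapse = ""))
    if (!identical(as.character(e$serialized), expect)) {
      stop("malformed serialized text: expected '", expect, "'")
    }
  }
  f <- paste(rep(e$values, lens), collapse = "")
  rank <- as.integer(e$rank)
  if (is.na(rank) || rank < 0L || rank >= nchar(f)) {
    stop("rank ", e$rank, " out of range")
  }
  structure(list(transform = f, rank = rank), class = "bwt")
}

#' Compression cost of a string in octets
#'
#' The octet (character) length of the run-length serialization of the
#' Burrows-Wheeler transform of `s`: decimal rank, then decimal count plus
#' character for every run. This is the cost function `C(x)` of the
#' normalized compression distance. Under this convention
#' `compressed_length("BANANA")` is 7 (rank digit `3` plus runs `2N 1B 3A`)
#' and `compressed_length("BANANACANADA")` is 11.
#'
#' @param s a single non-empty character string.
#' @return Integer octet count.
#' @examples
#' compressed_length("BANANA")        # 7
#' compressed_length("BANANACANADA")  # 11
#' @export
compressed_length <- function(s) {
  rle_encode(bwt_forward(s))$octet_length
}

#' @export
print.bwt <- function(x, ...) {
  n <- nchar(x$transform)
  shown <- if (n > 60) paste0(substr(x$transform, 1, 57), "...") else x$transform
  cat("Cyclic BWT: n = ", n, ", rank = ", x$rank, "\n  F = ", shown, "\n",
      sep = "")
  invisible(x)
}

#' @export
print.bwt_rle <- function(x, ...) {
  shown <- if (nchar(x$serialized) > 60) {
    paste0(substr(x$serialized, 1, 57), "...")
  } else {
    x$serialized
  }
  cat("RLE(BWT): ", length(x$lengths), " runs, ", x$octet_length,
      " octets\n  ", shown, "\n", sep = "")
  invisible(x)
}

# Integer code points of a single non-empty character string.
string_codes <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop("input must be a single character string")
  }
  if (nchar(s) == 0L) stop("input string must be non-empty")
  utf8ToInt(s)
}
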