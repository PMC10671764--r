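#' Read sequences from a FASTA file
#'
#' Sequences are returned as a named character vector, the container used
#' throughout the package: names are record identifiers (the header up to the
#' first whitespace), values are residue strings. Under the default `"dna"`
#' normalization residues are uppercased and `U` is mapped to `T`, so RNA and
#' DNA input mix freely; `"verbatim"` keeps residues exactly as read (line
#' breaks removed). Characters outside `ACGT` (IUPAC codes, `N`, or arbitrary
#' letters in toy inputs) are kept as literal symbols — the compression codec
#' treats them as ordinary characters.
#'
#' @param path path to a FASTA file.
#' @param mode `"dna"` (default: uppercase, U to T) or `"verbatim"`.
#' @return Named character vector of sequences, input order preserved.
#' @export
read_fasta <- function(path, mode = c("dna", "verbatim")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty identifier in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA identifier(s): ", paste(dup, collapse = ", "))
  }
  seqs <- as.character(set)
  empty <- ids[nchar(seqs) == 0L]
  if (length(empty)) {
    stop("empty FASTA record(s): ", paste(empty, collapse = ", "))
  }
  if (mode == "dna") seqs <- normalize_dna(seqs)
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- as_seqs(seqs)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Uppercase and map U -> T (RNA to DNA).
normalize_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

# Validate/coerce a named character vector of sequences.
as_seqs <- function(seqs) {
  if (!is.character(seqs)) stop("sequences must be a character vector")
  ids <- names(seqs)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids))) {
    stop("every sequence must carry a non-empty name")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate sequence identifier(s): ", paste(dup, collapse = ", "))
  }
  seqs
}

#' Write a labelled distance matrix in PHYLIP square format
#'
#' First line holds the number of taxa; each following line holds a label and
#' its full row of distances with at least six significant digits, so
#' `read_distance_matrix(write_distance_matrix(D, f))` reproduces `D` to
#' within 1e-6.
#'
#' @param D an [ncd_matrix()] result, or a square numeric matrix with
#'   dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  m <- as_dist_matrix(D)
  labels <- rownames(m)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(labels[i], paste(formatC(m[i, ], format = "g", digits = 8),
                           collapse = " "))
  }, character(1))
  writeLines(c(as.character(nrow(m)), rows), path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path path to a file written by [write_distance_matrix()] or any
#'   square-dialect PHYLIP distance file.
#' @return A square numeric matrix with labels as dimnames.
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) stop("distance matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("malformed distance matrix: empty file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop("malformed distance matrix header: '", lines[1], "'")
  }
  if (length(lines) != n + 1L) {
    stop("distance matrix declares ", n, " rows but file has ",
         length(lines) - 1L)
  }
  labels <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(fields) != n + 1L) {
      stop("row ", i, " has ", length(fields) - 1L, " values, expected ", n)
    }
    labels[i] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (any(is.na(vals))) stop("non-numeric distance in row ", i)
    m[i, ] <- vals
  }
  dimnames(m) <- list(labels, labels)
  m
}

# Accept an ncd_matrix or a plain labelled square matrix.
as_dist_matrix <- function(D) {
  if (inherits(D, "ncd_matrix")) D <- D$values
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D)) {
    stop("distance matrix must be a square numeric matrix")
  }
  if (is.null(rownames(D))) {
    stop("distance matrix must carry labels as dimnames")
  }
  D
}
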