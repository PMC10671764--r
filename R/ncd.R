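#' Normalized compression distance between two sequences
#'
#' Computes `Cx`, `Cy` and `Cxy` as the octet lengths of the run-length
#' serialized Burrows-Wheeler transforms of `x`, `y` and their concatenation
#' `xy` (see [compressed_length()]), and returns
#' \describe{
#'   \item{`"max"`}{`(Cxy - min(Cx, Cy)) / max(Cx, Cy)` — the standard NCD
#'     normalization (default);}
#'   \item{`"min"`}{`(Cxy - min(Cx, Cy)) / min(Cx, Cy)` — a variant with
#'     the minimum in the denominator, under which the classic worked example
#'     `ncd_pair("BANANA", "CANADA", dialect = "min")` equals 4/7 = 0.57.}
#' }
#' `Cxy` can in principle fall below `min(Cx, Cy)` for adversarial inputs;
#' the distance is then clamped at 0 and a warning is raised, so the result
#' is always non-negative.
#'
#' @param x,y non-empty character strings.
#' @param dialect `"max"` or `"min"`.
#' @return A single non-negative number.
#' @examples
#' ncd_pair("BANANA", "CANADA", dialect = "min")  # 4/7
#' ncd_pair("BANANA", "CANADA")                     # 4/9
#' @export
ncd_pair <- function(x, y, dialect = c("max", "min")) {
  dialect <- match.arg(dialect)
  ncd_from_costs(compressed_length(x), compressed_length(y),
                 compressed_length(paste0(x, y)), dialect)
}

ncd_from_costs <- function(cx, cy, cxy, dialect) {
  num <- cxy - min(cx, cy)
  if (num < 0) {
    warning("Cxy (", cxy, ") < min(Cx, Cy) (", min(cx, cy),
            "); distance clamped at 0")
    num <- 0
  }
  den <- if (dialect == "min") min(cx, cy) else max(cx, cy)
  num / den
}

#' Pairwise NCD matrix for a set of sequences
#'
#' Computes the normalized compression distance for every ordered pair and
#' symmetrizes by the arithmetic mean of the two concatenation orders:
#' `values[i, j] = (d(i, j) + d(j, i)) / 2` for `i != j`. The raw
#' (pre-symmetrization) matrix is kept so [metric_report()] can quantify how
#' far the codec is from exact symmetry. The diagonal records `d(i, i)` as
#' computed — typically a small positive value rather than an exact 0,
#' because the serialization of a doubled string is never shorter than that
#' of the string itself; clustering consumes only off-diagonal entries.
#'
#' Per-sequence costs are computed once; only the `n(n-1)` concatenation
#' costs depend on the pair.
#'
#' @param seqs named character vector of at least two sequences with unique
#'   names.
#' @param dialect `"max"` (default) or `"min"`, as in [ncd_pair()].
#' @return An object of class `ncd_matrix`: a list with `labels`, `values`
#'   (symmetrized), `raw` (one row per concatenation order), and `dialect`.
#' @export
ncd_matrix <- function(seqs, dialect = c("max", "min")) {
  dialect <- match.arg(dialect)
  seqs <- as_seqs(seqs)
  if (length(seqs) < 2L) stop("need at least two sequences")
  n <- length(seqs)
  labels <- names(seqs)
  cost <- vapply(seqs, compressed_length, integer(1))
  raw <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cxy <- compressed_length(paste0(seqs[[i]], seqs[[j]]))
      raw[i, j] <- ncd_from_costs(cost[i], cost[j], cxy, dialect)
    }
  }
  values <- (raw + t(raw)) / 2
  diag(values) <- vapply(seq_len(n), function(i) {
    ncd_from_costs(cost[i], cost[i],
                   compressed_length(paste0(seqs[[i]], seqs[[i]])), dialect)
  }, numeric(1))
  structure(
    list(labels = labels, values = values, raw = raw, dialect = dialect),
    class = "ncd_matrix"
  )
}

#' @export
print.ncd_matrix <- function(x, ...) {
  cat("NCD matrix (", x$dialect, " dialect): ", length(x$labels),
      " sequences\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Diagnostics on the metric properties of a distance matrix
#'
#' The normalized compression distance is, in the ideal, a metric:
#' `d(x, x) = 0`, `d(x, y) = d(y, x)`, and the triangle inequality holds.
#' A run-length codec only approximates the ideal compressor, so each
#' property can fail by a small margin in practice. This report measures the
#' failures instead of assuming them away: the largest diagonal value, the
#' largest asymmetry between the two concatenation orders (when the raw
#' matrix is available), and an exhaustive scan of all ordered triples
#' `(i, j, k)` counting violations of `d(i, k) <= d(i, j) + d(j, k)`.
#'
#' @param D an [ncd_matrix()] result or a labelled square numeric matrix.
#' @return A list of class `ncd_metric_report`: `n`, `max_diagonal`,
#'   `max_asymmetry` (`NA` if no raw matrix), `n_triples`, `n_violations`,
#'   `violation_fraction`, and `max_violation` (largest excess of
#'   `d(i, k) - d(i, j) - d(j, k)` over the scanned triples, 0 if none).
#' @export
metric_report <- function(D) {
  raw <- if (inherits(D, "ncd_matrix")) D$raw else NULL
  m <- as_dist_matrix(D)
  n <- nrow(m)
  max_asym <- if (is.null(raw)) NA_real_ else {
    off <- row(raw) != col(raw)
    max(abs(raw - t(raw))[off]) / 2
  }
  n_triples <- n * (n - 1) * (n - 2)
  n_viol <- 0L
  max_excess <- 0
  if (n >= 3) {
    for (j in seq_len(n)) {
      bound <- outer(m[, j], m[j, ], "+")
      excess <- m - bound
      keep <- row(m) != j & col(m) != j & row(m) != col(m)
      n_viol <- n_viol + sum(excess[keep] > 0)
      max_excess <- max(max_excess, excess[keep])
    }
  }
  structure(
    list(
      n = n,
      max_diagonal = max(abs(diag(m))),
      max_asymmetry = max_asym,
      n_triples = n_triples,
      n_violations = n_viol,
      violation_fraction = if (n_triples > 0) n_viol / n_triples else 0,
      max_violation = max(max_excess, 0)
    ),
    class = "ncd_metric_report"
  )
}

#' @export
print.ncd_metric_report <- function(x, ...) {
  cat("Metric diagnostics over", x$n, "labels\n")
  cat("  max |d(x,x)|       :", format(x$max_diagonal), "\n")
  cat("  max asymmetry      :", format(x$max_asymmetry), "\n")
  cat("  triangle scan      :", x$n_violations, "of", x$n_triples,
      "ordered triples violate (fraction",
      format(x$violation_fraction), ")\n")
  cat("  max violation      :", format(x$max_violation), "\n")
  invisible(x)
}
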