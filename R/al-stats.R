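#' Archetypal-loop (AL) constants
#'
#' The archetypal loop is a 22-base circular RNA proposed as a relic of the
#' earliest peptide-synthesis machinery; its hairpin head fragments into the
#' ten pentamers used by [al_proximity()]. Two forms of the ring constant are
#' shipped: `al_ring()` returns the sequence exactly as printed in the
#' primary literature, DNA-normalized (23 characters — it carries an
#' anomalous extra `T`), and `al_ring(trimmed = TRUE)` the 22-mer with that
#' anomalous character removed. AL-pair operations always take the ring as
#' an explicit argument, never implicitly.
#'
#' @param trimmed if `TRUE`, return the 22-mer with the anomalous
#'   duplicated character (position 10) removed; otherwise the
#'   23-character sequence as printed.
#' @return A character string.
#' @export
al_ring <- function(trimmed = FALSE) {
  printed <- normalize_dna("AAUGGUACUTGCCAUUCAAGAUG")  # 23 characters
  if (!trimmed) return(printed)
  paste0(substr(printed, 1, 9), substr(printed, 11, 23))
}

#' Default AL-pentamer set
#'
#' The ten pentamers of the head of the AL hairpin. Note the mismatch
#' carried over from the source literature: the set has ten members, yet the
#' published match probability is 9/1024 ("nine pentamers"). See
#' [al_params()] modes.
#'
#' @return Character vector of ten 5-mers.
#' @export
al_pentamers <- function() {
  c("ATTCA", "TTCAA", "TCAAG", "CAAGA", "AAGAT",
    "AGATG", "GATGA", "AATGA", "ATGAA", "TGAAT")
}

#' Parameters for the AL-proximity statistic
#'
#' @param pentamers set of 5-mers over `{A,C,G,T}` to scan for.
#' @param p per-position match probability of the binomial null. In
#'   `"published"` mode the published value 9/1024 is used as-is even though the
#'   default set has ten members (fidelity to the printed statistic); in
#'   `"consistent"` mode `p = length(pentamers)/1024`, the exact null for a
#'   uniform i.i.d. sequence, which is the mode used for statistical
#'   calibration.
#' @param mode `"published"` or `"consistent"`.
#' @param circular scan the sequence as a circle (windows wrap; `P = n`).
#' @param degenerate also match each pentamer's purine/pyrimidine
#'   (R = A/G, Y = C/T) family image.
#' @return A list of class `al_params`.
#' @export
al_params <- function(pentamers = al_pentamers(), p = 9 / 1024,
                      mode = c("published", "consistent"),
                      circular = FALSE, degenerate = FALSE) {
  mode <- match.arg(mode)
  pentamers <- toupper(pentamers)
  if (any(nchar(pentamers) != 5L)) stop("every pentamer must have length 5")
  if (mode == "consistent") p <- length(unique(pentamers)) / 1024
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  structure(
    list(pentamers = pentamers, p = p, mode = mode,
         circular = isTRUE(circular), degenerate = isTRUE(degenerate)),
    class = "al_params"
  )
}

# Purine/pyrimidine two-letter projection.
ry_project <- function(x) chartr("ACGT", "RYRY", x)

# All 5-mer windows of seq (character vector of windows).
pentamer_windows <- function(seq, circular = FALSE) {
  n <- nchar(seq)
  if (circular) {
    ext <- paste0(seq, substr(seq, 1, 4))
    starts <- seq_len(n)
  } else {
    if (n < 5L) stop("sequence of length ", n, " has no 5-mer window")
    ext <- seq
    starts <- seq_len(n - 4L)
  }
  substring(ext, starts, starts + 4L)
}

#' Count AL-pentamer occurrences in a sequence
#'
#' Slides a 5-character window over the sequence (every start position;
#' overlapping matches all count) and counts windows belonging to the
#' pentamer set. With `params$circular` the window wraps around the end;
#' with `params$degenerate` a window also matches when its
#' purine/pyrimidine projection equals that of a set member.
#'
#' @param seq a single sequence string.
#' @param params an [al_params()] object.
#' @return Integer count of matching windows.
#' @examples
#' count_pentamer_hits("ATTCAAG", al_params())  # 3
#' @export
count_pentamer_hits <- function(seq, params = al_params()) {
  stopifnot(inherits(params, "al_params"))
  w <- pentamer_windows(toupper(seq), params$circular)
  hits <- w %in% params$pentamers
  if (params$degenerate) {
    hits <- hits | ry_project(w) %in% ry_project(params$pentamers)
  }
  sum(hits)
}

#' AL-proximity z-statistic of a sequence
#'
#' For a sequence of length `n`, counts the observed number `O` of windows
#' matching the AL-pentamer set over the `P = n - 4` possible start
#' positions (`P = n` when circular), and standardizes it against the
#' binomial null with per-position probability `p`:
#' `E = P * p`, `sigma = sqrt(P * p * (1 - p))`, `z = (O - E) / sigma`.
#' A strongly positive `z` means the sequence is enriched in AL fragments
#' beyond chance; the published whole-genome "AL proximity" is exactly this
#' `z` in published mode.
#'
#' @inheritParams count_pentamer_hits
#' @return A list of class `al_result`: `n`, `O`, `P`, `E`, `sigma`, `z`.
#' @examples
#' al_proximity("ATTCA", al_params())$z  # about +10.62
#' @export
al_proximity <- function(seq, params = al_params()) {
  stopifnot(inherits(params, "al_params"))
  n <- nchar(seq)
  P <- if (params$circular) n else n - 4L
  if (P < 1L) {
    stop("sequence of length ", n, " leaves no window: statistic undefined")
  }
  O <- count_pentamer_hits(seq, params)
  E <- P * params$p
  sigma <- sqrt(P * params$p * (1 - params$p))
  structure(
    list(n = n, O = O, P = P, E = E, sigma = sigma, z = (O - E) / sigma),
    class = "al_result"
  )
}

#' @export
print.al_result <- function(x, ...) {
  cat(sprintf("AL-proximity: n = %d, O = %d, E = %.4f, sigma = %.4f, z = %+.3f\n",
              x$n, x$O, x$E, x$sigma, x$z))
  invisible(x)
}

#' Windowed AL-proximity profile
#'
#' Applies [al_proximity()] to half-open windows `[start, start + window)`
#' (0-based starts) advanced by `step`, for per-region enrichment profiles
#' along a long sequence. The final partial window is dropped unless it is
#' the only window.
#'
#' @param seq a single sequence string.
#' @param window window length in nucleotides (at least 5).
#' @param step step between window starts (default: `window`, i.e. tiling).
#' @param params an [al_params()] object (circular scanning is ignored
#'   within windows).
#' @return A data frame with columns `start` (0-based), `n`, `O`, `z`;
#'   zero rows (with a warning) when `window > nchar(seq)`.
#' @export
al_proximity_profile <- function(seq, window, step = window,
                                 params = al_params()) {
  if (window < 5L) stop("window must be at least 5")
  if (step < 1L) stop("step must be positive")
  n <- nchar(seq)
  if (window > n) {
    warning("window (", window, ") longer than sequence (", n, ")")
    return(data.frame(start = integer(), n = integer(), O = integer(),
                      z = numeric()))
  }
  params <- al_params(pentamers = params$pentamers, p = params$p,
                      mode = params$mode, circular = FALSE,
                      degenerate = params$degenerate)
  starts <- seq(0L, n - window, by = step)
  res <- lapply(starts, function(s0) {
    al_proximity(substr(seq, s0 + 1L, s0 + window), params)
  })
  data.frame(
    start = starts,
    n = window,
    O = vapply(res, `[[`, integer(1), "O"),
    z = vapply(res, `[[`, numeric(1), "z")
  )
}

# Translate codons (character vector of 3-mers) with the standard code;
# STOP is "*".
translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  if (any(is.na(aa))) {
    stop("untranslatable codon(s): ",
         paste(unique(codons[is.na(aa)]), collapse = ", "))
  }
  aa
}

#' Enumerate AL-pairs on a circular ring
#'
#' An AL-pair is the pair of amino acids encoded by two codons read on the
#' circular ring whose start offsets are at most `max_span` nucleotides
#' apart. Every ordered pair of offsets `(i, j)` with
#' `1 <= (j - i) mod n <= max_span` contributes one pair, so the multiset
#' has exactly `n * max_span` entries. Codons wrap around the ring; STOP
#' codons are emitted with the symbol `"*"`.
#'
#' @param ring a single sequence string, treated as circular.
#' @param max_span maximal codon start separation in nucleotides
#'   (default 12).
#' @return A data frame with columns `aa1`, `aa2`, `span`.
#' @export
enumerate_al_pairs <- function(ring, max_span = 12L) {
  ring <- normalize_dna(ring)
  n <- nchar(ring)
  if (n < 1L) stop("ring must be non-empty")
  if (max_span < 1L) {
    return(data.frame(aa1 = character(), aa2 = character(),
                      span = integer()))
  }
  ext <- paste0(ring, substr(ring, 1, 2))
  codons <- substring(ext, seq_len(n), seq_len(n) + 2L)
  aa <- translate_codons(codons)
  grid <- expand.grid(i = seq_len(n) - 1L, span = seq_len(max_span))
  j <- (grid$i + grid$span) %% n
  data.frame(aa1 = aa[grid$i + 1L], aa2 = aa[j + 1L], span = grid$span)
}

#' Enrichment of AL-pairs among successive residues of a protein
#'
#' Scores how many successive amino-acid pairs of a protein belong to the
#' set of unordered AL-pairs of a ring (see [enumerate_al_pairs()]); pairs
#' containing a STOP symbol cannot occur in a protein and are excluded from
#' the null. The null model is binomial: each of the `P = length - 1`
#' successive pairs matches with probability
#' `p = (distinct stop-free AL-pairs) / 210`, 210 being the number of
#' unordered amino-acid pairs with identity (20 choose 2 plus 20).
#'
#' @param protein a single string of one-letter amino-acid codes.
#' @param ring circular nucleotide ring defining the AL-pairs.
#' @param max_span maximal codon start separation on the ring.
#' @return A list of class `al_pair_result`: `O`, `P`, `E`, `sigma`, `z`,
#'   `p`, and `matches` (data frame of matched protein pairs with the ring
#'   spans at which each pair occurs).
#' @export
al_pair_statistic <- function(protein, ring, max_span = 12L) {
  protein <- toupper(protein)
  if (nchar(protein) < 2L) stop("protein must have at least 2 residues")
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
  if (!all(res %in% valid)) {
    stop("non-amino-acid symbol(s): ",
         paste(unique(res[!res %in% valid]), collapse = ", "))
  }
  pairs <- enumerate_al_pairs(ring, max_span)
  pairs <- pairs[pairs$aa1 != "*" & pairs$aa2 != "*", , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  al_keys <- key(pairs$aa1, pairs$aa2)
  distinct <- unique(al_keys)
  p <- length(distinct) / 210
  P <- length(res) - 1L
  prot_keys <- key(res[-length(res)], res[-1])
  hit <- prot_keys %in% distinct
  O <- sum(hit)
  E <- P * p
  sigma <- sqrt(P * p * (1 - p))
  matches <- if (any(hit)) {
    idx <- which(hit)
    do.call(rbind, lapply(idx, function(i) {
      spans <- sort(unique(pairs$span[al_keys == prot_keys[i]]))
      data.frame(position = i, pair = prot_keys[i],
                 spans = paste(spans, collapse = ","))
    }))
  } else {
    data.frame(position = integer(), pair = character(),
               spans = character())
  }
  structure(
    list(O = O, P = P, E = E, sigma = sigma, z = (O - E) / sigma, p = p,
         matches = matches),
    class = "al_pair_result"
  )
}

#' @export
print.al_pair_result <- function(x, ...) {
  cat(sprintf(
    "AL-pair enrichment: O = %d of P = %d pairs (E = %.2f, sigma = %.3f, z = %+.3f)\n",
    x$O, x$P, x$E, x$sigma, x$z))
  invisible(x)
}
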