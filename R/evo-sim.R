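#' Configuration for the genome-evolution simulator
#'
#' Describes a star phylogeny: `n_ancestors` independent random ancestors,
#' each giving rise to `clade_size` descendants by repeated application of
#' the eleven classical genomic operators (crossing over, mutation,
#' translocation, insertion, deletion, transposition, inversion,
#' repetition, symmetrization, palindromization, circular permutation).
#' Event counts per descendant are Poisson with the configured per-genome
#' means; segment lengths are uniform over `segment_length`.
#'
#' The default rates describe moderately diverged clades: point
#' substitutions at 1% of the genome length per lineage, a handful of
#' segmental events (50-500 bp) per lineage, and roughly one
#' whole-molecule event (rotation, recombination) each. These defaults are
#' the regime under which compression distances separate clades clearly;
#' see the package vignette for the reasoning.
#'
#' @param n_ancestors number of independent ancestral genomes.
#' @param clade_size descendants per ancestor.
#' @param genome_length ancestor length in bases.
#' @param operator_rates named numeric vector of mean events per descendant
#'   genome; names must be among the eleven operators. Omitted operators
#'   default to 0; `NULL` gives the package defaults.
#' @param segment_length `c(min, max)` lengths for segment operators.
#' @param seed integer seed making the simulation reproducible.
#' @return A list of class `evo_config`.
#' @export
evo_config <- function(n_ancestors = 3L, clade_size = 8L,
                       genome_length = 20000L, operator_rates = NULL,
                       segment_length = c(50L, 500L), seed = 42L) {
  stopifnot(n_ancestors >= 1L, clade_size >= 1L, genome_length >= 1L,
            length(segment_length) == 2L,
            segment_length[1] >= 1L,
            segment_length[2] >= segment_length[1])
  defaults <- c(
    mutation = round(0.01 * genome_length),
    crossing_over = 1, translocation = 2, insertion = 2, deletion = 2,
    transposition = 2, inversion = 2, repetition = 2, symmetrization = 1,
    palindromization = 1, circular_permutation = 1
  )
  if (is.null(operator_rates)) {
    operator_rates <- defaults
  } else {
    if (is.null(names(operator_rates)) ||
        !all(names(operator_rates) %in% evo_operators())) {
      stop("operator_rates must be named with operators among: ",
           paste(evo_operators(), collapse = ", "))
    }
    if (any(operator_rates < 0)) stop("operator rates must be >= 0")
    full <- stats::setNames(numeric(length(evo_operators())),
                            evo_operators())
    full[names(operator_rates)] <- operator_rates
    operator_rates <- full
  }
  structure(
    list(n_ancestors = as.integer(n_ancestors),
         clade_size = as.integer(clade_size),
         genome_length = as.integer(genome_length),
         operator_rates = operator_rates,
         segment_length = as.integer(segment_length),
         seed = as.integer(seed)),
    class = "evo_config"
  )
}

#' The eleven genomic operators
#'
#' @return Character vector of recognized operator names.
#' @export
evo_operators <- function() {
  c("crossing_over", "mutation", "translocation", "insertion", "deletion",
    "transposition", "inversion", "repetition", "symmetrization",
    "palindromization", "circular_permutation")
}

#' Uniform random genome
#'
#' I.i.d. uniform bases over `{A, C, G, T}`. Uses the current R random
#' number stream; pass `seed` to make a single call reproducible on its
#' own.
#'
#' @param length genome length (at least 1).
#' @param seed optional integer seed applied before drawing.
#' @return A character string.
#' @export
random_genome <- function(length, seed = NULL) {
  if (length < 1L) stop("length must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
        collapse = "")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

mirror <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

# Uniform integer in [a, b] (safe for a == b, unlike sample(a:b, 1)).
sample_int_range <- function(a, b) {
  if (a >= b) return(a)
  a + sample.int(b - a + 1L, 1L) - 1L
}

# Sample a segment length and start; returns list(start, len) 1-based.
sample_segment <- function(n, segment_length, max_len = n) {
  len <- sample_int_range(segment_length[1], segment_length[2])
  if (len > max_len) {
    stop("sampled segment of length ", len,
         " does not fit in sequence of length ", n)
  }
  list(start = sample.int(n - len + 1L, 1L), len = len)
}

#' Apply one genomic operator to a sequence
#'
#' Operator semantics (segment operators draw their segment uniformly):
#' \describe{
#'   \item{mutation}{one base substituted by a different base}
#'   \item{insertion}{random segment inserted at a random position}
#'   \item{deletion}{segment removed}
#'   \item{inversion}{segment replaced by its reverse complement}
#'   \item{repetition}{segment duplicated in place (tandem)}
#'   \item{translocation}{segment excised and reinserted elsewhere}
#'   \item{transposition}{segment copied elsewhere, original kept}
#'   \item{symmetrization}{segment replaced by its mirror (reversal
#'     without complementation)}
#'   \item{palindromization}{segment followed by its reverse complement}
#'   \item{circular_permutation}{whole sequence rotated by a random
#'     offset}
#'   \item{crossing_over}{binary: the sequence's suffix is exchanged with
#'     `partner`'s suffix at a random point; the modified first sequence
#'     is returned}
#' }
#'
#' @param seq a single sequence string.
#' @param op one of [evo_operators()].
#' @param partner second sequence, required for `crossing_over`.
#' @param segment_length `c(min, max)` segment lengths.
#' @param offset optional fixed rotation offset for
#'   `circular_permutation` (random when `NULL`).
#' @return The derived sequence string.
#' @examples
#' apply_operator("ACGT", "circular_permutation", offset = 1)  # "CGTA"
#' @export
apply_operator <- function(seq, op, partner = NULL,
                           segment_length = c(50L, 500L), offset = NULL) {
  n <- nchar(seq)
  if (n < 1L) stop("sequence must be non-empty")
  switch(op,
    mutation = {
      i <- sample.int(n, 1L)
      old <- substr(seq, i, i)
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      paste0(substr(seq, 1L, i - 1L), new, substr(seq, i + 1L, n))
    },
    insertion = {
      len <- sample_int_range(segment_length[1], segment_length[2])
      at <- sample.int(n + 1L, 1L) - 1L
      paste0(substr(seq, 1L, at), random_genome(len),
             substr(seq, at + 1L, n))
    },
    deletion = {
      s <- sample_segment(n, segment_length, max_len = n - 1L)
      paste0(substr(seq, 1L, s$start - 1L),
             substr(seq, s$start + s$len, n))
    },
    inversion = {
      s <- sample_segment(n, segment_length)
      paste0(substr(seq, 1L, s$start - 1L),
             revcomp(substr(seq, s$start, s$start + s$len - 1L)),
             substr(seq, s$start + s$len, n))
    },
    repetition = {
      s <- sample_segment(n, segment_length)
      seg <- substr(seq, s$start, s$start + s$len - 1L)
      paste0(substr(seq, 1L, s$start + s$len - 1L), seg,
             substr(seq, s$start + s$len, n))
    },
    translocation = {
      s <- sample_segment(n, segment_length, max_len = n - 1L)
      seg <- substr(seq, s$start, s$start + s$len - 1L)
      rest <- paste0(substr(seq, 1L, s$start - 1L),
                     substr(seq, s$start + s$len, n))
      at <- sample.int(nchar(rest) + 1L, 1L) - 1L
      paste0(substr(rest, 1L, at), seg, substr(rest, at + 1L, nchar(rest)))
    },
    transposition = {
      s <- sample_segment(n, segment_length)
      seg <- substr(seq, s$start, s$start + s$len - 1L)
      at <- sample.int(n + 1L, 1L) - 1L
      paste0(substr(seq, 1L, at), seg, substr(seq, at + 1L, n))
    },
    symmetrization = {
      s <- sample_segment(n, segment_length)
      paste0(substr(seq, 1L, s$start - 1L),
             mirror(substr(seq, s$start, s$start + s$len - 1L)),
             substr(seq, s$start + s$len, n))
    },
    palindromization = {
      s <- sample_segment(n, segment_length)
      seg <- substr(seq, s$start, s$start + s$len - 1L)
      paste0(substr(seq, 1L, s$start + s$len - 1L), revcomp(seg),
             substr(seq, s$start + s$len, n))
    },
    circular_permutation = {
      k <- if (is.null(offset)) sample.int(n, 1L) - 1L else offset %% n
      if (k == 0L) seq else paste0(substr(seq, k + 1L, n),
                                   substr(seq, 1L, k))
    },
    crossing_over = {
      if (is.null(partner)) stop("crossing_over requires a partner sequence")
      n2 <- nchar(partner)
      k <- sample.int(min(n, n2) - 1L, 1L)
      paste0(substr(seq, 1L, k), substr(partner, k + 1L, n2))
    },
    stop("unknown operator: ", op)
  )
}

# Expected length effect of each operator, for per-event bookkeeping.
length_effect <- function(op, before, after) {
  ok <- switch(op,
    mutation = ,
    inversion = ,
    symmetrization = ,
    circular_permutation = after == before,
    insertion = ,
    repetition = ,
    palindromization = after > before,
    deletion = after < before,
    TRUE)
  if (!ok) stop("operator ", op, " produced an inconsistent length (",
                before, " -> ", after, ")")
  invisible(ok)
}

#' Simulate a clade-structured genome set
#'
#' Draws `n_ancestors` independent uniform genomes and derives
#' `clade_size` descendants from each: per descendant, every operator
#' fires a Poisson-distributed number of times at the clade's rate, and
#' the events are applied in random order. Crossing over recombines the
#' descendant with its own ancestor, so descendants stay conditionally
#' independent given the ancestor (a star phylogeny — recombining with
#' siblings instead would introduce sub-lineage structure the model does
#' not declare). Sequence identifiers are assigned in shuffled order so
#' they encode nothing about the clades; the ground truth is returned
#' separately.
#'
#' @param config an [evo_config()].
#' @return A list with `sequences` (named character vector) and `truth`
#'   (data frame: `id`, `clade`).
#' @export
simulate_phylogeny <- function(config = evo_config()) {
  stopifnot(inherits(config, "evo_config"))
  set.seed(config$seed)
  total <- config$n_ancestors * config$clade_size
  ids <- sprintf("g%03d", seq_len(total))
  ids <- sample(ids)  # shuffle: id order carries no clade signal
  seqs <- character(total)
  clades <- character(total)
  k <- 0L
  for (a in seq_len(config$n_ancestors)) {
    ancestor <- random_genome(config$genome_length)
    for (d in seq_len(config$clade_size)) {
      g <- ancestor
      events <- unlist(lapply(names(config$operator_rates), function(op) {
        rep(op, stats::rpois(1L, config$operator_rates[[op]]))
      }))
      if (length(events) > 1L) events <- sample(events)
      for (op in events) {
        partner <- if (op == "crossing_over") ancestor else NULL
        before <- nchar(g)
        # a sequence eroded to a single base supports only point events
        if (before < 2L &&
            !op %in% c("mutation", "insertion", "circular_permutation")) {
          next
        }
        # segment lengths are clamped so events always fit the current
        # (possibly shrunken) sequence
        sl <- pmax(pmin(config$segment_length, before - 1L), 1L)
        g <- apply_operator(g, op, partner = partner, segment_length = sl)
        length_effect(op, before, nchar(g))
      }
      k <- k + 1L
      seqs[k] <- g
      clades[k] <- paste0("clade", a)
    }
  }
  names(seqs) <- ids
  truth <- data.frame(id = ids, clade = clades)
  truth <- truth[order(truth$id, method = "radix"), ]
  rownames(truth) <- NULL
  list(sequences = seqs, truth = truth)
}
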