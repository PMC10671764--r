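# Independent oracles, deliberately naive: these re-derive expected values
# by direct enumeration and never share code with the implementation.

# Rotation-sort BWT: build all n cyclic rotations, sort them bytewise,
# read the last character of each; rank = first sorted position of the
# original rotation.
naive_bwt <- function(s) {
  n <- nchar(s)
  rot <- substring(strrep(s, 2), seq_len(n), seq_len(n) + n - 1L)
  ord <- order(rot, method = "radix")
  sorted <- rot[ord]
  list(
    transform = paste(substring(sorted, n, n), collapse = ""),
    rank = min(which(sorted == rot[1])) - 1L
  )
}

# Brute-force pentamer hit count: test every window against the set.
naive_pentamer_count <- function(seq, pentamers, circular = FALSE) {
  n <- nchar(seq)
  if (circular) seq <- paste0(seq, substr(seq, 1, 4))
  last <- if (circular) n else n - 4L
  hits <- 0L
  for (i in seq_len(last)) {
    if (substr(seq, i, i + 4L) %in% pentamers) hits <- hits + 1L
  }
  hits
}

# Random string over an alphabet of the first k uppercase letters.
random_string <- function(n, k) {
  paste(sample(LETTERS[seq_len(k)], n, replace = TRUE), collapse = "")
}

# All strings of length n over an alphabet (character vector).
all_strings <- function(n, alphabet) {
  grid <- do.call(expand.grid, rep(list(alphabet), n))
  do.call(paste0, grid)
}

# 4-point configuration with two tight pairs, used by several graph tests:
# a,b close; c,d close; the pairs far apart.
two_pair_matrix <- function(within = 0.1, across = 0.9) {
  labs <- c("a", "b", "c", "d")
  m <- matrix(across, 4, 4, dimnames = list(labs, labs))
  m["a", "b"] <- m["b", "a"] <- within
  m["c", "d"] <- m["d", "c"] <- within
  diag(m) <- 0
  m
}
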