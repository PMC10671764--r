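test_that("random genomes are reproducible and compositionally uniform", {
  expect_identical(random_genome(8, seed = 1), random_genome(8, seed = 1))
  expect_equal(nchar(random_genome(1)), 1L)
  expect_error(random_genome(0), "at least 1")

  g <- random_genome(100000, seed = 2)
  freq <- table(strsplit(g, "")[[1]]) / nchar(g)
  expect_true(all(freq > 0.24 & freq < 0.26))
})

test_that("operators follow their defining identities", {
  expect_equal(apply_operator("ACGT", "circular_permutation", offset = 1),
               "CGTA")
  expect_equal(apply_operator("ACGT", "circular_permutation", offset = 0),
               "ACGT")
  # whole-sequence inversion of a reverse-complement palindrome is a no-op
  set.seed(3)
  expect_equal(apply_operator("ACGT", "inversion",
                              segment_length = c(4, 4)), "ACGT")
  # tandem repetition duplicates the segment in place
  set.seed(14)
  out <- apply_operator("ACGT", "repetition", segment_length = c(2, 2))
  expect_equal(nchar(out), 6L)
  expect_true(out %in% c("ACACGT", "ACGCGT", "ACGTGT"))

  expect_error(apply_operator("ACGT", "frobnicate"), "unknown operator")
  # insertion segment is new material, so any length fits
  expect_no_error(apply_operator("ACGT", "insertion",
                                 segment_length = c(10, 10)))
  expect_error(apply_operator("ACG", "deletion",
                              segment_length = c(10, 10)), "does not fit")
  expect_error(apply_operator("ACGT", "crossing_over"), "partner")
})

test_that("each operator's length bookkeeping holds over random events", {
  set.seed(21)
  keeps <- c("mutation", "inversion", "symmetrization",
             "circular_permutation")
  grows <- c("insertion", "repetition", "palindromization")
  for (i in 1:60) {
    s <- random_genome(sample(200:400, 1))
    op <- sample(setdiff(evo_operators(), "crossing_over"), 1)
    out <- apply_operator(s, op, segment_length = c(5, 50))
    if (op %in% keeps) expect_equal(nchar(out), nchar(s))
    if (op %in% grows) expect_gt(nchar(out), nchar(s))
    if (op == "deletion") expect_lt(nchar(out), nchar(s))
  }
})

test_that("mutation changes exactly one position", {
  set.seed(8)
  for (i in 1:20) {
    s <- random_genome(50)
    s2 <- apply_operator(s, "mutation")
    d <- which(strsplit(s, "")[[1]] != strsplit(s2, "")[[1]])
    expect_length(d, 1L)
  }
})

test_that("simulated phylogenies are reproducible with hidden labels", {
  cfg <- evo_config(n_ancestors = 2, clade_size = 3, genome_length = 500,
                    seed = 11)
  sim1 <- simulate_phylogeny(cfg)
  sim2 <- simulate_phylogeny(cfg)
  expect_identical(sim1, sim2)
  expect_length(sim1$sequences, 6L)
  expect_setequal(sim1$truth$id, names(sim1$sequences))
  expect_equal(unname(sort(table(sim1$truth$clade))), c(3L, 3L),
               ignore_attr = TRUE)
})

test_that("zero rates reproduce ancestors; heavy mutation erodes structure", {
  zero <- evo_config(n_ancestors = 2, clade_size = 3, genome_length = 300,
                     operator_rates = c(mutation = 0), seed = 5)
  sim <- simulate_phylogeny(zero)
  for (cl in unique(sim$truth$clade)) {
    ids <- sim$truth$id[sim$truth$clade == cl]
    expect_length(unique(sim$sequences[ids]), 1L)
  }

  light <- evo_config(n_ancestors = 2, clade_size = 3,
                      genome_length = 2000,
                      operator_rates = c(mutation = 20), seed = 6)
  heavy <- evo_config(n_ancestors = 2, clade_size = 3,
                      genome_length = 2000,
                      operator_rates = c(mutation = 600), seed = 6)
  gap <- function(cfg) {
    sim <- simulate_phylogeny(cfg)
    D <- ncd_matrix(sim$sequences)$values
    truth <- setNames(sim$truth$clade, sim$truth$id)
    same <- outer(truth, truth, "==")[names(truth), names(truth)]
    diag(same) <- NA
    v <- D[names(truth), names(truth)]
    mean(v[!same & !is.na(same)]) - mean(v[same & !is.na(same)])
  }
  expect_gt(gap(light), gap(heavy))  # divergence shrinks the margin
})

test_that("configs validate rates and recognize all eleven operators", {
  expect_length(evo_operators(), 11L)
  expect_error(evo_config(operator_rates = c(mutation = -1)), ">= 0")
  expect_error(evo_config(operator_rates = c(warp = 1)), "among")
  cfg <- evo_config(operator_rates = c(mutation = 5))
  expect_equal(unname(cfg$operator_rates["deletion"]), 0)
})
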