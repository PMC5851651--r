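# Hand-built miniature objects used across test files. Everything is
# constructed in code; no stored fixtures.

# A fully specified L = 3, q = 2 Potts model over alphabet {A, C} whose
# energies can be summed by hand.
hand_potts <- function() {
  h <- matrix(c(
    0.5, -0.5,   # position 1: A, C
    1.0,  0.0,   # position 2
    -1.0, 2.0),  # position 3
    nrow = 3, byrow = TRUE)
  J <- array(0, dim = c(3, 2, 2))
  # pair order: (1,2), (1,3), (2,3)
  J[1, , ] <- matrix(c(0.2, -0.1, 0.0, 0.3), 2, byrow = TRUE)
  J[2, , ] <- matrix(c(0.0, 0.5, -0.2, 0.1), 2, byrow = TRUE)
  J[3, , ] <- matrix(c(1.0, 0.0, 0.0, -1.0), 2, byrow = TRUE)
  potts_model(h, J, c("A", "C"))
}

# A tiny allele model with a constant-free 2x20 matrix whose peptide scores
# are easy to verify.
hand_pssm <- function(e_n = 3L, seed = 5L) {
  random_pssm(e_n = e_n, seed = seed, allele = sprintf("TEST-%d", seed))
}

# Write a small alignment FASTA and return its path.
write_test_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

# Toy problems used by several files: small enough for brute force.
toy_problem_for <- function(seed, ...) {
  make_toy_problem(toy_spec(seed = seed, ...))
}

expect_front_equal <- function(a, b, tol = 1e-6) {
  expect_equal(nrow(a$z), nrow(b$z))
  expect_lt(max(abs(a$z - b$z)), tol)
}
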