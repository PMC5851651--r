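test_that("PSSM files round-trip at full precision", {
  m <- random_pssm(e_n = 9, seed = 41)
  m$tau <- 3.14159
  path <- tempfile(fileext = ".tsv")
  write_pssm(m, path)
  back <- read_pssm(path, e_n = 9)
  expect_identical(back$phi, m$phi)
  expect_identical(back$tau, m$tau)
  expect_identical(back$allele, m$allele)
})

test_that("PSSM reader rejects malformed input", {
  m <- random_pssm(e_n = 8, seed = 42)
  path <- tempfile(fileext = ".tsv")
  write_pssm(m, path)
  expect_error(read_pssm(path, e_n = 9), "core length mismatch")
  # header missing
  lines <- readLines(path)
  writeLines(lines[-1], path)
  expect_error(read_pssm(path, e_n = 8), "allele")
})

test_that("z-normalization pools all cells and preserves peptide ordering", {
  m <- random_pssm(e_n = 9, seed = 43)
  zn <- znormalize(m)
  expect_equal(mean(zn$phi), 0, tolerance = 1e-9)
  expect_equal(sd(as.vector(zn$phi)), 1, tolerance = 1e-9)
  expect_error(znormalize(zn), "already")
  const <- allele_model("CONST", matrix(2, 9, 20,
                                        dimnames = list(NULL, aa_alphabet())))
  expect_error(znormalize(const), "zero-variance")
})

test_that("normalized peptide scores obey the affine identity", {
  set.seed(44)
  m <- random_pssm(e_n = 9, seed = 45)
  mu <- mean(m$phi)
  sigma <- sd(as.vector(m$phi))
  zn <- znormalize(m)
  for (i in 1:25) {
    pep <- paste(sample(aa_alphabet(), 9, replace = TRUE), collapse = "")
    raw <- peptide_score(m, pep)
    expect_equal(peptide_score(zn, pep), (raw - 9 * mu) / sigma,
                 tolerance = 1e-9)
  }
})

test_that("threshold transformation preserves epitope calls", {
  m <- random_pssm(e_n = 4, seed = 46)
  ctx <- paste(sample(aa_alphabet(), 30, replace = TRUE), collapse = "")
  m$tau <- binding_threshold(m, 80, "protein", ctx)
  zn <- znormalize(m)
  pop_raw <- hla_population(list(m), 0.5)
  pop_zn <- hla_population(list(zn), 0.5)
  raw_calls <- scan_epitopes(ctx, pop_raw)
  zn_calls <- scan_epitopes(ctx, pop_zn)
  expect_identical(raw_calls$start, zn_calls$start)
})

test_that("peptide scores sum matrix cells", {
  zero <- allele_model("Z", matrix(0, 3, 20,
                                   dimnames = list(NULL, aa_alphabet())))
  expect_equal(peptide_score(zero, "ACD"), 0)
  onehot <- allele_model("OH", {
    phi <- matrix(0, 3, 20, dimnames = list(NULL, aa_alphabet()))
    phi[1, "A"] <- 1; phi[2, "C"] <- 1; phi[3, "D"] <- 1
    phi
  })
  expect_equal(peptide_score(onehot, "ACD"), 3)
  expect_equal(peptide_score(onehot, "AAD"), 2)
  m <- random_pssm(e_n = 3, seed = 47)
  expect_equal(peptide_score(m, "WYK"),
               unname(m$phi[1, "W"] + m$phi[2, "Y"] + m$phi[3, "K"]))
  expect_error(peptide_score(m, "WY"), "length")
  expect_error(peptide_score(m, "WYX"), "bad symbol")
})

test_that("percentile thresholds come from the context window distribution", {
  m <- random_pssm(e_n = 9, seed = 48)
  set.seed(49)
  prot <- paste(sample(aa_alphabet(), 20, replace = TRUE), collapse = "")
  scores <- vapply(1:12, function(s) {
    peptide_score(m, substr(prot, s, s + 8))
  }, 0)
  expect_equal(binding_threshold(m, 50, "protein", prot),
               unname(quantile(scores, 0.5)))
  # percentile 100: the maximum; nothing scores strictly above it
  m$tau <- binding_threshold(m, 100, "protein", prot)
  pop <- hla_population(list(m), 1)
  expect_equal(nrow(scan_epitopes(prot, pop)), 0L)
  expect_error(binding_threshold(m, 95, "protein", "ACD"), "shorter")
})

test_that("uniform-random threshold mode is seeded and reproducible", {
  m <- random_pssm(e_n = 5, seed = 50)
  t1 <- binding_threshold(m, 95, "uniform-random", n_samples = 2000, seed = 7)
  t2 <- binding_threshold(m, 95, "uniform-random", n_samples = 2000, seed = 7)
  t3 <- binding_threshold(m, 95, "uniform-random", n_samples = 2000, seed = 8)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
})

test_that("a planted strong binder is the only window called", {
  set.seed(51)
  background <- paste(sample(aa_alphabet(), 50, replace = TRUE),
                      collapse = "")
  binder <- "WWWWYYYY"
  m <- random_pssm(e_n = 8, seed = 52, planted_binder = binder)
  seqfull <- paste0(substr(background, 1, 20), binder,
                    substr(background, 21, 40))
  m$tau <- max(deimmunize:::window_scores(m, seqfull)[-21]) + 1e-9
  pop <- hla_population(list(m), 1)
  calls <- scan_epitopes(seqfull, pop, offset = 1000L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 1020L)
  expect_true(all(calls$margin > 0))
})

test_that("immunogenicity is the population-weighted hinge sum", {
  m1 <- random_pssm(e_n = 4, seed = 53)
  m2 <- random_pssm(e_n = 4, seed = 54)
  set.seed(55)
  seqx <- paste(sample(aa_alphabet(), 10, replace = TRUE), collapse = "")
  m1$tau <- 1; m2$tau <- 0.5
  pop <- hla_population(list(m1, m2), c(0.7, 0.3))
  # hand computation over the 7 windows
  by_hand <- 0
  for (m_and_p in list(list(m1, 0.7), list(m2, 0.3))) {
    for (s in 1:7) {
      sc <- peptide_score(m_and_p[[1]], substr(seqx, s, s + 3))
      by_hand <- by_hand + m_and_p[[2]] * max(0, sc - m_and_p[[1]]$tau)
    }
  }
  expect_equal(immunogenicity_score(seqx, pop), by_hand, tolerance = 1e-12)
  expect_gte(immunogenicity_score(seqx, pop), 0)
  # empty population scores zero
  expect_equal(immunogenicity_score(seqx, hla_population(list(), numeric(0))), 0)
})

test_that("immunogenicity is allele-monotone and frequency-linear", {
  m1 <- random_pssm(e_n = 4, seed = 56)
  m2 <- random_pssm(e_n = 4, seed = 57)
  m1$tau <- 0; m2$tau <- 0
  set.seed(58)
  seqx <- paste(sample(aa_alphabet(), 12, replace = TRUE), collapse = "")
  base <- immunogenicity_score(seqx, hla_population(list(m1), 0.5))
  more <- immunogenicity_score(seqx, hla_population(list(m1, m2), c(0.5, 0.3)))
  expect_gte(more, base)
  # scaling all frequencies scales the score exactly
  half <- immunogenicity_score(seqx, hla_population(list(m1, m2),
                                                    c(0.25, 0.15)))
  expect_equal(half, more / 2, tolerance = 1e-12)
})

test_that("mutating far from every epitope window changes nothing", {
  # single called epitope at the right end; left-end mutations cannot touch
  # any window overlapping it
  binder <- "WWYY"
  m <- random_pssm(e_n = 4, seed = 60, planted_binder = binder)
  set.seed(61)
  left <- paste(sample(aa_alphabet(), 12, replace = TRUE), collapse = "")
  seqx <- paste0(left, binder)
  variants <- c(seqx, vapply(c("A", "K", "P"), function(aa) {
    paste0(aa, substr(seqx, 2, 16))
  }, ""))
  # threshold above every non-binder window of every variant, below the
  # planted binder window (position 13)
  other_scores <- unlist(lapply(variants, function(v) {
    deimmunize:::window_scores(m, v)[-13]
  }))
  m$tau <- max(other_scores) + 1e-6
  pop <- hla_population(list(m), 0.8)
  s0 <- immunogenicity_score(seqx, pop)
  expect_equal(scan_epitopes(seqx, pop)$start, 13L)
  for (v in variants[-1]) {
    expect_equal(scan_epitopes(v, pop)$start, 13L)
    expect_equal(immunogenicity_score(v, pop), s0, tolerance = 1e-12)
    expect_equal(epitope_count(v, pop), 1L)
  }
})

test_that("population frequencies are validated", {
  m <- random_pssm(e_n = 4, seed = 59)
  expect_error(hla_population(list(m), -0.1))
  expect_error(hla_population(list(m), 1.2))
  expect_error(scan_epitopes("ACDEFG", hla_population(list(m), 0.5)),
               "thresholds unset")
})
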