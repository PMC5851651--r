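test_that("read_alignment anchors focus columns on the target record", {
  path <- write_test_fasta(list(
    tgt = "AC-DEF-GHI",   # two gaps in ten columns
    s1  = "ACQDEFRGHI",
    s2  = "A--DE--GH-"))
  aln <- read_alignment(path, "fasta", target_id = "tgt", offset = 100L)
  expect_equal(alignment_length(aln), 8L)
  expect_equal(aln$target_positions, 100:107)
  # target is gap-free over focus columns by construction
  expect_false(any(deimmunize:::focus_matrix(aln)[aln$target_index, ] == "-"))
})

test_that("read_alignment errors on missing target and ragged input", {
  path <- write_test_fasta(list(a = "ACDE", b = "ACD"))
  expect_error(read_alignment(path, "fasta", target_id = "a"),
               "inconsistent")
  path2 <- write_test_fasta(list(a = "ACDE", b = "ACDF"))
  expect_error(read_alignment(path2, "fasta", target_id = "zz"),
               "not found")
})

test_that("a2m insert states are dropped before anchoring", {
  path <- write_test_fasta(list(
    tgt = "ACkkDEF",      # lowercase = insert relative to the model
    s1  = "AC..DEF"))
  aln <- read_alignment(path, "a2m", target_id = "tgt")
  expect_equal(alignment_length(aln), 5L)
  expect_equal(unname(deimmunize:::focus_matrix(aln)[2, ]),
               c("A", "C", "D", "E", "F"))
})

test_that("stockholm input is converted on read", {
  path <- tempfile(fileext = ".sto")
  writeLines(c(
    "# STOCKHOLM 1.0",
    "tgt   ACD",
    "s1    A-D",
    "",
    "tgt   EF-",
    "s1    EFG",
    "//"), path)
  aln <- read_alignment(path, "stockholm", target_id = "tgt")
  expect_equal(alignment_length(aln), 5L)
  expect_equal(nrow(aln$seqs), 2L)
})

test_that("filter_alignment applies the row >= and column > gap rules", {
  path <- write_test_fasta(list(
    tgt = "ACDEFGHIKL",
    bad = "A---------",  # 90% gaps: removed (>= 70%)
    ok1 = "ACDEFG---L",  # 30% gaps: kept
    ok2 = "-CDEFGHIKL",
    ok3 = "-CDEFGHIKL",
    ok4 = "-CDEFGHIKL"))
  aln <- read_alignment(path, "fasta", target_id = "tgt")
  filt <- filter_alignment(aln)
  expect_false("bad" %in% filt$ids)
  # column 1 has 4/5 gaps among survivors (> 50%): removed
  expect_equal(alignment_length(filt), 9L)
  expect_equal(filt$target_positions, 2:10)
})

test_that("filter_alignment is idempotent and errors when nothing survives", {
  prob <- write_test_fasta(list(
    tgt = "ACDEFGHIKL",
    s1 = "AC--------", s2 = "ACDEF-----", s3 = "----FGHIKL"))
  aln <- read_alignment(prob, "fasta", target_id = "tgt")
  once <- filter_alignment(aln)
  twice <- filter_alignment(once)
  expect_identical(once$focus_columns, twice$focus_columns)
  expect_identical(once$ids, twice$ids)
  # the target record is always retained, so an aggressive row rule leaves
  # exactly the target
  only_tgt <- filter_alignment(aln, max_row_gap = 1e-9)
  expect_identical(only_tgt$ids, "tgt")
})

test_that("survivor count matches a hand-filtered toy", {
  # 10 sequences over 10 focus columns with planned gap fractions
  gapfrac <- c(0, .1, .2, .3, .4, .5, .6, .7, .8, .9)
  recs <- lapply(gapfrac, function(g) {
    s <- rep("A", 10)
    if (g > 0) s[seq_len(round(10 * g))] <- "-"
    paste(s, collapse = "")
  })
  names(recs) <- sprintf("s%02d", seq_along(recs))
  recs <- c(list(tgt = "ACDEFGHIKL"), recs)
  aln <- read_alignment(write_test_fasta(recs), "fasta", "tgt")
  filt <- filter_alignment(aln, max_row_gap = 0.7, max_col_gap = 0.99)
  # rows with >= 70% gaps (0.7, 0.8, 0.9) are dropped; 8 survive (+ target)
  expect_equal(nrow(filt$seqs), 8L)
})

test_that("sequence weights implement inverse cluster sizes", {
  recs <- list(tgt = "ACDEFGHIKL")
  for (i in 1:4) recs[[paste0("dup", i)]] <- "ACDEFGHIKL"
  aln <- sequence_weights(read_alignment(write_test_fasta(recs), "fasta", "tgt"))
  expect_equal(unname(aln$weights), rep(1 / 5, 5))
  expect_equal(aln$meff, 1)

  # all pairwise identities below theta: every weight 1
  recs2 <- list(tgt = "AAAAAAAAAA", s1 = "CCCCCCCCCC", s2 = "DDDDDDDDDD")
  aln2 <- sequence_weights(read_alignment(write_test_fasta(recs2), "fasta", "tgt"))
  expect_equal(unname(aln2$weights), rep(1, 3))
  expect_equal(aln2$meff, 3)
})

test_that("Meff is invariant under duplicating the alignment", {
  prob <- make_toy_problem(toy_spec(seed = 3))
  aln <- gibbs_sample(random_potts(8, 4, seed = 3), 40, burn_in = 30, seed = 4)
  w1 <- sequence_weights(aln, theta = 0.8)
  dup <- aln
  dup$seqs <- rbind(aln$seqs, aln$seqs)
  dup$ids <- c(aln$ids, paste0(aln$ids, "_copy"))
  w2 <- sequence_weights(dup, theta = 0.8)
  expect_equal(w2$meff, w1$meff, tolerance = 1e-9)
  expect_equal(unname(w2$weights[seq_len(40)]), unname(w1$weights / 2),
               tolerance = 1e-12)
})

test_that("site frequencies match hand-weighted counts", {
  recs <- list(tgt = "AC", s1 = "AC", s2 = "GC", s3 = "GT", s4 = "-T")
  aln <- read_alignment(write_test_fasta(recs), "fasta", "tgt")
  aln$weights <- c(0.5, 0.5, 1, 1, 2)   # hand-set weights
  f <- site_frequencies(aln)
  expect_equal(sum(f$f[1, ]), 1)
  expect_equal(unname(f$f[1, "A"]), 1 / 5)      # (0.5 + 0.5) / 5
  expect_equal(unname(f$f[1, "G"]), 2 / 5)
  expect_equal(unname(f$f[1, "-"]), 2 / 5)
  expect_equal(unname(f$f[2, "C"]), 2 / 5)
  expect_equal(unname(f$f[2, "T"]), 3 / 5)

  single <- read_alignment(write_test_fasta(list(tgt = "AC")), "fasta", "tgt")
  fs <- site_frequencies(sequence_weights(single))
  expect_equal(unname(fs$f[1, "A"]), 1)
  expect_equal(unname(fs$f[2, "C"]), 1)
})

test_that("mutation sets apply the conservation threshold and keep the wild type", {
  f <- matrix(0, 1, 4, dimnames = list(NULL, c("A", "G", "T", "-")))
  f[1, ] <- c(0.6, 0.3, 0.1, 0)
  freqs <- structure(list(f = f, alphabet = colnames(f),
                          target_positions = 1L),
                     class = "site_frequencies")
  ms <- mutation_sets(freqs, "T", zeta = 0.25)
  expect_setequal(ms$M[[1]], c("A", "G", "T"))
  expect_equal(ms$M[[1]][1], "T")   # wild type first

  # zeta = 1 with no unanimous column: wild type only
  ms1 <- mutation_sets(freqs, "T", zeta = 1.0)
  expect_equal(ms1$M[[1]], "T")
  # zeta = 0: everything observed plus wild type
  ms0 <- mutation_sets(freqs, "C", zeta = 0)
  expect_setequal(ms0$M[[1]], c("C", "A", "G", "T"))
})

test_that("gaps are renormalized out of mutation-set frequencies", {
  f <- matrix(c(0.3, 0.1, 0, 0.6), 1, 4,
              dimnames = list(NULL, c("A", "G", "T", "-")))
  freqs <- structure(list(f = f, alphabet = colnames(f),
                          target_positions = 1L),
                     class = "site_frequencies")
  # A has renormalized frequency 0.75, G 0.25; gap never allowed
  ms <- mutation_sets(freqs, "A", zeta = 0.3)
  expect_equal(sort(ms$M[[1]]), c("A"))
  ms2 <- mutation_sets(freqs, "A", zeta = 0.2)
  expect_setequal(ms2$M[[1]], c("A", "G"))
  expect_false("-" %in% ms2$M[[1]])
})

test_that("larger zeta gives nested candidate sets", {
  aln <- gibbs_sample(random_potts(6, 4, seed = 9), 60, burn_in = 30, seed = 10)
  aln <- sequence_weights(aln)
  freqs <- site_frequencies(aln)
  wt <- apply(deimmunize:::focus_matrix(aln), 2, function(col) col[1])
  zetas <- c(0, 0.1, 0.3, 0.6)
  sets <- lapply(zetas, function(z) mutation_sets(freqs, wt, z))
  for (zi in seq_along(zetas)[-1]) {
    for (i in 1:6) {
      expect_true(all(sets[[zi]]$M[[i]] %in% sets[[zi - 1]]$M[[i]]))
    }
  }
  # invariant: wild type always a member
  for (s in sets) for (i in 1:6) expect_true(wt[i] %in% s$M[[i]])
})
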