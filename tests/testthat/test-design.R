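make_small_problem <- function(seed = 5, ...) {
  make_toy_problem(toy_spec(seed = seed, ...))
}

test_that("variable counts follow the candidate-set sizes", {
  # n = 5, two candidates everywhere: 10 x-vars and 40 w-vars (10 pairs)
  model <- random_potts(5, 4, seed = 91)
  wt <- model$alphabet[c(1, 2, 3, 4, 1)]
  M <- lapply(1:5, function(i) c(wt[i], setdiff(model$alphabet, wt[i])[1]))
  m <- random_pssm(e_n = 3, seed = 92)
  m$tau <- 0
  pop <- hla_population(list(m), 0.5)
  prob <- design_problem(wt, M, k = 2, pop, model)
  inst <- build_instance(prob)
  expect_equal(nrow(inst$xvars), 10L)
  expect_equal(nrow(inst$wvars), 40L)
  # one C1 row per position, one C4 row
  classes <- vapply(inst$constraints, `[[`, "", "class")
  expect_equal(sum(classes == "C1"), 5L)
  expect_equal(sum(classes == "C4"), 1L)
})

test_that("an all-wild-type problem has a single feasible point", {
  model <- random_potts(6, 3, seed = 93)
  wt <- model$alphabet[c(1, 2, 3, 1, 2, 3)]
  M <- as.list(wt)
  m <- random_pssm(e_n = 3, seed = 94)
  m$tau <- binding_threshold(m, 50, "protein", paste(wt, collapse = ""))
  pop <- hla_population(list(m), 0.6)
  prob <- design_problem(wt, M, k = 2, pop, model)
  inst <- build_instance(prob)
  sol <- solve_single(inst, "z1")
  expect_equal(sol$sequence, paste(wt, collapse = ""))
  expect_equal(nrow(sol$mutations), 0L)
  front <- solve_pareto(inst)
  expect_equal(nrow(front$z), 1L)
})

test_that("the wild-type assignment reproduces the plain-sequence objectives", {
  prob <- make_small_problem(11)
  inst <- build_instance(prob)
  wt_choice <- inst$compiled$wt
  sol <- decode(inst, wt_choice)
  wtseq <- paste(prob$wild_type, collapse = "")
  expect_equal(unname(sol$z["z1"]),
               immunogenicity_score(wtseq, prob$population),
               tolerance = 1e-9)
  expect_equal(unname(sol$z["z2"]),
               -statistical_energy(prob$model, wtseq), tolerance = 1e-9)
  # symbolic objective evaluation agrees too (certifies the Table encoding)
  vals <- deimmunize:::symbolic_assignment(inst, wt_choice)
  zs <- deimmunize:::symbolic_objectives(inst, vals)
  expect_equal(unname(zs), unname(sol$z), tolerance = 1e-9)
  expect_true(all(deimmunize:::check_constraints(inst, vals)))
})

test_that("symbolic objectives and constraints hold at arbitrary assignments", {
  set.seed(95)
  for (seed in c(12, 13)) {
    prob <- make_small_problem(seed)
    inst <- build_instance(prob)
    for (trial in 1:5) {
      free <- inst$free
      # start from the wild type and mutate at most k random positions
      choice <- inst$compiled$wt
      mutable <- which(lengths(prob$M[free]) > 1L)
      flip <- sample(mutable, min(prob$k, length(mutable)))
      for (f in flip) {
        alts <- setdiff(seq_along(prob$M[[free[f]]]), choice[f])
        choice[f] <- sample(alts, 1L)
      }
      sol <- decode(inst, choice)
      vals <- deimmunize:::symbolic_assignment(inst, choice)
      zs <- deimmunize:::symbolic_objectives(inst, vals)
      expect_equal(unname(zs), unname(sol$z), tolerance = 1e-9)
      ok <- deimmunize:::check_constraints(inst, vals)
      expect_true(all(ok), info = paste("violated:",
                                        paste(names(ok)[!ok], collapse = " ")))
    }
  }
})

test_that("relaxed linking rows are satisfied by optimal integral designs", {
  prob <- make_small_problem(14)
  exact <- build_instance(prob)
  relaxed <- build_instance(prob, relaxed_linking = TRUE)
  f_ex <- solve_pareto(exact)
  f_rx <- solve_pareto(relaxed)
  # optimal objective values agree between the two formulations
  expect_front_equal(f_ex, f_rx)
  # the sign-split inequality rows hold at every solver solution
  for (p in f_rx$points) {
    choice <- vapply(relaxed$free, function(i) {
      match(substr(p$sequence, i, i), prob$M[[i]])
    }, 0L)
    vals <- deimmunize:::symbolic_assignment(relaxed, choice)
    expect_true(all(deimmunize:::check_constraints(relaxed, vals)))
  }
})

test_that("solve_single matches exhaustive enumeration", {
  for (seed in c(21, 22, 23)) {
    prob <- make_small_problem(seed)
    inst <- build_instance(prob)
    bf <- brute_force_pareto(prob)
    s1 <- solve_single(inst, "z1")
    s2 <- solve_single(inst, "z2")
    expect_equal(unname(s1$z["z1"]), min(bf$z[, 1]), tolerance = 1e-9)
    expect_equal(unname(s2$z["z2"]), min(bf$z[, 2]), tolerance = 1e-9)
  }
})

test_that("k = 0 pins the design to the wild type", {
  prob <- make_small_problem(24, k = 0)
  inst <- build_instance(prob)
  sol <- solve_single(inst, "z2")
  expect_equal(sol$sequence, paste(prob$wild_type, collapse = ""))
  front <- brute_force_pareto(prob)
  expect_equal(nrow(front$z), 1L)
})

test_that("a box excluding all feasible points reports infeasibility", {
  prob <- make_small_problem(25)
  inst <- build_instance(prob)
  sol <- solve_single(inst, "z1",
                      box = rectangle(c(-Inf, -1e9), c(Inf, -1e9 - 1)))
  expect_null(sol)
})

test_that("decode rejects inconsistent assignments", {
  prob <- make_small_problem(26)
  inst <- build_instance(prob)
  # two x set at one position
  ids <- inst$xvars$id[inst$xvars$i == inst$free[1]]
  assign <- setNames(numeric(nrow(inst$xvars)), inst$xvars$id)
  assign[ids[1:2]] <- 1
  other <- setdiff(seq_len(prob$n), inst$free[1])
  assign[sprintf("x_%d_%s", other, prob$wild_type[other])] <- 1
  expect_error(decode(inst, assign), "C1 violated")
  # solver-reported objective that does not match the decoded sequence
  expect_error(decode(inst, inst$compiled$wt, solver_z = c(-999, -999)),
               "objective mismatch")
})

test_that("solver solutions respect the budget and are proven optimal", {
  for (seed in c(27, 28)) {
    prob <- make_small_problem(seed, k = 1)
    inst <- build_instance(prob)
    front <- solve_pareto(inst)
    for (p in front$points) {
      expect_lte(nrow(p$mutations), 1L)
    }
  }
})

test_that("LP export lists every variable and constraint", {
  prob <- make_small_problem(29)
  inst <- build_instance(prob)
  path <- tempfile(fileext = ".lp")
  write_lp(inst, path, "z2")
  txt <- readLines(path)
  expect_true(any(grepl("^Minimize", txt)))
  body <- paste(txt, collapse = "\n")
  for (id in sample(inst$xvars$id, 3)) {
    expect_true(grepl(id, body, fixed = TRUE))
  }
  expect_equal(sum(grepl("^ (C|H)", txt)), length(inst$constraints))
})

test_that("build_instance validates thresholds and model alignment", {
  prob <- make_small_problem(30)
  prob$population$alleles[[1]]$tau <- NA_real_
  expect_error(build_instance(prob), "thresholds unset")
  model <- random_potts(4, 4, seed = 96)
  m <- random_pssm(e_n = 3, seed = 97); m$tau <- 0
  expect_error(
    design_problem(c("A", "C", "D"), list("A", "C", "D"), 1,
                   hla_population(list(m), 0.5), model),
    "length")
})
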