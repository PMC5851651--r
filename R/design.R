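# The bi-objective mixed-integer encoding of the de-immunization problem:
# binary selection variables x[i,a], pairing variables w[i,j,a,b], hinge
# slacks for the immunogenicity objective, constraints C1-C4, plus a
# compiled evaluation form consumed by the exact branch-and-bound backend.

#' Define a de-immunization design problem
#'
#' @param wild_type Wild-type sequence (string or character vector) of
#'   length `n`, aligned to the Potts model.
#' @param msets A `mutation_sets` object (or plain list of allowed residue
#'   vectors per position, each containing the wild type).
#' @param k Maximum number of positions where a design may differ from the
#'   wild type.
#' @param population An `hla_population` with binding thresholds set.
#' @param model A `potts_model` of length `n`.
#' @param offset Protein numbering of position 1 (default taken from
#'   `msets` when available).
#' @return Object of class `design_problem`.
#' @export
design_problem <- function(wild_type, msets, k, population, model,
                           offset = NULL) {
  wt <- if (length(wild_type) == 1L) seq_chars(wild_type) else wild_type
  n <- length(wt)
  if (inherits(msets, "mutation_sets")) {
    M <- msets$M
    if (is.null(offset)) offset <- msets$target_positions[1]
  } else {
    M <- msets
  }
  if (is.null(offset)) offset <- 1L
  stopifnot(length(M) == n, k >= 0)
  for (i in seq_len(n)) {
    if (!(wt[i] %in% M[[i]])) {
      stop("wild-type residue not in candidate set at position ", i)
    }
  }
  if (model$L != n) {
    stop("Potts model length ", model$L, " != sequence length ", n)
  }
  structure(list(wild_type = wt, M = M, k = as.integer(k),
                 population = population, model = model,
                 offset = as.integer(offset), n = n,
                 e_n = population$e_n),
            class = "design_problem")
}

#' @export
print.design_problem <- function(x, ...) {
  nfree <- sum(lengths(x$M) > 1L)
  cat(sprintf(
    "design_problem: n = %d (%d mutable), k = %d, %d alleles, e_n = %d\n",
    x$n, nfree, x$k, length(x$population$alleles), x$e_n))
  invisible(x)
}

#' Build the mixed-integer instance of a design problem
#'
#' Constructs the full symbolic program — binary `x[i,a]` per candidate
#' residue, `w[i,j,a,b]` per residue pair (pairs of two immutable positions
#' are folded into a constant), continuous hinge slacks `y[h,win]` for the
#' immunogenicity objective, the one-residue-per-position rows (C1), the
#' `w`-to-`x` linking rows (C2/C3, exact equalities by default or the
#' sign-split relaxation behind `relaxed_linking`), and the mutation budget
#' row (C4) — together with a compiled evaluation form used by the exact
#' branch-and-bound backend.
#'
#' With the default `fitness_sense = "neg_energy"` the second objective is
#' `z2 = -E(S')`, so minimizing it maximizes statistical energy (fitness);
#' `"table"` flips the sign. The constant energy contribution of immutable
#' positions is folded into `z2`, so reported values are full-sequence
#' energies comparable across designs.
#'
#' @param problem A `design_problem`.
#' @param relaxed_linking Use the positive/negative sign-split relaxation of
#'   the linking constraints instead of exact equalities (single-objective
#'   safe only; default `FALSE`).
#' @param fitness_sense `"neg_energy"` (default) or `"table"`.
#' @return Object of class `design_instance`.
#' @export
build_instance <- function(problem, relaxed_linking = FALSE,
                           fitness_sense = c("neg_energy", "table")) {
  fitness_sense <- match.arg(fitness_sense)
  ssign <- if (fitness_sense == "neg_energy") -1 else 1
  pop <- problem$population
  check_thresholds(pop)
  n <- problem$n
  M <- problem$M
  wt <- problem$wild_type
  model <- problem$model
  e_n <- problem$e_n
  if (n < e_n) stop("sequence shorter than epitope core length")
  free <- which(lengths(M) > 1L)
  nf <- length(free)

  # ---- compiled evaluation form ---------------------------------------
  aidx <- lapply(M, function(m) encode_seq(m, model$alphabet))
  wt_idx <- encode_seq(wt, model$alphabet)
  # constant energy: fields of immutable positions (compiled form only; the
  # symbolic form carries fields on the x variables) and couplings of
  # immutable-immutable pairs (folded into a constant in both forms)
  imm <- setdiff(seq_len(n), free)
  e_const_fields <- sum(model$h[cbind(imm, wt_idx[imm])])
  e_const_pairs <- 0
  if (length(imm) >= 2L) {
    for (a in seq_along(imm)[-length(imm)]) {
      for (b in (a + 1L):length(imm)) {
        i <- imm[a]; j <- imm[b]
        e_const_pairs <- e_const_pairs + get_J(model, i, j)[wt_idx[i], wt_idx[j]]
      }
    }
  }
  e_const <- e_const_fields + e_const_pairs
  field <- vector("list", nf)
  for (fidx in seq_len(nf)) {
    i <- free[fidx]
    hv <- model$h[i, aidx[[i]]]
    for (j in imm) {
      hv <- hv + get_J(model, i, j)[aidx[[i]], wt_idx[j]]
    }
    field[[fidx]] <- ssign * hv
  }
  pair_tab <- NULL
  pairJ <- list()
  if (nf >= 2L) {
    fp <- all_pairs(nf)
    pair_tab <- fp
    pairJ <- vector("list", nrow(fp))
    for (p in seq_len(nrow(fp))) {
      i <- free[fp[p, 1]]; j <- free[fp[p, 2]]
      pairJ[[p]] <- ssign *
        get_J(model, i, j)[aidx[[i]], aidx[[j]], drop = FALSE]
    }
  } else {
    pair_tab <- matrix(integer(0), ncol = 2)
  }
  # windows: per allele, every full-length window of the whole sequence
  nw <- n - e_n + 1L
  windows <- list()
  z1const <- 0
  for (al in seq_along(pop$alleles)) {
    m <- pop$alleles[[al]]
    p_h <- pop$p[[al]]
    for (s in seq_len(nw)) {
      posns <- s:(s + e_n - 1L)
      slots_pos <- intersect(posns, free)
      fixed <- 0
      for (j in setdiff(posns, slots_pos)) {
        fixed <- fixed + m$phi[j - s + 1L, wt[j]]
      }
      if (length(slots_pos) == 0L) {
        z1const <- z1const + p_h * max(0, fixed - m$tau)
      } else {
        contrib <- lapply(slots_pos, function(j) {
          unname(m$phi[j - s + 1L, M[[j]]])
        })
        windows[[length(windows) + 1L]] <- list(
          base = fixed - m$tau, weight = p_h,
          allele = m$allele, start = s,
          slots = match(slots_pos, free), contrib = contrib)
      }
    }
  }
  compiled <- list(
    nf = nf, k = min(problem$k, nf),
    nopt = lengths(M)[free],
    wt = vapply(seq_len(nf), function(f) match(wt[free[f]], M[[free[f]]]), 0L),
    field = field, pairs = pair_tab, pairJ = pairJ,
    z2const = ssign * e_const, z1const = z1const,
    windows = windows)

  # ---- symbolic variables and constraint registry ---------------------
  xv <- data.frame(
    i = rep(seq_len(n), lengths(M)),
    a = unlist(M, use.names = FALSE),
    stringsAsFactors = FALSE)
  xv$id <- sprintf("x_%d_%s", xv$i, xv$a)
  wlist <- list()
  ap <- all_pairs(n)
  for (p in seq_len(nrow(ap))) {
    i <- ap[p, 1]; j <- ap[p, 2]
    if (length(M[[i]]) == 1L && length(M[[j]]) == 1L) next
    grid <- expand.grid(a = M[[i]], b = M[[j]],
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$i <- i; grid$j <- j
    wlist[[length(wlist) + 1L]] <- grid
  }
  wv <- if (length(wlist)) do.call(rbind, wlist) else
    data.frame(a = character(0), b = character(0),
               i = integer(0), j = integer(0))
  if (nrow(wv)) {
    wv$id <- sprintf("w_%d_%d_%s_%s", wv$i, wv$j, wv$a, wv$b)
    wv$coef <- ssign * mapply(function(i, j, a, b) {
      get_J(model, i, j)[match(a, model$alphabet), match(b, model$alphabet)]
    }, wv$i, wv$j, wv$a, wv$b)
  } else {
    wv$id <- character(0); wv$coef <- numeric(0)
  }
  # fields ride on x; couplings of pairs with at least one free position on
  # their w variables; immutable-immutable couplings in the constant
  xv$coef <- ssign * model$h[cbind(xv$i, match(xv$a, model$alphabet))]
  constraints <- list()
  add_con <- function(name, class, vars, coefs, sense, rhs) {
    constraints[[length(constraints) + 1L]] <<- list(
      name = name, class = class, vars = vars, coefs = coefs,
      sense = sense, rhs = rhs)
  }
  for (i in seq_len(n)) {
    ids <- xv$id[xv$i == i]
    add_con(sprintf("C1_%d", i), "C1", ids, rep(1, length(ids)), "=", 1)
  }
  if (nrow(wv)) {
    for (key in unique(paste(wv$i, wv$j))) {
      sub <- wv[paste(wv$i, wv$j) == key, , drop = FALSE]
      i <- sub$i[1]; j <- sub$j[1]
      if (!relaxed_linking) {
        for (a in unique(sub$a)) {
          ids <- sub$id[sub$a == a]
          add_con(sprintf("C2_%d_%d_%s", i, j, a), "C2",
                  c(ids, sprintf("x_%d_%s", i, a)),
                  c(rep(1, length(ids)), -1), "=", 0)
        }
        for (b in unique(sub$b)) {
          ids <- sub$id[sub$b == b]
          add_con(sprintf("C3_%d_%d_%s", i, j, b), "C3",
                  c(ids, sprintf("x_%d_%s", j, b)),
                  c(rep(1, length(ids)), -1), "=", 0)
        }
      } else {
        for (r in seq_len(nrow(sub))) {
          wid <- sub$id[r]
          xa <- sprintf("x_%d_%s", i, sub$a[r])
          xb <- sprintf("x_%d_%s", j, sub$b[r])
          if (sub$coef[r] >= 0) {
            add_con(paste0("C2p_", wid), "C2", c(wid, xa, xb),
                    c(1, -1, -1), ">=", -1)
          } else {
            add_con(paste0("C2n1_", wid), "C2", c(wid, xa), c(1, -1), "<=", 0)
            add_con(paste0("C2n2_", wid), "C3", c(wid, xb), c(1, -1), "<=", 0)
          }
        }
      }
    }
  }
  wt_ids <- sprintf("x_%d_%s", seq_len(n), wt)
  add_con("C4", "C4", wt_ids, rep(-1, n), "<=", problem$k - n)
  # hinge rows: y_h_win >= sum(phi * x) + fixed - tau
  yv <- NULL
  if (length(windows)) {
    yv <- data.frame(
      id = vapply(windows, function(w)
        sprintf("y_%s_%d", gsub("[^A-Za-z0-9]", "", w$allele), w$start), ""),
      allele = vapply(windows, `[[`, "", "allele"),
      start = vapply(windows, function(w) w$start, 0L),
      weight = vapply(windows, function(w) w$weight, 0),
      stringsAsFactors = FALSE)
    for (widx in seq_along(windows)) {
      w <- windows[[widx]]
      vars <- yv$id[widx]
      coefs <- 1
      for (sidx in seq_along(w$slots)) {
        i <- free[w$slots[sidx]]
        vars <- c(vars, sprintf("x_%d_%s", i, M[[i]]))
        coefs <- c(coefs, -w$contrib[[sidx]])
      }
      add_con(sprintf("H_%s", yv$id[widx]), "hinge", vars, coefs,
              ">=", w$base)
    }
  }
  structure(list(
    problem = problem, compiled = compiled,
    free = free, relaxed_linking = relaxed_linking,
    fitness_sense = fitness_sense, ssign = ssign,
    xvars = xv, wvars = wv, yvars = yv,
    constraints = constraints,
    e_const = e_const, e_const_pairs = e_const_pairs, z1const = z1const
  ), class = "design_instance")
}

#' @export
print.design_instance <- function(x, ...) {
  cat(sprintf(
    "design_instance: %d x-vars, %d w-vars, %d hinge slacks, %d constraints\n",
    nrow(x$xvars), nrow(x$wvars),
    if (is.null(x$yvars)) 0L else nrow(x$yvars), length(x$constraints)))
  invisible(x)
}

# ---------------------------------------------------------------------------

unbounded_box <- function() c(-Inf, Inf, -Inf, Inf)

#' Proven-optimal single-objective solve
#'
#' Minimizes one of the two objectives over the feasible designs whose
#' objective vector lies in a rectangle, optionally with an extra upper
#' bound on the other objective (the epsilon-constraint used by the
#' lexicographic step). Backends plug in via S3; the default backend is the
#' package's exact branch-and-bound.
#'
#' @param instance A `design_instance` (or any object with a
#'   `solve_single` method).
#' @param objective `"z1"` (immunogenicity) or `"z2"` (fitness objective).
#' @param box A [rectangle()] restricting `(z1, z2)`, or `NULL` for
#'   unbounded.
#' @param extra_bound Optional `list(objective =, value =)` upper bound.
#' @param ... Passed to methods.
#' @return A `solution_point` (see [decode()]) or `NULL` when the box
#'   contains no feasible design (status infeasible).
#' @export
solve_single <- function(instance, objective = c("z1", "z2"), box = NULL,
                         extra_bound = NULL, ...) {
  UseMethod("solve_single")
}

box_vector <- function(box, extra_bound) {
  bv <- if (is.null(box)) unbounded_box() else
    c(box$corner1[1], box$corner2[1], box$corner2[2], box$corner1[2])
  if (!is.null(extra_bound)) {
    if (extra_bound$objective == "z1") {
      bv[2] <- min(bv[2], extra_bound$value)
    } else {
      bv[4] <- min(bv[4], extra_bound$value)
    }
  }
  bv
}

#' @export
solve_single.design_instance <- function(instance,
                                         objective = c("z1", "z2"),
                                         box = NULL, extra_bound = NULL,
                                         ...) {
  objective <- match.arg(objective)
  bv <- box_vector(box, extra_bound)
  res <- bb_solve_cpp(instance$compiled, if (objective == "z1") 1L else 2L,
                      bv)
  if (res$status == "infeasible") return(NULL)
  decode(instance, res$assign, solver_z = c(res$z1, res$z2))
}

#' Decode a solver assignment into a design
#'
#' Rebuilds the mutant sequence from the per-free-position choices, checks
#' the one-residue-per-position and mutation-budget constraints, and
#' independently recomputes both objectives from the plain sequence
#' (sliding-window hinge immunogenicity; full Potts energy). A mismatch
#' beyond 1e-6 against the solver-reported objective values is an error —
#' this certifies the hinge linearization and the linking constraints.
#'
#' @param instance A `design_instance`.
#' @param assignment Either an integer vector of 1-based choices per free
#'   position, or a named 0/1 vector over the `x` variable ids.
#' @param solver_z Optional `(z1, z2)` reported by the backend to verify.
#' @return Object of class `solution_point`: objective pair `z`, decoded
#'   `sequence`, `mutations` data frame (protein numbering), `status`.
#' @export
decode <- function(instance, assignment, solver_z = NULL) {
  problem <- instance$problem
  free <- instance$free
  M <- problem$M
  seq <- problem$wild_type
  if (!is.null(names(assignment))) {
    on <- names(assignment)[assignment > 0.5]
    on_x <- grep("^x_", on, value = TRUE)
    parts <- regmatches(on_x, regexec("^x_(\\d+)_(.+)$", on_x))
    pos <- vapply(parts, function(p) as.integer(p[2]), 0L)
    aa <- vapply(parts, function(p) p[3], "")
    if (anyDuplicated(pos) || length(pos) != problem$n) {
      stop("inconsistent assignment: C1 violated (", length(pos),
           " selections for ", problem$n, " positions)")
    }
    seq[pos] <- aa
  } else {
    choice <- as.integer(assignment)
    if (length(choice) != length(free)) {
      stop("assignment length ", length(choice), " != number of free positions ",
           length(free))
    }
    for (f in seq_along(free)) {
      if (choice[f] < 1L || choice[f] > length(M[[free[f]]])) {
        stop("assignment index out of range at free position ", f)
      }
      seq[free[f]] <- M[[free[f]]][choice[f]]
    }
  }
  n_mut <- sum(seq != problem$wild_type)
  if (n_mut > problem$k) {
    stop("decoded sequence violates mutation budget: ", n_mut, " > ",
         problem$k)
  }
  z1 <- immunogenicity_score(chars_to_string(seq), problem$population)
  z2 <- instance$ssign * statistical_energy(problem$model,
                                            chars_to_string(seq))
  if (!is.null(solver_z)) {
    if (max(abs(c(z1, z2) - solver_z)) > 1e-6) {
      stop(sprintf(
        "objective mismatch: solver (%.9g, %.9g) vs recomputed (%.9g, %.9g)",
        solver_z[1], solver_z[2], z1, z2))
    }
  }
  mpos <- which(seq != problem$wild_type)
  mutations <- data.frame(
    pos = mpos + problem$offset - 1L,
    wt = problem$wild_type[mpos],
    new = seq[mpos], stringsAsFactors = FALSE)
  structure(list(z = c(z1 = z1, z2 = z2),
                 sequence = chars_to_string(seq),
                 mutations = mutations,
                 status = "optimal"),
            class = "solution_point")
}

#' @export
print.solution_point <- function(x, ...) {
  cat(sprintf("solution_point: z1 = %.6g, z2 = %.6g, %s\n",
              x$z["z1"], x$z["z2"], mutation_string(x)))
  invisible(x)
}

#' Mutation string of a design (e.g. "V2333E" or "wt")
#' @param point A `solution_point`.
#' @return Character scalar.
#' @export
mutation_string <- function(point) {
  m <- point$mutations
  if (is.null(m) || nrow(m) == 0L) return("wt")
  paste(sprintf("%s%d%s", m$wt, m$pos, m$new), collapse = ",")
}

#' Export the symbolic program in LP text format
#'
#' Writes the chosen objective and the full constraint registry in the
#' conventional LP file format for inspection with external tools.
#'
#' @param instance A `design_instance`.
#' @param path Output path.
#' @param objective `"z1"` or `"z2"`.
#' @return Invisibly, `path`.
#' @export
write_lp <- function(instance, path, objective = c("z1", "z2")) {
  objective <- match.arg(objective)
  con <- file(path, "w")
  on.exit(close(con))
  term <- function(coefs, vars) {
    paste(sprintf("%+.12g %s", coefs, vars), collapse = " ")
  }
  writeLines("Minimize", con)
  if (objective == "z1") {
    if (is.null(instance$yvars) || nrow(instance$yvars) == 0L) {
      writeLines(" obj: 0 x_dummy", con)
    } else {
      writeLines(paste(" obj:",
                       term(instance$yvars$weight, instance$yvars$id)), con)
    }
  } else {
    writeLines(paste(" obj:",
                     term(c(instance$xvars$coef, instance$wvars$coef),
                          c(instance$xvars$id, instance$wvars$id))), con)
  }
  writeLines("Subject To", con)
  for (cn in instance$constraints) {
    sense <- switch(cn$sense, "=" = "=", ">=" = ">=", "<=" = "<=")
    writeLines(sprintf(" %s: %s %s %.12g", cn$name,
                       term(cn$coefs, cn$vars), sense, cn$rhs), con)
  }
  writeLines("Binary", con)
  writeLines(paste("", paste(c(instance$xvars$id, instance$wvars$id),
                             collapse = " ")), con)
  writeLines("End", con)
  invisible(path)
}

# Evaluate the symbolic objective/constraints at a full assignment derived
# from per-free-position choices (used by tests to certify the encoding).
symbolic_assignment <- function(instance, choice) {
  problem <- instance$problem
  M <- problem$M
  free <- instance$free
  seq <- problem$wild_type
  for (f in seq_along(free)) seq[free[f]] <- M[[free[f]]][choice[f]]
  xval <- setNames(numeric(nrow(instance$xvars)), instance$xvars$id)
  xval[sprintf("x_%d_%s", seq_len(problem$n), seq)] <- 1
  wval <- setNames(numeric(nrow(instance$wvars)), instance$wvars$id)
  if (nrow(instance$wvars)) {
    sel <- sprintf("w_%d_%d_%s_%s", instance$wvars$i, instance$wvars$j,
                   seq[instance$wvars$i], seq[instance$wvars$j]) ==
      instance$wvars$id
    wval[sel] <- 1
  }
  yval <- NULL
  if (!is.null(instance$yvars)) {
    wins <- instance$compiled$windows
    yval <- setNames(vapply(seq_along(wins), function(widx) {
      w <- wins[[widx]]
      v <- w$base
      for (sidx in seq_along(w$slots)) {
        i <- free[w$slots[sidx]]
        v <- v + w$contrib[[sidx]][match(seq[i], M[[i]])]
      }
      max(0, v)
    }, 0), instance$yvars$id)
  }
  c(xval, wval, yval)
}

symbolic_objectives <- function(instance, values) {
  z1 <- instance$z1const
  if (!is.null(instance$yvars) && nrow(instance$yvars)) {
    z1 <- z1 + sum(instance$yvars$weight * values[instance$yvars$id])
  }
  z2 <- instance$ssign * instance$e_const_pairs +
    sum(instance$xvars$coef * values[instance$xvars$id])
  if (nrow(instance$wvars)) {
    z2 <- z2 + sum(instance$wvars$coef * values[instance$wvars$id])
  }
  c(z1 = z1, z2 = unname(z2))
}

check_constraints <- function(instance, values, tol = 1e-9) {
  ok <- vapply(instance$constraints, function(cn) {
    lhs <- sum(cn$coefs * values[cn$vars])
    switch(cn$sense,
           "=" = abs(lhs - cn$rhs) <= tol,
           ">=" = lhs >= cn$rhs - tol,
           "<=" = lhs <= cn$rhs + tol)
  }, TRUE)
  names(ok) <- vapply(instance$constraints, `[[`, "", "name")
  ok
}
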