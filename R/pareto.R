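# Exact bi-objective solving: lexicographic minimization, Pareto-front
# boundaries, phase-1 epsilon-slicing and phase-2 rectangle splitting, with
# a deterministic parallel-execution contract.

#' Objective-space rectangle
#'
#' The rectangle spanned by two points: `corner1` is the top-left corner
#' (smallest z1, largest z2) and `corner2` the bottom-right. Feasible
#' designs are restricted to `z1 in [corner1[1], corner2[1]]` and
#' `z2 in [corner2[2], corner1[2]]`; infinite corners are allowed.
#'
#' @param corner1,corner2 Numeric `(z1, z2)` pairs.
#' @return Object of class `rectangle`.
#' @export
rectangle <- function(corner1 = c(-Inf, Inf), corner2 = c(Inf, -Inf)) {
  stopifnot(length(corner1) == 2L, length(corner2) == 2L)
  if (corner1[1] > corner2[1] || corner2[2] > corner1[2]) {
    stop("invalid rectangle: need corner1 z1 <= corner2 z1 and corner2 z2 <= corner1 z2")
  }
  structure(list(corner1 = as.numeric(corner1),
                 corner2 = as.numeric(corner2)),
            class = "rectangle")
}

point_z <- function(point) unname(point$z)

same_point <- function(a, b, delta = 1e-6) {
  all(abs(point_z(a) - point_z(b)) <= delta)
}

#' Lexicographic minimization within a rectangle
#'
#' The sequential operation that yields a nondominated point of the box:
#' minimize the primary objective over the rectangle, then minimize the
#' secondary objective subject to the primary staying within `delta` of its
#' optimum.
#'
#' @param instance A design instance (any object with a [solve_single()]
#'   method).
#' @param primary `"z1"` or `"z2"`.
#' @param rect A [rectangle()] or `NULL` for unbounded.
#' @param delta Tolerance tying the second stage to the first-stage
#'   optimum; also the duplicate tolerance of the front.
#' @return A `solution_point`, or `NULL` when the rectangle is infeasible.
#' @export
lexmin <- function(instance, primary = c("z1", "z2"), rect = NULL,
                   delta = 1e-6) {
  primary <- match.arg(primary)
  secondary <- if (primary == "z1") "z2" else "z1"
  s1 <- solve_single(instance, primary, box = rect)
  if (is.null(s1)) return(NULL)
  cap <- unname(s1$z[primary]) + delta
  s2 <- solve_single(instance, secondary, box = rect,
                     extra_bound = list(objective = primary, value = cap))
  if (is.null(s2)) {
    # impossible by construction: s1 satisfies the stage-2 constraints
    stop("internal error: lexmin stage 2 infeasible after feasible stage 1")
  }
  s2
}

#' Pareto front boundaries
#'
#' The two endpoints of the front: `z_T` (lexicographically best in z1,
#' then z2) and `z_B` (best in z2, then z1), both over the unbounded
#' rectangle. The two solves are independent and may run concurrently.
#'
#' @inheritParams lexmin
#' @param workers Number of parallel workers for the two solves.
#' @return List with elements `z_T` and `z_B` (`solution_point`s).
#' @export
compute_boundaries <- function(instance, delta = 1e-6, workers = 1L) {
  res <- worker_lapply(list("z1", "z2"), function(primary) {
    lexmin(instance, primary, rect = NULL, delta = delta)
  }, workers)
  if (is.null(res[[1]]) || is.null(res[[2]])) stop("infeasible instance")
  list(z_T = res[[1]], z_B = res[[2]])
}

#' Phase 1: evenly sliced initial points
#'
#' Divides the z1 range between the boundary points into `m` evenly spaced
#' slice boundaries and solves one lexicographic minimization per
#' boundary, each restricted to `z1 <= tau_i` and solved z2-first. This
#' epsilon-constraint orientation guarantees every returned point is
#' globally nondominated (any dominator would itself satisfy the z1 bound
#' and beat the lexicographic optimum), so the result is a possibly
#' incomplete subset of the Pareto front that always contains the bottom
#' boundary `z_B`.
#'
#' @inheritParams lexmin
#' @param z_T,z_B Boundary points from [compute_boundaries()].
#' @param m Number of slices (`>= 1`).
#' @param workers Parallel workers; slices are independent.
#' @return List of `solution_point`s sorted by increasing z1.
#' @export
phase1_slices <- function(instance, z_T, z_B, m, delta = 1e-6,
                          workers = 1L) {
  stopifnot(m >= 1L)
  zT <- point_z(z_T); zB <- point_z(z_B)
  if (abs(zB[1] - zT[1]) <= delta) {
    return(dedupe_points(list(z_B), delta))
  }
  taus <- zT[1] + seq_len(m) * (zB[1] - zT[1]) / m
  taus <- pmin(pmax(taus, zT[1]), zB[1])
  pts <- worker_lapply(as.list(taus), function(tau) {
    lexmin(instance, "z2",
           rect = rectangle(c(zT[1], zT[2]), c(tau, zB[2])),
           delta = delta)
  }, workers)
  pts <- Filter(Negate(is.null), pts)
  pts <- c(pts, list(z_B))
  attr_calls <- m
  out <- dedupe_points(pts, delta)
  attr(out, "lexmin_calls") <- attr_calls
  out
}

dedupe_points <- function(points, delta = 1e-6) {
  if (length(points) <= 1L) return(points)
  zs <- t(vapply(points, point_z, numeric(2)))
  ord <- order(zs[, 1], zs[, 2])
  points <- points[ord]
  zs <- zs[ord, , drop = FALSE]
  keep <- rep(TRUE, length(points))
  for (i in seq_along(points)[-1]) {
    prev <- max(which(keep[seq_len(i - 1L)]))
    if (all(abs(zs[i, ] - zs[prev, ]) <= delta)) keep[i] <- FALSE
  }
  points[keep]
}

# Remove dominated points (minimization in both objectives).
nondominated <- function(points, delta = 0) {
  if (length(points) <= 1L) return(points)
  zs <- t(vapply(points, point_z, numeric(2)))
  ord <- order(zs[, 1], zs[, 2])
  points <- points[ord]
  zs <- zs[ord, , drop = FALSE]
  best_z2 <- Inf
  keep <- logical(length(points))
  for (i in seq_along(points)) {
    if (zs[i, 2] < best_z2 - delta) {
      keep[i] <- TRUE
      best_z2 <- zs[i, 2]
    }
  }
  points[keep]
}

#' Search the rectangle between two adjacent nondominated points
#'
#' One step of the rectangle-splitting recursion: the rectangle spanned by
#' adjacent points `z_i`, `z_j` is halved at the mean z2; the bottom half
#' is searched z1-first, and the top half — restricted to the left of any
#' bottom discovery by `eps` — z2-first. Rediscovering the corner points
#' proves the corresponding half empty; newly found points spawn child
#' rectangles.
#'
#' @inheritParams lexmin
#' @param z_i,z_j Adjacent nondominated points with `z_i$z[1] <= z_j$z[1]`.
#' @param eps Exclusion offset on z1 separating the two halves.
#' @return List with `new_points`, `children` (list of point pairs) and
#'   `lexmin_calls`.
#' @export
split_rectangle <- function(instance, z_i, z_j, delta = 1e-6, eps = 1e-6) {
  zi <- point_z(z_i); zj <- point_z(z_j)
  if (same_point(z_i, z_j, delta)) {
    return(list(new_points = list(), children = list(), lexmin_calls = 0L))
  }
  mid <- (zi[2] + zj[2]) / 2
  calls <- 1L
  zb <- lexmin(instance, "z1",
               rect = rectangle(c(zi[1], mid), c(zj[1], zj[2])),
               delta = delta)
  if (is.null(zb)) {
    # cannot happen: z_j lies in the bottom half by construction
    stop("internal error: bottom half infeasible although z_j is inside")
  }
  new_bottom <- !same_point(zb, z_j, delta)
  top_u1 <- point_z(zb)[1] - eps
  zt <- NULL
  if (top_u1 >= zi[1] && zi[2] >= mid) {
    calls <- calls + 1L
    zt <- lexmin(instance, "z2",
                 rect = rectangle(c(zi[1], zi[2]), c(top_u1, mid)),
                 delta = delta)
  }
  new_top <- !is.null(zt) && !same_point(zt, z_i, delta)
  new_points <- list()
  children <- list()
  if (new_top) {
    new_points <- c(new_points, list(zt))
    children <- c(children, list(list(z_i, zt)))
  }
  if (new_bottom) {
    new_points <- c(new_points, list(zb))
    children <- c(children, list(list(zb, z_j)))
  }
  list(new_points = new_points, children = children, lexmin_calls = calls)
}

worker_lapply <- function(x, f, workers = 1L) {
  if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(x, f, mc.cores = workers)
  } else {
    lapply(x, f)
  }
}

#' Exact Pareto front by parallel two-phase rectangle splitting
#'
#' Computes the complete nondominated set of the bi-objective design
#' problem: boundary points first, then `m` evenly spaced
#' epsilon-constraint slices as an initial approximation, then recursive
#' rectangle splitting between adjacent points until every rectangle is
#' proven empty. Rectangles and slices are independent work items, so the
#' result is independent of the number of workers and of processing order.
#'
#' @inheritParams lexmin
#' @param m Number of phase-1 slices; defaults to the number of workers.
#' @param workers Parallel workers (forked; 1 = sequential).
#' @param eps Exclusion offset on z1 between rectangle halves. Front
#'   points closer than `eps`/`delta` in an objective may merge; both are
#'   configurable.
#' @return Object of class `pareto_front`: `points` (list of
#'   `solution_point`s, increasing z1, decreasing z2), matrix `z`, and
#'   `stats` (lexicographic solver calls, rectangles explored).
#' @export
solve_pareto <- function(instance, m = NULL, workers = 1L,
                         delta = 1e-6, eps = 1e-6) {
  workers <- max(1L, as.integer(workers))
  if (is.null(m)) m <- workers
  m <- max(1L, as.integer(m))
  calls <- 2L
  bounds <- compute_boundaries(instance, delta, workers)
  z_T <- bounds$z_T; z_B <- bounds$z_B
  if (same_point(z_T, z_B, delta)) {
    return(new_pareto_front(list(z_T), stats = list(
      lexmin_calls = calls, rectangles = 0L, phase1_points = 1L),
      delta = delta, eps = eps))
  }
  p1 <- phase1_slices(instance, z_T, z_B, m, delta, workers)
  calls <- calls + m
  points <- dedupe_points(c(list(z_T), p1), delta)
  points <- nondominated(points)
  n_phase1 <- length(points)
  gaps <- adjacent_gaps(points)
  n_rect <- 0L
  while (length(gaps)) {
    res <- worker_lapply(gaps, function(g) {
      split_rectangle(instance, g[[1]], g[[2]], delta, eps)
    }, workers)
    n_rect <- n_rect + length(gaps)
    calls <- calls + sum(vapply(res, `[[`, 0L, "lexmin_calls"))
    new_pts <- unlist(lapply(res, `[[`, "new_points"), recursive = FALSE)
    points <- nondominated(dedupe_points(c(points, new_pts), delta))
    children <- unlist(lapply(res, `[[`, "children"), recursive = FALSE)
    gaps <- canonical_gaps(children, points, delta)
  }
  new_pareto_front(points, stats = list(
    lexmin_calls = calls, rectangles = n_rect,
    phase1_points = n_phase1), delta = delta, eps = eps)
}

adjacent_gaps <- function(points) {
  if (length(points) < 2L) return(list())
  lapply(seq_len(length(points) - 1L), function(i) {
    list(points[[i]], points[[i + 1L]])
  })
}

# Deterministic ordering/dedup of child rectangles: keyed on the z-vectors
# of their corner points, sorted by left corner.
canonical_gaps <- function(children, points, delta) {
  if (length(children) == 0L) return(list())
  keys <- vapply(children, function(g) {
    paste(sprintf("%.9e", c(point_z(g[[1]]), point_z(g[[2]]))),
          collapse = "|")
  }, "")
  children <- children[!duplicated(keys)]
  lefts <- vapply(children, function(g) point_z(g[[1]])[1], 0)
  children[order(lefts)]
}

new_pareto_front <- function(points, stats, delta, eps) {
  points <- dedupe_points(points, delta)
  z <- t(vapply(points, point_z, numeric(2)))
  colnames(z) <- c("z1", "z2")
  structure(list(points = points, z = z, stats = stats,
                 delta = delta, eps = eps),
            class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("pareto_front: %d nondominated designs\n", length(x$points)))
  print(utils::head(as.data.frame(x), 10))
  if (length(x$points) > 10L) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.pareto_front <- function(x, ...) {
  data.frame(
    z1 = x$z[, 1], z2 = x$z[, 2],
    mutations = vapply(x$points, function(p) {
      if (is.null(p$mutations)) NA_character_ else mutation_string(p)
    }, ""),
    stringsAsFactors = FALSE)
}

#' Brute-force Pareto front by exhaustive enumeration
#'
#' Testing oracle: enumerates every mutant within the mutation budget,
#' evaluates both objectives directly on the plain sequences, and extracts
#' the nondominated set. Refuses search spaces larger than `limit`.
#'
#' @param problem A `design_problem`.
#' @param limit Maximum number of candidate sequences (default 200000).
#' @param fitness_sense Sign convention for z2, as in [build_instance()].
#' @return A `pareto_front`.
#' @export
brute_force_pareto <- function(problem, limit = 200000L,
                               fitness_sense = c("neg_energy", "table")) {
  fitness_sense <- match.arg(fitness_sense)
  ssign <- if (fitness_sense == "neg_energy") -1 else 1
  M <- problem$M
  wt <- problem$wild_type
  free <- which(lengths(M) > 1L)
  k <- min(problem$k, length(free))
  alts <- lapply(free, function(i) setdiff(M[[i]], wt[i]))
  n_alt <- lengths(alts)
  # count candidates: sum over subsets S of free, |S| <= k, of prod(n_alt)
  count <- 1
  if (k >= 1L && length(free)) {
    for (size in seq_len(k)) {
      combs <- utils::combn(length(free), size)
      count <- count + sum(apply(combs, 2L, function(s) prod(n_alt[s])))
    }
  }
  if (count > limit) {
    stop("search space of ", count, " candidates exceeds limit ", limit)
  }
  e_wt <- statistical_energy(problem$model, chars_to_string(wt))
  z1_wt <- immunogenicity_score(chars_to_string(wt), problem$population)
  eval_candidate <- function(pos, aa) {
    seq <- wt
    seq[pos] <- aa
    mut <- data.frame(pos = pos, aa = aa)
    z2 <- ssign * (e_wt + mutation_effect(problem$model, wt, mut))
    z1 <- immunogenicity_score(chars_to_string(seq), problem$population)
    structure(list(
      z = c(z1 = z1, z2 = z2), sequence = chars_to_string(seq),
      mutations = data.frame(pos = pos + problem$offset - 1L,
                             wt = wt[pos], new = aa,
                             stringsAsFactors = FALSE),
      status = "enumerated"), class = "solution_point")
  }
  points <- list(structure(list(
    z = c(z1 = z1_wt, z2 = ssign * e_wt),
    sequence = chars_to_string(wt),
    mutations = data.frame(pos = integer(0), wt = character(0),
                           new = character(0)),
    status = "enumerated"), class = "solution_point"))
  if (k >= 1L && length(free)) {
    for (size in seq_len(k)) {
      combs <- utils::combn(length(free), size)
      for (ci in seq_len(ncol(combs))) {
        sel <- combs[, ci]
        grid <- expand.grid(alts[sel], KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
        for (g in seq_len(nrow(grid))) {
          points[[length(points) + 1L]] <-
            eval_candidate(free[sel], as.character(grid[g, ]))
        }
      }
    }
  }
  front <- nondominated(dedupe_points(points, 1e-9))
  new_pareto_front(front, stats = list(candidates = count),
                   delta = 1e-9, eps = 0)
}

# ---------------------------------------------------------------------------
# Enumerated-point backend: a drop-in instance over an explicit finite set
# of objective vectors, used to test the Pareto logic independently of the
# MILP machinery.

#' Explicit point-set instance (testing backend)
#'
#' An instance whose feasible objective vectors are given explicitly; the
#' [solve_single()] method minimizes over the listed points. Demonstrates
#' the pluggable backend contract and lets the Pareto logic be exercised
#' against enumerable ground truth.
#'
#' @param z Numeric matrix with columns `(z1, z2)`.
#' @return Object of class `enum_instance`.
#' @export
enum_instance <- function(z) {
  z <- as.matrix(z)
  stopifnot(ncol(z) == 2L)
  structure(list(z = z), class = "enum_instance")
}

#' @export
solve_single.enum_instance <- function(instance, objective = c("z1", "z2"),
                                       box = NULL, extra_bound = NULL,
                                       ...) {
  objective <- match.arg(objective)
  bv <- box_vector(box, extra_bound)
  z <- instance$z
  tol <- 1e-9
  ok <- z[, 1] >= bv[1] - tol & z[, 1] <= bv[2] + tol &
    z[, 2] >= bv[3] - tol & z[, 2] <= bv[4] + tol
  if (!any(ok)) return(NULL)
  idx <- which(ok)
  col <- if (objective == "z1") 1L else 2L
  best <- idx[which.min(z[idx, col])]
  structure(list(z = c(z1 = z[best, 1], z2 = z[best, 2]),
                 sequence = NULL,
                 mutations = NULL,
                 status = "optimal"), class = "solution_point")
}
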