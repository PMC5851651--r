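# Reporting: per-design changes versus the wild type, fitness-landscape
# percentiles, and tabular/FASTA export of a Pareto front.

#' Percent change of each design versus the wild type
#'
#' `100 * (z - z_wt) / |z_wt|` per objective. When a wild-type objective
#' is (numerically) zero the absolute difference is reported instead and
#' the corresponding `*_absolute` flag is set.
#'
#' @param front A `pareto_front`.
#' @param wild_type_point A `solution_point` for the wild type (e.g. from
#'   [decode()] of the all-wild-type assignment).
#' @return Data frame with columns `mutations`, `pct_immunogenicity`,
#'   `pct_fitness_objective` and the two absolute-scale flags.
#' @export
percent_change <- function(front, wild_type_point) {
  zw <- point_z(wild_type_point)
  change <- function(z, w) {
    if (abs(w) > 1e-12) 100 * (z - w) / abs(w) else z - w
  }
  data.frame(
    mutations = vapply(front$points, mutation_string, ""),
    pct_immunogenicity = vapply(front$z[, 1], change, 0, w = zw[1]),
    pct_fitness_objective = vapply(front$z[, 2], change, 0, w = zw[2]),
    immunogenicity_absolute = abs(zw[1]) <= 1e-12,
    fitness_absolute = abs(zw[2]) <= 1e-12,
    stringsAsFactors = FALSE)
}

#' Percentile of a design within the mutant fitness landscape
#'
#' Ranks a design's statistical-energy change against the landscape of all
#' single mutants (exhaustive) and, for higher loads, sampled double/triple
#' mutants. The percentile is the fraction of landscape mutants with an
#' energy change at or below the design's, per mutation load.
#'
#' @param model A `potts_model`.
#' @param wild_type Wild-type sequence of model length.
#' @param k_max Highest mutation load to rank against (1..3).
#' @param design_effect The design's `E(mutant) - E(wild type)`.
#' @param sample_budget Mutants sampled per load beyond singles (>= 100).
#' @param seed RNG seed for the sampled landscapes.
#' @param exhaustive Force exhaustive enumeration also for double/triple
#'   landscapes (toys only).
#' @return Named numeric vector of percentiles, one per load `1..k_max`.
#' @export
landscape_percentile <- function(model, wild_type, k_max = 3L,
                                 design_effect, sample_budget = 10000L,
                                 seed = 1L, exhaustive = FALSE) {
  stopifnot(k_max >= 1L)
  if (!exhaustive && sample_budget < 100L) {
    stop("sample_budget below 100 gives meaningless percentiles")
  }
  wt <- if (length(wild_type) == 1L) seq_chars(wild_type) else wild_type
  L <- model$L
  alts <- lapply(seq_len(L), function(i) setdiff(model$alphabet, wt[i]))
  single_effects <- unlist(lapply(seq_len(L), function(i) {
    vapply(alts[[i]], function(a) {
      mutation_effect(model, wt, data.frame(pos = i, aa = a))
    }, 0)
  }))
  landscapes <- list(`1` = single_effects)
  if (k_max >= 2L) {
    with_seed(seed, {
      for (load in 2L:k_max) {
        if (exhaustive) {
          combs <- utils::combn(L, load)
          eff <- c()
          for (ci in seq_len(ncol(combs))) {
            sel <- combs[, ci]
            grid <- expand.grid(lapply(sel, function(i) alts[[i]]),
                                KEEP.OUT.ATTRS = FALSE,
                                stringsAsFactors = FALSE)
            eff <- c(eff, vapply(seq_len(nrow(grid)), function(g) {
              mutation_effect(model, wt,
                              data.frame(pos = sel,
                                         aa = as.character(grid[g, ])))
            }, 0))
          }
        } else {
          eff <- vapply(seq_len(sample_budget), function(s) {
            sel <- sample.int(L, load)
            aa <- vapply(sel, function(i) sample(alts[[i]], 1L), "")
            mutation_effect(model, wt, data.frame(pos = sel, aa = aa))
          }, 0)
        }
        landscapes[[as.character(load)]] <- eff
      }
    })
  }
  vapply(landscapes, function(eff) {
    100 * mean(eff <= design_effect)
  }, 0)
}

#' Tabulate a Pareto front against its wild type
#'
#' One row per design with the mutation string (protein numbering), the
#' predicted epitope count, and the changes in immunogenicity and fitness
#' objective versus the wild type. Sign convention: `delta_I` is
#' `z1(design) - z1(wt)` (negative = de-immunized); `delta_fitness` is
#' `z2(design) - z2(wt)` on the instance's fitness-objective scale, so
#' positive values are fitness losses under the default sense.
#'
#' @param front A `pareto_front` of decoded designs.
#' @param problem The `design_problem` that produced it.
#' @param wild_type_point Optional precomputed wild-type `solution_point`.
#' @return Data frame (`id`, `mutations`, `epitopes`, `delta_I`,
#'   `delta_fitness`, `z1`, `z2`).
#' @export
design_report <- function(front, problem, wild_type_point = NULL) {
  if (is.null(wild_type_point)) {
    wtseq <- chars_to_string(problem$wild_type)
    wild_type_point <- structure(list(
      z = c(z1 = immunogenicity_score(wtseq, problem$population),
            z2 = -statistical_energy(problem$model, wtseq)),
      sequence = wtseq,
      mutations = data.frame(pos = integer(0), wt = character(0),
                             new = character(0)),
      status = "wild-type"), class = "solution_point")
  }
  zw <- point_z(wild_type_point)
  epi <- vapply(front$points, function(p) {
    epitope_count(p$sequence, problem$population)
  }, 0L)
  data.frame(
    id = seq_along(front$points) - 1L,
    mutations = vapply(front$points, mutation_string, ""),
    epitopes = epi,
    delta_I = front$z[, 1] - zw[1],
    delta_fitness = front$z[, 2] - zw[2],
    z1 = front$z[, 1],
    z2 = front$z[, 2],
    stringsAsFactors = FALSE)
}

#' Write a Pareto front as TSV and FASTA
#'
#' The TSV mirrors the design-report layout (a header line states the sign
#' convention of the fitness column); the FASTA carries the mutation
#' strings in its headers.
#'
#' @param front A `pareto_front`.
#' @param problem The `design_problem`.
#' @param tsv,fasta Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report data frame.
#' @export
write_front <- function(front, problem, tsv = NULL, fasta = NULL) {
  rep <- design_report(front, problem)
  if (!is.null(tsv)) {
    con <- file(tsv, "w")
    writeLines(paste(
      "# delta_fitness = z2(design) - z2(wt); z2 minimizes the negative",
      "statistical energy, so positive values are predicted fitness losses"),
      con)
    write.table(rep, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(fasta)) {
    headers <- sprintf(">design_%d %s", rep$id, rep$mutations)
    seqs <- vapply(front$points, function(p) {
      if (is.null(p$sequence)) "" else p$sequence
    }, "")
    writeLines(paste0(headers, "\n", seqs), fasta)
  }
  invisible(rep)
}
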