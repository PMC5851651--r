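# HLA class II epitope scoring: per-allele position-specific scoring
# matrices, z-score normalization, binding thresholds, sliding-window
# scanning and the population-weighted hinge-loss immunogenicity objective.

#' Construct an allele binding model
#'
#' A TEPITOPE-style linear binding model for one HLA class II allele: a
#' matrix `phi[j, a]` of binding contributions per core position `j`
#' (1..`e_n`) and residue `a`; a peptide of length `e_n` scores
#' `sum_j phi[j, peptide[j]]`. A peptide is called an epitope when its
#' score strictly exceeds the binding threshold `tau`.
#'
#' @param allele Allele name, e.g. `"DRB1*15:01"`.
#' @param phi Numeric `e_n x 20` matrix, columns named by the standard
#'   amino acids.
#' @param tau Binding threshold on the same scale as peptide scores
#'   (`NA` until calibrated, see [binding_threshold()]).
#' @param normalized Whether `phi` has been z-score normalized.
#' @param norm_params List `(mean, sd)` recorded by [znormalize()].
#' @return Object of class `allele_model`.
#' @export
allele_model <- function(allele, phi, tau = NA_real_,
                         normalized = FALSE, norm_params = NULL) {
  stopifnot(is.matrix(phi), all(is.finite(phi)))
  if (is.null(colnames(phi))) colnames(phi) <- aa_alphabet()
  stopifnot(identical(sort(colnames(phi)), sort(aa_alphabet())))
  phi <- phi[, aa_alphabet(), drop = FALSE]
  structure(list(allele = allele, phi = phi, e_n = nrow(phi), tau = tau,
                 normalized = normalized, norm_params = norm_params),
            class = "allele_model")
}

#' @export
print.allele_model <- function(x, ...) {
  cat(sprintf("allele_model %s: core length %d, %s, tau = %s\n",
              x$allele, x$e_n,
              if (x$normalized) "z-normalized" else "raw",
              if (is.na(x$tau)) "unset" else format(x$tau)))
  invisible(x)
}

#' Read / write an allele PSSM as TSV
#'
#' File format: a comment line `# allele: NAME` (and, when present,
#' `# tau: VALUE`, `# normalized: TRUE/FALSE`), then a header `pos` plus the
#' 20 amino-acid one-letter codes, then one row per core position. Values
#' are written at full double precision, so the round trip is exact.
#'
#' @param path File path.
#' @param e_n Expected core length; a file with a different number of rows
#'   is an error (default 9).
#' @return `read_pssm` returns an `allele_model`; `write_pssm` the path,
#'   invisibly.
#' @export
read_pssm <- function(path, e_n = 9L) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0L) return(NULL)
    trimws(sub(paste0("^#\\s*", key, ":"), "", ln[1]))
  }
  allele <- get_field("allele")
  if (is.null(allele)) stop("malformed PSSM: missing '# allele:' header")
  tab <- read.delim(text = lines[!startsWith(lines, "#")],
                    check.names = FALSE)
  if (!identical(names(tab)[1], "pos")) {
    stop("malformed PSSM: first column must be 'pos'")
  }
  aas <- names(tab)[-1]
  if (!setequal(aas, aa_alphabet())) {
    stop("unknown or missing amino acid columns: ",
         paste(symdiff_chr(aas, aa_alphabet()), collapse = " "))
  }
  if (nrow(tab) != e_n) {
    stop("core length mismatch: file has ", nrow(tab),
         " rows, expected e_n = ", e_n)
  }
  phi <- as.matrix(tab[, aa_alphabet(), drop = FALSE])
  rownames(phi) <- NULL
  tau <- get_field("tau")
  normalized <- isTRUE(as.logical(get_field("normalized")))
  allele_model(allele, phi,
               tau = if (is.null(tau)) NA_real_ else as.numeric(tau),
               normalized = normalized)
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' @rdname read_pssm
#' @param model An `allele_model`.
#' @export
write_pssm <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# allele: %s", model$allele), con)
  if (!is.na(model$tau)) {
    writeLines(sprintf("# tau: %.17g", model$tau), con)
  }
  writeLines(sprintf("# normalized: %s", model$normalized), con)
  writeLines(paste(c("pos", aa_alphabet()), collapse = "\t"), con)
  for (j in seq_len(model$e_n)) {
    writeLines(paste(c(j, sprintf("%.17g", model$phi[j, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Z-score normalize an allele matrix
#'
#' Transforms every cell to `(phi - mu) / sigma` with `mu`, `sigma` pooled
#' over all cells of this allele's matrix, making scores comparable across
#' alleles. A previously set threshold is transformed consistently,
#' `tau -> (tau - e_n * mu) / sigma`, so epitope calls are preserved.
#'
#' @param model An `allele_model`, not yet normalized.
#' @return The normalized `allele_model`.
#' @export
znormalize <- function(model) {
  if (model$normalized) stop("matrix already normalized")
  mu <- mean(model$phi)
  sigma <- sd(as.vector(model$phi))
  if (sigma == 0) stop("zero-variance matrix cannot be normalized")
  model$phi <- (model$phi - mu) / sigma
  if (!is.na(model$tau)) model$tau <- (model$tau - model$e_n * mu) / sigma
  model$normalized <- TRUE
  model$norm_params <- list(mean = mu, sd = sigma)
  model
}

#' Score a single peptide
#'
#' @param model An `allele_model`.
#' @param peptide Peptide of length `e_n` (string or character vector).
#' @return Numeric score `sum_j phi[j, peptide[j]]`.
#' @export
peptide_score <- function(model, peptide) {
  p <- if (length(peptide) == 1L) seq_chars(peptide) else peptide
  if (length(p) != model$e_n) {
    stop("peptide length ", length(p), " != core length ", model$e_n)
  }
  a <- match(p, colnames(model$phi))
  if (anyNA(a)) stop("bad symbol in peptide: ", paste(p[is.na(a)], collapse = " "))
  sum(model$phi[cbind(seq_len(model$e_n), a)])
}

# Scores of all e_n-windows of a sequence for one allele; vectorized.
window_scores <- function(model, seq) {
  s <- if (length(seq) == 1L) seq_chars(seq) else seq
  n <- length(s)
  e_n <- model$e_n
  if (n < e_n) stop("sequence shorter than core length")
  a <- match(s, colnames(model$phi))
  if (anyNA(a)) stop("bad symbol in sequence: ",
                     paste(unique(s[is.na(a)]), collapse = " "))
  nw <- n - e_n + 1L
  sc <- numeric(nw)
  for (j in seq_len(e_n)) {
    sc <- sc + model$phi[j, a[j:(j + nw - 1L)]]
  }
  sc
}

#' Calibrate a binding threshold
#'
#' The threshold `tau` is the stated percentile of the allele's score
#' distribution, taken either over all `e_n`-windows of a context protein
#' (mode `"protein"`, reproducing a whole-protein epitope screen) or over
#' uniformly random peptides (mode `"uniform-random"`, seeded).
#'
#' @param model An `allele_model`.
#' @param percentile Percentile in (0, 100); default 95.
#' @param background `"protein"` or `"uniform-random"`.
#' @param context Context protein sequence (required for mode
#'   `"protein"`).
#' @param n_samples Number of random peptides for mode
#'   `"uniform-random"`.
#' @param seed RNG seed for mode `"uniform-random"`.
#' @return The threshold, a numeric scalar. Assign it with
#'   `model$tau <- ...` or use [calibrate_population()].
#' @export
binding_threshold <- function(model, percentile = 95,
                              background = c("protein", "uniform-random"),
                              context = NULL, n_samples = 10000L,
                              seed = 1L) {
  stopifnot(percentile > 0, percentile <= 100)
  background <- match.arg(background)
  if (background == "protein") {
    if (is.null(context)) stop("mode 'protein' requires a context sequence")
    sc <- window_scores(model, context)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    pep <- matrix(sample(aa_alphabet(), n_samples * model$e_n,
                         replace = TRUE), n_samples, model$e_n)
    a <- match(pep, colnames(model$phi))
    dim(a) <- dim(pep)
    sc <- numeric(n_samples)
    for (j in seq_len(model$e_n)) sc <- sc + model$phi[j, a[, j]]
  }
  quantile(sc, percentile / 100, names = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Define a target population
#'
#' @param alleles List of `allele_model`s.
#' @param p Numeric allele frequencies, same length/order as `alleles` (or
#'   named by allele); must be nonnegative and sum to at most 1.
#' @return Object of class `hla_population`.
#' @export
hla_population <- function(alleles, p) {
  names <- vapply(alleles, `[[`, "", "allele")
  if (!is.null(names(p))) p <- p[names]
  p <- as.numeric(p)
  stopifnot(length(p) == length(alleles), all(p >= 0),
            sum(p) <= 1 + 1e-9)
  e_n <- unique(vapply(alleles, `[[`, 0L, "e_n"))
  if (length(e_n) > 1L) stop("alleles have differing core lengths")
  structure(list(alleles = alleles, p = setNames(p, names),
                 e_n = if (length(alleles)) e_n else 9L),
            class = "hla_population")
}

#' @export
print.hla_population <- function(x, ...) {
  cat(sprintf("hla_population: %d alleles (total frequency %.3f)\n",
              length(x$alleles), sum(x$p)))
  invisible(x)
}

#' Calibrate thresholds for every allele of a population
#'
#' @param population An `hla_population`.
#' @inheritParams binding_threshold
#' @return The population with all `tau` set.
#' @export
calibrate_population <- function(population, percentile = 95,
                                 background = "protein", context = NULL,
                                 n_samples = 10000L, seed = 1L) {
  population$alleles <- lapply(population$alleles, function(m) {
    m$tau <- binding_threshold(m, percentile, background, context,
                               n_samples, seed)
    m
  })
  population
}

check_thresholds <- function(population) {
  taus <- vapply(population$alleles, `[[`, 0, "tau")
  if (anyNA(taus)) {
    stop("binding thresholds unset for: ",
         paste(names(population$p)[is.na(taus)], collapse = ", "))
  }
  invisible(taus)
}

#' Scan a sequence for predicted epitopes
#'
#' Slides a window of the core length over the sequence and reports, per
#' allele, every window whose score strictly exceeds that allele's
#' threshold.
#'
#' @param seq Protein sequence (string or character vector).
#' @param population An `hla_population` with thresholds set.
#' @param offset Protein numbering of the first residue (default 1), so
#'   reported starts are in protein numbering.
#' @return Data frame with columns `start` (1-based protein numbering),
#'   `allele`, `score`, `margin` (`score - tau`, positive for every call).
#' @export
scan_epitopes <- function(seq, population, offset = 1L) {
  check_thresholds(population)
  out <- lapply(population$alleles, function(m) {
    sc <- window_scores(m, seq)
    hit <- which(sc > m$tau)
    data.frame(start = hit + as.integer(offset) - 1L,
               allele = rep(m$allele, length(hit)),
               score = sc[hit], margin = sc[hit] - m$tau)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(start = integer(0), allele = character(0),
                      score = numeric(0), margin = numeric(0))
  }
  out <- out[order(out$start, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Population-weighted immunogenicity of a sequence
#'
#' The design objective O1 evaluated on a plain sequence:
#' `sum_h p_h * sum_windows max(0, score - tau_h)`. All full-length windows
#' of the sequence contribute, so mutations that create or destroy epitopes
#' overlapping a region boundary are accounted for.
#'
#' @inheritParams scan_epitopes
#' @return Nonnegative numeric scalar.
#' @export
immunogenicity_score <- function(seq, population) {
  check_thresholds(population)
  total <- 0
  for (idx in seq_along(population$alleles)) {
    m <- population$alleles[[idx]]
    sc <- window_scores(m, seq)
    total <- total + population$p[[idx]] * sum(pmax(0, sc - m$tau))
  }
  total
}

#' Number of predicted epitopes of a sequence
#'
#' Counts (window, allele) pairs above threshold, so one peptide binding
#' two alleles counts twice.
#'
#' @inheritParams scan_epitopes
#' @return Integer count.
#' @export
epitope_count <- function(seq, population) {
  nrow(scan_epitopes(seq, population))
}
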