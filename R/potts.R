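# Pairwise maximum-entropy (Potts) sequence model: container, statistical
# energy, incremental mutation effects and exact text serialization.

#' Construct a Potts model
#'
#' Container for a pairwise maximum-entropy model over sequences of length
#' `L` with alphabet size `q`: single-site fields `h[i, a]` and couplings
#' `J[p, a, b]` stored once per position pair `i < j` (pair `p` in
#' lexicographic order); `J_ij(a, b)` for `i > j` is accessed as
#' `J_ji(b, a)`. The statistical energy of a sequence is
#' `E(X) = sum_i h_i(X_i) + sum_{i<j} J_ij(X_i, X_j)`; under the model
#' `P(X)` is proportional to `exp(E(X))`, so higher energy means a fitter,
#' more probable sequence.
#'
#' @param h Numeric `L x q` matrix of fields.
#' @param J Numeric array `npairs x q x q` of couplings (`npairs =
#'   L*(L-1)/2`), or `NULL` for a field-only model.
#' @param alphabet Character vector of the `q` residue symbols.
#' @param lambda_h,lambda_j l2 regularization strengths recorded from
#'   inference (metadata).
#' @param meta Optional list of provenance metadata (Meff, theta, ...).
#' @return Object of class `potts_model`.
#' @export
potts_model <- function(h, J = NULL, alphabet,
                        lambda_h = NA_real_, lambda_j = NA_real_,
                        meta = list()) {
  L <- nrow(h)
  q <- ncol(h)
  stopifnot(length(alphabet) == q)
  npairs <- (L * (L - 1L)) %/% 2L
  if (is.null(J)) J <- array(0, dim = c(npairs, q, q))
  stopifnot(dim(J)[1] == npairs, dim(J)[2] == q, dim(J)[3] == q)
  if (!all(is.finite(h)) || !all(is.finite(J))) {
    stop("non-finite model parameters")
  }
  structure(list(L = L, q = q, h = h, J = J, alphabet = alphabet,
                 lambda_h = lambda_h, lambda_j = lambda_j, meta = meta),
            class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  cat(sprintf("potts_model: L = %d, q = %d (alphabet %s)\n",
              x$L, x$q, paste(x$alphabet, collapse = "")))
  if (!is.null(x$meta$meff)) cat(sprintf("  Meff = %.2f\n", x$meta$meff))
  invisible(x)
}

# Coupling submatrix J_ij as a q x q matrix, for any i != j.
get_J <- function(model, i, j) {
  if (i < j) {
    model$J[pair_index(i, j, model$L), , ]
  } else {
    t(model$J[pair_index(j, i, model$L), , ])
  }
}

encode_model_seq <- function(model, seq) {
  s <- if (length(seq) == 1L && is.character(seq)) seq_chars(seq) else seq
  if (length(s) != model$L) {
    stop("sequence length ", length(s), " != model length ", model$L)
  }
  encode_seq(s, model$alphabet)
}

#' Statistical energy of a sequence
#'
#' `E(X) = sum_{i<j} J_ij(X_i, X_j) + sum_i h_i(X_i)`. Energy differences
#' between sequences are gauge-invariant; absolute values depend on the
#' gauge of the parameters.
#'
#' @param model A `potts_model`.
#' @param seq Sequence (string or character vector) of length `L` over the
#'   model alphabet.
#' @return Numeric scalar.
#' @export
statistical_energy <- function(model, seq) {
  s <- encode_model_seq(model, seq)
  e <- sum(model$h[cbind(seq_len(model$L), s)])
  if (model$L >= 2L) {
    ij <- all_pairs(model$L)
    p <- seq_len(nrow(ij))
    e <- e + sum(model$J[cbind(p, s[ij[, 1]], s[ij[, 2]])])
  }
  e
}

#' Energy change of a set of substitutions
#'
#' Computes `E(mutant) - E(wild type)` incrementally, touching only the
#' field and coupling terms that involve a mutated position.
#'
#' @param model A `potts_model`.
#' @param wild_type Wild-type sequence of length `L`.
#' @param mutations A data.frame with columns `pos` (1..L) and `aa`
#'   (replacement residue), a named character vector (names = positions), or
#'   an empty value for no mutation.
#' @return Numeric scalar `delta E`; positive means the mutant has higher
#'   statistical energy (is fitter under the model) than the wild type.
#' @export
mutation_effect <- function(model, wild_type, mutations) {
  wt <- encode_model_seq(model, wild_type)
  mut <- normalize_mutations(mutations)
  if (nrow(mut) == 0L) return(0)
  pos <- mut$pos
  if (anyDuplicated(pos)) stop("duplicate mutated positions")
  if (any(pos < 1L | pos > model$L)) stop("mutation position out of range")
  new <- match(mut$aa, model$alphabet)
  if (anyNA(new)) stop("mutation to symbol outside alphabet")
  delta <- sum(model$h[cbind(pos, new)]) - sum(model$h[cbind(pos, wt[pos])])
  others <- setdiff(seq_len(model$L), pos)
  for (m in seq_along(pos)) {
    i <- pos[m]
    for (j in others) {
      Jij <- get_J(model, i, j)
      delta <- delta + Jij[new[m], wt[j]] - Jij[wt[i], wt[j]]
    }
  }
  if (length(pos) >= 2L) {
    for (m in seq_len(length(pos) - 1L)) {
      for (l in (m + 1L):length(pos)) {
        i <- pos[m]; j <- pos[l]
        Jij <- get_J(model, i, j)
        delta <- delta + Jij[new[m], new[l]] - Jij[wt[i], wt[j]]
      }
    }
  }
  delta
}

normalize_mutations <- function(mutations) {
  if (is.null(mutations) || length(mutations) == 0L) {
    return(data.frame(pos = integer(0), aa = character(0)))
  }
  if (is.data.frame(mutations)) {
    stopifnot(all(c("pos", "aa") %in% names(mutations)))
    return(data.frame(pos = as.integer(mutations$pos),
                      aa = as.character(mutations$aa)))
  }
  data.frame(pos = as.integer(names(mutations)),
             aa = unname(as.character(mutations)))
}

#' Serialize / restore a Potts model as plain text
#'
#' Tab-separated container with a header (dimensions, alphabet,
#' regularization, metadata), one row per field entry and one row per
#' coupling entry, written at full double precision so that the round trip
#' is bit-exact.
#'
#' @param model A `potts_model`.
#' @param path File path.
#' @return `write_potts` returns `path` invisibly; `read_potts` the model.
#' @export
write_potts <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  writeLines(c(
    sprintf("# potts_model\tL=%d\tq=%d", model$L, model$q),
    sprintf("# alphabet\t%s", paste(model$alphabet, collapse = "")),
    sprintf("# lambda_h\t%s\tlambda_j\t%s",
            fmt(model$lambda_h), fmt(model$lambda_j)),
    sprintf("# meta\t%s", jsonlite::toJSON(model$meta, auto_unbox = TRUE,
                                           digits = NA))
  ), con)
  h <- model$h
  ia <- which(!is.na(h), arr.ind = TRUE)
  writeLines(sprintf("h\t%d\t%d\t%s", ia[, 1], ia[, 2], fmt(h[ia])), con)
  ij <- all_pairs(model$L)
  for (p in seq_len(nrow(ij))) {
    Jp <- model$J[p, , ]
    ab <- which(Jp != 0 | TRUE, arr.ind = TRUE)
    writeLines(sprintf("J\t%d\t%d\t%d\t%d\t%s", ij[p, 1], ij[p, 2],
                       ab[, 1], ab[, 2], fmt(Jp[ab])), con)
  }
  invisible(path)
}

#' @rdname write_potts
#' @export
read_potts <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  dims <- regmatches(hdr[1], regexec("L=(\\d+)\\tq=(\\d+)", hdr[1]))[[1]]
  L <- as.integer(dims[2]); q <- as.integer(dims[3])
  alphabet <- seq_chars(strsplit(hdr[2], "\t")[[1]][2])
  lam <- strsplit(hdr[3], "\t")[[1]]
  parse_num <- function(x) if (identical(x, "NA")) NA_real_ else as.numeric(x)
  meta <- jsonlite::fromJSON(strsplit(hdr[4], "\t")[[1]][2])
  parts <- strsplit(body, "\t", fixed = TRUE)
  kind <- vapply(parts, `[[`, "", 1L)
  h <- matrix(0, L, q)
  hp <- parts[kind == "h"]
  hi <- vapply(hp, function(p) as.integer(p[2]), 0L)
  ha <- vapply(hp, function(p) as.integer(p[3]), 0L)
  h[cbind(hi, ha)] <- vapply(hp, function(p) as.numeric(p[4]), 0)
  J <- array(0, dim = c((L * (L - 1L)) %/% 2L, q, q))
  jp <- parts[kind == "J"]
  if (length(jp)) {
    ji <- vapply(jp, function(p) as.integer(p[2]), 0L)
    jj <- vapply(jp, function(p) as.integer(p[3]), 0L)
    ja <- vapply(jp, function(p) as.integer(p[4]), 0L)
    jb <- vapply(jp, function(p) as.integer(p[5]), 0L)
    pv <- mapply(pair_index, ji, jj, MoreArgs = list(L = L))
    J[cbind(pv, ja, jb)] <- vapply(jp, function(p) as.numeric(p[6]), 0)
  }
  potts_model(h, J, alphabet,
              lambda_h = parse_num(lam[2]), lambda_j = parse_num(lam[4]),
              meta = as.list(meta))
}
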