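# Evolutionary coupling scores: Frobenius norms in zero-sum gauge, average
# product correction, per-position enrichment, and significance calling via
# a Gaussian + lognormal mixture.

#' Evolutionary coupling scores with average product correction
#'
#' For each position pair the coupling submatrix is transformed to the
#' zero-sum gauge (double-centred over the non-gap states; the gap state is
#' excluded) and its Frobenius norm taken. The average product correction
#' `apc(i,j) = fn(i,j) - mean_i * mean_j / mean_all` (means over
#' off-diagonal entries) removes shared background from finite sampling and
#' phylogeny.
#'
#' @param model A `potts_model`.
#' @return Object of class `ec_result`: symmetric matrices `fn` and `apc`
#'   with zero diagonal.
#' @export
ec_scores <- function(model) {
  L <- model$L
  keep <- which(model$alphabet != "-")
  fn <- matrix(0, L, L)
  ij <- all_pairs(L)
  for (p in seq_len(nrow(ij))) {
    Jp <- model$J[p, keep, keep]
    Jc <- Jp - outer(rowMeans(Jp), rep(1, ncol(Jp))) -
      outer(rep(1, nrow(Jp)), colMeans(Jp)) + mean(Jp)
    v <- sqrt(sum(Jc^2))
    fn[ij[p, 1], ij[p, 2]] <- v
    fn[ij[p, 2], ij[p, 1]] <- v
  }
  apc <- apply_apc(fn)
  structure(list(fn = fn, apc = apc, L = L), class = "ec_result")
}

# APC on a symmetric score matrix with zero diagonal; means exclude the
# diagonal.
apply_apc <- function(fn) {
  L <- nrow(fn)
  if (L < 2L) return(fn * 0)
  row_mean <- rowSums(fn) / (L - 1L)
  all_mean <- sum(fn) / (L * (L - 1L))
  if (all_mean == 0) return(fn * 0)
  corr <- outer(row_mean, row_mean) / all_mean
  apc <- fn - corr
  diag(apc) <- 0
  apc
}

#' Per-position EC enrichment
#'
#' Cumulative coupling strength of a position to all others: the row sum of
#' the APC-corrected score matrix, optionally restricted to the top `top_n`
#' scoring pairs, and optionally normalized by the mean over positions.
#'
#' @param ec An `ec_result`.
#' @param top_n Use only the `top_n` highest-scoring pairs (default all).
#' @param normalize Divide by the mean enrichment (default `TRUE`).
#' @return Numeric vector of length `L`.
#' @export
ec_enrichment <- function(ec, top_n = NULL, normalize = TRUE) {
  sc <- ec$apc
  if (!is.null(top_n)) {
    ut <- upper.tri(sc)
    vals <- sc[ut]
    if (top_n < length(vals)) {
      cut <- sort(vals, decreasing = TRUE)[top_n]
      sc[sc < cut] <- 0
    }
  }
  enr <- rowSums(sc)
  if (normalize) {
    m <- mean(enr)
    if (m != 0) enr <- enr / m
  }
  enr
}

#' Significant long-range couplings via a Gaussian-lognormal mixture
#'
#' Fits a two-component mixture (Gaussian background + lognormal signal
#' tail) to the APC scores of long-range pairs by EM and returns the pairs
#' whose posterior probability of belonging to the lognormal component
#' reaches `prob`. If EM degenerates (component collapse or no positive
#' scores) the call falls back to a rank cutoff of the top `L` pairs and
#' flags the result.
#'
#' @param ec An `ec_result`.
#' @param min_separation Minimum `|i - j|` for a pair to count as
#'   long-range (default 5).
#' @param prob Posterior probability threshold (default 0.9).
#' @return Data frame `i`, `j`, `score`, `prob`, sorted by decreasing
#'   score, with attributes `mixture` (fitted parameters) and `fallback`.
#' @export
top_ecs <- function(ec, min_separation = 5L, prob = 0.9) {
  L <- ec$L
  ij <- all_pairs(L)
  lr <- ij[ij[, 2] - ij[, 1] >= min_separation, , drop = FALSE]
  if (nrow(lr) < 50L) {
    stop("need at least 50 long-range pairs (have ", nrow(lr), ")")
  }
  scores <- ec$apc[lr]
  fit <- fit_gauss_lognorm(scores)
  if (fit$degenerate) {
    ord <- order(scores, decreasing = TRUE)
    keep <- ord[seq_len(min(L, length(ord)))]
    post <- rep(NA_real_, length(scores))
  } else {
    post <- fit$posterior
    keep <- which(post >= prob)
  }
  out <- data.frame(i = lr[keep, 1], j = lr[keep, 2],
                    score = scores[keep], prob = post[keep])
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mixture") <- fit$params
  attr(out, "fallback") <- fit$degenerate
  out
}

# EM for a Gaussian (background) + lognormal (signal) mixture. The
# lognormal has zero density at scores <= 0, so negative APC scores are
# automatically background. Moment-based initialization split at the 90th
# percentile.
fit_gauss_lognorm <- function(x, max_iter = 1000L, tol = 1e-9) {
  n <- length(x)
  q90 <- quantile(x, 0.9, names = FALSE)
  bg <- x[x < q90]
  sig <- x[x >= q90 & x > 0]
  degenerate_out <- function() {
    list(degenerate = TRUE, params = NULL, posterior = NULL)
  }
  if (length(sig) < 3L || sd(bg) == 0) return(degenerate_out())
  mu1 <- mean(bg); s1 <- max(sd(bg), 1e-8)
  mu2 <- mean(log(sig)); s2 <- max(sd(log(sig)), 1e-3)
  pi2 <- length(sig) / n
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    d1 <- (1 - pi2) * dnorm(x, mu1, s1)
    d2 <- numeric(n)
    pos <- x > 0
    d2[pos] <- pi2 * dlnorm(x[pos], mu2, s2)
    tot <- d1 + d2
    if (any(tot <= 0) || !all(is.finite(tot))) return(degenerate_out())
    r <- d2 / tot
    ll <- sum(log(tot))
    pi2 <- mean(r)
    if (pi2 < 1e-8 || pi2 > 1 - 1e-8) return(degenerate_out())
    w1 <- 1 - r
    mu1 <- sum(w1 * x) / sum(w1)
    s1 <- sqrt(sum(w1 * (x - mu1)^2) / sum(w1))
    sw2 <- sum(r[pos])
    if (sw2 < 1e-8) return(degenerate_out())
    mu2 <- sum(r[pos] * log(x[pos])) / sw2
    s2 <- sqrt(sum(r[pos] * (log(x[pos]) - mu2)^2) / sw2)
    if (s1 < 1e-10 || s2 < 1e-6) return(degenerate_out())
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  d1 <- (1 - pi2) * dnorm(x, mu1, s1)
  d2 <- numeric(n)
  pos <- x > 0
  d2[pos] <- pi2 * dlnorm(x[pos], mu2, s2)
  list(degenerate = FALSE,
       params = list(mu_norm = mu1, sd_norm = s1,
                     meanlog = mu2, sdlog = s2, weight_lognorm = pi2,
                     loglik = ll, iterations = iter),
       posterior = d2 / (d1 + d2))
}
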