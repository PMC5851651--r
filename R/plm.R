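# Pseudo-likelihood maximization for Potts model inference.
#
# The weighted negative log-pseudo-likelihood sums, over sequences s and
# sites i, the conditional multinomial logistic likelihood of residue X_si
# given the rest of the sequence, with shared symmetric couplings (each
# J_ij appears in the conditionals of both i and j), plus l2 penalties
# lambda_h * ||h||^2 + lambda_j * ||J||^2 (each pair counted once).

#' Infer a Potts model by pseudo-likelihood maximization
#'
#' Fits fields and couplings to a reweighted alignment by minimizing the
#' weighted negative log-pseudo-likelihood under l2 regularization, using
#' L-BFGS-B on the jointly symmetric parameterization. The regularization
#' default for couplings scales with the effective sequence number
#' (`0.01 * Meff`), the standard choice when the pseudo-likelihood is a
#' weighted sum rather than an average.
#'
#' @param aln An `alignment` with weights computed, or an already encoded
#'   integer matrix together with `alphabet` and `weights`.
#' @param lambda_h l2 strength on fields (default 0.01).
#' @param lambda_j l2 strength on couplings (default `0.01 * Meff`).
#' @param max_iter Maximum L-BFGS-B iterations.
#' @param tol Convergence tolerance on the gradient infinity norm.
#' @param alphabet,weights Only used when `aln` is a plain integer matrix.
#' @return A `potts_model`; `meta$converged` records whether the final
#'   gradient norm reached `tol`, and `meta$grad_norm` its value. A
#'   non-converged fit is returned with a warning, not an error.
#' @export
infer_plm <- function(aln, lambda_h = 0.01, lambda_j = NULL,
                      max_iter = 500L, tol = 1e-4,
                      alphabet = NULL, weights = NULL) {
  if (inherits(aln, "alignment")) {
    if (is.null(aln$weights)) stop("weights not computed; run sequence_weights()")
    enc <- encode_seq(focus_matrix(aln), aln$alphabet)
    alphabet <- aln$alphabet
    weights <- aln$weights
  } else {
    enc <- aln
    stopifnot(!is.null(alphabet), !is.null(weights))
  }
  L <- ncol(enc)
  q <- length(alphabet)
  if (L < 2L) stop("need at least two positions")
  n <- nrow(enc)
  meff <- sum(weights)
  if (is.null(lambda_j)) lambda_j <- 0.01 * meff
  npairs <- (L * (L - 1L)) %/% 2L
  nh <- L * q

  # one-hot design matrix, n x (L*q), and linear indices of observed states
  X <- matrix(0, n, L * q)
  obs_col <- sweep(enc, 2L, (seq_len(L) - 1L) * q, `+`)
  X[cbind(rep(seq_len(n), L), as.vector(obs_col))] <- 1
  w <- weights
  ij <- all_pairs(L)
  blk <- function(i) ((i - 1L) * q + 1L):(i * q)

  unpack_J <- function(jpar) {
    Jfull <- matrix(0, L * q, L * q)
    Jarr <- array(jpar, dim = c(npairs, q, q))
    for (p in seq_len(npairs)) {
      i <- ij[p, 1]; j <- ij[p, 2]
      Jfull[blk(i), blk(j)] <- Jarr[p, , ]
      Jfull[blk(j), blk(i)] <- t(Jarr[p, , ])
    }
    Jfull
  }

  obj_env <- new.env()
  fn_gr <- function(par) {
    h <- par[seq_len(nh)]
    Jfull <- unpack_J(par[-seq_len(nh)])
    Z <- X %*% Jfull
    Z <- Z + matrix(h, n, L * q, byrow = TRUE)
    nll <- 0
    P <- matrix(0, n, L * q)
    for (i in seq_len(L)) {
      zi <- Z[, blk(i), drop = FALSE]
      m <- apply(zi, 1L, max)
      ez <- exp(zi - m)
      se <- rowSums(ez)
      lse <- m + log(se)
      nll <- nll + sum(w * (lse - Z[cbind(seq_len(n), obs_col[, i])]))
      P[, blk(i)] <- ez / se
    }
    D <- w * (P - X)                       # n x (L*q), weighted residuals
    Gfull <- crossprod(X, D)               # (L*q) x (L*q)
    gh <- colSums(D)
    gj <- array(0, dim = c(npairs, q, q))
    for (p in seq_len(npairs)) {
      i <- ij[p, 1]; j <- ij[p, 2]
      gj[p, , ] <- Gfull[blk(i), blk(j)] + t(Gfull[blk(j), blk(i)])
    }
    jpar <- par[-seq_len(nh)]
    val <- nll + lambda_h * sum(h^2) + lambda_j * sum(jpar^2)
    grad <- c(gh + 2 * lambda_h * h, as.vector(gj) + 2 * lambda_j * jpar)
    obj_env$grad <- grad
    obj_env$par <- par
    val
  }
  fn <- function(par) fn_gr(par)
  gr <- function(par) {
    if (!identical(par, obj_env$par)) fn_gr(par)
    obj_env$grad
  }

  par0 <- numeric(nh + npairs * q * q)
  fit <- optim(par0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = max_iter, pgtol = tol, factr = 10))
  fn_gr(fit$par)
  gnorm <- max(abs(obj_env$grad))
  converged <- gnorm <= tol || fit$convergence == 0L
  if (!converged) {
    warning(sprintf(
      "pseudo-likelihood maximization did not converge (grad norm %.3g)",
      gnorm))
  }
  h <- matrix(fit$par[seq_len(nh)], L, q, byrow = TRUE)
  J <- array(fit$par[-seq_len(nh)], dim = c(npairs, q, q))
  potts_model(h, J, alphabet, lambda_h = lambda_h, lambda_j = lambda_j,
              meta = list(meff = meff, n_sequences = n,
                          converged = converged, grad_norm = gnorm,
                          nll = fit$value))
}
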