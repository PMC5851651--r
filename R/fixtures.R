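# Synthetic-data generators: random allele matrices, random Potts models,
# Gibbs-sampled alignments, and fully wired toy design problems. All
# generators are pure functions of their seed (R's default Mersenne
# Twister), so fixtures are reproducible and need no stored data.

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Random allele binding matrix
#'
#' An allele model with i.i.d. standard-normal cells. When
#' `planted_binder` is given, its residues' cells are boosted so that the
#' planted peptide is the strongest possible window by a clear margin.
#'
#' @param e_n Core length.
#' @param seed RNG seed.
#' @param planted_binder Optional peptide of length `e_n`.
#' @param boost Added to the planted residues' cells (default 4).
#' @param allele Name for the generated allele.
#' @return An `allele_model` (threshold unset).
#' @export
random_pssm <- function(e_n = 9L, seed = 1L, planted_binder = NULL,
                        boost = 4, allele = sprintf("SYN-%04d", seed)) {
  stopifnot(e_n >= 1L)
  with_seed(seed, {
    phi <- matrix(rnorm(e_n * 20L), e_n, 20L,
                  dimnames = list(NULL, aa_alphabet()))
    if (!is.null(planted_binder)) {
      p <- if (length(planted_binder) == 1L) seq_chars(planted_binder)
      else planted_binder
      stopifnot(length(p) == e_n)
      phi[cbind(seq_len(e_n), match(p, aa_alphabet()))] <-
        apply(phi, 1L, max) + boost
    }
    allele_model(allele, phi)
  })
}

#' Random Potts model
#'
#' Gaussian fields and sparse symmetric couplings: each position pair
#' carries a full q x q Gaussian coupling block with probability
#' `coupling_density`, zero otherwise.
#'
#' @param L Number of positions (`>= 2`).
#' @param q Alphabet size (`>= 2`); the alphabet is the first `q` standard
#'   amino acids.
#' @param coupling_density Fraction of coupled pairs in \[0, 1\].
#' @param scale Standard deviation of fields and coupling entries.
#' @param seed RNG seed.
#' @return A `potts_model`.
#' @export
random_potts <- function(L, q = 4L, coupling_density = 0.3, scale = 1,
                         seed = 1L) {
  stopifnot(L >= 2L, q >= 2L, coupling_density >= 0, coupling_density <= 1)
  with_seed(seed, {
    alphabet <- aa_alphabet()[seq_len(q)]
    h <- matrix(rnorm(L * q, sd = scale), L, q)
    npairs <- (L * (L - 1L)) %/% 2L
    J <- array(0, dim = c(npairs, q, q))
    coupled <- runif(npairs) < coupling_density
    for (p in which(coupled)) {
      J[p, , ] <- matrix(rnorm(q * q, sd = scale), q, q)
    }
    potts_model(h, J, alphabet,
                meta = list(seed = seed, coupling_density = coupling_density,
                            scale = scale))
  })
}

#' Sample sequences from a Potts model by Gibbs sampling
#'
#' Runs `n_chains` independent single-site Gibbs samplers (default one
#' chain per requested sequence, which vectorizes the conditional updates
#' across chains and gives effectively independent draws). Each chain is
#' initialized uniformly at random, burned in for `burn_in` full sweeps,
#' and then sampled every `thin` sweeps round-robin until `n_seq`
#' sequences are collected.
#'
#' @param model A `potts_model`.
#' @param n_seq Number of sequences to return.
#' @param burn_in Burn-in sweeps per chain (default 200).
#' @param thin Sweeps between successive draws from the same chain.
#' @param seed RNG seed.
#' @param n_chains Number of independent chains (default `n_seq`).
#' @return An `alignment` over the model alphabet (no gaps), with
#'   `focus_columns` covering all positions and no weights set.
#' @export
gibbs_sample <- function(model, n_seq, burn_in = 200L, thin = 1L,
                         seed = 1L, n_chains = n_seq) {
  stopifnot(n_seq >= 1L, n_chains >= 1L, burn_in >= 0L, thin >= 1L)
  L <- model$L; q <- model$q
  with_seed(seed, {
    # full coupling matrix once: block (j, i) feeds the conditional at i
    Jfull <- matrix(0, L * q, L * q)
    ij <- all_pairs(L)
    blk <- function(i) ((i - 1L) * q + 1L):(i * q)
    for (p in seq_len(nrow(ij))) {
      i <- ij[p, 1]; j <- ij[p, 2]
      Jfull[blk(i), blk(j)] <- model$J[p, , ]
      Jfull[blk(j), blk(i)] <- t(model$J[p, , ])
    }
    C <- n_chains
    state <- matrix(sample.int(q, C * L, replace = TRUE), C, L)
    X <- matrix(0, C, L * q)
    X[cbind(rep(seq_len(C), L),
            as.vector(sweep(state, 2L, (seq_len(L) - 1L) * q, `+`)))] <- 1
    Ucum <- upper.tri(matrix(0, q, q), diag = TRUE) * 1
    sweep_once <- function() {
      for (i in seq_len(L)) {
        # the diagonal block of Jfull is zero, so position i does not
        # contribute to its own conditional
        logits <- X %*% Jfull[, blk(i), drop = FALSE]
        logits <- sweep(logits, 2L, model$h[i, ], `+`)
        m <- do.call(pmax, as.data.frame(logits))
        P <- exp(logits - m)
        P <- P / rowSums(P)
        u <- runif(C)
        new <- 1L + rowSums((P %*% Ucum) < u)
        # update one-hot block
        X[cbind(seq_len(C), (i - 1L) * q + state[, i])] <<- 0
        state[, i] <<- as.integer(new)
        X[cbind(seq_len(C), (i - 1L) * q + new)] <<- 1
      }
    }
    for (s in seq_len(burn_in)) sweep_once()
    out <- matrix(0L, n_seq, L)
    got <- 0L
    while (got < n_seq) {
      take <- min(C, n_seq - got)
      out[(got + 1L):(got + take), ] <- state[seq_len(take), , drop = FALSE]
      got <- got + take
      if (got < n_seq) for (s in seq_len(thin)) sweep_once()
    }
    mat <- matrix(model$alphabet[out], n_seq, L)
    new_alignment(mat, sprintf("sample_%d", seq_len(n_seq)),
                  focus_columns = seq_len(L), target_index = 1L,
                  target_offset = 1L, alphabet = model$alphabet)
  })
}

#' Toy design-problem specification
#'
#' Conditions of the desk-scale study: short sequences (`n <= 10`),
#' small candidate sets (`|M_i| <= 4`), up to three simultaneous
#' mutations and two to three synthetic alleles, so the complete mutant
#' space is enumerable by the brute-force oracle.
#'
#' @param n Sequence length.
#' @param q Potts alphabet size.
#' @param max_options Maximum candidate residues per position.
#' @param n_alleles Number of synthetic alleles.
#' @param e_n Epitope core length.
#' @param k Mutation budget.
#' @param percentile Threshold percentile for the synthetic alleles;
#'   the median (50) keeps roughly half of all windows immunogenic so the
#'   two objectives genuinely trade off on short toy sequences.
#' @param seed RNG seed.
#' @return Object of class `toy_spec`.
#' @export
toy_spec <- function(n = 8L, q = 4L, max_options = 3L, n_alleles = 2L,
                     e_n = 4L, k = 2L, percentile = 50, seed = 1L) {
  stopifnot(n >= e_n, q >= 2L, max_options >= 1L, n_alleles >= 1L, k >= 0L)
  structure(list(n = as.integer(n), q = as.integer(q),
                 max_options = as.integer(max_options),
                 n_alleles = as.integer(n_alleles), e_n = as.integer(e_n),
                 k = as.integer(k), percentile = percentile,
                 seed = as.integer(seed)),
            class = "toy_spec")
}

#' Build a complete toy design problem
#'
#' Wires a random Potts model, a random wild type, random candidate sets
#' and random allele matrices with protein-context percentile thresholds
#' into a solvable `design_problem`, reproducibly from the seed.
#'
#' @param spec A [toy_spec()].
#' @return A `design_problem`.
#' @export
make_toy_problem <- function(spec = toy_spec()) {
  model <- random_potts(spec$n, spec$q, coupling_density = 0.4,
                        scale = 0.8, seed = spec$seed)
  with_seed(spec$seed + 1000L, {
    alphabet <- model$alphabet
    wt <- alphabet[sample.int(spec$q, spec$n, replace = TRUE)]
    M <- lapply(seq_len(spec$n), function(i) {
      n_opt <- sample.int(min(spec$max_options, spec$q), 1L)
      opts <- union(wt[i], sample(alphabet, n_opt))
      opts[seq_len(min(length(opts), spec$max_options))]
    })
    alleles <- lapply(seq_len(spec$n_alleles), function(a) {
      m <- random_pssm(spec$e_n, seed = spec$seed + a,
                       allele = sprintf("SYN-%d.%d", spec$seed, a))
      m$tau <- binding_threshold(m, percentile = spec$percentile,
                                 background = "protein",
                                 context = chars_to_string(wt))
      m
    })
    p <- rep(0.9 / spec$n_alleles, spec$n_alleles)
    pop <- hla_population(alleles, p)
    design_problem(wt, M, spec$k, pop, model)
  })
}
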