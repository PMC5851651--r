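# deimmunize

Population-specific de-immunization of protein therapeutics by exact
bi-objective sequence design.

Biotherapeutics such as coagulation Factor VIII trigger anti-drug
antibodies when peptides from the protein are presented on HLA class II
molecules and recognized by CD4+ T cells. Removing those T-cell epitopes by
point mutation is only useful if the mutant still folds and works, and the
right epitopes to remove depend on which HLA alleles the target patient
population actually carries. `deimmunize` frames the design task as an
exact bi-objective mixed-integer program over mutants *S′* of a wild type
*S* with at most *k* substitutions from conservation-derived candidate sets
*M<sub>i</sub>*:

$$\min_{S'} \Big( I(S'\mid H, p_H),\; -E(S') \Big)$$

* **Immunogenicity** — each allele *h* scores peptides with a linear
  position-specific scoring matrix Φ<sub>h</sub> over a 9-mer core; every
  sliding window's score above the allele's binding threshold τ<sub>h</sub>
  contributes through a hinge loss, weighted by the allele's population
  frequency p<sub>h</sub>:
  *I(S) = Σ<sub>h</sub> p<sub>h</sub> Σ<sub>i</sub> max(0, Σ<sub>j</sub>
  Φ<sub>h</sub>(j, S<sub>i+j</sub>) − τ<sub>h</sub>)*.
* **Fitness** — the evolutionary statistical energy of a pairwise
  maximum-entropy (Potts) model of the protein family, *E(X) =
  Σ<sub>i</sub> h<sub>i</sub>(X<sub>i</sub>) + Σ<sub>i&lt;j</sub>
  J<sub>ij</sub>(X<sub>i</sub>, X<sub>j</sub>)*, inferred from a reweighted
  multiple sequence alignment by l2-regularized pseudo-likelihood
  maximization. Higher energy means a more probable, fitter sequence, so
  the second objective minimizes −E.

The solver returns the **complete, proven-optimal Pareto front** of
designs using a parallel two-phase rectangle-splitting strategy over a
lexicographic-minimization primitive, backed by an exact branch-and-bound
core specialized to the design ILP (one-hot position structure, mutation
budget, objective-space box constraints). Alongside the designer, the
package provides alignment filtering and sequence reweighting,
evolutionary-coupling scores with average product correction and
Gaussian-lognormal significance calling, epitope scanning and report
generation, and seeded synthetic-data generators that make every component
testable without external downloads.

## Worked example

A fully synthetic, seeded design problem (10 positions, candidate sets of
up to 4 residues, three synthetic alleles, budget k = 3):

```r
library(deimmunize)

prob  <- make_toy_problem(toy_spec(n = 10, q = 4, max_options = 4,
                                   n_alleles = 3, e_n = 4, k = 3, seed = 30))
inst  <- build_instance(prob)
front <- solve_pareto(inst, m = 4)
design_report(front, prob)[, 1:5]
```

```
   id    mutations epitopes delta_I delta_fitness
1   0      A2C,A8D        9  -1.430         4.810
2   1  A2C,A8D,C9E        7  -1.403         0.563
3   2 A2C,C9E,E10C       10  -0.779        -1.008
4   3 C1D,C9E,E10C        9  -0.634        -1.603
5   4          C9E        9  -0.606        -4.248
6   5     C9E,E10C       10  -0.576        -5.129
7   6  C3A,E5C,C9E        9  -0.164        -5.713
8   7  E5C,C7E,C9E       11   0.116        -5.735
9   8      E5C,C9E       10   0.254        -5.996
10  9  D4A,E5C,C9E        12   1.489        -7.686
```

The wild type (`CACDECCACE`) scores I = 2.639 with 9 predicted epitope
calls. Ten mutually nondominated designs trade immunogenicity against
fitness: `delta_I` is the change in the population-weighted hinge score
(design 0 removes 54% of the wild type's predicted immunogenicity at the
price of the largest fitness loss), `delta_fitness` is the change in the
minimized objective −E (positive = predicted fitness loss; designs toward
the bottom are fitter than the wild type but barely de-immunized), and
`epitopes` recounts threshold-exceeding (window, allele) pairs on the
decoded sequence. Every reported objective pair is independently
recomputed from the plain sequence; the front is provably identical to
exhaustive enumeration of all 680 candidate mutants
(`brute_force_pareto(prob)`).

For real inputs the same pipeline starts from files: `read_alignment()` /
`filter_alignment()` / `sequence_weights()` on the family MSA,
`infer_plm()` for the model, `read_pssm()` + `calibrate_population()` for
the allele matrices, then `design_problem()` → `build_instance()` →
`solve_pareto()`. A thin command-line wrapper with `prepare`, `infer`,
`scan-mutations`, `design` and `fixtures` subcommands is installed at
`inst/cli/deimmunize`.

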