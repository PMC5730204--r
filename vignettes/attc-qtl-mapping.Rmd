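---
title: "Dissecting main and epistatic QTL effects in an augmented triple test cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting main and epistatic QTL effects in an augmented triple test cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attcqtl)
```

## The design and why it matters

Heterosis — the superiority of an F1 hybrid over its inbred parents — is
classically probed with the North Carolina design III (NCIII) and the
triple test cross (TTC): a segregating base population is crossed back to
both parental inbreds (families $L_1$, $L_2$) and, in the TTC, to the F1
($L_3$). The difficulty is that with epistasis present, the additive and
dominance effects estimated from such designs are *confounded* with
epistatic contributions: what a single-population scan estimates are
**augmented** effects, mixtures of main and interaction terms.

The augmented TTC (aTTC) adds a selfing family ($L_4$) of every base
line. With a recombinant inbred line (RIL) base population the selfed
family is genetically identical to the RIL itself (selfing a fully
homozygous line reproduces its genotype), so $L_4$ costs nothing extra:
the RIL trial itself stands in for it. From the four family means, six
data transformations are available; this package works with the
combination

$$Z_1 = \bar L_1 + \bar L_2,\qquad Z_2 = \bar L_1 - \bar L_2,\qquad
  Z_4 = \bar L_1 + \bar L_2 - \bar L_4 .$$

Under the $F_\infty$ metric (homozygotes coded $x_a = \pm 1$, the
heterozygote carrying the dominance code $x_d = 1$), the expectations of
these transformations over a line's tester families are *exactly linear*
in a small set of augmented parameters:

| data  | main term | epistatic term |
|-------|-----------|----------------|
| $Z_1$ | $a_k^* = a_k + \tfrac12\sum_{l\neq k}(i_{a_kd_l}-i_{d_ka_l})$ | $i_{a_ka_l}+i_{d_kd_l}$ |
| $Z_2$ | $d_k^* = d_k - \tfrac12\sum_{l\neq k}(i_{a_ka_l}-i_{d_kd_l})$ | $i_{a_kd_l}+i_{d_ka_l}$ |
| $Z_4$ | — | $i_{a_ka_l}-i_{d_kd_l}$ and $i_{a_kd_l}-i_{d_ka_l}$ |

The four per-pair sums and differences invert *exactly*:
$i_{aa} = \tfrac12[(i_{aa}{+}i_{dd}) + (i_{aa}{-}i_{dd})]$ and so on,
after which the main-effect contamination sums can be subtracted. That
two-step dissection — scan each transformation, then solve the linear
system — is what `integrate_scans()` implements, and it is algebraically
exact: the package's round-trip tests compose random effect sets through
the augmentation formulas and recover them to round-off, including
multi-partner sums over three or more interacting QTL.

A worked single-locus consistency check, which the test suite asserts
against the family-mean oracle (`expected_Z()`): a line homozygous MM at
both of two interacting QTL has
$Z_4 = \mu + d_1 + d_2 + i_{d_1d_2}$ — main effects cancel between
$L_1 + L_2$ and $L_4$, leaving only dominance-flavoured terms. This is
the sense in which $Z_2$ and $Z_4$ "characterize heterosis".

One sign convention deserves note: the definition
$d_k^* = d_k - \tfrac12\sum(i_{a_ka_l}-i_{d_kd_l})$ is the one under
which the linear predictor reproduces the family-mean oracle exactly;
the package asserts this in tests rather than assuming it, and the
dissection inverts with the matching $+\tfrac12$ correction.

## The oversaturated scan

Each transformation is regressed on *all* markers at once: $q$ main
columns plus all $\binom q2$ pairwise interaction columns ($p = 5050$
for $q = 100$), with $p \gg n$. The scan is a two-stage procedure:

1. an **empirical Bayes LASSO**: each coefficient has a
   $N(0, \sigma_j^2)$ prior; $\sigma_j^2$ carries an exponential prior
   whose rate has a gamma$(a, b)$ hyperprior, giving the marginal prior
   density $p(\sigma_j^2) \propto (b + \sigma_j^2)^{-(a+1)}$. The
   $\sigma_j^2$ are estimated by greedy penalised-marginal-likelihood
   maximisation, one column at a time (add / re-estimate / delete), so
   excluded coefficients are exactly zero. Columns with posterior
   $t_j = |\hat\beta_j| / \hat\sigma_{\beta_j} > 2$ are retained;
2. an **ordinary least squares refit** of the retained columns with a
   per-term likelihood-ratio test,
   $\mathrm{LOD} = \tfrac n2 \log_{10}(\mathrm{RSS}_{-j}/\mathrm{RSS})$,
   reporting terms with $\mathrm{LOD} > 2.5$ together with the variance
   they explain.

The thresholds $t > 2$ and $\mathrm{LOD} > 2.5$ are the design's fixed
reporting conventions (both configurable); no multiplicity correction is
applied beyond them.

### Numerical choices in the EB scan

* Columns and response are standardised internally, so the
  hyperparameters act on a unit-free scale; estimates are reported on
  the original scale.
* The optimal prior variance per column is the positive root of a
  quadratic in $\sigma_j^2$; the tests verify this closed form against
  direct numerical maximisation.
* The residual variance is re-estimated after every action. Because
  that makes the greedy objective non-monotone, the fitter tracks the
  full penalised marginal likelihood (profiled over the residual
  variance) and returns the best state visited; it stops when no action
  improves the objective by more than `tol` ($10^{-6}$), when the
  objective has not improved for 20 consecutive actions (a cycling
  indicator), or at the `10 p` action cap.
* **Default hyperparameters** `a = 1, b = 3e-4`. The choice is an
  operating-characteristic calibration, made from the null analysis
  below rather than from any data: under a pure-noise response the best
  chance association among the $\min(n, p)$ effective directions of an
  oversaturated design has a $\chi^2_1$-type statistic of roughly
  $2\log(\min(n,p)) \approx 11$–13 for $n$ in the hundreds. A candidate
  column enters the greedy scan when its marginal-likelihood gain
  $\tfrac12(\chi^2 - 1 - \log\chi^2)$ exceeds the prior penalty
  $(a{+}1)\log(1 + \sigma_j^2/b)$; with `a = 1, b = 3e-4` the implied
  entry threshold sits near $\chi^2 \approx 30$ at these sample sizes,
  safely above the null maximum, so a zero-effect genome almost never
  reports a term while the benchmark signals (whose statistics are in
  the hundreds) always enter. Weaker-penalty settings (e.g.
  `a = b = 0.1`) let the best few chance columns in, the residual
  variance then shrinks, and admission cascades — the classic
  empirical-Bayes avalanche. `select_hyperparameters()` offers 3-fold
  cross-validation over a grid whose small-`b` points cover this
  strong-shrinkage regime; the study harness fixes the default pair
  across replicates, mirroring the practice of selecting
  hyperparameters once and holding them fixed.

### Why the Z4 scan uses a marker-plus-product parametrisation

The natural per-pair design for $Z_4$ has one $(i_{aa}{-}i_{dd})$ column
with codes $-x_kx_l/2$ and one $(i_{ad}{-}i_{da})$ column with codes
$(x_k - x_l)/2$. The second block is rank-deficient *by construction*:
every column is a difference of two marker vectors, so the supports
$\{(k,l), (k',l')\}$ and $\{(k,l'), (k',l)\}$ are indistinguishable
whenever the two effects are similar — and no amount of data can
separate them. The expectation of $Z_4$ is, however, exactly linear in
the $q$ marker columns $x_k$ plus the $\binom q2$ product columns
$x_kx_l$ (which is also the generic oversaturated model a practitioner
would fit, with $p = 5050$ for all three transformations): each pair
loads $-(i_{aa}{-}i_{dd})/2$ on its product column and
$\pm(i_{ad}{-}i_{da})/2$ on its two marker columns. `scan_transformation()`
therefore fits that identifiable basis for $Z_4$ and reports the
pair-level contract: the product coefficient, doubled and sign-flipped,
is the $(i_{aa}{-}i_{dd})$ estimate (the factor 2 is exactly the
post-hoc correction that the $\pm1$ coding convention requires); the
$(i_{ad}{-}i_{da})$ estimate is the difference of the two marker
loadings, with a 2-df likelihood-ratio LOD. Marker loadings are paired
primarily through the detected product pairs — in the benchmark
architecture every interacting pair carries both kinds of effect — and
by magnitude matching otherwise; a pair whose $(i_{aa}{-}i_{dd})$
effect is zero therefore relies on the fallback, a documented
limitation of what is identifiable. `build_design("Z4")` still exposes
the per-pair coding (at effect scale by default, `scale = "printed"`
for the $\pm1$ codes), and the oracle-identity tests run against it.

### Z3, Z5 and Z6

`expected_Z()` supports all six transformations, and
`build_design()` derives $Z_5$/$Z_6$ codings by enumeration from the
family-mean oracle. With loci treated as independent within $L_3$
families (see below), those codings satisfy the oracle identity exactly
but are partially aliased — the $Z_5$ pair columns lie in the span of
intercept and mains, and the $Z_6$ $i_{dd}$ coefficient is constant —
so they are provided for expectation checks, not joint fitting, and the
study harness uses $Z_1/Z_2/Z_4$ only.

## The simulator and what it does (not) emulate

`simulate_ril_genotypes()` draws fully homozygous RIL genomes marker by
marker along each chromosome: Haldane's map function converts interval
lengths to recombination fractions $r$, and adjacent markers disagree
with the selfed-RIL fixation probability $R = 2r/(1+2r)$. No
interference, no segregation distortion, no missing data — features of
real genotype matrices that the simulation does not emulate, so passing
tests certify the estimator under clean Mendelian sampling, not
robustness to genotyping artefacts. The default genome is 100 markers
in four chromosomes of 25, evenly spaced at 5 cM (99 consecutive
intervals, 495 cM).

Family phenotypes are the family-mean genotypic values plus i.i.d.
normal noise per replicate observation, with `m` replicates per family;
$L_3$ families (when simulated) treat loci as independently
segregating, which is exact for the family *means* used downstream —
linkage within an $L_3$ family affects only its internal variance,
which the residual term absorbs.

**Heritability** is defined at the transformation level:
$h = \mathrm{Var}_G(Z) / (\mathrm{Var}_G(Z) + c\,\sigma_e^2/m)$, where
$c$ is the sum of squared family-mean weights (2 for $Z_1/Z_2$, 3 for
$Z_4$) and one $\sigma_e$ is shared by all family types, giving
$\sigma_e^2 = \mathrm{Var}_G(Z)(1-h)m/(hc)$ — so `m` matters, as the
benchmark tables show. Because $\mathrm{Var}_G$ differs between
transformations (about 30, 54 and 18 trait-units$^2$ for $Z_1$, $Z_2$,
$Z_4$ under the benchmark architecture), a single shared $\sigma_e$
cannot put every transformation at the same $h$. The study harness
therefore simulates each transformation as its own experiment by
default (`calibrate = "each"`), calibrated to its own $h$ — matching a
protocol in which the three transformations are separate simulation
studies — with `calibrate = "Z1"` (one shared dataset anchored on one
transformation) available. Estimator means are unbiased under either
choice; only powers and spreads differ.

## The study harness

`run_study()` repeats simulate → scan → dissect over a treatment grid
(benchmark levels: $n \in \{800, 400, 200\}$, $h \in \{0.8, 0.5, 0.2\}$,
$m \in \{5, 10\}$). A true term counts as detected when a significant
term of the same kind sits at exactly its marker index (pairs: both
indices; a ±1-marker window is available via `match_window` for
robustness analyses). Summaries are conditional on detection — means
with empirical power below 1 are averages over the detecting replicates
— plus a zero-imputed mean over all replicates. All randomness descends
from one master seed through per-replicate, per-stage substreams, so a
study is exactly reproducible from its configuration.

The six-QTL benchmark architecture (`preset_architecture()`) places
three interaction patterns on the default genome: both partners with
main effects (markers 20, 36), one of two (45, 70), and neither
(80, 95). The acceptance script runs this architecture at $n = 800$,
$h = 0.8$, $m = 10$ with 20 replicates — a desk-scale problem size that
keeps the full study in the minutes range while leaving Monte Carlo
standard errors a few hundredths of a trait unit; 100 replicates
reproduces the reference precision.

## Degenerate inputs and edge behaviour

* A zero-effect architecture has $\mathrm{Var}_G = 0$, so heritability
  calibration is undefined; `simulate_phenotypes()` accepts an explicit
  `sigma_e` instead (the study harness defaults a null genome to
  $\sigma_e = 1$).
* Noiseless data (`sigma_e = 0`) make every Z vector equal its oracle
  expectation; the scan then interpolates and the dissection returns
  the presets exactly — the strongest end-to-end self-check.
* Identical design columns (tightly linked markers at small $n$) are
  collapsed before the refit, keeping the lowest marker index; columns
  aliased with the refit model are dropped with a message.
* A pair detected in some transformations only is dissected with the
  missing augmented components set to zero and flagged `incomplete`
  (`drop_incomplete = TRUE` discards such pairs instead).
* Dominance-degree classes partition $[0, \infty)$ with left-closed
  boundaries at 0.2, 0.8, 1.2; a zero denominator with nonzero
  numerator classifies as overdominant, zero over zero as `NA`.

## Known limitations

* Real-data inputs must be fully homozygous line × marker tables; there
  is no imputation and no support for heterozygous (F2/BC) base
  populations or F2-metric parameterisations.
* The $(i_{ad}{-}i_{da})$ pairing in the $Z_4$ scan is identifiable
  only through the product-pair template or magnitude matching (see
  above).
* Fixed thresholds mean genome-wide error control is implicit in the
  hyperparameter calibration, not a formal FDR guarantee.
* Conditional-on-detection means are biased away from zero at low
  power; at the benchmark's $n = 800$, $h = 0.8$ every power is 1 and
  the issue does not arise.
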