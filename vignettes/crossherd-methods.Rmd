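---
title: "Methods: additive and dominance genomic analysis of cow weight and cumulative weight weaned"
author: "crossherd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: additive and dominance genomic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Commercial beef herds are crossbred on purpose: crossing breeds raises
heterozygosity, and the resulting heterosis improves fitness-linked
traits such as fertility and longevity. Two traits summarize a cow's
economics over her lifetime: her own weight at each pregnancy test (CW,
kg) and her cumulative weight weaned (WtW, kg) — the running sum of her
calves' weaning weights, with one record per breeding exposure and a
zero contribution when an exposure produces no weaned calf. WtW folds
fertility, calf survival and milk into a single longevity-weighted
production trait. `crossherd` implements the full analysis chain for
these traits — record construction, genotype QC, additive and dominance
genomic relationship matrices, random-regression REML, back-solved
variant effects with permutation significance, and pedigree/genomic
heterosis indicators — together with a synthetic multibreed herd
generator, so every stage can be exercised and tested end to end with
known truth.

## Record construction

A WtW record is created at every breeding exposure, starting with the
exposure intended to calve at age 2. Its value is the weaning weight of
the calf from that breeding (zero if none) plus all previous calves'
weaning weights, so WtW is non-decreasing in age within cow. The age
code attached to every record is the *intended calving age* in years;
a cow that tests open moves to the opposite calving season, shifting
her next intended age by 0.5 years, and she is culled after a second
consecutive open test. CW records are the observed weights at each
pregnancy test (records with a missing weight are skipped, not
imputed — CW is an observation, not a derived quantity).

Fixed-effect codes: an *opportunity group* concatenates the birth
season with the maximum single-breed composition bin (50 to <75%, 75 to
<87.5%, >=87.5%). We add a `<50%` bin because advanced-generation
crosses can have no breed above one half; without it the coding would
be partial. A cumulative calf sex covariate (males weaned minus females
weaned) absorbs the sex difference in weaning weight; it enters the WtW
model only, since CW does not accumulate calf contributions.

## Relationship matrices

Variants pass a 0.95 call-rate filter (variants first, then animals)
and a strict minor-allele-frequency filter (kept only when MAF >
0.005, so a variant at exactly 0.005 is removed). Close, nearly
redundant variants — within 50 kbp and |r| > 0.98 — are pruned scanning
left to right, keeping the left-most variant of each redundant group;
|r| rather than signed r is used because the sign flips under allele
relabeling, and the left-most rule makes pruning deterministic and
idempotent. The pruned-to-retained map is kept so pruned variants can
inherit significance later.

With alternate-allele frequency $p_j$ estimated from the analyzed
animals themselves (no external base population is assumed), the
additive GRM uses centered allele counts,
$$M_{ij} = m_{ij} - 2p_j, \qquad G = \frac{MM'}{2\sum_j p_j(1-p_j)},$$
and the dominance GRM uses genotypic dominance-deviation coding,
$$h_{ij} = \{-2p_j^2,\; 2p_jq_j,\; -2q_j^2\} \text{ for } m_{ij} =
\{0, 1, 2\}, \qquad D = \frac{HH'}{\sum_j (2p_jq_j)^2}.$$
Under exact Hardy–Weinberg proportions each column of $H$ sums to
zero, which the tests verify on a constructed fixture. A configuration
switch substitutes centered 0/1 heterozygosity indicators for the
deviation coding, since descriptions of "heterozygosity coefficients"
admit both readings; the deviation coding is the default because it is
the one consistent with a variance-component interpretation of $D$.
Missing calls (at most a few percent after QC) are mean-imputed per
variant, deterministically. Genomic inbreeding is $F_g = G_{ii} - 1$.

## The random-regression model

For one trait, records $y_{rt}$ of cow $i$ at intended calving age $t$
follow
$$y = X\beta + Z u_a + Z u_d \,(+\, Z u_{pe}) + e,$$
where row $r$ of $Z$ carries the normalized Legendre basis
$\phi(x_r)$, $x = 2(t-2)/(8-2) - 1 \in [-1,1]$, in cow $r$'s
coefficient columns. Default basis order is 1 (intercept + slope):
the age trends in these traits are smooth and monotone, and order 1 is
the smallest basis that lets genetic variance change with age.
Coefficient vectors have covariance $K_a \otimes G$ (additive),
$K_d \otimes D$ (dominance) and optionally $K_{pe} \otimes I$
(permanent environment), with homogeneous residual variance
$\sigma^2_e$. The permanent-environment term is a switch rather than a
fixed part of the model, and the residual is homogeneous by default,
because neither choice is identifiable from the descriptions we build
on; both variants can be fitted. Only univariate analyses are
implemented.

### REML

Variance components are estimated by restricted maximum likelihood on
the mixed-model-equation formulation. Writing $C$ for the MME
coefficient matrix at the current parameters, the restricted
log-likelihood is evaluated through
$$-2\ell_R = (N-p)\log 2\pi + N\log\sigma^2_e + \log|\Sigma| +
\log|C| + y'Py,$$
with $y'Py = (y'y - \hat\theta'W'y)/\sigma^2_e$ — identities the test
suite verifies against a dense $V$-based evaluation. Each iteration
computes the full inverse of $C$ (one Cholesky factorization and one
`chol2inv`), from which both the exact EM updates and the score vector
are available:

* **EM step** (monotone by theory):
  $K_{lm} \leftarrow (\hat u_l' A^{-1}\hat u_m +
  \mathrm{tr}(A^{-1} C^{u_l u_m}))/q$ per random term with structure
  $A$, and the matching residual update.
* **AI step**: the average-information matrix
  $\mathrm{AI}_{ij} = \tfrac12 y'P\dot V_i P \dot V_j Py$ and gradient
  give a Newton proposal, damped by a small ridge.
* **Over-relaxed EM**: an extrapolation $\theta + \gamma(\theta_{EM} -
  \theta)$ with an adaptive factor $\gamma$ (grown on acceptance,
  shrunk on rejection).

A proposal is accepted only if it is admissible (positive semidefinite
$K$ projected by an eigenvalue floor, positive residual) *and* raises
the restricted log-likelihood, so the accepted trace is monotone — an
invariant asserted in every test run. The AI step dominates near
well-conditioned interior optima (the small-instance oracle test
converges in a handful of AI steps to within $10^{-4}$ of a
brute-force maximization); close to a boundary (a dominance slope
variance near zero) it tends to overshoot, and the adaptive
over-relaxed EM carries convergence instead. Termination is on
$|\Delta \ell_R| <$ `tol` (default $10^{-6}$) or `max_iter`; a fit
stopped by the iteration cap is flagged `converged = FALSE` and
returns the best iterate.

GRMs computed from a finite variant panel are routinely singular; a
ridge of $10^{-6} \times$ mean diagonal (escalated tenfold until the
Cholesky factor is numerically sane) is added before inversion and
logged in the fit object.

### Projections and heritability

Animal effects are projected to age 8 — the age at which a cow has had
the opportunity to wean six calves — as $\hat u(8) = \phi(1)'\hat c$,
separately for the additive and dominance coefficients; total merit is
their sum. Age-wise variance fractions are
$h^2_a(t) = \phi(t)'K_a\phi(t) / (\phi' K_a \phi + \phi' K_d \phi +
\phi' K_{pe} \phi + \sigma^2_e)$ and analogously for dominance.

## Variant effects

Per-variant effects are back-solved from the projected animal effects:
$\hat\alpha = M'(MM')^{-1}\hat u_a$ and $\hat d = H'(HH')^{-1}\hat
u_d$, computed against the cached Gram identities $MM' = c_a G$ and
$HH' = c_d D$ (checked at entry). This is the minimum-norm solution,
so $M\hat\alpha$ reconstructs $\hat u_a$ exactly — asserted to
$10^{-6}$ relative in the tests. Effect vectors are z-standardized
with the sample SD (denominator $m-1$; pinned by a test). For
significance, the entries of the animal-effect vector are permuted $B
= 5000$ times (tests use scaled-down $B$); each permutation is
back-solved and z-scored, the per-variant SD of permuted z-scores is
the null scale, and $p_j = 2\Phi(-|z_j|/SE_j)$. This two-sided normal
reading is the one interpretation under which a "standard error of the
z-scores" yields a per-variant p; the permutation test is verified to
hold its nominal 0.05 level under an exchangeable null. Significance
is Bonferroni at family-wise 0.05 over the tested variants, and pruned
variants inherit the effect, p and flag of their retained
representative.

## Heterosis metrics

* **pHet** — expected retained heterozygosity from pedigree breed
  compositions, $1 - \sum_b s_b d_b$, after composites are decomposed
  to base breeds (Brangus = 3/8 Brahman + 5/8 Angus, and so on) and
  Angus/Red Angus are merged.
* **gHet** — fraction of heterozygous calls among non-missing calls
  (missing calls excluded from the denominator).
* **ROH / HRR** — consecutive-method runs with minimum spans of 1 Mb
  and 100 kb. The length minima are the only pinned constants; the
  secondary parameters (minimum 15/3 variants, maximum 1 Mb gap, one
  missing call allowed, no opposite-state call allowed) mirror common
  consecutive-method tooling and are exposed as arguments. The scan is
  greedy left-to-right: a run grows from the left-most qualifying call
  until a budget would be exceeded, is trimmed to end on a qualifying
  call, and scanning resumes after it; the tests prove this equals an
  exhaustive window enumeration with the same selection rule on random
  fixtures.

Cows are split at the mean total merit (additive + dominance) for each
trait into Low/High halves and into quadrants LL, LH, HH, HL (CW
letter first); ties at a mean go to the Low half, deterministically.
Group summaries report means with SE = SD/$\sqrt{n}$, and simple
least-squares $R^2 \times 100$ quantifies how much of the projected
dominance and total effects each metric explains.

## The synthetic herd generator

The generator's defaults emulate the structure the analysis assumes:

* **Breed panel.** Balding–Nichols divergence: per-variant ancestral
  frequencies $p_0 \sim U(0.05, 0.95)$ and breed frequencies
  Beta-distributed around $p_0$ with variance $F_{ST}\,p_0(1-p_0)$.
  Default $F_{ST}$ 0.1–0.15, matching moderate cattle breed
  divergence; the default desk-scale genome is 5 chromosomes of 100 Mb.
* **Pedigree.** A crossbreeding plan names purebred, composite, F1,
  backcross and three-way matings; founders per breed are few (order
  10–25) so that closed purebred lines accumulate the
  identity-by-descent that produces runs of homozygosity, while F1s
  carry essentially none. Offspring composition is always the parental
  mean.
* **Genotypes.** Gene dropping with Haldane recombination at 1 cM/Mb.
* **Events.** Each cow runs through the exposure/culling regime
  described above. Conception is Bernoulli with a logit shifted by
  centered genomic heterozygosity (the mechanism is an invention of
  the simulator — real data record outcomes, not mechanisms — chosen
  to create a tunable productivity–heterosis association). Calf
  weaning weight is base + sex effect + the cow's genetic value +
  noise, collapsing maternal genetic detail into the cow's own scale.
  True genetic values come either from coefficient sampling
  ($K \otimes G$ exactly, for parameter-recovery studies) or from
  per-variant effects with a positive dominance mean (directional
  dominance, for end-to-end heterosis studies).

What the generator does **not** emulate: genotyping error and
imputation artifacts, selection across generations, breed-specific
trait means for real breeds, maternal genetic effects as a separate
variance component, and seasonal environmental trends. Passing tests
therefore demonstrate the correctness and calibration of the
*machinery* under the stated generating model, not the magnitudes any
particular real herd would produce.

## Numerical choices and problem sizes

Tolerances: REML default `tol` $10^{-6}$ on the restricted logL;
Gram-identity check at $10^{-6}$ relative; GRM ridge $10^{-6}$ mean
diagonal, escalated as needed. The eigenvalue floor on $K$ proposals
is $10^{-10}\,\mathrm{var}(y)$.

The simulation studies shipped with the package use problem sizes
chosen to estimate their targets comfortably on a single workstation
core: variance-ratio recovery runs 1000 cows x 1000 variants per seed
with a $10^{-3}$ likelihood tolerance and a 10-iteration budget (the
age-8 variance fractions move by well under 0.01 beyond that point,
far inside the $\pm 0.1$ assertion), the permutation-calibration study
uses 200 animals x 500 variants x 500 permutations, and the end-to-end
heterosis study uses ~550 cows x 2000 variants. The acceptance script
re-runs the same studies at the same sizes.

## Known limitations

* The AI step is not trusted blindly: near boundaries it is usually
  rejected in favor of over-relaxed EM, which costs more iterations
  than a constrained Newton method would.
* Back-solving treats the GRM as exchangeable with $MM'/c$; after
  mean-imputation of missing calls this is exact, but with other
  imputation schemes the Gram check would fail (by design).
* The permutation p-values are approximate (normal tail on a
  permutation-estimated scale); their null calibration is verified
  empirically, not analytically.
* Composite-breed decomposition handles the standard composites; a
  user-supplied pedigree with novel composites must declare their
  base-breed fractions in the crossbreeding plan.
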