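---
title: "Gene-culture coevolution: hitchhiking, interference and sweep signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-culture coevolution: hitchhiking, interference and sweep signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcsweep)
```

## The model

`gcsweep` models a haploid biallelic genetic locus **A** (alleles $A/a$)
coevolving with a binary, vertically transmitted cultural trait **C**
(innovation $C$ vs. ancestral $c$). An individual's *phenogenotype* is the
joint state, e.g. $AC$. The population is summarised by three numbers:

* $x$ — frequency of the cultural innovation $C$,
* $Q$ — frequency of $A$ among $C$-practitioners,
* $R$ — frequency of $A$ among $c$-practitioners,

so the phenogenotype frequencies are $xQ$, $x(1-Q)$, $(1-x)R$,
$(1-x)(1-R)$, and the allele frequency is $p = xQ + (1-x)R$. At the
boundaries $x \in \{0, 1\}$ the unused conditional frequency carries a
flagged placeholder of $0.5$, which keeps every derived quantity finite
without affecting any phenogenotype frequency.

Fitness is multiplicative: $W_{AC} = (1+s_C)(1+s_A)$,
$W_{aC} = 1+s_C$, $W_{Ac} = 1+s_A$, $W_{ac} = 1$. With a neutral **A**
locus ($s_A = 0$) the mean fitness is exactly $1 + x s_C$.

Mating is random union of phenogenotypes (with replacement — the mating
frequencies are products of fitness-weighted frequencies, normalised by
$\bar W^2$), giving ten unordered mating classes. Genetic inheritance is
Mendelian; the cultural trait is then learned from the parents under one of
two rules:

* **Affinity bias** — the offspring copies the cultural trait of its
  genetically *more similar* parent (same focal allele) with probability
  $1-\beta_i$, the other parent with probability $\beta_i$
  ($\beta_1$ for $A$-bearing, $\beta_2$ for $a$-bearing offspring). The
  $\beta$s act exactly like recombination rates between gene and culture.
* **Cultural trait bias** — the offspring's own genotype biases the choice
  of trait: $A$-offspring adopt $C$ with probability $\gamma_1$,
  $a$-offspring with probability $\gamma_2$, whenever the parents differ.

`next_generation_exact()` sums mating frequencies times offspring
distributions over all ten classes. It is the package's single source of
truth: every closed form below is required (and tested) to agree with it to
$10^{-12}$, which is also how the bracketing of the printed recursions was
pinned down. Both rules with all bias parameters at $\tfrac12$ collapse to
copying a uniformly random parent, and the two engines then agree exactly.

Two structural facts follow from the transmission table and are enforced as
invariants rather than assumed:

* genetic transmission is unbiased in every family — e.g. offspring of
  $AC \times ac$ families carry $A$ with probability exactly $\tfrac12$
  under both rules and any biases;
* cultural transmission is *distorted* whenever $\beta_1 \neq \beta_2$ or
  $\gamma_i \neq \tfrac12$: offspring of $AC\times ac$ families adopt $C$
  with probability $(1-\beta_1+\beta_2)/2$ under affinity bias and
  $(\gamma_1+\gamma_2)/2$ under trait bias.

## Deterministic cultural hitchhiking

With $s_A = 0$ the one-generation closed forms (`step_affinity()`,
`step_trait_bias()`) iterate the system cheaply; for $s_A \neq 0$ no closed
form is published and both functions fall back to the exact engine. The
$R'$ recursion is not printed anywhere; it was derived by the same
family-accounting as $Q'$ and is verified against the engine across random
states.

A cultural sweep is started from the single-introduction convention
$x_0 = 1/N$, $Q_0 = 1$ (the innovation arises once, on the $A$ background),
$R_0 = 0.5$:

```{r hitchhike}
traj <- run_sweep(pheno_state(1e-6, 1, 0.5), fitness_params(0, 0.1),
                  affinity_bias(0.05, 0.001), t_max = 200)
attr(traj, "outcome")
attr(traj, "p_final")     # neutral allele dragged above 0.5
attr(traj, "H_hat")       # final relative heterozygosity
```

The summary statistic is the relative heterozygosity
$\hat H = \hat Q(1-\hat Q) / (R_0(1-R_0))$, the post-sweep expected
heterozygosity at the neutral locus over its initial value (the factor is
$4$ at $R_0 = \tfrac12$). By convention $\hat Q$ is read at $t = 200$; the
`stop_at_absorption` switch exposes the alternative of reading it at the
fixation generation (the two differ negligibly because $Q$ freezes once
$x \to 1$).

With $\beta_1 = \beta_2 = r$ the affinity model *is* classic two-locus
genetic hitchhiking with recombination rate $r$. The package carries an
independently coded selection-then-recombination haplotype recursion
(`msh_reference_step()`) and tests that the two match to $10^{-12}$
per generation; `heterozygosity_surface()` tabulates $\hat H$ and final $p$
over bias grids, reproducing the qualitative regions of the deterministic
analysis (strong hitchhiking only at very low $\beta_2$; under trait bias,
loss of $C$ when both $\gamma$s are small, and reversal of the association
when $\gamma_2 \gg \gamma_1$).

## Stochastic selective interference

`fixation_experiment()` embeds the exact engine in a finite-population
Wright-Fisher scheme: each generation, the four phenogenotype counts are
resampled multinomially around the engine's expected frequencies
(the standard infinite-gamete construction; the per-pair mating alternative
is isolated behind `wf_step()` so it could be swapped). A single $A$ copy
is introduced into a resident population with cultural frequency $x_0$
(deterministically rounded), landing on the $C$ background with probability
$x_0$. The no-culture baseline uses identical machinery with $x_0 = 0$;
with multiplicative fitness, an all-$C$ baseline gives identical
$A$-dynamics, which is itself a unit test. The default experiment follows
the package-wide illustration values $s_A = s_C = 0.1$, $N = 10^3$,
$x_0 = 0.5$.

```{r interference}
fx <- fixation_experiment(stochastic_run_config(
  N = 1000, fit = fitness_params(0.1, 0.1),
  model = affinity_bias(0.001, 0.001), x0 = 0.5,
  replicates = 5000, seed = 1))
fx
```

A ratio below one is the gene-culture analogue of the Hill-Robertson
effect; conditional fixation times lengthen at the same time. Under trait
bias the direction flips with the preference: $\gamma_1 > \gamma_2$
facilitates fixation, $\gamma_1 < \gamma_2$ hinders it. The baseline is
checked against the haploid diffusion formula
$(1-e^{-2s})/(1-e^{-2Ns})$ (`kimura_reference()`); note that at $s = 0.1$
the diffusion value $0.1813$ exceeds the exact Wright-Fisher probability
($\approx 0.177$, the branching-process value) by about $2.5\%$, which is
why the agreement test uses a four-standard-error Monte-Carlo band rather
than a tighter one. `max_generations` defaults to $100N$, and replicates
that fail to absorb are reported explicitly, never dropped silently.

## Secondary hitchhiking on a five-locus chromosome

The agent-based simulator (`sweep_experiment()`) extends the model to five
linked biallelic loci with the focal locus at the centre, flanked by pairs
of loci at recombination distances $r$ of 0.001/0.2 (heterozygosity
profiles) or 0.001/0.01 (haplotype spectra). Adjacent-interval crossover
probabilities are derived from the stated distances under independent
intervals; individuals are haploid with biparental, fitness-weighted
reproduction, symmetric allele flips at rate $\mu$ at the non-focal loci,
and cultural transmission driven by the focal-locus alleles.

After a neutral burn-in of $5N$ generations from a monomorphic start,
a sweep is attempted: a *genetic* sweep introduces one copy of a beneficial
focal allele; a *cultural* sweep introduces, in one random individual, the
favoured trait $C$ *together with a single new neutral marker allele at the
focal position* — the multilocus transcription of the single-origin
convention $x_0 = 1/N$, $Q_0 = 1$. The trait stays associated with that
founder haplotype only through the transmission rule: with $\beta \to 0$
the sweep drags one haplotype to fixation (a hard-sweep signature), while
larger $\beta$ lets $C$ fix without moving the genome. Only successful
sweeps are retained. By default one burn-in seeds many attempts, with
$N/10$ generations of neutral drift between attempts (fully independent
burn-ins sit behind a flag; for *neutral* reference snapshots the
between-snapshot drift should be raised to about $N$ generations, since
unlike sweep attempts nothing else decorrelates successive records).

Per successful sweep the simulator records per-locus heterozygosity
$2p(1-p)$ and the 32-class haplotype spectrum, which feeds the
`h_statistics()` layer: $H_1 = \sum_i p_i^2$,
$H_2 = H_1 - p_1^2$, and the soft-sweep diagnostic $H_2/H_1$. Haplotypes
are the five-locus genetic strings (the cultural state is never part of the
haplotype); `collapse_haplotypes()` restricts spectra to a subset of loci,
e.g. the four flanks.

## Fixation probability across sweep timings

For a weakly beneficial mutation arising *during* an established cultural
sweep, the sweep is treated deterministically,
$x(T) = 1/(1+e^{-T})$ with $T = s_C t$ and midpoint at $T=0$ (the package
follows this logistic; the description of the midpoint as "$x = 0$" in the
source analysis is taken as shorthand for $x = \tfrac12$, which is what the
logistic gives). The scaled mean fixation probability
$\Pi = (x P_x + y P_y)/2s_A$ and background difference
$\Delta = (P_x - P_y)/2s_A$ obey

$$\frac{\partial \Pi}{\partial T} = xy(\rho_1-\rho_2)\Delta
  - \theta\,\Pi(1-\Pi) + \theta x y \Delta^2, \qquad
\frac{\partial \Delta}{\partial T} =
  \Delta\big((\rho_1 y + \rho_2 x) + (2\Pi - 1)\theta
  + (x-y)(1-\theta\Delta)\big) - \Pi,$$

with $\rho_i = r_i/s_C$, $\theta = s_A/s_C$, and background-jump rates
$r_1 = r_2 = \beta_1$ (affinity) or $r_1 = 1-\gamma_1$, $r_2 = \gamma_1$
(trait bias). These scaled equations were re-derived by chain rule from the
unscaled $(P_x, P_y)$ system before implementation, so the printed forms
are used verbatim rather than guessed at.

The natural boundary lies *after* the sweep: a mutation arising once $C$
has fixed has the unlinked probability $2s_A$, i.e. $\Pi = 1$. The exact
boundary value of $\Delta$ is not determined by that argument; the solver
integrates backward (lsoda, `rtol = 1e-8`, `atol = 1e-10`) from
$T_{\max} = 20$ with $\Delta = 0$, an explicit, overridable assumption —
the backward dynamics contract $\Delta$ onto its slaved branch within about
one unit of rescaled time, so the choice is immaterial on the default grid
$T \in [-20, 20]$ (which covers $x$ from $\sim 2\times 10^{-9}$ to
$1 - 2\times10^{-9}$).

```{r ode}
fc <- fixation_curve(trait_bias(0.45, 0.5), s_A = 0.1, s_C = 0.1)
min(fc$Pi)            # < 1: interference when A-offspring shun C
net_sweep_effect(fc)  # integral of (Pi - 1) over timings
```

Three cross-checks pin the solver down: (i) for $\rho_1 = \rho_2$ it must
match an independently coded single-recombination-parameter genetic
hitchhiking ODE to $10^{-6}$; (ii) direct integration of the unscaled
$(P_x, P_y)$ equations in real time must reproduce $\Pi$ to within 2%;
(iii) `simulation_crosscheck()` compares $\Pi(T_0)$ with the
Wright-Fisher fixation-probability ratio when the mutant is introduced at
$x_0 = x(T_0)$. The distortion-corrected coefficient
$\tilde s_C = s_C + 2(\gamma_2 - \tfrac12)
(1 + s_C - 2 s_C x)$ is exposed via `effective_selection()`, but the
default pipeline keeps $\gamma_2 = \tfrac12$ (where $\tilde s_C = s_C$ and
the logistic is exact); $\gamma_2 \neq \tfrac12$ is accepted with a warning
as an extension beyond the solver's assumptions.

## Scope of the synthetic experiments

The simulators *are* the study system here — there is no external data.
What they emulate: vertical transmission with the two bias rules, drift,
selection, recombination, symmetric mutation. What they deliberately omit:
diploidy (the haploid model approximates intermediate dominance),
oblique/horizontal transmission, assortative mating, more than one cultural
trait, continuous chromosomes and new mutation at the focal locus. Passing
tests therefore certify the model's internal logic and its agreement with
the deterministic and diffusion limits — not that any real cultural trait
behaves this way.

Default problem sizes were chosen as desk-scale versions of the study
conditions: deterministic sweeps use $N = 10^6$-style initial frequencies
($x_0 = 10^{-6}$) and 200 generations; stochastic interference runs use
$N = 10^3$, $s_A = s_C = 0.1$, $\gamma_2 = 0.5$, $\beta_2 = 0.001$ and
$10^4$-scale replicate counts; chromosome experiments default to
$N = 10^3$, $\mu = 10^{-4}$, burn-in $5N$, and 100-200 retained sweeps
(the full-scale $N = 10^4$, $\geq 200$ sweeps setting is a flag away).
At the scaled $N$, per-locus diversity ($4N\mu = 0.4$) is lower than at
study scale, which compresses all haplotype-homozygosity ratios toward
zero; the *ordering* of conditions (hard $\approx$ perfect-copying
cultural $<$ intermediate-$\beta$ cultural $<$ neutral) is what the tests
assert, not the ratios' absolute values.

## Numerical conventions

* Deterministic iteration never reaches exact fixation; $C$ counts as fixed
  at $x > 1 - 10^{-9}$ and lost at $x < 10^{-9}$.
* Frequencies are renormalised once per generation against accumulated
  round-off; conservation is tested at $10^{-12}$ over $10^4$ random
  states.
* Bias parameters are accepted on all of $[0, 1]$ even though the
  interesting dynamics live at $\beta \leq 0.07$ and
  $\gamma \in [0.45, 0.95]$.
* All stochastic cores consume R's own RNG stream (including inside C++),
  so a single `set.seed()`/config seed reproduces any experiment exactly;
  ties in haplotype frequency are broken arbitrarily because $H_1$ and
  $H_2$ are tie-invariant (asserted by test).
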