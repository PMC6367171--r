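---
title: "Kin selection and the social evolution of sleep: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kin selection and the social evolution of sleep: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepkin)
```

## The question

Sleep removes an individual from social life for a large fraction of every
day, so how much an individual sleeps has consequences for its social
partners: a wakeful group member can guard the group against night-time
threats, and a wakeful rival can poach matings while its competitors sleep.
`sleepkin` implements a kin-selection analysis of this trade-off in a
group-structured population, asking three nested questions: how does
genetic relatedness among group mates shape the favoured sleep level; when
do the sexes favour different sleep levels; and when do the maternal- and
paternal-origin copies of a gene disagree about their carrier's sleep —
the conflict that predicts genomic imprinting of sleep loci and the
phenotypic signatures of its clinical disruption.

## Life cycle and parameters

The population is an island model with an infinite number of patches, each
housing `n_f` breeding females and `n_m` breeding males (defaults 4 and 4).
One generation proceeds:

1. **Night phase.** Each adult sleeps a fraction `z` of the night
   (`z` is bounded to `[m, 1]`; `m`, default 0.05, is the physiological
   minimum). Mean wakefulness `V` of the patch's adults protects the whole
   brood: the patch's offspring survive the night with probability
   `S = 1 - a (1 - V)`, where `a` in `[0, 1]` is the threat level.
2. **Reproduction.** Sleep buys viability: a parent of sex `x` multiplies
   its offspring production by `b_x z` (`b_x = 0` meaning no viability
   differences). Wakefulness buys contested matings: a fraction `c_x` of
   each sex's mating opportunities is decided by a within-patch contest
   with weight `w = (1 - c_x) + c_x (1 - z)`; a female's fecundity share
   and a male's paternity share are proportional to `w`. Mothers are
   drawn by fecundity share, fathers by paternity share.
3. **Dispersal.** Each offspring disperses with a sex-specific probability
   (`d_f`, `d_m`). With probability `d_B` all of a patch's dispersers
   travel together as a single bud which takes over the entire
   immigration of one destination patch ("tribe splitting"); otherwise
   they scatter independently among the patches not fed by a bud.
4. **Regulation.** Each patch's `n_f + n_m` breeding slots are filled by
   uniform sampling from the juveniles present after dispersal.

Two co-natal adults of sexes `x`, `y` (same natal patch) arise with
probability `phi_xy = (1 - d_x)(1 - d_y) + d_x d_y d_B`; the budding
mechanism is exactly what makes `phi` close pairwise, which is why the
"one bud monopolises one destination" routing was chosen over Poisson bud
arrivals (under which two immigrants could stem from different buds and
`phi` would not reduce to this closed form).

The two **selective scenarios** of interest are *protection* (`a > 0`,
`c_f = c_m = 0`: wakefulness is group vigilance) and *mating competition*
(`a = 0`, `c_f` or `c_m > 0`: wakefulness is mate poaching). All standard
panels use `d_m = 0`, `d_B = 1`, `b_f = b_m = 1` and sweep the female
dispersal rate `d_f` — female-biased dispersal, the pattern inferred for
ancestral human populations.

### A note on the two reward channels

The viability (`b`) and contest (`c`) channels are deliberately
*structurally* different: `b` scales absolute offspring production, while
`c` redistributes a fixed pool of matings within the patch. If both acted
on one linear weight, the mating scenario at `b = c = 1` would be exactly
neutral (the weight would be constant in `z`), leaving no mating-
competition model at all. With the contest form `w = 1 - c z`, `c` is
interpretable as the fraction of matings decided by night-time effort:
`c = 1` is a pure effort-proportional contest, in which a fully sleeping
individual cedes all contested matings, and interior sleep optima exist
throughout the dispersal range. `c` is accordingly bounded to `[0, 1]`.

## Relatedness

`solve_consanguinities()` computes the stationary neutral
identity-by-descent (IBD) structure from a four-variable linear recursion
(between-adult IBD `A_ff`, `A_mm`, `A_fm` and the inbreeding coefficient
`F`), built from the sib-share probabilities `1/n_f` (same mother) and
`1/n_m` (same father), Mendelian halving, and the co-natal probabilities
`phi_xy`. Conditioning the sampled gene on its parental origin yields the
full slot-resolved consanguinity matrix, from which
`relatedness_coefficients()` forms whole-genome and parent-of-origin
relatedness under the ratio-of-consanguinities scaling (recipient
consanguinity over actor self-consanguinity `(1 + F)/2`, so relatedness
to self alone is 1). Group relatedness `r_f`, `r_m` includes the actor
itself, because night survival is shared with self.

Two structural facts the package leans on:

* the whole-genome coefficient is exactly the mean of the maternal- and
  paternal-origin coefficients, because a random gene of self is IBD to a
  specific own gene with probability `(1 + F)/2` in every origin class;
* origin asymmetry (`r_mat != r_pat`) requires *both* sex-biased
  dispersal and equal-sex group sizes only jointly: with `d_f = d_m` and
  `n_f = n_m` the asymmetry vanishes exactly, but unequal sex numbers
  alone (`1/n_f != 1/n_m`) already produce asymmetry under unbiased
  dispersal.

The recursion is verified end to end by `pedigree_oracle()`, a compiled
neutral simulation of the exact life cycle that founds every allele with
a unique label and estimates IBD directly. Within-patch identity is
normalised by the measured between-patch background,
`(Q_w - Q_b)/(1 - Q_b)`: a lineage pair that escapes its patch behaves as
two random global lineages, so the normalisation removes the
finite-metapopulation background that the infinite-island recursion sets
to zero. This estimator was preferred over infinite-alleles mutation with
`u -> 0` extrapolation because the background term is hyperbolic in `u`
and linear extrapolation is badly biased for it. Oracle family sizes are
iid uniform-parent draws, which reproduces the recursion's sib-share
probabilities exactly rather than to `O(1/brood)`.

## Fitness and selection gradients

`expected_fitness()` is a direct-fitness kernel: the
reproductive-value-weighted number of breeding offspring of a focal adult
(daughter slots valued `1/(2 n_f)`, son slots `1/(2 n_m)`, each sex class
totalling 1/2), normalised to 1 at the resident. Offspring compete for
slots against the natal patch's philopatric juveniles plus resident
immigrants at home; against their own co-bud juveniles plus the
destination's philopatric residents when budding (this is the kin
competition that budding retains even at full dispersal); and against
pure residents when scattering.

`selection_gradient()` assembles class-specific gradients by the
Taylor–Frank method: central finite differences (step `1e-6`) of the
kernel in each actor role, weighted by the relatedness of the focal
class's gene to that role. Parent-of-origin classes use `r_mat`/`r_pat`.
These are the exact allele-lineage coefficients: the copies of an
origin-conditional (or imprinted) allele that currently sit in the slot
where they are not expressed still experience selection through the
expressed copies they are correlated with — in their own carrier
(probability `F`) and in patchmates (the partner's expressed-slot
consanguinity). Averaging a lineage over the two slots it occupies gives
self weight 1 and partner weight `r_mat` (or `r_pat`) exactly, because
the slot-resolved consanguinity matrix is symmetric. A corollary used by
the tests: the gradient of an origin-ignorant gene is the exact mean of
the two origin-class gradients.

`hamilton_decomposition()` splits the monomorphic gradient into
`-C + B r_eff`: the marginal direct effect of sleeping more, the summed
marginal effect on all patchmates, and the effective relatedness
weighting them. At an interior optimum the two cancel, forcing sleeping
more to be *selfish* (`C < 0`, `B < 0` — the protection scenario: the
sleeper keeps the fecundity benefit and dumps the vigilance burden on
the group) or *altruistic* (`C > 0`, `B > 0` — the mating scenario: the
sleeper cedes contested matings to its rivals).

## Optima

`solve_optimum()` handles three trait architectures:

* **monomorphic** — grid scan (1001 points) of the gradient over
  `[m, 1]`, sign changes refined by bisection to `1e-10`, boundary
  assignment when the gradient points outward at `m` or 1, convergence
  stability from the gradient's slope.
* **sex-specific** — damped iterated best response (damping 0.5,
  fixed-point tolerance `1e-8`) between the female and male 1-D
  problems, multi-started from `{m, (m+1)/2, 1}` per class; stability
  additionally requires the best-response Jacobian's spectral radius
  below 1.
* **parent-of-origin** — `z_mat*` and `z_pat*` are each class's
  *full-control* optimum: the root of the class gradient with a
  monomorphic resident. This is the level of sleep the class favours,
  and exactly the state an imprinted locus expressed from that slot
  evolves to, since after loudest-voice silencing the expressed allele
  alone sets the phenotype. The joint best-response system on allelic
  values under additive co-expression is *not* used for these optima: it
  is the escalating tug-of-war (exposed as `solve_allelic_escalation()`)
  in which each class drags its allelic value toward its own side until
  a boundary stops it — the instability that the loudest-voice argument
  resolves into imprinting, not a level anyone "favours". The
  origin-ignorant optimum `z_naive*` always lies between `z_mat*` and
  `z_pat*`.

Numerical choices worth recording: gradients are evaluated no closer than
`2e-6` to the boundaries of the strategy space, so that the
finite-difference stencil never leaves it — next to a degenerate state
(night survival `S -> 0` as `z -> 1` under `a = 1`) an unphysical
evaluation produces arbitrarily wrong values. A configuration in which
the median gradient magnitude over the grid is below `1e-8` is reported
as *neutral* (`z* = NA`): this is a real feature of the model, e.g. at
`d_f = d_m = 0` a patch is a closed lineage whose members' fates are
fully shared, so no sleep level is favoured over another. A related and
initially surprising exact feature: at `d_f = 1, d_m = 0, d_B = 1` every
competitive arena is purely intra-patch (daughters compete only within
their own bud, sons only at home), group survival cancels from all
fitness ratios, and full sleep is favoured regardless of the threat.

## Imprinting and perturbation predictions

When `z_mat* != z_pat*` (ties below `1e-8` count as no conflict),
`predict_imprinting()` applies loudest-voice-prevails: at a sleep
*promoter* the origin favouring more sleep is expressed and the other
silences itself; at a sleep *inhibitor* the logic is mirrored. Under the
standard female-biased panels, paternal-origin relatedness is the higher
one, so protection yields maternal-favours-more-sleep and mating
competition the reverse; male-biased dispersal swaps every prediction.

`predict_perturbation()` is pure dosage logic on active gene copies:
deletions remove an allele with its expression state, hypo-methylation
re-activates silenced alleles, hyper-methylation silences expressed ones
(the two swap under the methylation-as-activation convention), and a
uniparental disomy duplicates one parent's allele with its epigenetic
state. More active copies of a promoter mean more sleep; phenotype calls
are qualitative (`more_sleep` / `less_sleep` / `unchanged`) by design.
`figure4_table()` enumerates the full 2 scenarios x 2 locus types x 6
perturbations table.

## The individual-based simulator

`run_ibm()` (compiled, single xoshiro256++ stream, bit-identical for a
given seed) simulates the full stochastic life cycle with evolving
diploid alleles: Bernoulli night destruction of whole broods, Poisson
broods per female (mean `10 x` fecundity by default), contest-weighted
paternity, Mendelian transmission with per-component Gaussian mutation
(rate 0.01, sd 0.02, reflected into `[m, 1]`), the budding dispersal
routing described above, and uniform regulation with a global-pool
refill for patches left without candidates (a destroyed brood with no
immigrants — recolonisation is allowed, which keeps the metapopulation
alive even at `a = 1`). Expression modes cover the monomorphic,
sex-specific, additive parent-of-origin, and imprinted
(maternal-/paternal-expressed) architectures.

The simulator is the package's end-to-end oracle: equilibrium class
means (batch-means standard errors over the post-burn-in trajectory)
are compared with the analytic optima. The standard problem size for
these comparisons is 1000 patches x 5000 generations x 3 seeds, started
from the midpoint of the strategy space with burn-in 2500.

### What the agreement does and does not show

The analytic kernel is deterministic: it neglects demographic
stochasticity by design. Agreement within 0.05 of the analytic optimum
is obtained across the mating-competition panels (where `S = 1` and the
assumption holds; observed gaps are around 0.02), for moderate threat
levels in the protection scenario, and for the strong-threat defaults at
low-to-moderate female dispersal. At the strong-threat optimum, however,
night survival is only `S* ~ 0.1`: most broods are destroyed nightly,
destroyed patches are recolonised partly from the global pool, and the
realised relatedness falls below the neutral-recursion value. The
simulated equilibrium then sits systematically below the analytic
optimum, and the gap grows with `d_f` (about -0.03 at `d_f = 0.25`,
-0.05 at `d_f = 0.5`, -0.07 at `d_f = 0.75`). This is a known,
understood limitation of the deterministic approximation in the
near-lethal regime, not a property of real sleep biology the package
claims to capture; the relatedness machinery itself is validated
separately at exactly these parameters by the neutral pedigree oracle.

The simulator also makes no claim to realism beyond the model: patches
exchange migrants globally (no spatial geometry), generations do not
overlap, fecundity is effectively unlimited before regulation, and the
trait is a single scalar sleep level rather than a within-night
schedule. Passing tests therefore validate the mathematics of the
model, not predictions about any particular species.

## Worked example

```{r example, eval = FALSE}
p <- preset_params("fig3b", d_f = 0.5)$params   # mating competition
patch_relatedness(p)
opt <- solve_optimum(p, "parent_of_origin")
opt
predict_imprinting(opt, "promoter")
```

At these parameters paternal-origin relatedness exceeds maternal-origin
relatedness, the paternal-origin gene favours slightly more sleep, and a
sleep promoter is predicted to be paternally expressed; deleting the
paternal allele then reduces sleep while deleting the silenced maternal
allele changes nothing.
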