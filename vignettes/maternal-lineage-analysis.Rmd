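---
title: "Maternal lineage analysis with partial mtDNA haplotype data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal lineage analysis with partial mtDNA haplotype data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matriline)
```

## The model behind the package

In mammals the mitogenome is transmitted (essentially) only by mothers, so
in an error-free pedigree every *maternal line* — the set of all
descendants of a founder dam reachable through unbroken mother links,
males included — carries exactly one mtDNA haplotype. matriline exploits
this invariant in both directions:

* **downward**: two sequenced members of the same maternal line with
  different haplotypes prove a recording (or sample) error somewhere on
  the path between them;
* **upward**: in a conflict-free pedigree a single sequenced individual
  types its entire line, so sparse sequencing can be *imputed* to the
  whole population before, say, an association analysis between
  mitogenome polymorphism and a quantitative trait.

The package is organized as the pipeline `verif → stat → calc → sampl`
(each stage available as an R function and as a `run_module()` command):
verification and reliability indices, line statistics and imputation,
effective population sizes, and sampling design.

## Verification: conflicts, informative individuals, misplaced branches

A **conflicting pair** is two sequenced same-line individuals with
different haplotypes. The pairwise conflict count of individual $i$ is the
number of same-line sequenced individuals carrying a different haplotype.
An individual is flagged **conflicting** when its count exceeds that of
every individual it conflicts with — within one line this flags exactly
the carriers of the minority haplotype. Two tie rules are offered:

* `strict` — the literal "more conflicts than its opponents" rule. A
  1-vs-1 conflict then flags nobody, which is faithful but leaves the
  error unattributed.
* `both` (default) — equal counts flag both individuals. This is
  conservative: it surfaces unattributable pairs for curation instead of
  hiding them.

An **informative individual** lies on the maternal-tree path between two
sequenced individuals (endpoints included); only this part of the
pedigree can ever be checked by the available sequences. The indices are

$$\mathrm{HC} = 100\,\frac{|\text{conflicting}|}{|\text{haplotyped}|},\qquad
\mathrm{IC} = 100\,\frac{|\text{conflicting} \cap \text{informative}|}{|\text{informative}|},\qquad
\mathrm{MISPLACED} = 100\,\frac{|\text{misplaced}|}{|\text{conflicting}|}.$$

Indices with an empty denominator are reported as *undefined* (`NA` with a
reason), never silently as zero.

A conflicting individual is **misplaced** when its nearest sequenced
maternal ancestor carries the *same* haplotype: the pattern produced by a
whole branch recorded under the wrong line, where all conflicts share one
root cause. Note a structural consequence of this definition: the topmost
conflicting member of a wrongly-recorded branch can never itself satisfy
it (its nearest sequenced ancestor lies outside the branch), so the
package reports each branch at its *anchor* — the topmost conflicting
individual whose subtree contains the misplaced ones, obtained as the
maximal elements of the misplaced set united with their nearest sequenced
ancestors. The **pruned conflict count** then reduces each branch to a
single error:
$|\text{conflicting}| - \sum_b (\text{conflicts in branch } b - 1)$.

## Effective sizes from the probability of identity

For a uniparental line system with label frequencies $q$, the
probability of identity is $\mathrm{PI} = \sum_k q_k^2$. Three modes share
the same machinery:

* **maternal** — labels are founder dams; founder frequencies are uniform
  ($q_k = 1/k$ over the $k$ founder dams), reference frequencies are each
  dam's female line members in the reference population over all
  reference females.
* **haplotype** — labels are imputed mtDNA haplotypes; every line without
  a sequenced member receives the deterministic pseudo-haplotype
  `PSEUDO_<founder id>` so it counts as its own line. The reference map
  counts *all* reference individuals, both sexes, since males carry (but
  do not transmit) their line's mtDNA.
* **paternal** — the mirror image over sire links and reference males.

The increase in identity and the effective size are

$$\Delta\mathrm{PI} = \frac{\mathrm{PI}_r - \mathrm{PI}_f}{1 - \mathrm{PI}_f},
\qquad N_e = \frac{1}{\Delta\mathrm{PI}},$$

with $N_e = \infty$ when representation is unchanged and $N_e$ undefined
(with a reason) for a single founder line. A negative $\Delta\mathrm{PI}$
is impossible for nested populations and is treated as a hard input error
rather than clamped. The *reference population* is the set of individuals
born inside a year window — read from a two-line `reference_years.txt`
file, or defaulting to the full span of recorded birth years (a data-driven
replacement for a hard-coded constant); individuals without a birth year
are never reference members.

Two counting decisions were genuinely open and are fixed as follows.
Founder dams $k$ include every maternal-line root that is not a recorded
male — childless female founders count, while male line roots (e.g.
founder sires, which root singleton "lines" of their own) are excluded
from $k$ but still contribute their pseudo-haplotypes on the reference
side of the haplotype mode. Lines represented in the reference population
only by males drop out of the maternal reference map but stay in the
haplotype map, which is why `line_distributions()` lists them separately.

## Sampling design

Given a sequencing budget $N$ over $L$ lines with reference pool sizes
$R_l$ and previously sequenced counts $P_l$, stage one allocates slots:

* no priors, $N \ge L$: one guaranteed slot per line, the remaining
  $N - L$ spread proportionally to $R_l - 1$ by largest-remainder
  (Hamilton) division;
* no priors, $N < L$: one slot each to the $N$ largest lines by $R_l$;
* with priors: the $k$ prior-free lines are seeded with one new slot
  each; total targets come from a largest-remainder division of
  $N - k + \sum P_l$ proportional to $R_l$; the remaining $N - k$ new
  slots then fill the gaps $\max(N_l - P_l - \text{seed}, 0)$, scaled by
  another largest-remainder division when the gaps exceed the remaining
  budget. The literal reading — "new $=\max(N_l - P_l, 0)$" — can
  overspend the budget whenever some line is already sequenced beyond its
  proportional share, so the implementation distributes *new* slots; the
  proportional targets and all limiting cases are unchanged and the
  budget is never exceeded.

Remainder ties go to the larger $R_l$, then the lexicographically smaller
line id; all distance ties below go to the lexicographically smallest
individual id. Plans are therefore fully reproducible.

Stage two picks the individuals. Without seeds the first pick is the
**central individual** (minimum sum of tree distances to the rest of the
pool); each later pick greedily maximizes the sum of distances to the
already-selected set. Previously sequenced individuals act as the seed
group (and are never re-selected). The greedy heuristic addresses the
problem *with the first individual fixed*; the test suite checks it
against an exhaustive-enumeration oracle of that anchored problem — exact
agreement on all chains and stars up to 12 members, and within 10% of the
optimum on 200 random line trees (in practice it attains the anchored
optimum on all of them). The unconstrained optimum can differ: on a star
the best $k$-subset is $k$ leaves, while the anchored solution includes
the hub — the price of guaranteeing a central representative.

When an `available` column exists (the token `1`; anything else is a
valid negation), selection pools are restricted to available individuals;
unfillable slots are reported per line and never redistributed, so the
user can either raise the budget or select by hand.

## The synthetic-pedigree generator

`synth_pedigree()` is first-class, tested code: all fixtures in the test
suite are generated by it at run time. It emulates a closed herd with
discrete generations: founder dams and sires with unknown parents,
Poisson-distributed daughter and son counts per female (unequal $R_l$
arise naturally, keeping allocation and identity computations
non-degenerate), sires drawn uniformly from existing males, one birth-year
step per generation, founder haplotypes drawn *with replacement* from a
label pool so that shared-haplotype lines occur (making maternal and
haplotype $N_e$ differ), and a Bernoulli sequencing mask. Defaults (10
founder dams, 5 generations, Poisson means 1.6, 30% sequenced) give
populations of roughly 500 individuals in 15 lines.

Two error processes with exact ground truth can be injected:
a *single individual* conflict (one sequenced individual receives a
foreign haplotype) and a *misplaced branch* (a grandmother–mother–daughter
chain is overwritten with a foreign haplotype and at least four concordant
members are force-sequenced, so the chain is the strict minority). The
branch construction deliberately produces one anchor with two misplaced
descendants — the smallest configuration whose recovery exercises the
branch-pruning rule end to end.

What the generator does **not** model: mtDNA mutation (any within-line
difference is treated as an error, matching the analysis assumptions),
overlapping generations, inbreeding avoidance, selection, immigration and
missing birth years. Passing tests therefore demonstrate correctness of
the algorithms under clean discrete-generation demography, not robustness
to every messiness of field pedigrees.

## Input handling and numerical choices

The CSV dialect is deliberately simple: comma separation, a header whose
keywords (`ID`, `father`, `mother`, `YOB`, `gender`, plus optional
`haplotype`, `available`) locate the columns regardless of order, no
quoting, extra columns ignored. Unknown parents are empty or `0` by
default (configurable). Gender accepts `M/m/1` and `F/f/2`; anything else
is unknown gender, which is only fatal when it collides with a parental
role. Fatal checks (ancestry cycles via iterative resolution plus strong
components on the remainder; parental-role gender inconsistencies) are
all collected in one pass — strictly more informative than stopping at
the first, with the same accept/reject behavior. Missing-parent
auto-correction deletes single mentions and creates records for repeated
mentions (gender inferred from the role) and is idempotent.

Internally all per-individual computations are vectorized over depth
levels of the maternal forest (line assignment by pointer jumping,
subtree counts by level-wise aggregation), so verification, statistics
and effective sizes scale linearly: the test suite processes a
~120,000-record generated pedigree through `verif`, `stat` and `calc` in
a few seconds. Pairwise-distance work is confined to the sampling stage
and to the line pools it actually selects from. Test problem sizes were
chosen accordingly: 100 replicate pedigrees of ~500 individuals for the
recovery studies, trees of up to 12 members for exhaustive dispersion
enumeration, 500 random configurations for allocation accounting.

## Known limitations

* Haplotype differences are binary; a mutation model (treating rare
  within-line changes as events rather than errors) is out of scope.
* The paternal mode mirrors the maternal one; Y-haplotype effective size
  is not implemented.
* Conflict resolution itself is manual by design: the package locates and
  ranks the inconsistencies but does not rewrite ancestry links.
* Report files carry fixed names and a documented, human-readable layout;
  they are not byte-replicas of any other tool's output. Machine-readable
  CSV twins accompany the statistics reports.
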