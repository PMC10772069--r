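---
title: "Time-resolved kinship structure of founder-population genealogies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved kinship structure of founder-population genealogies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

founderkin analyses ascending genealogies of founder populations — the kind
of deep, register-based pedigrees available for colonial-era Quebec — and
asks how population structure emerged over time. This vignette explains the
models and procedures the package implements, the choices that were open and
how they were settled, and what the synthetic scenarios can and cannot show.

## The data model

A pedigree is one row per individual with `id`, `father`, `mother` (0 =
unknown), `sex`, and register-style metadata: `marriage_year` and
`marriage_region` refer to the individual's *parents'* marriage (siblings
share them; immigrants married outside the study area carry an
`origin_country` instead), plus proband flags and group labels for the
contemporary study subjects. Parent links must form a DAG; an ancestor may
occupy several genealogical positions at once (implex, or pedigree
collapse), which is the rule rather than the exception in founder
populations. Validation rejects duplicate ids, dangling parent references
and cycles outright; sex/role inconsistencies only warn, because real
registers contain them.

Completeness at generation $g$ is the filled fraction of the $2^g$ ancestor
*positions*, averaged over probands; an ancestor occupying $k$ positions
contributes $k$. Counting positions rather than distinct persons matches the
"maximum possible number of ancestors" denominator and makes completeness
non-increasing in $g$.

## Kinship and inbreeding at maximal depth

The kinship coefficient $\varphi(a,b)$ is the probability that one allele
drawn at random from each of $a$ and $b$ is identical by descent. The
engine uses the classical recursion
$$\varphi(a,a) = \tfrac12\,(1 + \varphi(f_a, m_a)), \qquad
\varphi(a,b) = \tfrac12\,(\varphi(f_u, v) + \varphi(m_u, v)),$$
where $u$ is whichever of $a,b$ has the larger generation index (the longest
chain of known ancestors) — $u$ then cannot be an ancestor of $v$, which
guarantees termination on any DAG, including heavy implex; ties break by
id. Unknown parents contribute 0. No depth truncation is applied anywhere:
"maximal depth" means the recursion exhausts the known pedigree. Inbreeding
is $F_a = \varphi(f_a, m_a)$.

The recursion is memoized on unordered pairs and implemented in C++ (the
same engineering choice the established genealogical packages make); the
memo is scoped to a single `kinship_matrix()` / mean computation to bound
memory. The independent check, `kinship_oracle_paths()`, is a pure R
path-counting implementation of Wright's formula
$\sum_A \sum_{p_1, p_2} (1/2)^{n+m+1} (1 + F_A)$ over path pairs that share
no individual besides the common ancestor $A$. Every term is a dyadic
rational, exactly representable in doubles, so the two routes are compared
at 1e-12 on hundreds of random pedigrees.

## Periods, imputation, and the temporal analyses

Ancestors are assigned to 25-year periods by their parents' marriage year;
bins are anchored so that 1751–1775 is a bin. Missing years are imputed
upward through the pedigree: earliest dated child's year − 30, else earliest
dated grandchild's year − 60, in a single pass from recent generations to
old, so imputed years cascade. Two choices here were genuinely open and are
settled as follows: among several dated children we take the *earliest*
year (conservative against inflating late periods), and cascading is
allowed but flagged (`$imputed`). Known years are never overwritten. The
parent–child same-bin overlap fraction is reported as a diagnostic; 25-year
bins keep it at a few percent.

Per period, two summaries are produced:

* **Classical (Torgerson) MDS** on the distance $1 - \varphi$ between the
  period's ancestors, after removing ancestors with no kinship ties to
  anybody in the period (all-zero off-diagonal row; a single filter pass).
  The first two coordinates are kept; negative eigenvalues are truncated to
  zero. MDS coordinates are defined only up to rotation and sign, so all
  tests compare inter-point distances, never raw axes.
* **Group trajectories**: for each proband group, the ancestor set is the
  union of the strict ancestors of that group's probands — one ancestor can
  therefore feed several groups. Mean pairwise kinship is averaged over a
  period's member pairs, mean inbreeding over members. The two need not
  agree: inbreeding reflects who actually married whom, kinship reflects the
  whole pool, and assortative (endogamous) mating drives them apart. When a
  period holds more pairs than `max_pairs`, an unbiased random subset of
  pairs is averaged instead; the default pipeline cap is 20,000 pairs.

## MRCAs, minimal distance, genetic contribution

"Most recent" is defined by descent, not by distance: a common ancestor $C$
of a pair is an MRCA iff no strict descendant of $C$ is also a common
ancestor of the pair. The common-ancestor set $S$ is upward-closed, so this
reduces to removing from $S$ every parent of a member of $S$ — an
observation that makes per-pair enumeration cheap. A pair may have several
MRCAs, and two MRCAs of one pair may sit at different minimal distances.
Pairs where one proband is an ancestor of the other take that proband as
the sole MRCA (registries contain such pairs; the convention is documented
rather than silently erroring).

Each record carries the minimal meiotic distance (shortest upward path to
the MRCA from each proband, summed — four meioses for first cousins) and
the genetic contribution to each proband, $GC = \sum_{paths} (1/2)^{len}$,
computed by a reverse-topological scatter pass per proband. GC products are
summed over a pair's MRCAs.

Group curves count MRCAs per pair, binned by minimal distance (an ancestor
serving many pairs is counted once per pair), cumulated over meioses, with
the per-bin GC-product sum kept non-cumulative. To remove sample-size bias
between groups, each group is resampled down to 47 subjects 1000 times
(without replacement); replicate $r$ reseeds the RNG with
$(seed + 982451653\,r) \bmod (2^{31}-1)$, so curves are exactly
reproducible. Groups at or below 47 subjects are used whole (flagged, one
replicate). Because a pair's MRCA set depends only on that pair's own
ancestry, the per-pair records are computed once and the bootstrap reduces
to averaging stored histograms over resampled pair sets — exact, and fast
enough for 1000 replicates.

## Gene dropping and IBD segments

The simulator assigns each founder two whole-genome haplotypes with unique
labels and drops them through the pedigree: each transmission recombines
the parent's two haplotypes with crossovers placed as a Poisson process of
rate 1 per 100 cM (Haldane model, no interference) and a random start
phase. Interference is immaterial at the ≥ 2 cM resolution used here. The
default map is 22 autosomes with human-like genetic lengths totalling
~3544 cM. Coordinates are cM, 0-based, half-open. Individuals with exactly
one known parent get a unique phantom founder on the unknown side; phantom
labels are unique per slot, so they can never generate spurious sharing.

IBD segments between two probands are maximal intervals with matching
founder labels in any of the four haplotype pairings, unioned per
chromosome before the 2 cM length filter (mirroring how pairwise IBD
callers report segments); per-pairing output is available via
`merge = "pairings"`. Two identities anchor the simulator to the kinship
engine and to closed-form theory, and are asserted within three Monte-Carlo
standard errors in the tests: the expected unfiltered pairing total is
$4\varphi L$, and the expected segment count for a unilineal relationship
with $a$ common ancestors at $d$ meioses is $a\,(dL/100 + c)/2^{d-1}$
($L$ total cM, $c$ chromosome count). A real-data IBD caller also applies a
detection-confidence filter (e.g. a LOD threshold); a noiseless simulation
has no analogue for it, and none is applied — absolute bin counts are
therefore not comparable to genotype-derived results, only orderings and
shapes are.

Sharing is summarised per group as the mean segment count per within-group
proband pair in 5 cM length bins starting at the 2 cM filter:
$[2,5), [5,10), \dots$

## The synthetic colonization scenarios

Real register genealogies are access-restricted, so the generator produces
pedigrees with the statistical structure the analyses assume. It runs a
chronological marriage market over 25-year periods: founder couples enter
per region on an immigration schedule (or are recruited from a source
region — the daughter-colony mechanism), couples draw Poisson numbers of
children reaching marriage, children enter the market about one generation
later (Normal(30, 5) years, matching the ~30-year marriage-to-marriage
interval such registers show), and mates are chosen within the region with
probability `endogamy`, otherwise from the pooled other regions. A region
can carry a carrying capacity: as a period's marrying cohort approaches it,
fertility is damped linearly towards replacement. This keeps small isolates
demographically stable — persistently drifting without either exploding or
going extinct. Unmatched singles wait up to `max_wait` further periods.
Probands are sampled last: parents married in the region within a recent
window, all four grandparents inside the scenario. An optional ±5-year
jitter on recorded years models confidentiality rounding (off by default).
Remarriage is not modelled.

`quebec_preset()` encodes an eight-group scenario at desk scale
(~18,000–21,000 individuals against ~94,000 in the real registry): urban
core regions founded 1608/1642 with immigration to 1750; a small
Charlevoix-like community (1675) recruited internally; a Saguenay-like
daughter colony founded 1838 from it with a high growth rate — the
bottleneck-then-25-fold-expansion pattern; Gaspé groups arriving 1757–1790,
among them a small, fully endogamous, capacity-limited Acadian-like isolate;
and a North Shore settlement (1850). Proband counts per group are 138, 70,
86, 47, 97, 71, 67 and 89. Founding sizes, growth rates and endogamy values
are not historical estimates: they were chosen, and verified across
scenario seeds, so that the pipeline reproduces the qualitative contrasts
the analysis is designed to detect — a kinship plateau after expansion
onset in the expansion group against a persistently rising inbreeding in
the isolate; a cumulative-MRCA crossover (the isolate ahead at ≤ 10
meioses, the expansion group ahead beyond ~13, its deep tail fed by the
bottleneck's implex); and the corresponding IBD-length contrast (the
isolate ahead in long bins, the expansion group ahead of the urban groups
in short bins).

What passing these checks shows is that the *pipeline* recovers built-in
structure of known direction; it does not validate the generator against
real demography. Real registers add missingness correlated with group and
era, record-linkage error, remarriage, migration waves with internal
structure, and genotype-level noise in IBD detection — none of which the
generator emulates. Assertions on synthetic scenarios are therefore
orderings and signs, never magnitudes.

## Numerical and reproducibility choices

* Kinship: memoized floating-point recursion in C++; the oracle uses exact
  dyadic arithmetic; agreement asserted at 1e-12.
* MDS: `stats::cmdscale`; negative eigenvalues truncated; tests compare
  distances only.
* All randomness flows through R's RNG — including the C++ gene-drop, which
  draws via R's API — so `set.seed()` governs everything. The pipeline fans
  one master seed out to fixed per-stage sub-seeds
  (`seed * 7919 + stage_offset * 104729 mod 2^31 - 1`); bootstrap replicates
  derive child seeds as documented above. Rerunning any stage with the same
  config and seed is bit-identical, which the tests assert on whole output
  files.
* Pipeline tables are CSV with 10 significant digits; the manifest records
  md5 checksums of every output.
* Problem sizes: the shipped analyses run the preset at ~20k individuals,
  cap per-period kinship means at 20,000 pairs (unbiased subsampling,
  package default), and use 1000×47 bootstrap replicates; the test suite
  uses smaller caps (documented in each call) chosen as the smallest sizes
  at which the asserted orderings are decisively resolved.

## Known limitations

* The marriage market is heuristic (single pass per period, uniform
  cross-region kernel); it is a scenario generator, not a demographic
  inference tool, and regional migration structure is not calibrated.
* Mean-kinship trajectories for small groups in late periods rest on few
  ancestors and are noisy at desk scale; the package reports member counts
  so users can judge.
* The gene-drop simulator is noiseless and sex-averaged (one map for both
  sexes, no interference); X-chromosomal kinship and genotype-level IBD
  detection are out of scope.
* Inbreeding for individuals with one unknown parent is 0 by definition,
  which understates inbreeding where records are incomplete — as does any
  pedigree-based estimate.
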