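---
title: "Contact-site propensities and score re-ranking: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-site propensities and score re-ranking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(contactprop)
```

## The contact model

Two residues form a **contact site** when the Euclidean distance between
their C&beta; atoms is at most a *cutoff* (in &Aring;) and their sequence
separation $|i - j|$ is at least a *separation* threshold (adjacent
residues have separation 1). Glycine, which has no C&beta;, is represented
by its C&alpha;; residues with neither atom resolved are excluded from all
pairs rather than silently placed at the origin. The distance predicate is
$d \le$ cutoff ("not greater than") and the separation predicate is
$|i-j| \ge$ separation; a strict-inequality variant of the latter is
available (`separation_strict`) for comparison with tools that use the
other convention.

Cutoffs of 6–12 Å and separations of 1–15 are the ranges the sweep helpers
target; the evaluation standard throughout the package is **8 Å /
separation 10**, the setting used by `truth_map()`.

The **contact degree** of a residue is the number of contact sites it
participates in. Average contact degree over an ensemble pools every
residue of every domain, including degree-0 residues. Because it is
ambiguous whether the spread of that quantity should be taken over residues
or over proteins, `average_contact_degree()` reports both (`sd` and
`sd_domains`). Across a cutoff or separation sweep the average degree is
well described by a power law $y = a\,x^{b}$; `fit_power_law()` estimates
$(a, b)$ by ordinary least squares on $\log y \sim \log x$ — the standard
deterministic choice — and reports $R^2$ on the *linear* scale against
$a\,x^b$, so the goodness-of-fit convention is explicit and others can
switch to a log-scale $R^2$ if they need to compare with a different
pipeline.

## Propensity statistics

For a structural class $k$ (alpha, beta, alpha+beta), the per-type contact
propensity is

$$W c_{a,k} = \frac{1}{N_{a,k}} \sum_{n=1}^{N_{a,k}}
  \frac{Ic_{a,n}}{Iw_{a,n}},$$

the unweighted mean over the $N_{a,k}$ proteins containing amino acid $a$
of the per-protein fraction of type-$a$ residues that form at least one
contact. Each protein contributes one ratio regardless of its size; the
standard deviation reported alongside is over those per-protein ratios. A
type absent from every protein has an *undefined* (NA) propensity, never a
zero. $W t_{a,t}$ is the same statistic over the proteins of a topology
$t$.

Pair statistics count each contact once under its unordered amino-acid
type pair (homotypic pairs such as Cys–Cys once per contact, with no
factor-2 correction):

$$f p_{a_1,a_2,k} = \frac{J c_{a_1,a_2,k}}{J w_k}, \qquad
  f pn_{a_1,a_2,k} = \frac{f p_{a_1,a_2,k}}{f_{a_1,k} \, f_{a_2,k}},$$

where $Jw_k$ is the total number of contact sites in the class and
$f_{a,k}$ the occurrence frequency of type $a$ over the 20 standard types
(the unknown placeholder X is excluded from frequency numerator and
denominator). Contacts involving X are reported under X rows of the pair
table; by default they still count toward $Jw_k$ — the literal "all
contact sites" — so $\sum fp = 1$ over the 21-letter pair alphabet, and a
flag (`include_x_in_total = FALSE`) removes them from the total instead.
`fpn` rows involving X, or where a frequency is zero while $fp$ is zero,
are undefined (NA); a zero frequency with positive $fp$ is inconsistent
input and raises an error.

How well a topology represents its class is summarized by

$$S_t = \sqrt{\frac{1}{N_{a,t}-1} \sum_{a}
  \left(W t_{a,t} - W c_{a,k(t)}\right)^2},$$

over the amino-acid types present in the topology (X excluded, at most
20). $S_t = 0$ exactly when the topology's profile coincides with its
class's, which is also the degenerate case of a "topology" containing the
whole class; with fewer than two types present it is undefined.

## Class assignment from secondary structure

DSSP codes H, G, I are simplified to helix, E to sheet, everything else to
coil; then every maximal helix run shorter than 5 residues and every sheet
run shorter than 3 is reassigned to coil (the simplification is
idempotent). Fractions are computed over the full residue count, and the
thresholds are applied strictly as stated by the underlying composition
scheme: more than 15 % helix and less than 10 % sheet is alpha; less than
15 % helix and more than 10 % sheet is beta; less than 15 % of both is
alpha+beta; anything else — including exact boundary values, which satisfy
no strict inequality — is unassigned and skipped by the re-ranking
pipeline.

The alpha+beta rule as stated selects domains *poor* in both secondary
structures, which is unusual for that label and may be a transcription
artifact of the original composition scheme; because the package cannot
know, it implements the rule literally and exposes
`assign_class(rule = "both_rich")` for the conventional both-rich variant
rather than silently guessing a default.

## The re-ranking algorithm

`rerank()` post-processes an external predictor's per-pair scores (for
instance direct information from direct coupling analysis). The idea: the
composition of the top $K$ pairs, viewed as amino-acid type pairs, should
resemble the class's contact pair frequencies; pairs whose type is
over-represented relative to the class get pushed out, pairs whose type is
under-represented get pulled in.

1. Pairs are sorted by score (descending; ties broken by $(i,j)$ so runs
   are deterministic). The first $K$ form the *top set*, the rest the
   *rest set*.
2. **Removal pass** — walking the top set from the lowest score upward,
   the pair's empirical frequency $Jc_{a_1,a_2}/K$ is computed with the
   pair counted (*inc*) and not counted (*exc*); if the *exc* value is
   strictly closer to the class frequency, the pair moves to the removal
   set. Counts update immediately, so later decisions see the shrunken top
   set (a frozen-counts variant is available via `live_update = FALSE` for
   sensitivity analysis). The denominator stays $K$ throughout, even while
   the top set is smaller — the target set size is a constant of the
   procedure, not the current cardinality.
3. **Addition pass** — walking the rest set from the highest score
   downward, a pair is appended to the end of the top set when including
   it brings the empirical frequency closer to the class value; accepted
   pairs update the counts immediately, mirroring the removal pass. The
   pass stops when the top set reaches $K$ or the rest set is exhausted.
4. **Backfill** — if the top set is still short of $K$, the most recently
   removed pairs return first, appended at the end.

Pairs containing an X residue are never evaluated or moved; if the initial
top $K$ contains them, they simply stay. In `mode = "fpn"` the same
procedure runs with both sides normalized: the class table's `fpn` column
on one side, $\,(Jc/K) / (f_{a_1,d} f_{a_2,d})$ with the domain's own
frequencies on the other.

For ranked evaluation the output keeps retained pairs in score order,
then additions in acceptance order, then backfills — "the end of the top
set" is taken literally, so early precision is driven by the retained
head of the ranking.

Two structural properties are worth knowing. When the input has exactly
$K$ pairs, the output *set* always equals the input set: anything the
removal pass discards is restored by backfill (though the order may
change). And a class table exactly equal to the top set's own empirical
distribution is a fixed point — nothing moves.

## Evaluation

`tp_curve()` reports cumulative precision: the fraction of the first $n$
ranked predictions that are true contacts under the 8 Å / separation-10
truth map, for $n$ from 1 to 200 by default. A predicted pair counts only
at exact $(i,j)$ identity. `mean_tp_curve()` averages per-domain curves
unweighted; a domain with fewer predictions than $n$ contributes only
where its curve is defined, rather than being padded with failures.

## What the generators emulate — and what they do not

The package is exercised end to end on generated structures with known
ground truth:

* `make_helix()` — ideal &alpha;-helix (rise 1.5 Å per residue, 100° turn,
  C&alpha; radius 2.3 Å, C&beta; at a fixed radial offset). Its only
  contacts are the classic $i,i\pm3/4$ turn neighbours, so at separation
  10 a straight helix is contact-free — the idealized extreme of
  single-helix topologies, which is also why helix ensembles are the
  sparse ("alpha") reference in density comparisons.
* `make_hairpin()` — two antiparallel extended strands (3.4 Å rise) at a
  fixed inter-strand C&beta; distance (default 5 Å), joined by a
  12-residue loop arcing away from the strands. Registered cross-strand
  pairs sit exactly at the gap distance with separation > loop length, so
  they all survive the separation-10 filter; this is the dense ("beta")
  ensemble.
* `make_coil()` — a self-avoiding random walk (3.8 Å step, 3.5 Å exclusion
  radius), used where unstructured geometry is wanted.
* `make_scores()` — true contacts draw scores from
  $N(\mu_s, \sigma_s)$ and non-contacts from $N(\mu_n, \sigma_n)$,
  emulating a predictor with imperfect separation. Gaussian is the only
  noise family; heavier-tailed score distributions are out of scope.

Sequence composition is stratified by burial: strand positions sample only
the eight hydrophobic types (V, I, L, F, M, W, Y, C) and loop positions
only eight polar/charged types (D, E, K, N, Q, S, G, P), each with natural
relative weights (`aa_composition_buried`, `aa_composition_exposed`).
This complete stratification is a deliberate idealization of the
hydrophobic-core enrichment of real structures: it guarantees that true
contacts carry a class-consistent pair-type signal for the pair-frequency
tables to pick up, while score noise is type-blind. Real proteins
stratify far less sharply — polar residues do occur in strand cores, and
their contacts then carry class-rare type pairs that the removal pass can
discard. Consequently, a passing improvement benchmark here demonstrates
that the algorithm exploits pair-frequency signal *where such signal
exists*, not that a gain of similar size is available on real contact
predictions.

All generators are seed-deterministic, restore the caller's RNG state, and
round-trip through PDB files to within the 1 mÅ coordinate precision of
the format.

## Study conditions of the benchmark

`rerank_benchmark()` fixes the protocol used by the acceptance script and
the improvement test: hairpins of 25 residues per strand plus the
12-residue loop (62 residues, ≈ 75–80 true contacts each); 100 training
domains to estimate the class `fp` table; 200 independent test domains;
scores with signal $N(1, 0.6)$ against noise $N(0, 0.6)$ (substantial
overlap, so the raw ranking is good but imperfect at depth 10); and the
standard top-set size $K = 200$. These sizes keep the full run in the
tens of seconds while leaving the paired comparison at depth 10 with a
standard error a few times smaller than the effects of interest. The
comparison is paired per domain: the improvement is the mean over domains
of (re-ranked − raw) TP rate at depth 10, reported with its standard
error.

The choice $K = 200$ matters more than it may appear: the empirical
frequencies $Jc/K$ and the class frequencies share a comparable scale only
when $K$ is large relative to the per-type-pair counts. With a small $K$
the empirical distribution of a single domain's top set is far coarser
than the class table and the removal pass over-fires; $K = 200$ is the
regime the procedure is designed for, and small-$K$ runs in the unit tests
exercise the mechanics, not the statistics.

## Numerical and degenerate-input choices

* Residues are renumbered consecutively in file order, so chain breaks do
  not inflate separations; `honor_gaps = TRUE` switches to author
  numbering where inflated separations are wanted.
* Alternate locations resolve to the highest occupancy; insertion-coded
  residues keep file order.
* Score tables are canonicalized to $i < j$ at read time; duplicate
  unordered pairs are an error, not a silent merge.
* Tables written by `write_table()` carry a single `#`-prefixed header and
  full double precision (`%.17g`), so a write/read round trip reproduces
  values bit-for-bit.
* Fewer than two usable residues yields an empty contact map with a
  warning; a class with zero contacts yields an all-NA `fp` table with a
  warning; `St` with fewer than two present types is NA with a warning.
  Undefined is always distinguished from zero.
* `fit_power_law()` refuses non-positive values and fewer than three
  points rather than fitting through them.

## Limitations

Only C&beta; contact definitions are supported — no heavy-atom,
side-chain-center, or Voronoi-tessellation contacts, which are known to
shift pair-propensity rankings. The statistics modules make no attempt to
correct for sequence redundancy; that is the caller's responsibility when
assembling real domain sets. The generators produce idealized geometry
(no Ramachandran validation, no side chains beyond C&beta;) and, as
discussed above, an idealized composition stratification. mmCIF input and
running DSSP itself are out of scope; DSSP output files and plain 3-state
strings are consumed as-is.
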