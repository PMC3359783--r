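---
title: "Profile-based kinome annotation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-based kinome annotation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinomescan)
```

## The annotation model

A eukaryotic protein kinase is recognised here by two layers of
evidence. The first is a *profile search*: every sequence is aligned
locally against a master kinase profile, a position-specific scoring
matrix (PSSM) summarising the catalytic domain across groups, and only
hits with E ≤ 10⁻⁴ proceed. The second is *motif anatomy*: a functional
kinase must be long enough to carry a complete domain (≥ 200 residues),
must conserve at least one glycine of the glycine-rich loop template
`GXGXXG` (positions 1, 3, 6 of the template are the glycines), and must
carry the catalytic aspartate of the catalytic loop (consensus
`HRDLKXXN`). A sequence that passes the profile search and the glycine
check but lacks the aspartate adopts the kinase fold without the
catalytic base: a protein-kinase-like non-kinase (PKLNK). Among
accepted kinases, those whose aspartate is immediately preceded by
arginine are RD kinases; the arginine is required exactly (lysine does
not count), because the RD property is defined by that residue's
interaction with the phosphorylated activation loop.

Accepted kinases (and PKLNKs, for fold context) are then assigned to
Hanks–Hunter subfamilies: a subfamily-profile hit is a candidate when
its percent identity exceeds 30 (strictly) and its profile coverage is
at least 0.70; the best candidate — by identity, then coverage, then
score, then profile name — fixes the subfamily, whose declared parent
fixes the group. Sequences with no candidate fall into
Other/Unclassified. The census reports per-group counts and half-up
rounded percentages with the accepted calls as denominator.

## Scoring, E-values and numerical choices

**Log-odds and pseudocounts.** Profile columns score residue `a` as
`2·log2(f_a / p_a)` half-bits, with
`f_a = (n_a + w·p_a) / (N + w)`; the background `p` defaults to uniform
0.05, which keeps the brute-force oracle arithmetic exact (published
amino-acid frequencies can be supplied instead). The pseudocount weight
defaults to 1 for subfamily and domain profiles. The synthetic master
profile is built with weight equal to its seed count (one master per
group): a broad-specificity profile must tolerate group-specific
residues, and the heavier regularisation caps the penalty of an
"absent" residue so that local alignments extend across the whole
domain instead of fragmenting at mutation clusters. Per column the
background-expected score is ≤ 0 by construction (it is a negative
Kullback–Leibler cross term), which the tests assert.

**Alignment.** The scanner is Smith–Waterman local dynamic programming
of a sequence against profile columns with affine gaps (open 11, extend
1, half-bit units — conventional protein-search scale). Local
alignments start and end in the match state; `X` scores 0 in every
column. Non-overlapping suboptimal hits are recovered greedily: after
each traceback the covered sequence positions are masked and the DP is
rerun, which is what lets one polypeptide report two kinase domains.
Ties between reported hits break by score, then leftmost sequence
start, then profile name.

**E-values.** Each profile is calibrated empirically: ≥ 200 i.i.d.
background decoys are scanned, and Gumbel parameters are fitted to the
maximal-score distribution by the method of moments
(`λ = π/(σ√6)`, `μ = mean − γ/λ`, `K = e^{λμ}/(m·n)`), giving
`E = K·m·n·e^{−λS}`. A zero-variance score distribution is a
calibration error. The calibration is deterministic per seed, shifting
all scores shifts only the location, and the database-wide E-value of
the best score among fresh decoys is ≈ 1 — all asserted in the tests.

**Pairwise identity.** Global (Needleman–Wunsch) alignment with match
+5 / mismatch −4 and gaps open 11 / extend 4; identity is identical
pairs over aligned non-gap pairs. The gap extension is deliberately
stiffer than the scanner's: with extension 1, gapping *around* a
mismatch run becomes cheaper than aligning through it once the run
exceeds ~11 residues, and unrelated sequences then inflate their
"identity" toward the chance-match ceiling (in the extreme, two random
sequences align only their chance matches and report 100%). With
extension 4, skipping a k-mismatch run always costs more (22 + 8k) than
the mismatches themselves (4k), so identity between unrelated sequences
stays near the 5–6% chance level and the planted identity hierarchy
(within-subfamily > within-group > between-group) is measured
faithfully.

**Identity reference.** The > 30% identity of the assignment rule is
measured against the profile *consensus* by default, because a profile
hit has no single member sequence; a member-based mode (maximum
identity against any stored seed) is available via
`default_config(identity_reference = "members")` for libraries built
with `keep_seeds = TRUE`.

**Coordinates.** All spans, internal and reported, are 1-based
inclusive — the R and Biostrings convention; reports print the same
coordinates the functions return.

**Rounding.** Census percentages round half-up to 2 decimals (0.005 →
0.01), matching how published kinome distribution tables are formatted;
a rounded group table can sum to slightly off 100 (the tests allow
±0.05).

## Architecture, clustering, pathway

Domain architectures collect all domain-profile hits at E ≤ 10⁻⁴ and
resolve overlaps greedily by score (ties: longer, then leftmost);
overlaps of ≤ 10 residues are tolerated because domain boundaries are
fuzzy. Twin kinases require two non-overlapping master-profile hits,
each with coverage ≥ 0.70 and its own mapped catalytic aspartate —
a Janus-like protein whose second domain lacks the aspartate is not a
twin. Transmembrane segments come from a Kyte–Doolittle sliding-window
predictor (window 19, mean hydropathy > 1.6, runs merged when closer
than 5 positions, spans extended to window edges); it replaces an HMM
tool because the pipeline's contribution is the downstream
receptor/soluble classing, not the membrane model. Any accepted kinase
with ≥ 1 predicted segment is a receptor kinase (a receptor tyrosine
kinase when its group is TK); the group itself is never changed by the
flag.

Clustering uses `(100 − identity)/100` distances. Single linkage at a
configurable threshold stands in for BLAST-based clustering, whose
original parameters are unpublished; outliers are the singletons of the
partition. Dendrograms are neighbor joining (via `ape`) on
catalytic-domain spans — the region the profile hit covers — with
negative branch lengths clamped to 0. Organism-specific clusters are
maximal clades of ≥ `min_size` leaves with ≥ 90% of leaves from one
organism.

Pathway mapping turns each template protein into a single-sequence
profile, searches the target proteome, and keeps the best hit at
E ≤ 10⁻⁴, rescuing at E ≤ 10⁻³ otherwise; the rescue pass approximates
an iterated-search second pass with a relaxed threshold against the
target proteome only. `close` requires identity > 30% *and* template
coverage > 0.70 (both strict); a significant hit below either level is
`remote`; no hit in either pass is `absent`. Among multiple hits the
best is chosen by E-value with identity as tie-break, a rule this
package fixes explicitly since "best homolog" is otherwise ambiguous.

## What the synthetic generator emulates — and what it does not

`generate_library()` plants one master domain per group (random
sequence, glycine loop at columns 9–14, `HRDLKxxN` catalytic loop at
the domain midpoint), derives subfamily founders at 30% substitution
and 5-sequence seed alignments at 10% substitution, never mutating the
motif columns. `generate_proteome()` draws kinases from subfamily
founders at a stated divergence (default study condition: 25%), PKLNKs
by a catalytic D→A substitution, twins as two same-subfamily domains
joined by a polar linker, truncated fragments cut below 200 residues
with both motifs retained (so the length filter alone rejects them),
receptor constructs with a 25-residue hydrophobic stretch, and decoys
as i.i.d. background draws. Substitutions are uniform over the 19
alternative residues, which makes expected identity ≈ 100·(1 − d)% and
keeps every divergence calculation checkable; a scoring-biased mutation
mode is deliberately not the default.

Benchmark problem sizes, chosen once as the study conditions: a
7-group × 2-subfamily library of 300-column domains calibrated on 200
decoys of length 350; a benchmark proteome of 200 kinases at 25%
divergence, 50 PKLNKs, 20 truncated fragments and 200 decoys; 20 twin
constructs; 50 additive 8-leaf matrices for topology recovery; a
20-template pathway fixture (15 close / 3 remote / 2 absent).

Passing these benchmarks shows the machinery is correct — the scanner
equals exhaustive enumeration, the cascade's decisions follow exactly
from planted anatomy, classification recovers a planted hierarchy well
inside its thresholds. It does **not** show field performance on real
proteomes: real kinase families have conserved *chemistry* rather than
conserved *letters* (a BLOSUM-type substitution structure the uniform
mutation model lacks), real alignments need indel handling inside
domains, real proteomes contain atypical kinases with non-canonical
catalytic loops, and real profile libraries are far larger. Two
consequences are worth naming. First, with uniform substitution and
match/mismatch scoring, a ~20%-identity homolog has negative expected
score per column and is undetectable in principle; the pathway
fixture's *remote* homologs are therefore built as high-identity
partial-coverage fragments, which exercise the same classification
boundary through the coverage condition instead. Second, the planted
motif geometry makes motif mapping easier than in real families where
the loops drift; the cascade's column-anchored design (locating motifs
through the profile alignment rather than by regular expressions) is
the part that transfers, not the measured 100% recall.

## Degenerate inputs and tie-breaks

Empty FASTA files, duplicate identifiers, empty record lists,
single-sequence alignments, all-gap profiles, uncalibrated scans,
zero-variance calibrations, unknown profile labels in hit lists, empty
template lists and mismatched truth tables are all errors with named
messages. Non-standard residue codes (B, Z, U, J, O, `*`) map to `X`
with a warning by default, since predicted ORF sets contain them; `X`
scores zero everywhere, so an all-`X` sequence can never reach the
reporting threshold. Sequences shorter than the hydropathy window
return an empty segment list with a message. Consensus ties take the
alphabetically first residue; census tables at subfamily level with all
calls unclassified are a one-row table, not an error.

## Known limitations

- One-pass profile search: no iterated (PSI-style) profile refinement,
  no word-hit heuristics, no composition-based statistics.
- The 27-outlier exclusion of the original protocol is approximated by
  single-linkage singletons at a configurable identity threshold
  (`flag_group_outliers()`), since the original clustering parameters
  are unpublished.
- Pairwise identity substitutes for multiple alignment in distance
  matrices; trees therefore reflect pairwise, not simultaneous,
  homology.
- PKLNK status is supported by profile coverage ≥ 0.5 rather than by
  structural fold recognition.
- The TM predictor is a hydropathy heuristic; signal peptides and
  topology are out of scope.
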