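---
title: "Methods: thermodynamics, thermoalignments and tiling paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamics, thermoalignments and tiling paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotile)
```

This vignette documents the models, numerical conventions and design
choices behind `thermotile`, in the spirit of a methods section: what is
computed, under which assumptions, and where the genuinely open choices
were resolved.

## The two-state nearest-neighbor model

All hybridization scoring rests on the two-state (all-or-none) duplex
model: enthalpy and entropy of a primer-template duplex are sums over
adjacent base-pair doublet steps plus one initiation term per terminal base
pair. The packaged parameter file
(`inst/extdata/nn_parameters_v1.tsv`) carries the unified Watson-Crick set
with its initiation and self-complementary symmetry terms, the four
published single-internal-mismatch sets (G·T, G·A, A·C, C·T), the
identical-base mismatch set (A·A, C·C, G·G, T·T), and the tandem G·T
doublets; each entry has a source tag. Step lookup is symmetric under
reading the duplex from the opposite strand, a property the test suite
checks exhaustively over all 112 parameterized doublets.

The template argument of `duplex_enthalpy_entropy()` is expressed in the
*primer frame*: the genomic window rewritten in the primer's sense, so a
column is complementary exactly when the two characters are equal. This
convention makes mismatch positions, 3'-terminal checks and re-extraction
audits trivial string comparisons.

The melting temperature is

$$T_m(K) = \frac{\Delta H^0 \times 1000}{\Delta S^0[\mathrm{Na^+}] + R \ln(C_T/x)}$$

with the entropy salt-adjusted as
$\Delta S^0[\mathrm{Na^+}] = \Delta S^0[1\,M] + 0.368\,(N/2)\ln[\mathrm{Na^+}]$.
Conventions, all documented constants:

* $N$, the duplex phosphate count, is $2(L-1)$ for an $L$-mer duplex
  (both strands, no 5'-terminal phosphates), applied uniformly.
* The sodium equivalent is $[\mathrm{mono}] + 120\sqrt{[\mathrm{Mg^{2+}}] -
  [\mathrm{dNTP}]}$ (mM); when dNTPs reach or exceed Mg$^{2+}$ the divalent
  contribution is zero (dNTPs chelate the magnesium).
* Default chemistry: 50 mM monovalent, 1.5 mM Mg$^{2+}$, 0.8 mM dNTPs,
  $C_T = 0.25\,\mu M$, $x = 4$; $R = 1.9872$ cal/(K·mol). All configurable
  via `reaction_conditions()`.
* Self-complementary oligos get the symmetry entropy term and $x = 1$.
* A denominator that fails to be negative cannot describe a melting duplex
  and raises a "non-physical duplex" error rather than returning NaN.

Two columns mismatched within one doublet step have no published parameters
outside the tandem G·T cases; such steps contribute (0, 0) and are flagged
on the profile. Alignments containing them are always far below priming
temperatures, so this neutral pseudo-step never gates a decision; a strict
mode (`on_unparameterized = "error"`) names the offending step and position
instead. When a thermoalignment carries a mismatch in its 5'-terminal
column, the initiation class (G/C vs A/T) follows the primer's terminal
base; 3'-terminal mismatches never reach scoring because such sites are
excluded upstream.

## Secondary structure

Hairpin and dimer evaluation uses an internal simplified exhaustive fold,
kept deliberately behind the `thermo_core` interface so an external
structure engine could be substituted without touching any filter logic:

* **Hairpins**: every perfect Watson-Crick stem of at least 3 bp closing a
  loop of 3-30 nt is enumerated; the stem is NN-scored and the loop added
  as a purely entropic penalty interpolated from published 37 °C loop
  increments. The hairpin transition is unimolecular (no $C_T$ term).
* **Homodimers / heterodimers**: every ungapped antiparallel offset of the
  two strands is scored after trimming to the outermost-paired core, with
  mismatch parameters applied inside. Homodimer Tm uses $x = 1$;
  cross-dimer stability is reported as $\Delta G^0_{37}$ in cal/mol with
  salt-adjusted entropy. The evaluation is bit-exactly symmetric in its two
  arguments (the argument order is canonicalized), a hard requirement.
  "No stable structure" is reported as $-\infty$ (Tm) or 0 (free energy),
  sentinels that can never trip a filter.

This engine ignores bulged stems, multi-loops and dangling ends; it is a
screen against self-interactions, not a folding server. The corresponding
filter removes an oligo when a structure melts within 20 °C (default) of
its on-target Tm, and a pair when the cross-dimer is more stable than
-2000 cal/mol. That threshold is stored in cal/mol: the value is sometimes
quoted in other units, but -2 kcal/mol is the physically sensible reading
for a dimer screen, and the configuration documents this explicitly.

## Unique oligo design

Enumeration slides a 1-bp window of every length in the configured range
(default 18-27 nt, bracketing typical PCR primer lengths) across both
strands, so a region of length $n$ yields $2\sum_L (n - L + 1)$ oligos.
Filter conventions, where the underlying rules admit readings:

* GC clamp: *more than three* G/C among the last five bases means $\ge 4$.
* Repeats: $\ge 4$ consecutive copies of a mono- or dinucleotide unit
  (AAAA, ATATATAT); the unit count is a setting.
* The A/T-end filter looks at the 3'-terminal base only.
* Tm and GC ranges are inclusive at both ends.
* Variant masking replaces SNPs with `n` and indels with `N`; the
  base-composition filter then removes any oligo containing a non-ACGT
  character (this also removes oligos over assembly gaps). With the
  polymorphism filter disabled, masked characters are resolved back to the
  reference base before that test.
* GC% uses only unmasked A/C/G/T characters in its denominator.

Each filter is a pure predicate, so the final pass set is independent of
evaluation order; the cascade order (sequence features, then thermodynamic
interactions, then exact matching) only determines the per-category
accounting and avoids computing expensive predicates for oligos already
excluded. Exact-match uniqueness is an exhaustive string search over both
genome strands (`Biostrings` pattern matching), which — unlike a capped
heuristic search — cannot miss a second occurrence.

## Off-target scanning

The scanner emulates a low-stringency seed-and-extend search: every exact
7-mer of the primer seeds a window on either strand, a vectorized banded
local alignment prescreens each seeded anchor, and surviving windows are
aligned with `Biostrings::pairwiseAlignment()` (match +1, mismatch -1, gap
open/extend 2, local). The prescreen uses linear gap cost 2 — a lower bound
on the affine cost — so it can only over-admit, never prune a reportable
window. Reported hits must reach 70% identity over the local alignment,
contain an exact run of seven matches, and score at least `score_min`
(default 10). The score floor plays the role of the permissive
expectation-value cutoff of heuristic aligners: without any alignment
statistics, every bare 7-mer match in the genome would otherwise qualify as
a "hit" and flood the specificity stage with thermodynamically irrelevant
alignments. Any site similar enough to matter for mispriming — say 70%
identity across most of a primer — scores well above the floor. Caps on
hits per subject and on subjects exist for parity with capped external
searches but default to off.

A hit is on-target, and excluded, when its subject interval overlaps the
primer's own site by at least 1 bp on the binding strand. External hit
tables in a BLAST-like tabular format can be imported in place of the
internal scanner for large genomes; reversed minus-strand coordinates are
normalized on import.

## Thermoalignments

Local alignments are usually truncated and sometimes gapped, but a real
priming interaction involves the whole primer against a contiguous
template. The end-filling and de-gapping rules (shift primer bases 3'-ward
over primer gaps, discard the template 5' overhang; shift template bases
over template gaps and re-extend at the primer-5' side) have a single net
effect, which is the implemented contract: *the template window is the
contiguous genomic window of exactly primer length that anchors the
primer's 3'-most aligned base at its hit-assigned template coordinate,
preserving strandedness*. Anchoring the 3' end operationalizes maximizing
complementarity at the site of polymerase extension. Because local
alignments never end in a gap column, the anchor is unique: the tie-break
(most 3'-terminal-5 complementarity, then fewer mismatches, then lower
coordinate) is specified for completeness but cannot fire. Windows that
would run past the subject's end are dropped with a message — a boundary
site cannot form a full-length template.

Per primer, thermoalignments with a mismatch at the exact 3'-terminal base
are excluded from Tm aggregation (such sites do not extend); mismatches at
positions 2-5 from the 3' end are recorded (fraction of hits) but never
filter. The maximum and the 90th-percentile off-target Tm are reported; the
percentile uses the nearest-rank definition
($\lceil 0.9n \rceil$-th order statistic), and only the maximum gates the
specificity decision: a primer passes when its on-target Tm is at least the
threshold (default +10 °C) above its maximum misprime Tm. A primer with no
scored off-target site has a sentinel maximum of $-\infty$ and is trivially
specific. The on-target Tm used in this margin is the duplex Tm of the
primer at its own site.

## Pair selection and tiling

Amplicon length is the distance between the two primers' 5' ends, counted
inclusively (`stop - start + 1`); the convention is documented rather than
derivable. Pair filters: amplicon length range, Tm difference at most
10 °C, the pair's lower Tm at least the misprime margin above the *maximum*
misprime Tm of *both* primers, cross-dimer floor, and (optionally) no
assembly-gap run inside the amplicon. Indel content is annotated, never
filtered.

Each surviving pair is a node; a directed edge $i \to j$ requires the
amplicons to overlap by at least 1 bp with $start_i < start_j$ and
$stop_j > stop_i$ (strict), so edges strictly increase both endpoints and
the graph is acyclic. The raw edge score is the cumulative length of the
two amplicons penalized by their overlap, $E = (len_i + len_j) - O_{ij}$ —
read as sum-then-subtract, i.e. the union length; an alternative reading
(union-then-subtract) would only shift all scores by the overlap and is not
implemented. Scores are rescaled against the graph-wide maximum,
$W = M_g - E \ge 0$, turning the longest-reach preference into a shortest
path problem. Per weakly connected subgraph, a zero-weight virtual source
feeds the minimal-start amplicons and the maximal-stop amplicons feed a
zero-weight virtual sink; the solver is a dynamic program in start order
(valid because the graph is a DAG), with deterministic tie-breaks: total
$W$, then fewer nodes, then lexicographically smallest start coordinates.
The test suite verifies on random instances that this program returns
exactly Dijkstra's distances and that its paths are coverage-maximal with
the fewest possible amplicons, by exhaustive path enumeration. Should a
subgraph's sink set be unreachable from its source set (a configuration we
have not observed, but which weak connectivity alone does not preclude),
the solver falls back to the farthest-reaching amplicon among reachable
ones.

One exception precedes the graph analysis: when several amplicons share a
primer, cover nested segments and overlap nothing outside that
shared-primer group, only the maximum-coverage amplicon is retained.
"Outside" is read as: any amplicon not in the shared-primer group.

The path's amplicons are assigned alternately (per subgraph) to multiplex
groups A and B, so consecutive overlapping amplicons land in different PCR
tubes; a post-assignment audit resolves cross-subgraph overlaps by
flipping, and opens a further group with a warning only if no two-group
assignment exists. Group compatibility scoring itself (primer-primer
interactions across a tube) is delegated to external multiplex software via
the exported input file.

## The synthetic-data generator

`fixture_spec()` / `generate_genome()` / `generate_variants()` produce
fully deterministic test genomes: i.i.d. background with a tunable GC
fraction, planted repeat families (a master sequence per family; copies
diverged by independent substitutions and optional single-nucleotide
deletions, with every edit recorded in a truth table), assembly-gap N runs,
and SNP/indel records emitted as VCF v4.1 with the single-position indel
convention (multi-base REF anchored at one POS). The default specification
describes the regime this tool exists for: a 50-kb genome in two
chromosomes whose 4-kb target is about 55% covered by planted repeats —
one exact family (caught by the uniqueness filter) and one 5%-diverged
family (caught by the specificity margin) — with variant densities of
45 SNPs and 4 indels per kb, the order observed in diversity panels of
large crop genomes. In-target repeat copies are laid out evenly with
random jitter; off-target copies are placed uniformly, rejecting overlaps.

What the generator does *not* emulate: nested/truncated transposon
structure, segmental duplications much longer than an amplicon, GC
isochores, sequencing artifacts, or population haplotype structure. Tests
passing on these fixtures demonstrate the correctness of the algorithms —
completeness of the scanner against known planted sites, coordinate
fidelity, filter logic, optimality of the tiling path — not wet-lab
performance on any particular real genome.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline on the
50-kb fixture (4-kb target, ~80,000 enumerated oligos, hundreds of
candidates, $10^3$-$10^4$ pairs); single stages are exercised on smaller
inline fixtures. These sizes were chosen so the whole suite completes in a
few minutes on one CPU while every pipeline branch, including the dense
overlap graphs that repeat-rich targets produce, is exercised. All
randomness flows through a single integer seed; identical inputs and
configuration produce byte-identical output files (timings are kept in the
returned object, never in the files).

## Known limitations

* Thermodynamics: no dangling-end or loop-sequence parameters, no RNA, no
  polymerase kinetics or amplification-efficiency prediction; the Tm model
  is equilibrium two-state.
* The off-target scan requires one exact 7-mer; a site diverged so evenly
  that no seed word survives is invisible (the same blind spot any
  seed-based search has), and the score floor additionally hides very
  short, isolated near-matches.
* The specificity decision uses the maximum misprime Tm only; the reported
  90th percentile is informational.
* Primer re-design inside uncovered tiling gaps is out of scope: selection
  is single-pass.
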