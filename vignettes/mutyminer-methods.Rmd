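---
title: "Methods: motif-anchored MutY authentication and its supporting statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-anchored MutY authentication and its supporting statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutyminer)
```

## What the pipeline decides, and why motifs

A BLAST-style similarity search against a metagenomic protein set
cannot by itself distinguish MutY from its helix-hairpin-helix (HhH)
relatives: the catalytic N-terminal fold is shared across the
superfamily, and endonuclease III homologs routinely score well against
MutY queries. What is diagnostic is chemistry, not overall similarity:
a small set of residues with defined biochemical roles, at positions
that are stable in a structural alignment. `mutyminer` therefore
separates *finding candidates* (alignment statistics) from
*authenticating them* (a reference-anchored motif catalog), and makes
the second step data-driven and editable.

## The motif catalog

The shipped catalog (`inst/extdata/muty_motif_catalog.json`) anchors
ten motifs in Geobacillus-type MutY numbering:

| motif | positions | allowed | role |
|---|---|---|---|
| catalytic_glu | 43 | E | acid–base catalysis |
| wedge_gln | 48 | Q | DNA wedge |
| wedge_tyr | 88 | Y | DNA wedge / base stacking |
| ts_tyr | 126 | Y, S, T, N | transition-state contact |
| catalytic_asp | 144 | D, E | catalysis |
| small_linker | 145 | G, A, V, T | backbone geometry |
| catalytic_asn | 146 | N | transition-state support |
| iron_sulfur | 192, 199, 202, 208 | C ×4 | 4Fe4S chelation |
| l_xxx_p | 265 (L, M, F) … 269 (P, E) | | C-domain hydrophobic core |
| og_recognition | 305–309 | \[HQNRK\]-x-F-\[ST\]-\[HQNRK\] | OG readout |

The allowed sets encode the substitutions observed among functional
homologs: Ser/Thr interchange at the OG-contacting position (both can
make the N7/O8 hydrogen bonds), polar residues standing in for the
flanking His pair, Glu for the catalytic Asp, hydrophobic residues for
the L of L-xxx-P and Glu for its P. The Phe of F-(S/T)-H is kept strict
because substitutions there have not been observed in functional
enzymes; loosen it in the JSON if your data say otherwise. Wildcard
pattern positions (`"*"`) accept any canonical residue but still count
as motif positions: if they fall in an alignment gap the motif is not
satisfied, because a pattern with a deleted spacer is not the pattern.

Anchor coordinates live in data, not code, because residue numbering
drifts across homologs. The packaged backing sequence is **synthetic**
— a random canonical-residue sequence with the anchor residues planted
at the coordinates above — which lets every stage of the pipeline run
and be tested offline. It is a stand-in, not a natural protein; to
analyze real data, point the catalog at a real, numbering-consistent
reference (the wedge-Gln anchor in particular should be checked against
your reference's numbering, as it is the least standardized of the
anchors).

## Alignment engine and search statistics

Local (Smith–Waterman) and global (Needleman–Wunsch) alignments use
BLOSUM62 with affine gaps: a gap of length $L$ costs
$\mathrm{open} + L\cdot\mathrm{ext}$, defaults open 11, extend 1.
Unknown residues (`X`), common in metagenomic gene calls, score 0
against everything; true ambiguity codes (B/Z/J/U/O) are rejected
rather than guessed. The backend is `Biostrings::pairwiseAlignment`;
the test suite cross-checks its scores against an independent plain-R
three-state dynamic program (and that oracle, in turn, against
exhaustive enumeration of all global alignments of tiny sequences).

Hit significance uses the Karlin–Altschul relation
$E = K m n e^{-\lambda S}$ with the standard gapped-search constants
$\lambda = 0.267$ nats, $K = 0.041$, query length $m$ and database size
$n$ in residues. Both constants are fields of `scoring_scheme()` and
adjustable. The prefilter keeps a subject only if its best hit passes
*both* identity ≥ 30% and E ≤ 1e-5 — exclusion on either failure.
Percent identity divides identical pairs by all alignment columns
(gap columns included, the Clustal identity-matrix convention); users
who prefer the shorter-sequence denominator can divide `identities` by
the ungapped length themselves.

## Two-part mapping and its failure mode

Candidates are mapped onto the reference in two passes: a first global
alignment only to locate the candidate residue corresponding to the
reference domain split (position 147; if that column is a candidate
gap, the C-part starts at the next aligned candidate residue), then
separate global realignments of the two parts. The C-terminal domain is
short and divergent, and in a single full-length alignment its columns
are hostage to the N-terminal domain's score; splitting removes that
coupling. Authentication additionally requires a candidate C-part of at
least `min_c_len = 160` residues, which removes truncated gene calls
that can never carry the OG-recognition motif.

The known limitation: residue mapping inherits the noise of optimal
pairwise alignment. Below roughly 65% identity, a register shift that
gains a point or two of score can carry a motif anchor into or past a
gap even when the candidate's actual residues are fine. The package
deliberately does **not** rescue such cases — an unaligned anchor is
reported as `unaligned`, a warning is emitted, and the candidate is
rejected — because silent rescue would blur the difference between "the
motif is present" and "I found something motif-like nearby". Expect a
small percentage of genuinely valid, deeply diverged candidates to need
manual inspection of the reported alignment, exactly as in practice
with structure-guided alignments. The round-trip tests quantify this:
at a 0.55–0.9 identity range, 49 of 50 planted positives authenticate
automatically and all decoys are rejected with their planted reasons;
the one failure is a one-point-optimal register shift across the
OG-recognition window.

## Physical properties

Molecular weight sums average-isotopic residue masses plus one water
(18.015 Da), reported in kDa. The isoelectric point solves
$\sum_i z_i(\mathrm{pH}) = 0$ for the Henderson–Hasselbalch charges of
the termini and D/E/C/Y/H/K/R side chains, with the Bjellqvist pKa set
(the one behind the common web calculators) as default and the EMBOSS
set selectable; net charge is strictly decreasing in pH, so bisection
on [0, 14] to 1e-4 finds the unique root, reported to 0.01. The test
suite checks bisection against a 0.001-pH grid scan and the analytic
two-group midpoint.

Thermostability has no sequence-only method with settled internals, so
the package ships an explicit surrogate: the mean over overlapping
dipeptides of a packaged coefficient table,
$50 + 15\,[x \in S] + 15\,[y \in S] + 5\,[x,y \in S]$ with
$S = \{\mathrm{I,V,Y,W,R,E,L}\}$, the residue set enriched in
thermophile proteomes. The index is a pure dipeptide-composition
function on a Celsius-like scale, binned at the configurable thresholds
55 and 65 into `<55`, `55–65`, `>65`, whole-protein and per-domain.
Treat the bins as a coarse, reproducible stability ranking — they are a
documented surrogate, not a melting-temperature prediction, and are
deliberately excluded from the package's reproduction claims.

## Abundance and inventory

TPM is computed per sample as
$\mathrm{tpm}_i = 10^6 (c_i/l_i) / \sum_j (c_j/l_j)$; each sample with
any signal sums to $10^6$ exactly (to floating-point), making values
comparable across samples with different depths. Gene lengths must be
in one consistent unit per table — TPM is a ratio of per-length rates,
so mixing bp and aa would silently bias it; the loader treats the unit
as a declaration, not a conversion. How multi-mapped reads were counted
upstream is inherited from the counts table, not resolved here. KO
inventories collapse MAG→gene→KO annotations to presence/absence
(`K` + 5 digits enforced), with per-MAG completeness/contamination
carried as passthrough metadata only.

## Assay statistics

Each culture's rifampicin-resistance frequency is
$(\mathrm{rif}/d_{\mathrm{rif}}) / (\mathrm{viable}/d_{\mathrm{via}})
\times 10^8$ per $10^8$ viable cells, with the permissive plate at
$10^{-7}$ dilution and equal plated volumes cancelling. When both an
undiluted and a 0.1-dilution selective plate exist, the plate in the
countable 30–300 colony range is used, else the undiluted plate —
standard plate-counting practice, applied deterministically.

Group location is the **median** (fluctuation-style count data are
heavy-tailed; jackpot cultures would dominate a mean), with a
10,000-resample bootstrap percentile 95% CI. The percentile type is the
default because, for a median at these group sizes, it holds close to
nominal coverage — the acceptance suite measures ≈95% coverage over
1000 simulated datasets of n = 30 — while the "basic" reflected
interval (selectable) undercovers badly for this discrete statistic.
Two groups are called significantly different iff their CIs do not
overlap; this is conservative relative to a two-sample test and is the
convention matched here. Fold changes divide each group median by the
reference-group median. Resampling is seeded per group
(`seed + group rank`), so identical inputs give bit-identical CIs.
The package reports frequencies, not Luria–Delbrück mutation rates —
no plating-efficiency or rate inference is attempted.

## What the generators emulate — and what they don't

`generate_candidates()` plants positives as reference mutants:
substitution-only mutagenesis at non-anchor positions up to a drawn
target identity (0.55–0.9 by default — between the 30% prefilter floor
and near-identical homologs), with anchors redrawn *within* their
allowed sets at rate 0.3 to emulate motif diversity. Because mutations
are substitution-only, candidates stay reference-length and realized
identity is exact, keeping truth labels sharp. Decoys break exactly one
named motif with a disallowed residue, or truncate before the domain
split. Background is uniform-random sequence (a composition argument
exists but realism there is not load-bearing — background dies at the
prefilter on E-value, which is driven by score, not composition).

What the generator does **not** emulate: indels, phylogenetically
correlated substitutions, compositional bias, fragmentary gene calls
other than clean truncation, or HhH relatives that share the N-terminal
motifs but diverge structurally. Passing the round-trip tests therefore
shows the pipeline's logic is correct under controlled conditions; it
does not show that real metagenomic candidates at 30–50% identity map
cleanly — see the failure-mode section above.

`generate_counts()` draws per-site gene proportions from a Dirichlet
(concentration 5) and Poisson counts around
length × depth × proportion, five repair genes × five sites × duplicate
samples by default. `generate_assay()` draws per-culture frequencies
lognormally around group medians (σ = 0.5) and back-computes plate
counts through the dilution model with Poisson noise; the default
groups use medians 101 (no-enzyme control), 12 (reference enzyme), 6,
12 and 48 (strong, equivalent and partial suppressors) with 24 cultures
per group — a fold-change structure of ≈8.4× control/reference that the
statistics recover within sampling tolerance.

## Numerical and reproducibility choices

Problem sizes in the tests and acceptance script are desk-scale by
design: 200-candidate pools for the mining funnel, 200 random pairs for
the alignment oracle, 100 peptides for the pI oracle, 1000 simulated
datasets (n = 30, 1000 resamples each) for CI coverage. All generators
and resamplers take explicit integer seeds; identical seeds give
byte-identical FASTA/TSV/JSON outputs (timestamps are never written).
Coordinates are 1-based inclusive throughout; the gap character is
`-`; empty local alignments are represented with score 0 and zero
columns rather than a zero-length pseudo-hit. Equal-scoring alignment
tracebacks are resolved deterministically by the alignment backend, so
rerunning never changes a mapping. Degenerate inputs fail loudly:
empty sequences, all-zero count vectors, zero viable counts and
fewer than three cultures per group are errors, not silent NAs.
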