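---
title: "Mining arthropod sequence data for inotocin signalling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining arthropod sequence data for inotocin signalling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inotoscan)
```

## The biological model

Oxytocin/vasopressin-family peptides — inotocin in insects — are
nonapeptides with a disulfide-bonded ring between cysteines 1 and 6 and
an amidated C-terminal tail. The precursor (prepropeptide) is ordered:
signal peptide, mature peptide, amidation signal, neurophysin domain.
The amidation signal is a glycine that donates the C-terminal amide,
followed by a dibasic convertase cleavage pair; the neurophysin domain
carries 14 conserved cysteines at short, characteristic spacings. The
receptor is a class-A GPCR whose closest paralogue family, the CCAP
receptors, must be separated out during mining.

`inotoscan` implements the mining workflow as five analysis modules
(search, precursor annotation, receptor classification,
census/consensus, phylogenetic mapping) plus a synthetic-data
generator. The `analysis/` scripts run them in order as a workflow;
the package functions are the API and everything the scripts print is
recomputed by them at run time.

## Homology search

Candidate discovery uses exact Smith–Waterman dynamic programming with
affine gaps rather than a heuristic seeded search: datasets at desk
scale are small, exactness makes results deterministic, and no external
binary is needed. A gap of length $g$ costs
$\text{open} + \text{extend}\cdot g$ (open = 11, extend = 1, BLOSUM62),
and traceback ties are broken diagonal → up → left, so reported
alignments are unique. Significance uses the Karlin–Altschul form
$E = K m n e^{-\lambda S}$ with the published gapped constants for
BLOSUM62/11/1 ($\lambda = 0.267$, $K = 0.041$); $n$ is the total
residue count of the searched dataset (translated length for
nucleotide entries, which are scanned in all six frames). The default
cutoff is $10^{-4}$.

Two deliberate simplifications: no composition-based statistics and no
low-complexity masking. The practical consequence, visible in
`analysis/02_search.R`, is that shuffled decoys derived from
hydrophobic-rich receptor scaffolds occasionally score past the cutoff
— their composition violates the assumptions behind the fixed
$\lambda, K$. They are guaranteed negatives for classification (below)
and therefore never reach a family call, but users mining real data
should expect the hit list to be a superset of what a
composition-corrected search would return.

## Precursor annotation

Annotation is a grammar, not a scoring model:

* **Ring**: `C-X4-C` scanned left to right.
* **Tail**: 3 residues (nonapeptide) tried first, then 4 (decapeptide).
  This order resolves the ambiguity of terminal-glycine decapeptides:
  for `…CFITNCPVGG-GKR…` the nonapeptide reading fails the signal test
  (`GGK` is not donor + dibasic) and the decapeptide reading is taken.
* **Amidation signal**: donor `G` immediately after the terminal
  residue, then a dibasic pair from `{KR, RK, KK}` (`RR` accepted with
  flag `unusual_dibasic`). Peptides whose own terminal residue is not
  glycine (terminal A/S variants) are treated as terminal-residue
  variants — the donor is still required to be `G` — and flagged
  `non_canonical_terminal`.
* **Rings without any valid signal** are still reported (flag
  `no_processing_site`) so unprocessed precursors remain representable
  and countable.
* **Neurophysin**: the cysteine chain downstream of the mature domain
  in which consecutive cysteines are at most 30 residues apart; at
  least 6 cysteines are required to call a framework, 14 makes it
  `complete`. Both thresholds are arguments.
* **Best mature candidate**: the first ring with a valid signal;
  failing that, the first ring followed within 150 residues by a
  framework. This mirrors the precursor architecture and is
  deterministic.
* **Signal region**: simply the prefix before the mature domain. No
  signal-peptide predictor is implemented; an advisory
  `weak_signal_like` flag fires when the first 30 residues lack an
  8-residue window of mean Kyte–Doolittle hydropathy > 1.5.

`completeness` is three-valued: `complete` (mature + framework),
`partial_neurophysin_only` (framework only — truncated transcripts),
`rejected`. Two different countable sets deliberately coexist: the
batch summary counts annotated precursors and their amidation
statistics, while the census counts complete precursors contributing a
mature peptide. On real collections these sets need not coincide, so
both are always reported rather than reconciled.

Coordinates are 1-based inclusive everywhere, the native R and
reporting convention; no 0-based layer exists internally.

## Receptor classification

Two diagnostic regions are scanned with positional windows as a
deterministic surrogate for transmembrane-helix location: TM2/ECL1
over the N-terminal 60% of the sequence, TM7 over the C-terminal 25%
(both configurable).

* TM2/ECL1: `X-P-Q-X2-W-X5–6-F` (12 residues with the short spacer,
  13 with the long one); anchors P2, Q3, W6 and the final F; an
  inotocin vote needs ≥ 3 of 4 identical. CCAP variant `X2-D-X8-W`,
  both anchors required.
* TM7: the NP scaffold at positions 3–4 is common to both families;
  inotocin anchors C1/W5 (≥ 1), CCAP anchors A1 and V/L/F at
  position 5 (≥ 1). Equal-strength window votes cancel to `none`;
  overlapping hits are pruned to the best per locus (more anchors,
  then leftmost).

Combining the two criteria: an inotocin call requires an inotocin vote
from either motif and, when CCAP votes exist too, a strictly greater
anchor margin (anchors matched minus the family's minimum for that
motif, maximised over hits). A CCAP call requires CCAP evidence and
**no inotocin vote at all**. The asymmetry is intentional: the CCAP
TM2 variant has only two informative positions and fires by chance
roughly once per 400 windows, so treating every cross-family vote as a
hard conflict would destroy recall, while the no-inotocin-vote
requirement guarantees that a sequence retaining three intact inotocin
TM2 anchors can never be called CCAP-like. Genuinely ambiguous
sequences fall to `unclassified` with flag `conflicting_evidence`.

Classification presumes candidate receptors — in the pipeline it is
applied to similarity-search hits, as receptor assignment on mined
data always is. Applied to arbitrary long random sequences the
positional scan will occasionally vote; decoys emitted by the
generator are sanitised against this so they are guaranteed negatives.

The grouping check (`pairwise_identity_tree`) is a neighbour-joining
tree over distances $1 - \text{identity}$ from pairwise global
alignments with free end gaps. It stands in for full phylogenetics,
which is out of scope; no support values are computed.

## Census, consensus and mapping

The census counts precursors, not species: a species with two
precursors encoding different peptides contributes two. Position
frequency matrices weight one count per precursor occurrence; columns
are exact distributions (sum to 1). Consensus: invariant positions
(top frequency = 1) are upper-case, majority positions (> 0.5)
lower-case, the rest `X`. Decapeptides join the census as distinct
keys but are excluded from the 9-column matrix.

Presence mapping marks each species `present`, `partial` or `absent`
for precursor and receptor; INT counts species with any component
present or partial, out of T sampled. Loss inference is single-gain
Dollo parsimony: the gain sits at the MRCA of all present leaves and
the losses are the maximal all-absent subtrees inside the gain clade —
a set that is unique, hence minimal and deterministic; minimality is
tested against exhaustive search over loss-edge subsets. The taxonomy
tree is always user-supplied (the packaged order-level tree ships as
`arthropod_orders.nwk`); the pipeline never infers it.

The contamination flag combines two conditions, both configurable: a
species that is the only member of its order with the system while
≥ 3 sampled ordermates lack it, and that shares a byte-identical
mature peptide with a species from another subphylum.

## The synthetic-data generator

The generator emulates the structure the analysis assumes — it is the
test bed, not a claim about real sequence evolution:

* **Shared base scaffolds.** All precursors derive from one fixed
  scaffold (signal, linker, neurophysin fillers, tail) and all
  receptors from another, both built once from a private RNG stream.
  Family members therefore are homologous and recoverable by local
  alignment, as mined orthologues are. Receptors of both families
  share the same scaffold so that an oxytocin/vasopressin-family query
  retrieves CCAP receptors too — classification, not search, must
  separate them.
* **Neurophysin template.** Thirteen fixed inter-cysteine lengths
  (`neurophysin_template()`), jittered by ±1 per record. Length 4 is
  excluded, and jitter draws whose combined spacing would create an
  accidental `C-X4-C` ring are redrawn, so no spurious mature-domain
  motif can arise inside the framework.
* **Label soundness.** Mutations are substitutions only, never touch
  the ring or framework cysteines, and never create new cysteines;
  receptor anchor residues are spared unless `anchor_sparing = FALSE`.
  Scaffolds and decoys are sanitised against chance diagnostic-motif
  windows. Consequently, at mutation rate 0 annotation and
  classification provably agree with the truth labels, which the suite
  asserts across seeds.
* **Composition.** Background residues are uniform over the 20 amino
  acids by default (`background = "proteome"` switches to average
  proteome frequencies).
* **Study-shaped sets.** `generate_survey_precursors()` composes the
  110-precursor survey (103 amidated terminal-glycine, 6 amidated
  non-glycine terminals, 1 unprocessed), and
  `expand_fixture_peptides()` expands the packaged 21-peptide /
  121-precursor reference table; the packaged table itself was
  transcribed with its published frequencies and amidation flags.

What the generator does **not** emulate: indels beyond the ±1
neurophysin jitter (truth intervals assume substitutions),
phylogenetically correlated divergence, codon-level structure,
assembly noise other than truncation, and realistic GPCR topology
beyond hydrophobic stretches at 7 positions. Passing tests on this
material validates the pipeline's logic and determinism, not its
sensitivity on real, divergent assemblies.

## Problem sizes and determinism

The suite runs at desk scale by choice: alignment oracles use 200
seeded pairs of short peptides (exhaustive matching enumeration up to
6-mers, an independent established implementation up to 15-mers),
Dollo minimality is enumerated on trees of 4–6 leaves for all
presence patterns and sampled patterns on 7–8, and end-to-end runs use
10–20 species with 50 decoys. Every stochastic step flows from an
explicit integer seed; the same configuration reproduces every emitted
file byte-identically, which the suite also asserts.

## Known limitations

* Fixed Karlin–Altschul constants mis-estimate significance for
  composition-biased sequences (see the search section); hit lists are
  conservative in neither direction for such inputs.
* The positional TM windows are a proxy; receptors with unusual domain
  proportions could place a true motif outside the scanned region.
* The 110-versus-121 precursor bookkeeping is intentionally left as
  two separate countable sets.
* The manifest converter for external supplementary formats is a
  documented assumption (one precursor/receptor per species with
  sequence text), not a parser for any specific published layout.
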