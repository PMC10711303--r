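---
title: "Reconstructing MRO proteomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing MRO proteomes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrolens)
```

## The problem

Mitochondrion-related organelles (MROs) — the mitosomes and hydrogenosomes
of anaerobic protists such as Archamoebae — retain only a small, lineage-
specific subset of the mitochondrial proteome.  Reconstructing that subset
from transcriptome-derived protein sets requires a chain of in-silico
steps, each with its own failure modes: assemblies from uni-eukaryotic but
xenic cultures are contaminated with bacterial and fungal transcripts;
subcellular-localization predictors are trained on organisms with canonical
mitochondria and membrane potential-dependent import, so their error rates
on MRO proteins must be measured, not assumed; and the resulting per-species
presence/absence patterns only become evolutionary statements once gains and
losses are placed on a species tree.  `mrolens` implements this chain as
testable, seedable components.

## Taxonomy-aware decontamination

A sequence is removed when its qualifying similarity-search hits "reliably
match" subjects outside the target clade (here Amoebozoa).  Two rounds are
applied:

| round | input | E-value cutoff | hits kept | identity | coverage |
|-------|-------|---------------|-----------|----------|----------|
| 1 | transcripts vs nucleotide db | 1e-2 | 5 | >= 75 % | >= 50 % |
| 2 | proteins vs protein db | 1e-5 | 1 | >= 70 % | none |

Round 2 operates only on proteins derived from round-1 survivors; a protein
whose source transcript was removed is excluded up front and flagged with
removal round 1.

Decisions that the threshold flags themselves do not fix:

* **Inclusivity.** A hit at exactly the threshold counts as contaminant
  evidence (`>=`), matching the usual semantics of cutoff flags.
* **Combining multiple hits.** With up to five hits per query, the default
  policy removes a sequence when it has at least one qualifying non-target
  hit *and* no target-clade hit among its qualifying hits — a target-clade
  veto.  The no-veto alternative (`NO_TARGET_AMONG_QUALIFYING`; any
  qualifying non-target hit removes) is selectable, because the original
  behaviour with co-occurring target hits is not documented.
* **Unknown taxonomy** is always `UNINFORMATIVE`: absence of evidence never
  removes data.
* **Defensive enforcement.** The E-value cutoff and best-N rule are applied
  inside the filter (bitscore desc, then E-value asc, then subject id), so
  raw and pre-filtered hit tables give identical reports.

## Benchmarking localization predictors

Each tool's verdicts on a labelled reference set (bona-fide MRO proteins as
positives; ribosomal and replisomal homologues as cytosolic negatives) are
reduced to TP/TN/FP/FN and two metrics:

$$\mathrm{sensitivity} = \frac{TP}{TP+FN}, \qquad
  \mathrm{specificity} = \frac{TP}{TP+FP}.$$

The second quantity is what most of the literature calls *precision*; the
package keeps the benchmark's own naming.  Conventions:

* **PT→MT rule.** Plastid predictions from a tool that cannot be run in a
  non-plant mode are counted as mitochondrial (`PT_TO_MT`), because plastid
  and mitochondrial N-terminal targeting signals share characteristics and
  the organisms studied have no plastid.
* **Missing predictions** count as negative calls by default (an
  unpredicted MRO protein is a false negative).  The alternative policy
  excludes unscored proteins from the tool's denominators; it exists
  because published per-tool denominators can differ when some references
  were never scored, and no recomputation can decide between the policies
  after the fact.
* **Rounding.** Metrics are kept exact; `round_half_up()` reproduces
  printed integer percentages (96.875 → 97).  A zero denominator yields
  `NA`, never 0 or 100.
* **Selection.** Tools below 50 % specificity (configurable) are excluded;
  survivors are ranked by specificity, then sensitivity, then name, and the
  top `k = 3` are kept.  Three-tool agreement is summarized as an 8-cell
  partition (Venn cells) per truth class and call polarity.

## Consensus MRO calling and the character matrix

A protein is called MRO when at least `k = 1` of the selected predictors
votes positive **or** it shows phylogenetic affinity with a previously
characterized MRO protein.  The affinity flag is an *input*: it encodes
expert inspection of gene trees, which this package deliberately does not
automate.  This matters for proteins with incomplete N-termini, which can
never receive a targeting-signal vote yet may clearly branch inside an
MRO-targeted clade.

Matrix coding was genuinely open.  The strict gloss ("only vote-supported
proteins count") conflicts with the treatment of affinity-only proteins,
which are reported present with evidence grade `CLADE_ONLY`.  We resolved it
as follows: `MRO_STRICT` counts every protein whose final call is MRO
(votes or affinity — the consensus rule itself already accepts affinity);
`MRO_PLUS_CLADE` additionally counts affinity-flagged proteins whose final
call was overridden to NON_MRO (possible under `k > 1` or user-supplied
calls).  Under the default rule the codings coincide, and
`MRO_PLUS_CLADE` always dominates `MRO_STRICT` elementwise.

## Gain/loss reconstruction

The narrative of organelle evolution here — single acquisitions (including
laterally acquired systems) followed by repeated independent losses — is
exactly the Dollo assumption, so **Dollo parsimony** is the default: each
character gains once, at the most recent common ancestor of the species
possessing it, with the minimal set of loss branches (one per maximal
all-absent subtree inside the gain clade).  The root state before the gain
is 0; a character present in all species gains at the root and is read as
ancestral.  An unconstrained binary Fitch mode is provided for comparison;
it can be cheaper (two independent gains instead of one gain plus two
losses) and is reported as a change count only, since unpolarized changes
are not gain/loss statements.

Internal nodes are labelled deterministically in postorder, so scenarios
are comparable across runs; every branch is identified by its child node.
`compare_topologies()` reruns the reconstruction under an alternative
placement of a conflicting clade (here Rhizomastixidae, either sister to
Pelomyxidae + Mastigamoebidae — the working topology — or sister to
Pelomyxidae alone) and tabulates per-character event deltas.

**Identifiability.** When the generator simulates single gain plus
per-branch loss, a gain node is recoverable only if surviving presences
still straddle it.  If every witness on one side of the gain is lost, *no*
method can name the original node; the reconstruction then returns the most
recent common ancestor of the survivors, which is strictly later.  At a
per-branch loss probability of 0.1 on the 8-taxon tree, roughly 7–8 % of
non-empty characters are unidentifiable in this sense, so unconditional
recovery sits near 92 %, not above 95 %.  The recovery test therefore
conditions on identifiability (where recovery must be, and is, exact);
the unconditional rate is a property of the loss process, not of the
algorithm.

## Orthogroup enrichment

To surface MRO proteins missed by targeted searches, orthogroup clustering
is integrated with targeting predictions: for an orthogroup with $n$
members of which $x$ are MRO-predicted, in a universe of $N$ proteins with
$K$ MRO-predicted, the upper-tail hypergeometric probability
$P[X \ge x]$ is computed and Benjamini–Hochberg corrected across groups.
The universe defaults to all proteins pooled across species, matching
pooled clustering.  A descriptive fraction-threshold mode is provided as
the non-inferential alternative.

The hypergeometric statistic is discrete, so its upper-tail p-values are
*super-uniform* under the null — provably so, to the tune of the largest
point mass, which a Kolmogorov–Smirnov test at $n = 1000$ detects reliably.
Calibration checks therefore use the randomized ("fuzzy") p-value
$P[X > x] + U\,P[X = x]$, $U \sim \mathrm{Uniform}(0,1)$, which is exactly
uniform under the null for any discrete statistic; a mid-p option is also
available.  Inference defaults to the conservative upper-tail form.

## The synthetic world

Every stage is testable against `sim_config()` generators with known ground
truth.  Defaults state the conditions the pipeline is meant for:

* **Scale.** 8 species on the working topology; 65 MRO and 800 cytosolic
  reference proteins; 500 transcripts of which 10 % are planted
  contaminants (20 % of those detectable only at protein level, i.e. in
  round 2); 200 binary characters; 100 orthogroups over a 5000-protein
  universe.
* **Predictors.** Three tools with sensitivities 0.46/0.45/0.77 and
  false-positive rates in the 10⁻³–10⁻² range, matching the performance
  regime of the selected benchmark tools; the third tool lacks a non-plant
  mode and emits 8 % of its positives as plastid calls, exercising PT→MT.
* **Contaminants** receive non-target best hits with identity drawn from a
  truncated normal above the round threshold (mean 85 %, sd 5) — they are
  contaminants *by construction*, which is what makes exact-recovery tests
  meaningful.
* **Loss process.** Characters gain at a uniformly chosen node and are
  lost below with per-branch probability 0.1.
* Sequence residues are random and decorative; ids, tables and labels
  carry all information.

What a green test does **not** establish: performance on real predictor
idiosyncrasies (per-tool missing scores, score calibration), on taxonomies
with nomenclature drift (membership is exact name match within the lineage
path), on contamination whose identity hovers at the threshold, or on gene
trees — homology affinity is always an input.  Identical seeds give
byte-identical outputs; generation never disturbs the caller's RNG stream.

## Numerical conventions

* Thresholds inclusive (`>=`); all tie-breaks deterministic (bitscore,
  E-value, lexicographic id; tool name for ranking).
* Reciprocal best hits: multiple HSPs to one subject collapse to the best
  first; a pair needs mutual unique bests under the tie-break rule.
* Metrics exact internally; `NA` on empty denominators; rounding half-up
  only at presentation.
* Run manifests contain parameters and MD5 sums but no timestamps, so
  reruns are byte-comparable; timestamps live in the plain-text log.

## Limitations

Homology affinity, orthogroup clustering and hit tables are consumed, not
computed — the package orchestrates and quantifies the downstream
inference.  Dollo parsimony ignores branch lengths and rate heterogeneity;
likelihood models of gene content are out of scope.  Taxonomy handling is
string-based; a taxid-to-lineage map must be applied upstream if hit tables
carry numeric taxids only.
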