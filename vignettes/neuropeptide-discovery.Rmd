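---
title: "Discovering neuropeptide precursors in predicted proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering neuropeptide precursors in predicted proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropep)
```

## The biological problem

Neuropeptides are short signalling peptides released from larger secreted
precursor proteins (preprohormones). A precursor typically carries an
N-terminal signal peptide, one or more — often many tandem — copies of the
mature peptide, and intervening spacer regions. Prohormone convertases
cleave the precursor at basic-residue motifs; carboxypeptidases then trim
the exposed basic residues, and two further modifications stabilize many
mature peptides: a glycine immediately preceding the cleavage site is
converted into a C-terminal amide, and an N-terminal glutamine may cyclize
into pyroglutamate. A proline at the second position likewise protects
against aminopeptidases.

Sequence conservation of neuropeptides is famously poor — often only the
C-terminal two or three residues plus the amide survive across lineages —
so homology search alone misses rapidly evolving and taxon-restricted
peptides. The strategy implemented here instead mines a predicted
proteome *structurally*: restrict to the putative secretome, scan for
cleavage architecture, then use homology and single-cell expression data
as *negative* and *positive* filters rather than as the discovery signal.
Notably, the amidation requirement is deliberately **not** imposed, which
is what allows non-amidated families (such as LW-peptides) to surface.

## Pipeline stages

1. **Secretome prefilter** (`apply_prefilter()`): keep proteins with a
   predicted signal peptide, no transmembrane segment outside the signal
   region, and no recognized functional domain. The package parses the
   tabular outputs of external signal/TM/domain annotators (one
   documented dialect per source, `parse_evidence()`); when signal
   evidence is absent, a policy switch decides between dropping, keeping,
   or a crude built-in hydrophobic-run heuristic
   (`heuristic_signal_peptide()`). TM or domain evidence absent for a
   record is treated as zero segments / no domain — a missing row cannot
   be guessed at, and the policy switch governs only the signal call.
2. **Cleavage scan** (`scan_precursors()`): the core computation,
   described below.
3. **Homology filter** (`filter_by_homology()`): a candidate whose best
   alignment hit exceeds 30% identity at e-value below 0.05 *and* is not
   described as a neuropeptide precursor / uncharacterized protein (a
   configurable keyword allow-list) is removed. Inequalities are strict;
   ties in the top hit are broken by bitscore then subject id for
   determinism. Candidates without hits are kept — removal requires
   positive evidence of a non-neuropeptide identity.
4. **Expression filter** (`filter_by_expression()`): only neuronally
   expressed candidates survive. The published workflow states the goal
   but no numeric rule; ours is a two-part invention with both knobs
   exposed: detection (best neuronal cluster mean above
   `min_neuronal_expression`, default any detection) and a neuronal
   share (best neuronal mean / best overall mean ≥ `min_neuronal_share`,
   default 0.5). The share tolerates genes that are also expressed
   outside neurons, while still rejecting gland- or muscle-dominated
   genes. All-zero profiles fail detection before any ratio is formed.
5. **Similarity clustering** (`build_graph()`, `connected_clusters()`,
   `force_layout()`): classification of survivors, in the style of
   all-vs-all BLAST graph clustering. Exact Smith-Waterman local
   alignment (BLOSUM62, gap open 11 / extend 1) replaces an external
   search binary; e-values use the ungapped Karlin-Altschul form
   `K·m·n·exp(−λ·s)` with K = 0.041, λ = 0.267. Applying ungapped
   constants to gapped scores is a documented approximation — the graph
   is used for grouping, not for homology statistics. Clusters are
   connected components at `e_cutoff` (default 1e-4, non-canonical); the
   seeded force-directed layout is contractually deterministic and
   cluster-separating, nothing more.

Every filter is independently skippable: the published workflow
interposes manual curation, so users must be able to intervene between
stages.

## The scanner model

Cleavage sites are located as maximal runs of K/R, qualified by the motif
set {KK, RK, KR, RR, GK, GR}:

* a run qualifies iff at least one adjacent pair within it — or the pair
  formed with an immediately preceding glycine — is a configured motif;
* a qualifying site consumes the entire run, plus the preceding glycine
  when present; that glycine is the amide donor, so the upstream peptide
  is flagged `amidated`;
* an isolated K or R without a preceding G is *not* a site: monobasic
  cleavage is outside the motif set;
* `X` (unknown residue) never matches K, R or G.

Consuming the maximal run resolves overlapping motifs (e.g. `GKR`,
`KKR`) deterministically and matches convertase/carboxypeptidase
biology: the whole basic stretch is removed from both flanking peptides.

Candidate peptides are the segments strictly between consumed regions,
starting after the signal peptide (`signal_end + 1`; sites inside the
signal region are ignored). A segment *counts* toward the precursor pass
criterion iff

* `min_len` (3) ≤ length ≤ `window` (20) — the window is read as the
  maximum mature-peptide length, consistent with typical neuropeptide
  sizes; an alternative reading (bounding inter-site distance including
  site residues) can be emulated by adjusting `window`;
* its C-terminal boundary is a cleavage site, or the protein terminus
  when the segment matches a peptide family (`allow_terminal_peptide`);
* under `require_n_motif = TRUE`, it additionally starts with Q
  (pyroglutamate), has P at position 2, or abuts an upstream site.

`require_n_motif` defaults to `FALSE`: the N-terminal motifs are treated
as bonus evidence, because well-supported peptides exist that satisfy
only the cleavage criterion, and the strict conjunctive reading is
available as a switch.

A precursor **passes** iff it yields at least one counting peptide — the
published criterion. The numeric score,
`1.0·n_passing + 2.0·n_repeat_groups + 0.5·n_modified`, is this
package's own ranking convenience (no published formula exists); repeat
groups are ≥2 counting peptides sharing C-terminal dipeptide and
amidation state, the hallmark of multi-copy precursors. The weights are
arguments of `score_precursor()` and the pass decision never depends on
them.

Family assignment matches 1–3-residue C-terminal patterns (X wildcard)
plus the amidation state, in table order: RFamide (R-F, amidated),
GLWamide (X-L-W, amidated — the canonical leading glycine is noted but
not required), PRXamide (P-R-X, amidated), LW_peptide (L-W,
non-amidated), KVamide, FRamide. The first match wins; everything else
is `unassigned`.

## The synthetic benchmark

`make_benchmark()` generates a ground-truthed proteome:

* **precursors** — architecture `signal + [spacer + motif + core +
  (G) + motif] × n_copies + spacer`, n_copies 2–4, cores sampled from
  the family templates above plus unassigned controls. Every planted
  core is flanked by consumed sites, so its mature coordinates are
  exact. Cores must not create or merge with sites (no adjacent basics,
  no G-before-basic, no terminal/initial K/R, no terminal G); GK/GR exit
  motifs carry their own donor glycine, so they are only used for
  amidated peptides and no extra G is planted. The planted signal
  peptide is recognized by the fallback heuristic by construction,
  keeping the benchmark free of external callers.
* **decoys** — `random` (K/R suppressed to ~1% combined, so chance
  cleavage architecture is rare), `tm` and `domainlike` (signal-bearing,
  with matching TM/domain evidence rows, so the prefilter drop reason is
  unambiguous).
* **evidence and expression** — half the precursors receive a benign
  (keyword-matching) alignment hit and half the decoys a damning one;
  precursors are planted as neuronal (Poisson mean 5 in two neuronal
  clusters — neuropeptide genes are typically expressed in several
  neuronal subpopulations — and 0.1 elsewhere), decoys as the
  non-neuronal mirror image. Rates are inventions chosen once for
  realism; nothing in the published workflow constrains them.

Adversarial mode (10% of precursors) inserts an isolated internal basic
into the core — which the scanner must ignore — and, in a quarter of
those, an embedded dibasic that genuinely splits the planted peptide;
such peptides are marked non-recoverable in the truth manifest. This
yields an expected exact-boundary recall of ≈0.97 while still probing
overlap resolution.

What passing these benchmarks does **not** show: performance on real
proteomes, where signal-peptide prediction is harder, spacers contain
monobasic and non-canonical sites, expression atlases are noisy and
cluster annotations contested, and the homology database matters. The
benchmark validates the machinery, not the biology.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere; writers state this in
  file headers.
* Orphaned evidence rows (ids absent from the FASTA) warn and are
  ignored — users commonly subset FASTAs.
* TM segments lying entirely within `1..signal_end` are discounted,
  since several TM callers report the signal peptide as a membrane
  segment.
* Layout integration uses a small fixed time step (0.01) with velocity
  damping 0.9 and a per-step displacement cap (0.1) for numerical
  stability; `min_dist` (1e-6) guards the repulsion singularity. Only
  determinism and qualitative cluster separation are contractual.
* The force-layout, benchmark-generation and pipeline entry points
  restore the global RNG state, so library use does not perturb user
  seeds.
* Problem sizes used by the shipped checks — 10,000 random sequences for
  the scanner/oracle and reconstruction sweeps, 200 precursors + 600
  decoys for end-to-end recovery, 10+10 sequences for cluster recovery —
  were chosen to exercise the combinatorics thoroughly while remaining
  quick on a laptop.
* The end-to-end recovery benchmark disables the clustering stage: it
  classifies survivors but removes none, so precision and recall are
  unaffected.

## Known limitations

* Monobasic cleavage, acidic processing sites and signal-peptidase
  specificity are out of scope; precursors processed exclusively at such
  sites will be missed.
* One tabular dialect per external annotator is supported, not every
  vendor variant.
* The e-value model is approximate (see above) and the default
  `e_cutoff` non-canonical; cluster membership near the threshold should
  not be over-interpreted.
* The expression filter operates on gene-by-cluster summaries; per-cell
  resolution, marker detection and atlas re-analysis are out of scope,
  and which clusters count as neuronal is the user's call via the
  annotation file.
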