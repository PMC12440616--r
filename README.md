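# neuropep

In silico discovery of neuropeptide precursor (preprohormone) genes in
predicted proteomes.

Neuropeptides are short secreted signalling peptides cut out of larger
precursor proteins by prohormone convertases at basic-residue cleavage
sites. Because mature peptides conserve little beyond their last two or
three residues, homology search alone misses rapidly evolving and
taxon-restricted peptides — including entirely non-amidated classes.
`neuropep` instead mines a proteome structurally:

1. **secretome prefilter** — keep proteins with a signal peptide, no
   transmembrane segment outside the signal region, and no recognized
   functional domain (parsed from external annotator tables, with a
   built-in fallback heuristic);
2. **cleavage scan** — locate dibasic / glycine-extended cleavage motifs
   (KK, RK, KR, RR, GK, GR), consume maximal basic runs, extract
   candidate mature peptides of 3–20 residues, and annotate C-terminal
   amidation (preceding glycine donor), N-terminal pyroglutamate (Q) and
   proline protection (P at position 2); a precursor passes with at
   least one qualifying peptide;
3. **homology filter** — remove candidates whose top alignment hit
   (>30% identity, e-value <0.05) identifies a non-neuropeptide
   homologue, keeping hits described as neuropeptide precursors or
   uncharacterized proteins;
4. **expression filter** — keep candidates detected in neuronal clusters
   of a single-cell atlas summary, with a configurable neuronal-share
   rule;
5. **similarity clustering** — all-vs-all Smith-Waterman (BLOSUM62,
   affine gaps), Karlin-Altschul e-value graph, connected-component
   clusters and a seeded force-directed 2D layout.

A synthetic-proteome generator (`make_benchmark()`) plants precursor
architectures, decoys, evidence tables and expression summaries with
exact ground truth, so the whole pipeline is testable end to end without
downloads or external binaries.

## Worked example

Four bundled synthetic precursors mimic reported precursor
architectures: a preprohormone with two amidated RFamides, a PRXamide
precursor, a two-peptide RFamide paralogue, and an LW-peptide precursor
whose three peptide copies all lack the glycine amide donor.

```r
library(neuropep)
w <- worked_example_precursors()
pf <- apply_prefilter(w$records)          # signal heuristic trims residues 1-14
scan <- scan_precursors(pf$kept)
scan$peptides[scan$peptides$counts_toward_pass, ]
```

```
                    parent_id start end     mature amidated pyroglu    xp     family
     PreprohormoneE_synthetic    19  25    QWLSARF     TRUE    TRUE FALSE    RFamide
     PreprohormoneE_synthetic    33  39    QSFHLRF     TRUE    TRUE FALSE    RFamide
 PRGamidePrecursorB_synthetic    19  26   QAPGLPRG     TRUE    TRUE FALSE   PRXamide
 PRGamidePrecursorB_synthetic    34  41   QNSFLPRG     TRUE    TRUE FALSE   PRXamide
     PreprohormoneD_synthetic    19  25    QNFHLRF     TRUE    TRUE FALSE    RFamide
     PreprohormoneD_synthetic    33  39    QWFNSRF     TRUE    TRUE FALSE    RFamide
         LWpeptideA_synthetic    19  28 EPEPPETGLW    FALSE   FALSE  TRUE LW_peptide
         LWpeptideA_synthetic    35  44 EPEPPETGLW    FALSE   FALSE  TRUE LW_peptide
         LWpeptideA_synthetic    51  60 EPEPPETGLW    FALSE   FALSE  TRUE LW_peptide
```

Each row is one mature peptide with its 1-based coordinates in the
precursor. The RF/PRX peptides end at a glycine-extended dibasic site,
so they are amidated and start with a pyroglutamate glutamine; the
LW peptides (sequence EPEPPETGLW) have no glycine before their sites and
come out non-amidated with the proline-protection flag instead.

```r
scan$scores
```

```
                 precursor_id n_peptides n_passing n_repeat_groups n_modified score passes
     PreprohormoneE_synthetic          5         2               1          2   5.0   TRUE
 PRGamidePrecursorB_synthetic          5         2               1          2   5.0   TRUE
     PreprohormoneD_synthetic          5         2               1          2   5.0   TRUE
         LWpeptideA_synthetic          7         3               1          3   6.5   TRUE
```

`n_peptides` counts every emitted segment (spacers included);
`n_passing` the peptides meeting the length/boundary criteria; a
precursor passes with at least one. The score
(`1·n_passing + 2·n_repeat_groups + 0.5·n_modified`) is a ranking aid,
not a published statistic.

A full file-based run (`run_pipeline()` or the `exec/neuropep` command
with subcommands `simulate | scan | filter-homology | filter-expression
| cluster | pipeline`) writes per-stage reasons tables, a mature-peptide
FASTA, the similarity edge list / clusters / layout and a JSON run
summary. See the vignette `vignettes/neuropeptide-discovery.Rmd` for the
model, parameter meanings and generator details.

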