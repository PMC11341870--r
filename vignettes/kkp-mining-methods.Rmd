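---
title: "Mining kinase-kinase-phosphatase modules: methods and design notes"
author: "kkpminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining kinase-kinase-phosphatase modules: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kkpminer)
```

## The biological question

Temperate phages and other mobile elements often carry small regulatory
modules that decide between lysogenic quiescence and lytic induction. One
such module is the tripartite kinase-kinase-phosphatase (KKP) operon:
two eukaryotic-like Ser/Thr protein kinases — a PfkA-like kinase with a
C-terminal cold shock domain (CSD, PF00313) and a PfkB-like kinase with a
C-terminal forkhead-associated domain (FHA, PF00498) — together with a
PP2C-family Ser/Thr phosphatase (PfpC-like, PF13672/COG0631). The kinases
act as the toxin-like arm that maintains prophage quiescence; the
phosphatase antagonizes them and permits controlled induction. KKP
modules sit overwhelmingly inside prophages (including Psu-marked P4
satellites) or next to other mobile-element genes.

`kkpminer` finds these modules in annotated genomes and reproduces the
analysis chain around them: domain-architecture classification, the
triplet neighboring-gene scan, genomic-context assignment, protein-identity
family grouping, kinase-tree annotation, and pairwise comparison of
nearly identical prophage regions. Everything is testable offline against
a seeded synthetic genome generator with planted ground truth.

## The mining procedure

### Gene universe and adjacency

CDS features are the gene universe; tRNA/rRNA features are retained in
the tables but never scanned. Genes on each contig are ordered by start
coordinate (ties by end, then gene id) and indexed 0..n−1. "Neighboring"
means strictly consecutive CDS indices; an option
(`allow_intervening = TRUE`, off by default) tolerates one intervening
gene of role `other`, and an optional intergenic bp cap is available but
off by default, since adjacency by index is the plain reading of a
triplet neighboring-gene search.

### Domain architectures and roles

Per-protein domain hits (HMMER3 domtblout dialect; Pfam or COG
accessions) are screened at an independent E-value of at most `1e-5` — a
conventional Pfam screening cutoff; the original screen relied on a
database's precomputed annotations and states no threshold. Surviving
hits are resolved into a non-overlapping architecture greedily by
descending bitscore (ties broken by position then accession, so input
order never matters); a hit is rejected if it overlaps an accepted
segment by more than 15 aa. Roles follow from segments:

* `PP2C` — phosphatase domain present, no kinase domain;
* `Pkinase_CSD` / `Pkinase_FHA` — kinase domain with the accessory
  domain *starting strictly after the kinase segment ends*. This
  operationalizes "fused with a variable C-terminus": an N-terminal
  accessory domain does not confer the role;
* `Pkinase_plain`, `Psu`, `other` — as named. A gene with both CSD and
  FHA after its kinase is assigned by the higher-bitscore accessory and
  flagged with a warning. A single global E-value cutoff applies to
  kinase and accessory domains alike.

### The triplet scan

Every run of three consecutive CDS on one strand is tested for the
phosphatase/kinase/kinase pattern *in transcription order* (descending
coordinates on the minus strand). The published search order is
phosphatase-first (P-K-K), while the operon itself is named
kinase-kinase-phosphatase; these conflict, and both are mirror images
under strand-annotation ambiguity, so the scanner default `pattern =
"both"` accepts either order and records which one matched (`"PKK"` or
`"KKP"` can be forced).

Candidates then pass two filters:

* **length** — every gene strictly between 900 and 1300 bp (the printed
  inequalities are strict; the bounds are applied to all three genes,
  the conservative reading);
* **architecture** — of the two kinases, exactly one `Pkinase_CSD` and
  one `Pkinase_FHA`, in either position.

A candidate failing any filter is kept with rejection codes (`LEN_SHORT`,
`LEN_LONG`, `NO_CSD`, `NO_FHA`, `DUP_ACCESSORY`); a candidate passing all
filters is an *authentic* KKP cluster, and its genes are role-resolved to
pfpC-like, pfkA-like (CSD) and pfkB-like (FHA) components. In overlapping
runs (e.g. P-K-K-K) every window is evaluated and reported; at most one
can be authentic because the accessory roles must differ.

### Genomic context

Each cluster is assigned one category with fixed precedence
`prophage > P4_prophage > MGE_linked > other`:

* **prophage** — the cluster span overlaps a predicted prophage interval
  by ≥ 1 bp. Full containment is not required because prophage boundary
  predictions are imprecise; `prophage_containment = TRUE` restores the
  stricter rule.
* **P4_prophage** — no interval overlap, but a Psu-role gene (phage P4
  polarity suppression protein, PF07455) lies within 20 CDS positions.
  Automated prophage callers frequently miss the ~11 kb P4 satellites;
  since ~20 CDS comfortably spans a P4 genome, 20 is the default rescue
  radius (configurable). Psu need not be co-strand with the cluster.
* **MGE_linked** — a mobile-genetic-element gene (integrase, transposase,
  restriction-modification, toxin-antitoxin, phage gene) within 5 genes
  *or* 3000 bp (OR semantics, matching the stated adjacency rule); gene
  distance is measured by index from the nearest cluster gene, bp
  distance from the cluster span. The MGE table is user-supplied,
  mirroring the original post-hoc manual curation of missed annotations.

Summaries report per-category counts and fractions, plus the
MGE-linked-among-non-prophage subtotal as "x out of y".

### Families and trees

Pairwise percent amino-acid identity is computed by global affine-gap
alignment with BLOSUM62 (gap open −11, extend −1). The identity
denominator is **all alignment columns** (gap columns count against
identity) — the stricter of the common conventions, configurable to
`"shorter"`. Cluster-level identity is the arithmetic mean of the three
component identities (pfkA-pfkA, pfkB-pfkB, pfpC-pfpC); the source
analysis states only a >90% amino-acid identity grouping without
specifying the combination, so mean-of-three is this package's choice
(min-of-three available). Families are single-linkage connected
components with edges strictly above the threshold (default 90);
numbering is deterministic by smallest member id and the representative
is the longest member (ties by id).

Tree *inference* (alignment, trimming, maximum likelihood, bootstraps) is
deliberately out of scope; the package annotates externally built Newick
trees. The tree is rerooted on the smallest clade containing all
configured outgroup leaves (for PfkA trees, a eukaryotic-kinase
outgroup), and each labelled clade is grown from the MRCA of its
reference leaves to the maximal subtree containing no other clade's
references and no outgroup leaf. Nested reference sets raise a monophyly
error; leaves outside all clades are `unassigned`.

### Region comparison

Prophage-region claims (one region "nearly identical" to another up to a
short internal deletion; core regions at >98% nucleotide identity) are
supported by exact global affine-gap alignment (Gotoh), implemented in
C++ with full traceback. Scoring defaults are megablast-like: match +1,
mismatch −2, gap open −5, gap extend −1 (a gap of length L costs
`open + L·extend`); the original reports name no aligner or scheme, so
these are package defaults and fully configurable. Tie-breaking is
deterministic — diagonal over gap, gap in the second sequence over gap in
the first, extension over opening — so outputs are reproducible to the
byte. For regions over 5 kb the dynamic program is restricted to a
diagonal band (half-width 256 by default), which keeps a ~12 kb prophage
pair at desk scale and is exact whenever the optimal path stays in band;
the band must be at least the length difference. The result carries the
column/match/mismatch/gap inventory and the maximal gap-run table (which
sequence, start column, length, flanking 10-mer on the carrier sequence);
`compare_regions()` drops terminal runs from its report by default, since
region boundaries are themselves imprecise.

## The synthetic data generator

`generate_dataset()` emulates the screening universe at desk scale:
single-contig genomes of ~100-140 CDS, log-normal background gene lengths
(median ~900 bp, sdlog 0.35, clamped to 150-3600 bp and rounded to
codons), exponential intergenic gaps (mean ~80 bp, occasionally
abutting), random strands, and background roles of 95% `other`, 3% lone
plain kinase, 2% lone PP2C — enough near-miss structure to exercise the
scanner without manufacturing accidental authentic clusters (background
kinases never carry accessories). Planted items:

* **authentic clusters** — three consecutive same-strand genes, lengths
  drawn from 903-1299 bp codon multiples, roles P-K-K in transcription
  order with CSD/FHA in random kinase positions;
* **decoys**, one rule violated each: `WRONG_ORDER` (K-P-K),
  `MIXED_STRAND`, `NON_ADJACENT` (an intervening CDS), `KK_PAIR_ONLY`
  (no phosphatase), `LEN_OUT` (one gene at 840 or 1398 bp), `NO_CSD`,
  `NO_FHA`;
* **contexts** for authentic clusters, sampled at prophage 0.60 /
  P4 0.15 / MGE-linked 0.15 / other 0.10 (defaults chosen once so every
  category is populated in a ~10-seed battery); prophage intervals pad
  the cluster span by 0.5-1.5 kb, Psu genes sit 3-10 CDS away, MGE genes
  1-4 CDS away. Planted items are spaced ≥ 40 CDS apart with forced
  `other` flanks so no item contaminates another's context window;
* **identity families** — trios of 300-aa proteins derived from common
  ancestors by point substitutions at one shared position set, giving
  *exact* pairwise identity at the target (e.g. 30 substitutions → 90.0%
  on a gapless alignment).

All randomness flows from one seed; per-genome substreams are derived by
counter, so enlarging a battery never perturbs existing genomes, and
identical configs write byte-identical files. The generator does **not**
simulate realistic phage genome architecture, GC content, codon usage, or
annotation noise (wrong coordinates, chimeric genes, missed calls).
Passing tests therefore demonstrate algorithmic correctness against the
stated rules, not robustness to real annotation error.

## Numerical and degenerate-input choices

* Length filter bounds are strict (`900 < len < 1300`); a gene at exactly
  900 or 1300 bp is rejected.
* `authentic_fraction()` on zero candidates returns `NA` flagged
  `undefined`, never 0.
* Interval inputs: BED is 0-based half-open and converted on read; all
  internal coordinates are 1-based inclusive (the GFF3/GenBank
  convention of the annotation sources).
* Identity matrices carry an exact 100 diagonal; family edges use strict
  `>` so a pair at exactly the threshold does not join.
* Alignment tie-breaks are fixed (see above); co-optimal gap placements
  next to repeated bases therefore resolve deterministically, though the
  reported gap *position* may differ by a few columns from the planted
  position while the run length is exact.
* The empty genome set, contigs with < 3 CDS, hitless genes, and
  comment-only hit tables all yield empty results rather than errors.

## Problem sizes used in the shipped analyses

The bundled analysis scripts and the acceptance battery run, per
invocation: 50 genomes x 100 CDS for scanner/oracle equivalence, 12
seeded genomes x 140 CDS x 2 clusters for planted-truth and context
recovery, one 320-CDS genome carrying all seven decoy classes, 500
random short pairs plus 100 planted-indel trials for the aligner, a
3-genome family plan, and one 12 kb prophage-pair alignment. These sizes
were chosen as the smallest batteries that exercise every rule and
every decoy class with double-digit counts per category.

## Known limitations

* GenBank flat-file ingestion reduces `join()` locations to their outer
  span; compound locations (rare in bacterial CDS) are not modelled.
* The scanner assumes per-contig CDS indices are meaningful, i.e.
  annotations are reasonably complete; heavily fragmented assemblies
  will split true triplets across contigs.
* Context assignment is evidence-precedence based and does not weigh
  conflicting evidence probabilistically.
* Protein identity from a single optimal alignment is reported even when
  co-optimal alignments with slightly different identities exist.
* Headline counts of the original genome-database screen (cluster totals
  over tens of thousands of genomes) require that database snapshot and
  its precomputed annotations; they are out of scope and are replaced by
  property-based checks on generated data.
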