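---
title: "Methods: homopolymer-aware OTU delineation and taxonomy for V9 amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homopolymer-aware OTU delineation and taxonomy for V9 amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpotu)
```

## The problem

Deep-sea sediment surveys of eukaryotic diversity amplify the short V9
hypervariable region of the 18S rRNA gene and sequence it at depth on 454
pyrosequencing. Two properties of that setting shape everything in this
package:

* **the dominant error mode is homopolymer run-length miscalling** — the
  instrument reads run lengths from light intensity, which saturates for long
  runs, so a large share of erroneous reads differ from their template only
  in the lengths of mononucleotide runs;
* **the amplicon is short (~130 bp)**, so a handful of error-induced
  differences is enough to inflate diversity estimates badly if reads are
  clustered by ordinary edit distance.

The pipeline therefore delineates OTUs under a global-alignment distance that
refuses to count run-length differences, and surrounds that core with the
standard stages of an amplicon survey: primer-based quality screening, strict
dereplication, consensus taxonomy, planktonic-origin classification, and
cross-sample occupancy summaries.

## The homopolymer-insensitive distance

`hp_distance(a, b)` is the minimum over all global alignments of the number
of *counted-difference* columns:

* a substitution column counts 1;
* an indel column counts **0** iff the inserted/deleted base equals the most
  recently aligned base of the *opposite* sequence — i.e. the indel merely
  lengthens or shortens a homopolymer run shared by both sequences at that
  point — and counts 1 otherwise;
* an indel before any opposite base has been aligned counts 1.

```{r}
hp_distance("ATGTGGGGTAT", "ATGTGGGTAT")$distance  # run-length change: free
hp_distance("ACGT", "ACGA")$distance               # substitution: counted
hp_distance("ATGGGGAT", "ATAT")$distance           # losing a whole run: counted
```

This column-costing rule was a genuine design choice: the distance is
specified by its behaviour (run-length changes are free) rather than by a
formula, and more than one rule reproduces the flagship example. We chose
this one because it (i) keeps the presence or absence of a run a counted
difference (`ATGGGGAT` vs `ATAT` is 4, not 0), (ii) admits an O(nm) dynamic
program, and (iii) makes the free-indel decision depend only on the already
aligned prefix, so the DP state stays two-dimensional. A run-length
compression shortcut (compare RLE skeletons) was rejected: it miscounts
substitutions adjacent to runs. Under this rule the distance can slightly
undercount on pathological inputs (an indel that happens to equal the
opposite neighbour is free even when the two runs are unrelated), which we
accept as the price of the simple state; the distance is never larger than
Levenshtein.

Correctness is checked against `hp_distance_oracle()`, an exhaustive
enumeration of all global alignment paths under the identical column costs.
The oracle shares no code with the DP (it is a plain recursion over paths)
and is feasible only for sequences up to ~12 bases; the test suite sweeps
tens of thousands of random and homopolymer-rich pairs through both routes.

`within_k(a, b, k)` is the clustering predicate. It runs the same DP with a
row-minimum early abandon: once every cell of a row exceeds `k` no completion
can return below it, so the scan stops. This prunes the vast majority of
tag-versus-seed comparisons (unrelated V9 sequences exceed `k = 3` within a
few rows) while returning exactly the unbanded answer whenever the true
distance is at most `k`.

## Read screening and dereplication

A read is retained iff it begins with an exact (IUPAC-aware, zero-mismatch)
match to the proximal primer and ends with one to the distal primer; both
primers are trimmed. Double-ended exact primer recovery is the pipeline's
*only* sequencing-quality filter — it guarantees that every retained insert
is truly orthologous over its full length, which matters because the
similarity formula divides by full query length. Reads with N in the insert
are rejected: the distance is defined over `{A,C,G,T}` and an ambiguous base
cannot be scored against a run. Primer sequences are configuration inputs,
never hard-coded.

Strict dereplication collapses identical inserts into unique tags carrying
total and per-sample counts. Tags are ordered by decreasing abundance with
ties broken lexicographically by sequence — the tie-break is arbitrary but
total, which makes clustering (and therefore the entire pipeline) a pure
function of its input.

## Greedy clustering and single-singletons

`greedy_cluster()` makes a single pass in abundance order: the most abundant
unassigned tag seeds an OTU, every later unassigned tag within `k` counted
differences of *that seed* joins it, and the next unassigned tag seeds the
next OTU. Members join the first qualifying seed and are never re-assigned
to a closer later seed; tags are never compared with non-seed members. The
default radius is `k = 3` on ~130 bp inserts (2-3% of the amplicon);
sweeping `k` from 0 to 8 is supported and the OTU count is non-increasing in
`k`.

Clustering is performed on the pooled tag set across samples so OTU
identities are comparable between samples — the occupancy and region-sharing
tables require a common OTU universe. Per-sample counts are carried through.

An OTU consisting of one tag seen exactly once (a *single-singleton*) is a
plausible sequencing artefact; `drop_single_singletons()` separates them, but
the pipeline default **keeps** them, because rare sequences are a genuine
object of interest in under-sampled deep-sea habitats and the saturation
curves are reported with and without them.

## Similarity, assignment and triage

Hits against a reference database carry the similarity

> sum over non-overlapping HSPs of (identities − gaps), divided by the full
> query length,

floored at 0. Dividing by query length rather than alignment length is
deliberately stringent: a hit covering only a conserved fragment cannot score
high. The HSP subset is chosen greedily by descending score, skipping
overlaps on query coordinates.

Two hit providers feed that formula identically: a built-in seeded local
aligner (7-mer seeding, affine Smith–Waterman at +5/−4 with gap open 8 and
extend 6) and a reader for NCBI BLAST XML. The internal aligner reports a
hit only when the query and reference share at least 4 seven-mers and the
resulting similarity reaches 0.30 — our substitute for BLAST's E-value
cutoff; both knobs are exposed. With ~130 bp sequences, 7-mer seeding alone
barely filters (a random pair shares a 7-mer with probability near 1), which
is why the shared-word *count* is the working prescreen.

Assignment (`assign_consensus()`) takes the retained hits with similarity at
or above 0.80 as the *good* set; with none the query is **unassigned**.
Ranks are then walked genus → family → order → class → phylum → kingdom →
domain, and the first rank where at least 75% of the good hits carrying a
name at that rank agree supplies the label. If no rank reaches consensus the
query is **undetermined**. Hits lacking a name at a rank leave the
denominator at that rank: curated lineages are ragged and an absent name is
no vote against a consensus. Both thresholds (≥ 0.80, boundary inclusive;
75%) are parameters with the study defaults.

Before clustering, every unique tag is triaged by the domain of its best hit
against a combined eukaryote + prokaryote database: archaeal and bacterial
tags are counted and discarded, tags with no reported hit at all are counted
as non-rRNA, and only eukaryotic tags (including those whose best hit is
below the 0.80 assignment floor — they become the unassigned class) proceed.

`resolution_profile()` reproduces the database-side control experiment:
reference V9 sequences are clustered greedily at a series of similarity
levels (0.85–0.99) and each cluster is scored by the deepest rank at which
all members agree, reporting the fraction of sequences in clusters with
consensus at each rank or deeper. Two clustering criteria are exposed:
global-identity fraction (the default) and the homopolymer-insensitive
distance with `k = round((1 − level) · median length)`.

## Planktonic-origin classification

An OTU is *putatively planktonic* if either

* its lineage contains a taxon from the phototroph list (the shipped default
  lists the green/red/glaucophyte algae, haptophytes, picobiliphytes,
  diatoms and the other phototrophic stramenopiles, plus Radiolaria), or
* its seed sequence matches an environmental-database record annotated as
  marine plankton at ≥ 0.90 similarity (boundary inclusive, configurable).

Habitat labels are a required column on the environmental database; the
original mining of collection-site metadata from publications is out of
scope, so fixtures and the generator supply labels directly. In the
per-sample summary, phototrophic OTUs are excluded from the environmental
marine-plankton row so no OTU is double-counted, and percentages are over
assigned OTUs only.

## Occupancy and region sharing

`occupancy()` classes each OTU by the number of samples (of `S`) in which it
has at least one read — presence is read count ≥ 1, with no minimum-abundance
filter — and sums reads per class; the classes partition both OTUs and reads
exactly. `region_sharing()` specialises to the two-region design: OTUs in
every sample of both regions ("bipolar"), in all samples of one region and
absent from the other ("endemic"), and the analogous at-least-one-sample
sets, whose three categories partition all OTUs.
`sharing_taxonomy_profile()` crosses those sets with the major-group rollup
and the plankton calls.

## The synthetic study

`sim_params()` fixes the conditions the package is exercised under; they are
the generator's defaults and are not tuned per test:

| parameter | default | what it emulates |
|---|---|---|
| samples | DSE1-3 = ANT, DSE4-6 = ARC | two-region, six-sample design |
| reads_per_sample | 10,000 | ~10^4 reads per sample (60,000 total) |
| n_taxa | 100 | eukaryotic genus-level taxa |
| v9_length | 130 ± 10 | V9 insert length |
| lognormal mu, sigma | 0, 2 | skewed abundances, many rare taxa |
| shared_fraction | 0.30 | bipolar taxa present in both regions |
| planktonic_fraction | 0.40 | half phototrophic clades, half via env records |
| arch/bact/junk rates | 0.035 / 0.09 / 0.0025 | prokaryotic + non-rRNA contamination |
| hp_indel_rate | 0.01 per run | miscall probability 0.01·(L−1), capped 0.5 |
| sub_rate | 0.002 per base | residual substitution errors |

The homopolymer miscall probability grows linearly with run length and runs
of length 1 are never touched, so homopolymer-only corpora sit at
`hp_distance` 0 from their templates — the property that validates the
distance design: such reads are invisible to `hp_distance` but visible to
Levenshtein, and clustering at `k = 3` recovers exactly the observed taxon
count.

Two generator choices deserve justification. First, taxa are placed on a
fixed set of real major-group names (Ciliophora, Dinophyceae, Cercozoa,
Bacillariophyta, Haptophyta, ...) so the shipped rollup and phototroph
tables apply unchanged to simulated lineages. Second, sister genera are
drawn ~25% divergent and any pair of taxon sequences closer than 10 counted
differences is resampled. Real congeneric V9 sequences are often far closer
(sometimes identical — a documented limit of the V9 region); the generator
deliberately makes taxa resolvable so that the ground truth is unambiguous:
every clustering or assignment error is then attributable to the pipeline,
not to an ill-posed truth. Passing tests therefore demonstrate correctness
of the machinery under separable taxa, not that real congeneric species are
distinguishable, and recovery rates on real data will be bounded by the
marker, not by the code. Within-genus reference species (2% divergence, two
per genus) exercise the consensus denominator without breaking separability.

Chimeras are not simulated and quality scores are not modelled (the pipeline
never reads them); both are extension hooks.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere inside the package; BLAST
  XML's 1-based closed coordinates are converted on read.
* Abundance ties in dereplication break lexicographically; tied alignment
  optima may return any minimum-cost alignment (only the distance is
  contractual); tied best hits order by reference id.
* Empty inputs: empty FASTA → empty table; empty hit list → unassigned with
  best similarity 0; an empty OTU set propagates zero-filled tables.
* `hit_similarity` floors at 0 (gaps can exceed identities on pathological
  HSP sets) and caps at 1.
* All randomness (generator, rarefaction) is seeded; a fixed seed gives
  byte-identical output.

## Problem sizes in the shipped analyses

The numbered scripts under `analysis/` and the heavier tests run the default
60,000-read, 100-taxon study described above; the distance oracle sweeps use
10,000 pairs of length ≤ 10, and the resolution-profile experiment runs on
the 200-sequence synthetic reference. These sizes were chosen so the whole
suite re-runs from scratch in minutes on one core while still exercising
every conservation invariant at realistic per-sample depths.

## Known limitations

* The free-indel rule is one consistent reading of "run-length differences
  are not counted"; alternative readings (e.g. requiring the run to exist on
  both sides beyond length 1) would count a handful of edge cases
  differently.
* The internal aligner reports one HSP per query/reference pair; multi-HSP
  hits only arise via BLAST XML. For ~130 bp queries this is immaterial.
* Greedy abundance clustering is order-dependent by design (that is the
  specified algorithm); it does not minimise any global criterion.
* The generator's taxa are more divergent than real congeneric V9 sequences
  (see above), and its contamination reads are random-sequence proxies, not
  real prokaryotic 16S fragments.
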