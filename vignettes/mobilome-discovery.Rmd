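---
title: "CRISPR-spacer-based mobilome discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CRISPR-spacer-based mobilome discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Uncultivated prokaryotic clades — here modelled on anaerobic methanotrophic
archaea of the ANME-1 order — cannot be linked to their viruses and plasmids
by culturing. CRISPR arrays offer a sequence-native record of past
infections: each spacer in a host array is a copy of a locus (the
protospacer) on an invading mobile genetic element (MGE). Mapping a trusted
spacer catalogue onto assembled contig pools therefore assigns MGEs to a host
clade without isolating either partner. `spacerlink` implements this
discovery procedure desk-scale: array detection, conservative repeat-level
trust filters, strict protospacer matching, retention filters, genome
completeness from terminal repeats, a hypergeometric gene-sharing network,
and hallmark-gene classification — plus a seeded synthetic-community
generator so every stage is testable without downloads.

## Models and assumptions, stage by stage

**Array detection** is a seed-and-extend scan for tandem exact repeats:
every k-mer (k = minimum repeat length, 20 bp) occurring at least three
times at spacings compatible with a repeat–spacer period seeds a candidate,
whose repeat is extended right and then left while all copies remain
identical, the repeat stays within 20–50 bp and every spacer keeps 15–75 bp.
Repeat copies are thus exact duplicates of the consensus — a deliberate
restriction (trivially within the ≤ 2-substitution tolerance the array model
allows) that makes the detector deterministic and exactly checkable against
an exhaustive all-substrings tandem scan. Real arrays with degenerate edge
repeats would be truncated rather than missed; the reference analyses
delegate detection to a dedicated typer, and detection accuracy is not the
scientific claim here. Overlapping candidates are resolved by more copies,
then longer span, then leftmost start. A three-copy minimum is used because
two-copy "arrays" are indistinguishable from chance duplications.

**Repeat trust.** Repeats are strand-canonicalized (lexicographic minimum of
sequence and reverse complement) and greedily clustered at ≥ 90% full-length
identity with ≤ 2 bp length difference — tolerant enough for array-edge
degeneracy, tight enough to stay clade-specific. A cluster is trusted only
when its members span ≥ 3 distinct contigs, guarding against binning
artefacts; clusters matching any off-target-clade repeat at the same
threshold are discarded. Spacer "uniqueness" is strand-canonical; because
orientation conventions differ between tools, the orientation-aware count is
also reported as metadata.

**Protospacer matching** is gap-free, full-length, ≤ 1 substitution by
default, both strands — the strictest defensible reading of "stringent"
mapping, exposed as a flag. Matches inside arrays detected on the target
pool (padded by one repeat length) are suppressed so array-on-array matches
never count as linkage. Retention demands ≥ 3 distinct protospacer loci
(distinct by start and strand, so stacked near-identical spacers count once)
and > 10 kb of contig. Counting loci rather than distinct spacers is a
documented choice: "three protospacers" reads as target-side loci.
PAM/flank context is ignored.

**Completeness and topology** are strictly termini-based: the longest exact
terminal match is computed in both senses; a direct terminal repeat (DTR)
≥ 20 bp calls a circularly permuted complete genome, else an inverted
terminal repeat (ITR) ≥ 20 bp calls a complete linear genome, else the
element stays unresolved. DTR is checked before ITR so palindromic ends
resolve deterministically. The 20 bp floor is the convention of completeness
tools; matching is exact (no mismatches), and the search is capped at
5,000 bp (or half the sequence) — terminal repeats beyond that are outside
the biological range this models. Elements circularized by assembly but
lacking detectable termini are *not* called complete here.

**ORF calling** scans six frames for stop-terminated ORFs ≥ 50 aa with
ATG/GTG/TTG starts (alternative starts translated as M, standard code).
Within a stop-to-stop segment the first start is taken (equivalently, the
longest ORF per stop); ORFs fully nested inside a longer same-strand ORF are
suppressed.

**Gene-sharing network.** Proteins are greedily clustered into families:
sorted by decreasing length (ties by identifier), each joins the first
centroid reaching 50% identity over 80% of the shorter sequence by local
alignment (BLOSUM62), else founds a family. A shared-8-mer screen
preselects candidate centroids before alignment, as greedy clustering tools
do; at these thresholds homologs essentially always share an exact 8-mer,
and unrelated proteins essentially never do, so the screen changes nothing
but the runtime. For genomes A and B with a and b families out of n total,
the edge weight is the hypergeometric upper tail P(X ≥ c) for c shared
families, computed by exact summation; the significance score is
−log10(p · n_pairs) with n_pairs the number of genome pairs tested (all
unordered pairs — the most conservative Bonferroni choice), and edges with
score ≥ 1 are kept. Clusters are connected components; sub-cluster
refinement and topology-confidence testing of the reference network tool are
out of scope. Cluster identifiers are canonicalized by smallest member name,
making the partition invariant to input order.

**Classification.** An element carrying at least one identifiable viral
structural protein — any major capsid protein class (HK97 fold, double or
single jelly-roll, α-helical, spindle), portal, or large terminase — is a
virus; replication-only hallmarks (pPolB, rPolB) never confer virus status,
so circular elements with only a polymerase stay unclassified MGEs
(plausibly plasmids). The reference analyses find structural proteins by
profile–profile comparison and structure prediction; desk-scale, the same
*rule* is applied over user-supplied marker sets with permissive local
alignment thresholds (30% identity over 50% of the marker). Permissive
thresholds can add spurious extra classes on large proteomes; recovery of a
planted class is therefore judged by membership, not by exact equality of
the class list. Elements with no marker but network-linked to viruses stay
unclassified — guilt by association is not formalized here.

## The synthetic world

The generator's defaults state one fixed world rather than a dial to turn:
5 hosts (20 kb) each carrying 2 arrays of 8 spacers (30–40 bp) on a single
shared clade repeat (30 bp); 10 viruses of 12–16 kb in 3 family groups;
80% of viruses targeted, the 80 spacer slots served round-robin so each
targeted virus receives ~10 planted protospacer loci; 5 decoys; 2
off-target hosts whose repeat is ≥ 10 substitutions from the clade repeat;
terminal repeats of 60 bp with a 40/40/20 DTR/ITR/none mix; 20 core genes
(80–120 aa) shared within each family group plus one structural marker gene
(150 aa) per group, cycling through the marker classes.

Two defaults deserve their arithmetic. *Loci per virus*: with a per-locus
mutation rate of 0.02 and ≤ 1 mismatch allowed, a ~35 bp locus is detectable
with probability ≈ 0.85, so ≥ 3 detected loci out of ~10 planted has
probability > 0.9999 — the retention filter is then a test of the filters,
not of luck. Real CRISPR-mapped MGEs typically carry many protospacers, so
ten is conservative realism. *Core genes per group*: uniform random
background sequence yields roughly 60–80 chance ORFs ≥ 50 aa per genome, all
singleton families. With ~85 families per genome and ~750 total, the null
expectation of shared families between two group members is ≈ 9; 21 shared
(20 core + marker) sits ≈ 4 standard deviations above it, giving
Bonferroni-corrected scores comfortably over the threshold, while unrelated
genomes share nothing. Fewer core genes (e.g. 6) would drown in this
chance-ORF background — a real property of the hypergeometric statistic at
small n, not a defect. These values were fixed by this calculation before
the recovery tests were run, and are not revisited.

Planted genes are synthetic ORFs built from a fixed codon table whose
Leu/Lys/His codons make every planted protein start M-L-K-H-K; that prefix
plants stop codons in both shifted frames of the same strand, and a TAA
guard precedes each start, so planted genes are always called exactly (no
chance ORF can contain or extend them). The generator emulates array
structure, linkage, family structure, termini and markers — not genome
composition (no codon bias or GC skew), not read-level noise, not assembly
artefacts. A green recovery suite therefore establishes that the *filters
and statistics* behave as specified on data with the assumed structure, not
that the pipeline is robust to assembly pathology.

## Numerical and degenerate-input choices

Single RNG seed propagated through every draw; identical config + seed is
byte-identical. Coordinates are 0-based half-open throughout; FASTA headers
tokenize at the first whitespace. Repeat extension goes right then left
(the right boundary is unaffected by later leftward growth, so results are
inextensible on both sides). Empty prediction sets score precision 1;
empty truth sets score recall 1. Hypergeometric p-values use exact density
summation (no normal approximation); p = 1 when c = 0. Spacers shorter
than 15 bp are rejected with a warning; infeasible generator configurations
(arrays that cannot reach three repeat copies, too few spacer slots to give
every targeted virus three loci, viruses too short to hold their planted
content) fail with explicit errors rather than silently degrading.

## Known limitations

Exact-copy repeat detection truncates degenerate array edges. Marker
classification is sequence-similarity only — structure-only capsid proteins
(the motivating case for structure prediction in the reference analyses)
are invisible to it, and permissive thresholds admit occasional spurious
classes. The published headline counts (tens of thousands of spacers,
hundreds of MGEs) require the original metagenome assemblies and deposited
supplementary files; the package verifies those only when the user supplies
the deposits (see `inst/extdata/deposited/README.md`), and reports nothing
about them otherwise.
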