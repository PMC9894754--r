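# spacerlink

CRISPR-spacer-based discovery of host-linked mobile genetic elements
(MGEs) in uncultivated prokaryotic clades, desk-scale and fully
reproducible.

Hosts record past infections in CRISPR arrays: each spacer is a copy of a
locus (protospacer) on an invading virus or plasmid. Given host contigs
and a pool of candidate MGE contigs, `spacerlink`:

1. detects repeat–spacer arrays (tandem exact repeats, 20–50 bp repeats,
   15–75 bp spacers, ≥ 3 copies) and builds a **clade-trusted spacer
   catalogue** — repeats must appear on ≥ 3 distinct contigs and must not
   be shared with an off-target sister clade;
2. maps spacers onto the pool (gap-free, full length, ≤ 1 substitution,
   both strands) and **retains MGEs with ≥ 3 distinct protospacer loci
   and > 10 kb**;
3. calls ORFs and exact terminal repeats: a direct terminal repeat (DTR)
   marks a complete circularly permuted genome, an inverted terminal
   repeat (ITR) a complete linear genome;
4. builds a **gene-sharing network**: protein families by greedy
   clustering (≥ 50% identity over ≥ 80% of the shorter sequence), edge
   significance as the hypergeometric tail P(X ≥ c) for c families
   shared between genomes with a and b families out of n, kept when
   −log10(p · n_pairs) ≥ 1; connected components delineate candidate
   family-level virus groups;
5. classifies each element: a viral structural protein (MCP/portal/TerL
   classes) makes it a **virus**; replication-only markers (pPolB/rPolB)
   leave it an **unclassified MGE** (plausibly a plasmid).

A seeded synthetic-community generator (`community_config()`,
`generate_community()`) plants all of this structure with a ground-truth
table, so the entire pipeline is testable offline.

## Worked example

The `analysis/` scripts run the whole study on the default synthetic
community (seed 101). `Rscript analysis/01_simulate.R` through
`06_classify_report.R` print:

```
hosts:           5
pool contigs:    15 (10 viruses, 5 decoys)
planted loci:    80
host-virus pairs:40

arrays detected:      10 on target clade, 4 off-target
repeat clusters:      1 (1 trusted, 0 removed as cross-clade)
unique spacers:       80 (orientation-aware: 80)

protospacer hits:  80
retained MGEs:     8 (total 8 across sources)

MGEs characterized: 8
ORFs called:        716
circular-DTR   linear-ITR   unresolved
           5            2            1

proteins:        716
families:        431
edges kept:      7 of 7 tested (28 pairs)
clusters:        3

report rows:  8
status:       virus=8
topology:     circular-DTR=5, linear-ITR=2, unresolved=1
linkage precision 1.000, recall 1.000 vs planted truth
```

Reading this: all 10 planted arrays are found and their one shared repeat
is trusted (5 contigs ≥ 3); the 80 unique spacers hit exactly the 80
planted loci; the 8 targeted viruses (and no decoy, no untargeted virus)
pass the ≥ 3-loci / > 10 kb filters — precision and recall 1.0 against
the truth table. Topology calls match the planted termini, the network's
3 connected components are exactly the 3 planted family groups, and every
retained element carries its group's planted structural marker, so all 8
are classified as viruses.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end to end on the seeded synthetic world —
catalogue construction, linkage with precision/recall against the planted
truth, network and classification — printing a run summary and writing
the JSON target report. See `vignettes/mobilome-discovery.Rmd` for the
models, the parameter rationale (including why the synthetic defaults are
what they are), and known limitations.
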