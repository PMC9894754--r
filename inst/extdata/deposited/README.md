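# Deposited study data (not redistributed)

The acceptance checks on published data expect the following files in
this directory. They are public deposits that cannot be bundled with the
package (size and licensing); download them once and drop them in here.

| file | content | source |
|------|---------|--------|
| `supplementary_data_1_spacers.fna` | ANME-1 CRISPR spacer catalogue (FASTA, 20,649 unique spacers) | Supplementary Data 1 of the source study (BioProjects PRJNA875076 / PRJNA721962) |
| `supplementary_data_2_mges.fna` | ANME-1-specific MGEs from Guaymas and Pescadero Basins (FASTA, 233 records, all > 10 kb) | Supplementary Data 2 of the source study |
| `OP413838.fna` | ahpuchvirus PBV299 genome (70.9 kb) | GenBank OP413838 |
| `OP413840.fna` | ahmunvirus PBV300 genome (linear, inverted terminal repeats) | GenBank OP413840 |
| `OP880253.fna` | ekchuahvirus GBV302 genome (80.6 kb) | GenBank OP880253 |

Without these files the corresponding acceptance tests fail with a
pointer to this README; every other test in the suite is self-contained
(inputs are generated in code).
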