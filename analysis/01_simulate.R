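#!/usr/bin/env Rscript
# Stage 1: state the synthetic world.
#
# Generates the default seeded host-virus community: five host contigs
# carrying repeat-spacer arrays on a shared clade repeat, ten viruses in
# three family groups (80% of them targeted by ~10 planted protospacer
# loci each), five decoys and two off-target-clade hosts.  Everything
# downstream works from the FASTA files written here; the truth tables
# are only used again in stage 6 for scoring.

suppressMessages(library(spacerlink))

cfg <- community_config(seed = 101L)
comm <- generate_community(cfg)
write_community(comm, "results/community")

message("hosts:           ", length(comm$hosts))
message("pool contigs:    ", length(comm$pool), " (",
        sum(startsWith(names(comm$pool), "VIRUS")), " viruses, ",
        sum(startsWith(names(comm$pool), "DECOY")), " decoys)")
message("planted loci:    ", nrow(comm$truth$protospacers))
message("host-virus pairs:", nrow(comm$truth$linked_pairs))
message("written to results/community/")
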