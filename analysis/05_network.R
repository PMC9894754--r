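#!/usr/bin/env Rscript
# Stage 5: the gene-sharing network.
#
# Proteins are greedily clustered into families (>= 50% identity over
# >= 80% of the shorter sequence); for every genome pair the shared
# family count is tested against the hypergeometric null and edges with
# -log10(p * n_pairs) >= 1 are kept.  Connected components delineate
# candidate family-level groups.

suppressMessages(library(spacerlink))
suppressMessages(library(Biostrings))

prot <- as.character(readAAStringSet("results/proteins.faa"))
families <- cluster_proteins(prot)
net <- build_network(families)

write.table(families, "results/protein_families.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(net$edges, "results/network_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(net$nodes, "results/network_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("proteins:        ", length(prot))
message("families:        ", net$n_total_families)
message("edges kept:      ", sum(net$edges$kept), " of ",
        nrow(net$edges), " tested (", net$n_pairs, " pairs)")
message("clusters:        ", length(unique(net$nodes$cluster)))
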