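#!/usr/bin/env Rscript
# Build the study's synthetic genome battery: 20 single-contig genomes,
# each with one or two planted authentic KKP clusters plus typed decoys,
# context scaffolding (prophage intervals, Psu genes, MGE genes) and a
# truth table. All downstream steps read the files written here.

suppressMessages(library(kkpminer))

out <- "results/synthetic_battery"
cfg <- synth_config(seed = 101, n_genomes = 20, genes_per_genome = 140,
                    n_authentic = 2,
                    decoys = c(LEN_OUT = 1),
                    family_plan = list(list(size = 3, identity = 95),
                                       list(size = 2, identity = 92)))
ds <- generate_dataset(cfg, out_dir = out)

message(sprintf("wrote %d genomes to %s", length(ds$genomes), out))
message(sprintf("planted items: %d authentic, %d decoys",
                sum(ds$truth$class == "authentic"),
                sum(ds$truth$class != "authentic")))
print(table(ds$truth$class))
print(table(ds$truth$context, useNA = "ifany"))
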