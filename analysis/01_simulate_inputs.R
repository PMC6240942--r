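#!/usr/bin/env Rscript
# Stage 1: generate ground-truthed inputs for the whole workflow.
#
# Writes a simulated CYP-like family (FASTA + SRS annotation TSV + edit
# log) and a simulated GC-MS variant screen (peak CSV + calibration CSV +
# truth JSON) under results/sim/. Later stages consume these files only.

library(srsmut)

seed <- 1L
out <- "results/sim"
sims <- run_simulate(
  out,
  family_config = family_sim_config(seed = seed, n_sequences = 4,
                                    indel_prob = 0.25),
  screen_config = screen_sim_config(seed = seed)
)

fam <- sims$family
cat("family: ancestor of", record_length(fam$ancestor), "residues,",
    length(fam$descendants), "descendants,",
    nrow(fam$edit_log), "logged edits\n")
cat("planted SRS residues in ancestor:",
    sum(srs_widths(fam$annotation)), "\n")
cat("screen:", length(unique(sims$screen$peaks$strain)), "strains x",
    max(sims$screen$peaks$replicate), "replicates ->",
    nrow(sims$screen$peaks), "peak rows\n")
cat("outputs in", out, "\n")
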