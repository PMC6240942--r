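#!/usr/bin/env Rscript
# Stage 3: enumerate mutation candidates for one family member.
#
# Treats desc1 as the engineering target and desc2 as the donor
# homologue; emits ExxR-offset SRS5 hotspots and reciprocal candidates
# under results/candidates/.

library(srsmut)

out <- "results/candidates"
cands <- run_propose("results/sim/family.fasta",
                     "results/sim/family_srs.tsv",
                     target_id = "desc1", donor_id = "desc2", out,
                     offsets = c(5L, 9L))

cat("candidates by rule:\n")
print(table(cands$rule))
cat("\nSRS5 hotspot positions (E of ExxR + 5 and + 9):\n")
print(cands[cands$rule == "hotspot_srs5",
            c("position", "variant_text", "provenance")], row.names = FALSE)
cat("\nfirst reciprocal candidates:\n")
print(utils::head(cands[cands$rule == "reciprocal", ]), row.names = FALSE)
cat("\nreport written to", file.path(out, "candidates.tsv"), "\n")
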