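#!/usr/bin/env Rscript
# Stage 5: guide-target analysis. Predict the silencing outcome of the
# mutagenized sensor target-site series from the positional rule table,
# then scan the X-cluster transcript with the trigger-locus 26G guide and
# tabulate the discovered sites.

library(sRNAmethyl)

seed <- 42L
out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

variants <- sensor_variants()
sensor <- data.frame(variant = names(variants), states = unname(variants),
                     call = vapply(variants, predict_silencing, character(1)))
write.table(sensor, file.path(out, "sensor_variants.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("sensor variant calls:\n")
print(sensor[, c("variant", "call")])

# the reference is rebuilt deterministically to recover the designed
# trigger guide (the guide sequence is not part of the FASTA output)
ref <- build_reference(reference_config(), seed = seed)
xtx <- feature_seq(ref, "xcluster_locus_1")
sites <- scan_transcript(ref$guide, xtx, min_complementarity = 0.69,
                         guide_id = "trigger_guide",
                         transcript_id = "xcluster_locus_1")
st <- sites_table(sites)
write.table(st, file.path(out, "target_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("\ntrigger guide %s\nfinds %d sites in the %d-nt X-cluster transcript (complementarity %.1f%%, %d G:U per site):\n",
            ref$guide, nrow(st), nchar(xtx),
            100 * st$complementarity[1], st$gu_count[1]))
print(st[, c("start", "end", "complementarity", "call")])
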