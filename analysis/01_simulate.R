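#!/usr/bin/env Rscript
# Stage 1: build the synthetic reference and simulate the sequencing
# libraries.
#
# The reference carries piRNA loci, coding loci, ERGO-1 and ALG-3/4 class
# 26G siRNA source loci, annotated mature miRNAs, an X-cluster-like locus
# with 7 embedded copies of a 26-nt motif, and a trigger locus whose
# antisense 26G read is partially complementary to that motif. The
# untreated library draws all five small RNA classes with their canonical
# lengths and 5' nucleotides; beta-elimination is then simulated as copy
# dropout of unmethylated species (piRNAs and ERGO-1 class 26G siRNAs are
# methylated, everything else is not).

library(sRNAmethyl)

seed <- 42L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ref <- build_reference(reference_config(), seed = seed)
write_reference(ref, out)

untreated <- simulate_library(ref, library_config(), seed = seed + 1L)
treated <- apply_beta_elimination(untreated, p_meth = 1.0, p_unmeth = 0.1,
                                  seed = seed + 2L)
write_library(untreated, file.path(out, "untreated.fa"))
write_library(treated, file.path(out, "treated.fa"))

truth <- aggregate(count ~ true_class + methylated, untreated, sum)
write.table(truth, file.path(out, "simulation_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("reference: %d nt, %d features; motif %s\n",
            sum(Biostrings::width(ref$sequences)), nrow(ref$features),
            ref$motif))
cat(sprintf("untreated library: %d species, %d copies\n",
            nrow(untreated), sum(untreated$count)))
cat(sprintf("beta-eliminated library: %d species, %d copies (%.1f%% of input survive)\n",
            nrow(treated), sum(treated$count),
            100 * sum(treated$count) / sum(untreated$count)))
print(truth)
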