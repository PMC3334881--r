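#!/usr/bin/env Rscript
# Stage 4: 3' end analysis. Decompose every read into genome-templated
# prefix + untemplated tail, measure trimming against the annotated mature
# length at the anchor locus, and tabulate per-class tailed and trimmed
# proportions plus tail nucleotide composition.

library(sRNAmethyl)

data_dir <- "results/data"
out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ref <- read_reference(file.path(data_dir, "reference.fa"),
                      file.path(data_dir, "reference.gff3"))
untreated <- read_library(file.path(data_dir, "untreated.fa"))

calls <- resolve_3prime(untreated, ref)
write.table(calls, file.path(out, "tail_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

aln <- map_library(untreated, ref)
assignments <- classify_library(untreated, aln, ref)
tails <- tailed_proportion(calls, untreated, assignments)
trims <- trimmed_proportion(calls, untreated, assignments)
tab <- merge(tails, trims, by = "class", all = TRUE)
write.table(tab, file.path(out, "tailing_by_class.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
comp <- tail_composition(calls, untreated)
write.table(comp, file.path(out, "tail_composition.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("proportion of placed copies carrying 3' untemplated nucleotides:\n")
print(tails)
cat(sprintf("unplaced reads: %d\n", length(attr(calls, "unplaced"))))
cat("tail composition (fraction of tailed copies by first tail nt):\n")
print(comp)
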