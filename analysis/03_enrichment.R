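#!/usr/bin/env Rscript
# Stage 3: beta-elimination enrichment. Reads-per-million normalization of
# the treated and untreated libraries, per-feature log2 ratios with status
# calls, per-class ratios (the methylated piRNA and ERGO-1 class 26G
# classes should come out enriched, everything else depleted), and the
# percent depletion of the most abundant X-cluster 22G species -- the
# analogue of the worked 22G siR-1 example. A small synthetic qPCR table
# demonstrates the 2^-ddCt quantification.

library(sRNAmethyl)

data_dir <- "results/data"
out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ref <- read_reference(file.path(data_dir, "reference.fa"),
                      file.path(data_dir, "reference.gff3"))
untreated <- read_library(file.path(data_dir, "untreated.fa"))
treated <- read_library(file.path(data_dir, "treated.fa"))

aln <- map_library(untreated, ref)
assignments <- classify_library(untreated, aln, ref)
cls <- stats::setNames(assignments$class, assignments$read_id)
total_u <- sum(untreated$count[cls[untreated$read_id] != "unmapped"])
total_t <- sum(treated$count[cls[treated$read_id] != "unmapped"])

fc_u <- feature_counts(untreated, aln, ref)
fc_t <- feature_counts(treated, aln[aln$read_id %in% treated$read_id, ], ref)
enr <- enrichment_table(fc_u, fc_t, total_u, total_t)
write.table(enr, file.path(out, "enrichment_features.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ratios <- class_ratio(treated, untreated, assignments)
write.table(ratios, file.path(out, "class_ratios.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("per-class ratio of normalized reads, beta-eliminated / untreated:\n")
print(ratios[, c("class", "ratio", "log2_ratio", "status")])

# the 22G siR-1 analogue: most abundant 22G species from the X-cluster
x22 <- untreated[cls[untreated$read_id] == "siRNA_22G", ]
xaln <- aln[aln$read_id %in% x22$read_id, ]
xfeat <- ref$features[ref$features$class == "xcluster_locus", ]
inx <- xaln$contig == xfeat$contig & xaln$start < xfeat$end &
  xaln$start + xaln$templated > xfeat$start
x22 <- x22[x22$read_id %in% xaln$read_id[inx], ]
top <- x22$read_id[which.max(x22$count)]
u_rpm <- rpm(x22$count[x22$read_id == top], total_u)
t_count <- treated$count[treated$read_id == top]
t_rpm <- rpm(if (length(t_count)) t_count else 0L, total_t)
dep <- percent_depletion(u_rpm, t_rpm)
cat(sprintf("top X-cluster 22G species '%s': %.0f RPM untreated, %.0f RPM treated, %.1f%% depleted\n",
            top, u_rpm, t_rpm, dep))
write.table(data.frame(read_id = top, rpm_untreated = u_rpm,
                       rpm_treated = t_rpm, percent_depletion = dep),
            file.path(out, "top_22g_depletion.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# 2^-ddCt demonstration: a target small RNA measured against a miRNA
# normalizer in mutant vs wild type (synthetic Ct values, 3 replicates)
ct <- data.frame(replicate = 1:3,
                 ct_target_mut = c(24.1, 24.4, 24.2),
                 ct_ref_mut = c(18.0, 18.2, 18.1),
                 ct_target_wt = c(21.9, 22.0, 21.8),
                 ct_ref_wt = c(18.1, 18.0, 18.0))
s <- ddct_summary(ct$ct_target_mut, ct$ct_ref_mut,
                  ct$ct_target_wt, ct$ct_ref_wt)
cat(sprintf("ddCt demo: fold change %.3f (range %.3f-%.3f), i.e. ~%.0f%% depletion in the mutant\n",
            s$fold_change, s$range[1], s$range[2],
            100 * (1 - s$fold_change)))
write.table(cbind(ct, fold_change = s$fold_change),
            file.path(out, "ddct_demo.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
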