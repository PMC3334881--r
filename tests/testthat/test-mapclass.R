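ref <- build_reference(tiny_ref_config(), seed = 30)
contig <- as.character(ref$sequences[[1]])

# a genomic window that occurs exactly once in the reference
unique_window <- function(len, seed = 1) {
  set.seed(seed)
  repeat {
    s <- sample(nchar(contig) - len, 1L)
    w <- substr(contig, s, s + len - 1L)
    if (nrow(oracle_hits(w, ref)) == 1L) return(list(seq = w, start = s - 1L))
  }
}

test_that("unique genomic windows map once, on the correct strand, with empty tail", {
  w <- unique_window(22L)
  al <- map_read(w$seq, ref)
  expect_equal(nrow(al), 1L)
  expect_equal(al$start, w$start)
  expect_equal(al$strand, "+")
  expect_equal(al$templated, 22L)
  expect_equal(al$tail, "")
  al2 <- map_read(oracle_rc(w$seq), ref)
  expect_equal(nrow(al2), 1L)
  expect_equal(al2$start, w$start)
  expect_equal(al2$strand, "-")
})

test_that("the X-cluster motif maps to every embedded copy (string-search oracle)", {
  al <- map_read(ref$motif, ref)
  oh <- oracle_hits(ref$motif, ref)
  expect_equal(nrow(al), tiny_ref_config()$n_motif_copies)
  expect_equal(al$start, oh$start)
  expect_equal(al$strand, oh$strand)
})

test_that("mapping an empty reference or too-short read errors", {
  empty <- structure(list(sequences = Biostrings::DNAStringSet(),
                          features = ref$features[0, ]),
                     class = "ReferenceSet")
  expect_error(map_read("ACGTACGTACGTACGTACGT", empty), "empty reference")
  expect_error(map_read("ACGTACG", ref), "min_prefix")
})

test_that("map_library placements equal naive string-search placements on mixed reads", {
  reads <- random_read_mix(ref, 200L, seed = 31)
  al <- map_library(reads, ref)
  for (i in seq_len(nrow(reads))) {
    got <- al[al$read_id == reads$read_id[i],
              c("contig", "start", "strand", "templated", "tail")]
    rownames(got) <- NULL
    want <- oracle_resolve(reads$sequence[i], ref)
    expect_equal(got, want, info = reads$sequence[i])
  }
})

test_that("reads are classified by length, 5' nucleotide, and locus", {
  # 21-nt 5'U read sense to a piRNA locus
  f <- ref$features[ref$features$class == "pirna_locus", ][1, ]
  tx <- feature_seq(ref, f$feature_id)
  p <- which(strsplit(tx, "")[[1]] == "T")
  p <- p[p <= nchar(tx) - 20][1]
  pir <- substr(tx, p, p + 20)
  expect_equal(classify_read(map_read(pir, ref), ref$features, pir),
               "piRNA_21U")
  # 22-nt 5'G read antisense to a coding locus
  f <- ref$features[ref$features$class == "coding_locus", ][1, ]
  tx <- feature_seq(ref, f$feature_id)
  p <- which(strsplit(tx, "")[[1]] == "C")
  p <- p[p > 22][1]
  sir <- oracle_rc(substr(tx, p - 21, p))
  expect_equal(substr(sir, 1, 1), "G")
  expect_equal(classify_read(map_read(sir, ref), ref$features, sir),
               "siRNA_22G")
  # annotated mature miRNA, exact coordinates
  f <- ref$features[ref$features$class == "mirna_mature", ][1, ]
  mir <- feature_seq(ref, f$feature_id)
  expect_equal(classify_read(map_read(mir, ref), ref$features, mir), "miRNA")
  # unmappable read
  set.seed(32)
  repeat {
    rnd <- paste(sample(c("A", "C", "G", "T"), 22L, replace = TRUE),
                 collapse = "")
    if (nrow(oracle_hits(rnd, ref)) == 0L) break
  }
  expect_equal(classify_read(map_read(rnd, ref), ref$features, rnd),
               "unmapped")
})

test_that("class labels partition the library copies", {
  lib <- simulate_library(ref, tiny_lib_config(), seed = 33)
  aln <- map_library(lib, ref)
  asg <- classify_library(lib, aln, ref)
  expect_setequal(asg$read_id, lib$read_id)
  expect_true(all(table(asg$read_id) == 1L))
  cls <- stats::setNames(asg$class, asg$read_id)
  expect_equal(sum(tapply(lib$count, cls[lib$read_id], sum)), sum(lib$count))
})

test_that("classification recovers simulation truth for >= 99% of untrimmed copies", {
  no_trim <- lapply(stats::setNames(nm = c("piRNA_21U", "miRNA", "siRNA_22G",
                                           "siRNA_26G_ERGO1",
                                           "siRNA_26G_ALG34")),
                    function(cl) list(trim_rate = 0))
  lib <- simulate_library(ref, tiny_lib_config(classes = no_trim), seed = 34)
  aln <- map_library(lib, ref)
  asg <- classify_library(lib, aln, ref)
  m <- merge(lib[, c("read_id", "count", "true_class")], asg, by = "read_id")
  expect_gte(sum(m$count[m$class == m$true_class]) / sum(m$count), 0.99)
})

test_that("size x 5'-nt profiles tally copies by observed length and first nucleotide", {
  uniform <- data.frame(read_id = "r1", sequence = paste(rep("T", 21),
                                                         collapse = ""),
                        count = 50L)
  prof <- size_firstnt_profile(uniform)
  expect_equal(prof["21", "U"], 50)
  expect_equal(sum(prof), 50)
  expect_true(all(size_firstnt_profile(uniform[0, ]) == 0))
  lib <- simulate_library(ref, tiny_lib_config(), seed = 35)
  prof <- size_firstnt_profile(lib)
  len <- nchar(lib$sequence)
  for (L in 18:28) {
    expect_equal(unname(rowSums(prof)[as.character(L)]),
                 sum(lib$count[len == L]))
  }
  expect_equal(sum(prof), sum(lib$count[len >= 18 & len <= 28]))
})

test_that("coverage tracks sum copies over templated spans", {
  f <- ref$features[ref$features$class == "coding_locus", ][1, ]
  w <- substr(contig, f$start + 10 + 1, f$start + 31 + 1)  # feature pos 10..31
  read <- data.frame(read_id = "c1", sequence = w, count = 3L)
  aln <- map_library(read, ref)
  aln <- aln[aln$start == f$start + 10, , drop = FALSE]
  track <- coverage_track(aln, read, ref, f$feature_id)
  expect_equal(length(track), f$end - f$start)
  expect_true(all(track[11:32] == 3))
  expect_true(all(track[-(11:32)] == 0))
  expect_true(all(coverage_track(aln[0, ], read, ref, f$feature_id) == 0))
})

test_that("coverage equals a brute-force per-position recount on a simulated library", {
  lib <- simulate_library(ref, tiny_lib_config(), seed = 36)
  aln <- map_library(lib, ref)
  f <- ref$features[ref$features$class == "pirna_locus", ][1, ]
  track <- coverage_track(aln, lib, ref, f$feature_id)
  counts <- stats::setNames(lib$count, lib$read_id)
  brute <- numeric(f$end - f$start)
  for (pos in seq_along(brute)) {
    g <- f$start + pos - 1L  # 0-based genomic position
    covering <- aln[aln$contig == f$contig & aln$start <= g &
                      aln$start + aln$templated > g, ]
    brute[pos] <- sum(counts[covering$read_id])
  }
  expect_equal(track, brute)
})
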