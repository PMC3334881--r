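# Shared fixtures and independent base-R oracles for the test suite.
# The oracles deliberately avoid the Biostrings matching machinery used by
# the implementation: reverse complement via chartr + rev, placements via
# gregexpr fixed-string search.

tiny_ref_config <- function(...) {
  base <- list(n_pirna_loci = 1L, n_coding_loci = 2L,
               n_ergo1_loci = 1L, n_alg34_loci = 1L,
               n_mirna = 8L, n_motif_copies = 3L)
  do.call(reference_config, utils::modifyList(base, list(...)))
}

tiny_lib_config <- function(classes = NULL, ...) {
  base <- list(piRNA_21U = list(n_species = 15L, copy_mean = 50),
               miRNA = list(n_species = 8L, copy_mean = 80),
               siRNA_22G = list(n_species = 15L, copy_mean = 60),
               siRNA_26G_ERGO1 = list(n_species = 8L, copy_mean = 50),
               siRNA_26G_ALG34 = list(n_species = 8L, copy_mean = 50))
  if (!is.null(classes)) {
    for (nm in names(classes)) base[[nm]] <- utils::modifyList(base[[nm]],
                                                               classes[[nm]])
  }
  library_config(classes = base, ...)
}

oracle_rc <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# all exact occurrences of `pattern` on both strands of the reference
oracle_hits <- function(pattern, ref) {
  out <- NULL
  for (nm in names(ref$sequences)) {
    g <- as.character(ref$sequences[[nm]])
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pattern else oracle_rc(pattern)
      m <- gregexpr(p, g, fixed = TRUE)[[1]]
      if (m[1] > 0) {
        out <- rbind(out, data.frame(contig = nm, start = as.integer(m) - 1L,
                                     strand = strand,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(contig = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive (prefix, suffix) split: placements at the maximal templated
# prefix length k >= min_prefix
oracle_resolve <- function(seq, ref, min_prefix = 15L) {
  len <- nchar(seq)
  for (k in seq(len, min_prefix, by = -1L)) {
    h <- oracle_hits(substr(seq, 1L, k), ref)
    if (nrow(h)) {
      h$templated <- k
      h$tail <- substr(seq, k + 1L, len)
      return(h)
    }
  }
  data.frame(contig = character(0), start = integer(0), strand = character(0),
             templated = integer(0), tail = character(0),
             stringsAsFactors = FALSE)
}

# mixed read set for mapper/decomposition oracle checks: exact genomic
# windows, tailed, trimmed, substituted, reverse-strand, and fully random
random_read_mix <- function(ref, n, seed) {
  set.seed(seed)
  g <- as.character(ref$sequences[[1]])
  glen <- nchar(g)
  bases <- c("A", "C", "G", "T")
  reads <- character(n)
  for (i in seq_len(n)) {
    type <- sample(c("exact", "tail", "trim_tail", "sub", "random"), 1L,
                   prob = c(0.3, 0.25, 0.2, 0.15, 0.1))
    L <- sample(18:28, 1L)
    s <- sample(glen - L, 1L)
    win <- substr(g, s, s + L - 1L)
    if (sample(c(TRUE, FALSE), 1L)) win <- oracle_rc(win)
    reads[i] <- switch(type,
      exact = win,
      tail = paste0(win, paste(sample(bases, sample(1:3, 1L), replace = TRUE),
                               collapse = "")),
      trim_tail = paste0(substr(win, 1L, L - sample(1:2, 1L)),
                         paste(sample(bases, sample(1:3, 1L), replace = TRUE),
                               collapse = "")),
      sub = {
        ch <- strsplit(win, "")[[1]]
        j <- sample(L, 1L)
        ch[j] <- sample(setdiff(bases, ch[j]), 1L)
        paste(ch, collapse = "")
      },
      random = paste(sample(bases, L, replace = TRUE), collapse = ""))
  }
  data.frame(read_id = sprintf("mix_%04d", seq_len(n)), sequence = reads,
             count = 1L, stringsAsFactors = FALSE)
}

# independent per-window complementarity for scanner checks: guide position
# i faces window position L - i + 1; WC and G:U count as paired
oracle_window_compl <- function(guide, window) {
  g <- strsplit(guide, "")[[1]]
  w <- rev(strsplit(window, "")[[1]])
  paired <- 0L
  for (i in seq_along(g)) {
    pair <- paste0(g[i], w[i])
    if (pair %in% c("AT", "TA", "GC", "CG", "GT", "TG")) paired <- paired + 1L
  }
  paired / length(g)
}
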