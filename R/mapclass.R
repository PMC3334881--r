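# Exact-match read mapping and class assignment.
#
# Reads are placed on the reference by exact full-length matching on both
# strands; reads with no full-length placement are decomposed into the
# longest genome-templated 5' prefix plus an untemplated 3' tail (see
# resolve_3prime()). Placements are reported in deterministic
# (contig, start, strand) order.

.empty_alignments <- function() {
  data.frame(read_id = character(0), contig = character(0),
             start = integer(0), strand = character(0),
             templated = integer(0), tail = character(0),
             stringsAsFactors = FALSE)
}

# Batched longest-prefix placement. Every read's 5' seed of width
# min_prefix is matched on both strands with a PDict, then each seed hit
# is extended base by base to the maximal templated prefix length k at
# that placement. The placements reported for a read are exactly those
# achieving its maximal k (>= min_prefix); a placement whose genomic
# continuation equals the next read base would extend further, so tails
# are strictly untemplated by construction.
.map_batch <- function(seqs, ref, min_prefix) {
  w <- as.integer(min_prefix)
  lens <- nchar(seqs)
  if (any(lens < w)) {
    .stopf("read %d is shorter than min_prefix = %d", which(lens < w)[1], w)
  }
  n <- length(seqs)
  pre <- Biostrings::DNAStringSet(substr(seqs, 1L, w))
  pd_fwd <- Biostrings::PDict(pre)
  pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(pre))
  rchars <- strsplit(seqs, "", fixed = TRUE)
  cand <- rep(list(NULL), n)
  for (nm in names(ref$sequences)) {
    subj <- ref$sequences[[nm]]
    gchars <- .chars(as.character(subj))
    glen <- length(gchars)
    sf <- Biostrings::startIndex(Biostrings::matchPDict(pd_fwd, subj))
    sr <- Biostrings::startIndex(Biostrings::matchPDict(pd_rev, subj))
    for (i in seq_len(n)) {
      rc <- rchars[[i]]
      len <- lens[i]
      for (s1 in sf[[i]]) {
        s0 <- s1 - 1L  # 0-based templated start
        k <- w
        while (k < len && s0 + k < glen && gchars[s0 + k + 1L] == rc[k + 1L]) {
          k <- k + 1L
        }
        cand[[i]] <- rbind(cand[[i]],
                           data.frame(contig = nm, start = s0, strand = "+",
                                      templated = k))
      }
      for (s1 in sr[[i]]) {
        s0 <- s1 - 1L  # seed span [s0, s0 + w); read 5' end at its right edge
        k <- w
        while (k < len) {
          gpos <- s0 + w - k - 1L  # next genomic base leftwards, 0-based
          if (gpos < 0L || .comp(gchars[gpos + 1L]) != rc[k + 1L]) break
          k <- k + 1L
        }
        cand[[i]] <- rbind(cand[[i]],
                           data.frame(contig = nm, start = s0 + w - k,
                                      strand = "-", templated = k))
      }
    }
  }
  lapply(seq_len(n), function(i) {
    h <- cand[[i]]
    if (is.null(h)) {
      h <- .empty_alignments()
      h$read_id <- NULL
      return(h)
    }
    kmax <- max(h$templated)
    h <- h[h$templated == kmax, , drop = FALSE]
    h$tail <- substr(seqs[i], kmax + 1L, lens[i])
    h <- h[order(h$contig, h$start, h$strand), , drop = FALSE]
    rownames(h) <- NULL
    h
  })
}

#' Map one read to the reference by exact matching
#'
#' Full-length exact matches on either strand are reported; when none
#' exists the read is decomposed by [resolve_3prime()] into its longest
#' templated 5' prefix and a 3' tail. All equally long placements are
#' returned, ordered by (contig, start, strand).
#'
#' @param read One-row library data.frame, or a character sequence.
#' @param ref A `ReferenceSet`.
#' @param min_prefix Minimum templated prefix length (nt).
#' @return Alignment data.frame with columns `read_id`, `contig`, `start`
#'   (0-based start of the templated span), `strand`, `templated` (prefix
#'   length), `tail` (untemplated 3' suffix, possibly empty); zero rows if
#'   the read cannot be placed.
#' @export
map_read <- function(read, ref, min_prefix = 15L) {
  if (length(ref$sequences) == 0L) .stopf("empty reference")
  if (is.character(read)) read <- data.frame(read_id = "read", sequence = read)
  if (nchar(read$sequence) < min_prefix) {
    .stopf("read '%s' is shorter than min_prefix = %d", read$read_id, min_prefix)
  }
  hits <- .map_batch(read$sequence, ref, min_prefix)[[1L]]
  if (!nrow(hits)) return(.empty_alignments())
  cbind(read_id = read$read_id, hits, stringsAsFactors = FALSE)
}

#' Map every read of a library
#'
#' @param reads Library data.frame.
#' @param ref A `ReferenceSet`.
#' @param min_prefix Minimum templated prefix length (nt).
#' @return Alignment data.frame (one row per placement) as in
#'   [map_read()]; unplaced reads contribute no rows.
#' @export
map_library <- function(reads, ref, min_prefix = 15L) {
  if (length(ref$sequences) == 0L) .stopf("empty reference")
  if (nrow(reads) == 0L) return(.empty_alignments())
  hits <- .map_batch(reads$sequence, ref, min_prefix)
  out <- lapply(seq_len(nrow(reads)), function(i) {
    h <- hits[[i]]
    if (!nrow(h)) return(NULL)
    cbind(read_id = reads$read_id[i], h, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- .empty_alignments()
  rownames(res) <- NULL
  res
}

# features overlapping a templated span (>= 1 nt overlap), same contig
.overlapping_features <- function(features, contig, start, end) {
  features[features$contig == contig &
             features$start < end & start < features$end, , drop = FALSE]
}

.TRANSCRIPT_CLASSES <- c("coding_locus", "xcluster_locus", "trigger_locus",
                         "sirna26g_ergo1_locus", "sirna26g_alg34_locus")

#' Assign each read of a library to a small RNA class
#'
#' Classes are assigned by length, 5' nucleotide, and annotation overlap,
#' with rules applied in priority order: (1) exact coordinate match to an
#' annotated mature miRNA; (2) 21-nt 5'U reads sense to a piRNA locus;
#' (3) 26-nt 5'G reads antisense to an ERGO-1 or ALG-3/4 class 26G locus;
#' (4) 22-nt 5'G reads antisense to any transcript locus; otherwise
#' `other`, or `unmapped` for reads without a placement. Lengths are
#' evaluated on the genome-templated prefix, so 3' tails do not change a
#' read's class. The labels partition the library.
#'
#' @param reads Library data.frame.
#' @param alignments Alignments from [map_library()].
#' @param ref A `ReferenceSet`.
#' @return data.frame with columns `read_id`, `class` where class is one
#'   of `miRNA`, `piRNA_21U`, `siRNA_22G`, `siRNA_26G_ERGO1`,
#'   `siRNA_26G_ALG34`, `other`, `unmapped`.
#' @export
classify_library <- function(reads, alignments, ref) {
  features <- ref$features
  cls <- vapply(seq_len(nrow(reads)), function(i) {
    al <- alignments[alignments$read_id == reads$read_id[i], , drop = FALSE]
    .classify_one(reads$sequence[i], al, features)
  }, character(1))
  data.frame(read_id = reads$read_id, class = cls, stringsAsFactors = FALSE)
}

#' Assign a single read to a small RNA class
#'
#' @param alignments Placements of the read (from [map_read()]).
#' @param features Feature table of a `ReferenceSet`.
#' @param read One-row library data.frame or character sequence.
#' @return Single class label (see [classify_library()]).
#' @export
classify_read <- function(alignments, features, read) {
  seq <- if (is.character(read)) read else read$sequence
  .classify_one(seq, alignments, features)
}

.classify_one <- function(seq, al, features) {
  if (nrow(al) == 0L) return("unmapped")
  first <- substr(seq, 1L, 1L)
  # collect per-placement overlapping features once
  ov <- lapply(seq_len(nrow(al)), function(j) {
    .overlapping_features(features, al$contig[j], al$start[j],
                          al$start[j] + al$templated[j])
  })
  for (j in seq_len(nrow(al))) {
    f <- ov[[j]]
    mi <- f[f$class == "mirna_mature" &
              f$start == al$start[j] &
              (f$end - f$start) == al$templated[j] &
              f$strand == al$strand[j], , drop = FALSE]
    if (nrow(mi)) return("miRNA")
  }
  for (j in seq_len(nrow(al))) {
    if (al$templated[j] == 21L && first == "T") {
      f <- ov[[j]]
      if (any(f$class == "pirna_locus" & f$strand == al$strand[j])) {
        return("piRNA_21U")
      }
    }
  }
  for (j in seq_len(nrow(al))) {
    if (al$templated[j] == 26L && first == "G") {
      f <- ov[[j]]
      if (any(f$class == "sirna26g_ergo1_locus" & f$strand != al$strand[j])) {
        return("siRNA_26G_ERGO1")
      }
      if (any(f$class == "sirna26g_alg34_locus" & f$strand != al$strand[j])) {
        return("siRNA_26G_ALG34")
      }
    }
  }
  for (j in seq_len(nrow(al))) {
    if (al$templated[j] == 22L && first == "G") {
      f <- ov[[j]]
      if (any(f$class %in% .TRANSCRIPT_CLASSES & f$strand != al$strand[j])) {
        return("siRNA_22G")
      }
    }
  }
  "other"
}

#' Size x 5'-nucleotide profile of a library
#'
#' @param reads Library data.frame.
#' @param lengths Integer read lengths to tabulate (rows). Reads outside
#'   this window are not counted.
#' @param read_ids Optional subset of read ids to profile (e.g. reads
#'   overlapping one feature).
#' @return Numeric matrix of summed copy counts, rows = read length,
#'   columns = 5' nucleotide (A, C, G, U).
#' @export
size_firstnt_profile <- function(reads, lengths = 18:28, read_ids = NULL) {
  if (!is.null(read_ids)) {
    reads <- reads[reads$read_id %in% read_ids, , drop = FALSE]
  }
  m <- matrix(0, nrow = length(lengths), ncol = 4L,
              dimnames = list(as.character(lengths), c("A", "C", "G", "U")))
  if (nrow(reads) == 0L) return(m)
  len <- nchar(reads$sequence)
  nt <- chartr("T", "U", substr(reads$sequence, 1L, 1L))
  keep <- len %in% lengths
  for (i in which(keep)) {
    m[as.character(len[i]), nt[i]] <- m[as.character(len[i]), nt[i]] +
      reads$count[i]
  }
  m
}

#' Per-position copy coverage of a feature
#'
#' Position `i` (0-based, feature-relative) totals the copies of reads
#' whose templated span covers that genomic position.
#'
#' @param alignments Alignments from [map_library()].
#' @param reads Library data.frame (copy counts).
#' @param ref A `ReferenceSet`.
#' @param feature_id Feature to profile.
#' @return Numeric vector of length `end - start` of the feature.
#' @export
coverage_track <- function(alignments, reads, ref, feature_id) {
  f <- ref$features[ref$features$feature_id == feature_id, ]
  if (nrow(f) != 1L) .stopf("unknown feature_id '%s'", feature_id)
  track <- numeric(f$end - f$start)
  if (nrow(alignments) == 0L) return(track)
  counts <- stats::setNames(reads$count, reads$read_id)
  al <- alignments[alignments$contig == f$contig, , drop = FALSE]
  for (j in seq_len(nrow(al))) {
    s <- max(al$start[j], f$start)
    e <- min(al$start[j] + al$templated[j], f$end)
    if (s < e) {
      idx <- (s - f$start + 1L):(e - f$start)
      track[idx] <- track[idx] + counts[[al$read_id[j]]]
    }
  }
  track
}

#' Per-feature copy counts
#'
#' A read's copy count is attributed once per feature it overlaps
#' (regardless of how many placements fall inside that feature), avoiding
#' double counting of multimapping reads within a locus.
#'
#' @param reads Library data.frame.
#' @param alignments Alignments from [map_library()].
#' @param ref A `ReferenceSet`.
#' @return data.frame with `feature_id`, `class`, `count`.
#' @export
feature_counts <- function(reads, alignments, ref) {
  features <- ref$features
  counts <- stats::setNames(reads$count, reads$read_id)
  total <- numeric(nrow(features))
  for (k in seq_len(nrow(features))) {
    f <- features[k, ]
    al <- alignments[alignments$contig == f$contig &
                       alignments$start < f$end &
                       alignments$start + alignments$templated > f$start, ,
                     drop = FALSE]
    ids <- unique(al$read_id)
    total[k] <- sum(counts[ids])
  }
  data.frame(feature_id = features$feature_id, class = features$class,
             count = total, stringsAsFactors = FALSE)
}
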