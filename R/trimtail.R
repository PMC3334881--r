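# 3' end decomposition: templated prefix, trim, untemplated tail.

# canonical mature lengths by locus class, used to express trimming
# relative to the expected species length when no per-species mature
# annotation exists (miRNAs carry their own mature_length annotation)
.DEFAULT_CLASS_LENGTHS <- c(pirna_locus = 21L,
                            sirna26g_ergo1_locus = 26L,
                            sirna26g_alg34_locus = 26L,
                            xcluster_locus = 22L,
                            coding_locus = 22L,
                            trigger_locus = 26L)

# anchor each placement to the overlapping feature with the largest
# overlap (ties broken by feature table order) and derive the annotated
# length at that locus
.annotate_anchor <- function(calls, ref, class_lengths = .DEFAULT_CLASS_LENGTHS) {
  features <- ref$features
  calls$anchor_id <- NA_character_
  calls$annotated_length <- NA_integer_
  for (j in seq_len(nrow(calls))) {
    s <- calls$start[j]
    e <- s + calls$templated[j]
    f <- .overlapping_features(features, calls$contig[j], s, e)
    if (nrow(f) == 0L) next
    ovl <- pmin(f$end, e) - pmax(f$start, s)
    f <- f[which.max(ovl), ]
    calls$anchor_id[j] <- f$feature_id
    ann <- if (!is.na(f$mature_length)) {
      f$mature_length
    } else if (f$class %in% names(class_lengths)) {
      class_lengths[[f$class]]
    } else {
      NA_integer_
    }
    calls$annotated_length[j] <- ann
  }
  calls$trim <- trim_length(calls$templated, calls$annotated_length)
  calls
}

#' Decompose read 3' ends into templated prefix and untemplated tail
#'
#' For each read, all placements with the maximal templated 5' prefix
#' length `k >= min_prefix` are found; the tail is the remaining 3'
#' suffix. Because `k` is maximal, the first tail nucleotide is never
#' templated at the placement (a placement whose next genomic base equals
#' the first tail base would have matched a longer prefix). Each call is
#' anchored to the feature with the largest overlap, and the trim length
#' is expressed relative to the annotated mature length at that locus
#' (mature miRNA annotation, or the canonical class length for small RNA
#' loci), floored at 0; `NA` when no annotation applies.
#'
#' @param reads Library data.frame (or a character vector of sequences).
#' @param ref A `ReferenceSet`.
#' @param min_prefix Minimum templated prefix length in nt (default 15).
#' @param class_lengths Named integer vector mapping locus classes to
#'   canonical mature lengths.
#' @return data.frame of tail calls: `read_id`, `contig`, `start`,
#'   `strand`, `templated`, `tail`, `anchor_id`, `annotated_length`,
#'   `trim`. Unplaced reads contribute no rows; their number is recorded
#'   in attribute `unplaced`.
#' @export
resolve_3prime <- function(reads, ref, min_prefix = 15L,
                           class_lengths = .DEFAULT_CLASS_LENGTHS) {
  if (min_prefix < 1L) .stopf("min_prefix must be >= 1")
  if (is.character(reads)) {
    reads <- data.frame(read_id = paste0("read_", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  }
  calls <- map_library(reads, ref, min_prefix = min_prefix)
  placed <- unique(calls$read_id)
  calls <- .annotate_anchor(calls, ref, class_lengths)
  attr(calls, "unplaced") <- setdiff(reads$read_id, placed)
  calls
}

#' Trim length relative to an annotated mature length
#'
#' @param templated Templated prefix length(s) in nt.
#' @param annotated_length Annotated mature length(s); `NA` when unknown.
#' @return `max(annotated_length - templated, 0)`, or `NA` when the
#'   annotation is unknown.
#' @export
trim_length <- function(templated, annotated_length) {
  ifelse(is.na(annotated_length), NA_integer_,
         pmax(as.integer(annotated_length) - as.integer(templated), 0L))
}

# one row per read: its tail/trim at the first placement (tails and
# templated lengths are identical across the equally-long placements)
.read_level_calls <- function(calls) {
  calls[!duplicated(calls$read_id), , drop = FALSE]
}

#' Per-class tailed proportion
#'
#' The proportion of placed copies carrying at least one 3' untemplated
#' nucleotide, relative to all placed copies of the class (tailed plus
#' untailed), per class.
#'
#' @param calls Tail calls from [resolve_3prime()].
#' @param reads Library data.frame (copy counts).
#' @param assignments data.frame `read_id`, `class` (e.g. from
#'   [classify_library()], or simulation truth).
#' @param classes Optional class labels to report (default: all observed).
#' @return data.frame with `class`, `placed_copies`, `tailed_copies`,
#'   `tailed_proportion`.
#' @export
tailed_proportion <- function(calls, reads, assignments, classes = NULL) {
  rc <- .read_level_calls(calls)
  df <- merge(rc[, c("read_id", "tail")], assignments, by = "read_id")
  df <- merge(df, reads[, c("read_id", "count")], by = "read_id")
  if (is.null(classes)) classes <- sort(unique(df$class))
  out <- lapply(classes, function(cl) {
    d <- df[df$class == cl, , drop = FALSE]
    placed <- sum(d$count)
    tailed <- sum(d$count[nchar(d$tail) > 0L])
    data.frame(class = cl, placed_copies = placed, tailed_copies = tailed,
               tailed_proportion = if (placed > 0) tailed / placed else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-class trimmed proportion
#'
#' Analogous to [tailed_proportion()], counting copies whose templated
#' prefix is shorter than the annotated mature length at the anchor locus;
#' copies without an applicable annotation are excluded.
#'
#' @inheritParams tailed_proportion
#' @return data.frame with `class`, `annotated_copies`, `trimmed_copies`,
#'   `trimmed_proportion`.
#' @export
trimmed_proportion <- function(calls, reads, assignments, classes = NULL) {
  rc <- .read_level_calls(calls)
  df <- merge(rc[, c("read_id", "trim")], assignments, by = "read_id")
  df <- merge(df, reads[, c("read_id", "count")], by = "read_id")
  df <- df[!is.na(df$trim), , drop = FALSE]
  if (is.null(classes)) classes <- sort(unique(df$class))
  out <- lapply(classes, function(cl) {
    d <- df[df$class == cl, , drop = FALSE]
    n <- sum(d$count)
    tr <- sum(d$count[d$trim > 0L])
    data.frame(class = cl, annotated_copies = n, trimmed_copies = tr,
               trimmed_proportion = if (n > 0) tr / n else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Composition of 3' untemplated tails
#'
#' Reported per tail-initiating nucleotide (U, A, C, G) as the fraction of
#' tailed copies, an exploratory summary of e.g. uridylation.
#'
#' @param calls Tail calls from [resolve_3prime()].
#' @param reads Library data.frame (copy counts).
#' @return data.frame with `first_tail_nt`, `copies`, `fraction`.
#' @export
tail_composition <- function(calls, reads) {
  rc <- .read_level_calls(calls)
  rc <- merge(rc[, c("read_id", "tail")], reads[, c("read_id", "count")],
              by = "read_id")
  rc <- rc[nchar(rc$tail) > 0L, , drop = FALSE]
  nts <- c("U", "A", "C", "G")
  first <- chartr("T", "U", substr(rc$tail, 1L, 1L))
  total <- sum(rc$count)
  out <- lapply(nts, function(nt) {
    n <- sum(rc$count[first == nt])
    data.frame(first_tail_nt = nt, copies = n,
               fraction = if (total > 0) n / total else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
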