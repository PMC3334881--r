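#' Configuration for simulating a collapsed small RNA library
#'
#' Per-class settings follow the classic C. elegans small RNA classes:
#' piRNAs (21 nt, 5' U, sense to piRNA loci, methylated), 22G siRNAs
#' (22 nt, 5' G, antisense to transcript loci, unmethylated), ERGO-1 class
#' 26G siRNAs (26 nt, 5' G, antisense, methylated), ALG-3/4 class 26G
#' siRNAs (26 nt, 5' G, antisense, unmethylated), and miRNAs (annotated
#' mature species, unmethylated). Trimming (3'->5' shortening) and tailing
#' (3' untemplated additions) are drawn per copy, so a species can split
#' into plain/trimmed/tailed/trimmed+tailed sub-species; tailing rates
#' default to low for miRNA/piRNA and high for siRNA classes.
#'
#' @param classes Optional named list of per-class overrides. Class names
#'   are `piRNA_21U`, `miRNA`, `siRNA_22G`, `siRNA_26G_ERGO1`,
#'   `siRNA_26G_ALG34`; per-class fields are `n_species`, `length`,
#'   `first_nt`, `locus_classes`, `orientation` ("sense"/"antisense"),
#'   `meth_prob`, `copy_mean`, `tail_rate`, `trim_rate`.
#' @param p_meth,p_unmeth Per-copy beta-elimination survival probabilities
#'   for methylated and unmethylated species (see
#'   [apply_beta_elimination()]).
#' @param size_range Size-selection window (nt) applied to the simulated
#'   output, mirroring gel size selection of 18-28 nt RNAs.
#' @param copy_dispersion Negative-binomial size parameter for species
#'   copy counts.
#' @param tail_length_probs Probabilities of tail lengths 1, 2, ... nt.
#' @param trim_length_probs Probabilities of trim lengths 1, 2, ... nt.
#' @return A list of simulation parameters for [simulate_library()].
#' @export
library_config <- function(classes = NULL,
                           p_meth = 1.0, p_unmeth = 0.1,
                           size_range = c(18L, 28L),
                           copy_dispersion = 2,
                           tail_length_probs = c(0.6, 0.3, 0.1),
                           trim_length_probs = c(0.7, 0.3)) {
  class_defaults <- list(
    piRNA_21U = list(n_species = 60L, length = 21L, first_nt = "T",
                     locus_classes = "pirna_locus", orientation = "sense",
                     meth_prob = 1.0, copy_mean = 800,
                     tail_rate = 0.05, trim_rate = 0.02),
    miRNA = list(n_species = 25L, length = NA_integer_, first_nt = NA_character_,
                 locus_classes = "mirna_mature", orientation = "sense",
                 meth_prob = 0.0, copy_mean = 2000,
                 tail_rate = 0.05, trim_rate = 0.02),
    siRNA_22G = list(n_species = 50L, length = 22L, first_nt = "G",
                     locus_classes = c("coding_locus", "xcluster_locus"),
                     orientation = "antisense",
                     meth_prob = 0.0, copy_mean = 1000,
                     tail_rate = 0.15, trim_rate = 0.10),
    siRNA_26G_ERGO1 = list(n_species = 25L, length = 26L, first_nt = "G",
                           locus_classes = "sirna26g_ergo1_locus",
                           orientation = "antisense",
                           meth_prob = 1.0, copy_mean = 800,
                           tail_rate = 0.30, trim_rate = 0.15),
    siRNA_26G_ALG34 = list(n_species = 25L, length = 26L, first_nt = "G",
                           locus_classes = "sirna26g_alg34_locus",
                           orientation = "antisense",
                           meth_prob = 0.0, copy_mean = 800,
                           tail_rate = 0.30, trim_rate = 0.15))
  if (!is.null(classes)) {
    for (nm in names(classes)) {
      if (!nm %in% names(class_defaults)) .stopf("unknown class '%s'", nm)
      class_defaults[[nm]] <- utils::modifyList(class_defaults[[nm]],
                                                classes[[nm]])
    }
  }
  cfg <- list(classes = class_defaults, p_meth = p_meth, p_unmeth = p_unmeth,
              size_range = as.integer(size_range),
              copy_dispersion = copy_dispersion,
              tail_length_probs = tail_length_probs,
              trim_length_probs = trim_length_probs)
  probs <- c(p_meth, p_unmeth,
             vapply(cfg$classes, function(x)
               c(x$meth_prob, x$tail_rate, x$trim_rate), numeric(3)))
  if (any(probs < 0 | probs > 1)) .stopf("probabilities must lie in [0, 1]")
  cfg
}

# genomic placement of a read drawn at transcript position p (1-based) of
# feature f. Returns the 0-based start of the untrimmed templated span and
# the read strand.
.placement <- function(f, p, L, orientation) {
  if (f$strand == "+") {
    gstart <- f$start + (p - 1L)
    strand <- if (orientation == "sense") "+" else "-"
  } else {
    gstart <- f$end - (p - 1L) - L
    strand <- if (orientation == "sense") "-" else "+"
  }
  list(gstart = gstart, strand = strand)
}

# templated read sequence for a span after trimming t nt off the read 3' end
.templated_seq <- function(contig, gstart, L, t, strand) {
  if (strand == "+") {
    substr(contig, gstart + 1L, gstart + L - t)
  } else {
    .revcomp(substr(contig, gstart + t + 1L, gstart + L))
  }
}

# genomic base that would extend the (trimmed) read at its 3' end, in read
# orientation; NA at a contig edge
.continuation_base <- function(contig, gstart, L, t, strand) {
  if (strand == "+") {
    pos <- gstart + L - t          # 0-based
    if (pos >= nchar(contig)) return(NA_character_)
    substr(contig, pos + 1L, pos + 1L)
  } else {
    pos <- gstart + t - 1L
    if (pos < 0L) return(NA_character_)
    .comp(substr(contig, pos + 1L, pos + 1L))
  }
}

.draw_tail <- function(contig, gstart, L, t, strand, tail_length_probs) {
  tl <- sample(seq_along(tail_length_probs), 1L, prob = tail_length_probs)
  cont <- .continuation_base(contig, gstart, L, t, strand)
  first <- sample(setdiff(.BASES, cont), 1L)
  paste(c(first, sample(.BASES, tl - 1L, replace = TRUE)), collapse = "")
}

#' Simulate a collapsed small RNA library from a synthetic reference
#'
#' Each read species is drawn from a distinct position of a locus of its
#' class, on the strand the class dictates (siRNAs antisense to the locus
#' transcript, piRNAs/miRNAs sense), with the class length and 5'
#' nucleotide. Copy counts are negative-binomial; per copy, trimming
#' shortens the templated 3' end and tailing appends nucleotides whose
#' first base is untemplated at the read's source placement. Ground-truth
#' columns record class, methylation, trim, tail, and the templated source
#' placement.
#'
#' @param ref A `ReferenceSet` from [build_reference()].
#' @param config A list from [library_config()].
#' @param seed Integer random seed.
#' @return A data.frame with one row per read species: `read_id`,
#'   `sequence`, `count`, and truth columns `true_class`, `methylated`,
#'   `true_trim`, `true_tail`, `true_contig`, `true_start` (0-based start
#'   of the templated span), `true_strand`. The number of species removed
#'   by the size-selection window is recorded in attribute
#'   `size_filtered`.
#' @export
simulate_library <- function(ref, config = library_config(), seed = 1L) {
  set.seed(seed)
  contig_chr <- as.character(ref$sequences)
  rows <- list()
  for (cl in names(config$classes)) {
    cls_spec <- config$classes[[cl]]
    if (cls_spec$n_species < 1L) next
    feats <- ref$features[ref$features$class %in% cls_spec$locus_classes, ,
                          drop = FALSE]
    if (nrow(feats) == 0L) {
      .stopf("no reference locus of class {%s} available for small RNA class '%s'",
             paste(cls_spec$locus_classes, collapse = ","), cl)
    }
    # enumerate candidate (feature, transcript position) starts satisfying
    # the class 5'-nt rule, then sample species without replacement
    cand <- list()
    for (j in seq_len(nrow(feats))) {
      f <- feats[j, ]
      tx <- feature_seq(ref, f$feature_id)
      if (cl == "miRNA") {
        cand[[j]] <- data.frame(j = j, p = 1L, L = f$mature_length)
        next
      }
      L <- cls_spec$length
      if (nchar(tx) < L) next
      txc <- .chars(tx)
      pmax_ <- nchar(tx) - L + 1L
      ok <- if (cls_spec$orientation == "sense") {
        which(txc[seq_len(pmax_)] == cls_spec$first_nt)
      } else {
        which(txc[seq_len(pmax_) + L - 1L] == .comp(cls_spec$first_nt))
      }
      if (length(ok)) cand[[j]] <- data.frame(j = j, p = ok, L = L)
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand) || nrow(cand) < cls_spec$n_species) {
      .stopf("class '%s': only %d candidate start positions for %d species",
             cl, if (is.null(cand)) 0L else nrow(cand), cls_spec$n_species)
    }
    cand <- cand[sample(nrow(cand), cls_spec$n_species), , drop = FALSE]

    for (i in seq_len(cls_spec$n_species)) {
      f <- feats[cand$j[i], ]
      p <- cand$p[i]
      L <- cand$L[i]
      pl <- .placement(f, p, L, cls_spec$orientation)
      contig <- contig_chr[[f$contig]]
      copies <- 1L + stats::rnbinom(1L, size = config$copy_dispersion,
                                    mu = max(cls_spec$copy_mean - 1, 0))
      ta <- cls_spec$tail_rate
      tr <- cls_spec$trim_rate
      split <- stats::rmultinom(1L, copies,
                                c((1 - tr) * (1 - ta), tr * (1 - ta),
                                  (1 - tr) * ta, tr * ta))[, 1L]
      names(split) <- c("plain", "trim", "tail", "trimtail")
      meth <- stats::runif(1L) < cls_spec$meth_prob
      base_id <- sprintf("%s_%04d", cl, i)
      for (v in names(split)) {
        if (split[[v]] == 0L) next
        t <- if (v %in% c("trim", "trimtail")) {
          sample(seq_along(config$trim_length_probs), 1L,
                 prob = config$trim_length_probs)
        } else 0L
        templ <- .templated_seq(contig, pl$gstart, L, t, pl$strand)
        tail <- if (v %in% c("tail", "trimtail")) {
          .draw_tail(contig, pl$gstart, L, t, pl$strand,
                     config$tail_length_probs)
        } else ""
        tstart <- if (pl$strand == "+") pl$gstart else pl$gstart + t
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = if (v == "plain") base_id else paste(base_id, v, sep = "."),
          sequence = paste0(templ, tail),
          count = split[[v]],
          true_class = cl,
          methylated = meth,
          true_trim = t,
          true_tail = tail,
          true_contig = f$contig,
          true_start = tstart,
          true_strand = pl$strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  reads <- do.call(rbind, rows)
  if (is.null(reads)) {
    reads <- data.frame(read_id = character(0), sequence = character(0),
                        count = integer(0), true_class = character(0),
                        methylated = logical(0), true_trim = integer(0),
                        true_tail = character(0), true_contig = character(0),
                        true_start = integer(0), true_strand = character(0))
  }
  len <- nchar(reads$sequence)
  keep <- len >= config$size_range[1] & len <= config$size_range[2]
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "size_filtered") <- sum(!keep)
  attr(out, "seed") <- seed
  out
}

#' Simulate beta-elimination of a small RNA library
#'
#' Periodate oxidation/beta-elimination removes the 3'-terminal nucleoside
#' of RNAs with a free 2',3'-diol and leaves an end incompatible with
#' adapter ligation, so unmethylated species drop out of the sequencing
#' library while 3' 2'-O-methylated species survive. The treatment is
#' modelled at ligation: each copy survives a Bernoulli draw with
#' probability `p_meth` (methylated species) or `p_unmeth` (unmethylated);
#' surviving copies are kept intact and species with no surviving copies
#' are removed. The input library is not modified.
#'
#' @param reads Library data.frame with a logical `methylated` column
#'   (e.g. from [simulate_library()]).
#' @param p_meth,p_unmeth Per-copy survival probabilities; methylation must
#'   protect, i.e. `p_unmeth <= p_meth`.
#' @param seed Integer random seed.
#' @return The treated library: same columns, updated `count`, zero-count
#'   species dropped.
#' @export
apply_beta_elimination <- function(reads, p_meth = 1.0, p_unmeth = 0.1,
                                   seed = 1L) {
  if (any(c(p_meth, p_unmeth) < 0) || any(c(p_meth, p_unmeth) > 1)) {
    .stopf("survival probabilities must lie in [0, 1]")
  }
  if (p_unmeth > p_meth) {
    .stopf("p_unmeth (%g) > p_meth (%g): methylation must protect against beta-elimination",
           p_unmeth, p_meth)
  }
  if (is.null(reads$methylated) || anyNA(reads$methylated)) {
    .stopf("beta-elimination requires a methylation status for every species")
  }
  set.seed(seed)
  surv <- stats::rbinom(nrow(reads), reads$count,
                        ifelse(reads$methylated, p_meth, p_unmeth))
  out <- reads
  out$count <- surv
  out <- out[out$count > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a collapsed small RNA library as FASTA
#'
#' Headers use the dialect `>{read_id} count={n}`.
#'
#' @param reads Library data.frame with `read_id`, `sequence`, `count`.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_library <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- sprintf("%s count=%d", reads$read_id, reads$count)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a collapsed small RNA library (FASTA or FASTQ)
#'
#' FASTA headers are expected in the `>{id} count={n}` dialect; records
#' lacking a `count=` field default to count 1 with a warning. FASTQ input
#' is accepted with per-record count 1. RNA alphabet (U) is normalized to
#' DNA; records containing characters outside ACGT (e.g. N) are rejected
#' with a warning giving the number of records dropped.
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"fasta"`, or `"fastq"`.
#' @return A library data.frame with `read_id`, `sequence`, `count` and
#'   `NA` truth columns.
#' @export
read_library <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE)) {
      "fastq"
    } else {
      "fasta"
    }
  }
  seqs <- Biostrings::readBStringSet(path, format = format)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  counts <- rep(NA_integer_, length(headers))
  m <- regmatches(headers, regexpr("count=[0-9]+", headers))
  has_count <- grepl("count=[0-9]+", headers)
  counts[has_count] <- as.integer(sub("count=", "", m))
  if (format == "fastq") {
    counts[] <- 1L
  } else if (any(!has_count)) {
    warning(sprintf("%d record(s) lack a count= field; defaulting to count 1",
                    sum(!has_count)), call. = FALSE)
    counts[!has_count] <- 1L
  }
  if (any(counts < 1L)) {
    .stopf("record %d: count must be a positive integer",
           which(counts < 1L)[1])
  }
  sequence <- .normalize_seq(as.character(seqs))
  ok <- .is_dna(sequence)
  if (any(!ok)) {
    warning(sprintf("rejected %d record(s) with characters outside ACGTU",
                    sum(!ok)), call. = FALSE)
  }
  out <- data.frame(read_id = ids[ok], sequence = unname(sequence[ok]),
                    count = counts[ok],
                    true_class = NA_character_, methylated = NA,
                    true_trim = NA_integer_, true_tail = NA_character_,
                    true_contig = NA_character_, true_start = NA_integer_,
                    true_strand = NA_character_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
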