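#' Specification for a synthetic small RNA reference
#'
#' Describes the toy genome used to exercise the full analysis: a single
#' contig carrying piRNA loci, coding loci, 26G siRNA source loci of the
#' ERGO-1 and ALG-3/4 classes, annotated mature miRNAs, an X-cluster-like
#' locus whose transcript contains `n_motif_copies` embedded copies of one
#' 26-nt motif (the repeated source of an abundant 22G siRNA), and a
#' separate trigger locus whose transcript carries the source site of a
#' 26-nt guide that is partially complementary to that motif
#' (Watson-Crick-paired at guide positions 1-10 and 14-19, mispaired at
#' 11-13, with two G:U wobbles among otherwise mismatched 3' positions,
#' i.e. 18 of 26 positions paired).
#'
#' @param contig_name Name of the simulated contig.
#' @param n_pirna_loci,n_coding_loci,n_ergo1_loci,n_alg34_loci Number of
#'   loci of each annotation class.
#' @param pirna_locus_length,coding_locus_length,sirna_locus_length,
#'   trigger_locus_length Locus lengths in nt.
#' @param n_mirna Number of annotated mature miRNA species.
#' @param mirna_mature_length Mature miRNA length in nt.
#' @param n_motif_copies Copies of the 26-nt motif embedded in the
#'   X-cluster transcript (must be >= 1 when the X-cluster is included).
#' @param motif_length Motif length in nt (>= 26; positional design of the
#'   trigger guide assumes at least 26 positions).
#' @param include_xcluster,include_trigger Include the X-cluster and
#'   trigger loci.
#' @param gap_range Integer range of random intergenic gap lengths.
#' @param spacer_range Integer range of random spacer lengths between
#'   motif copies inside the X-cluster transcript.
#' @param contig_length Optional hard contig length; an error is raised if
#'   the requested loci do not fit, and the contig is padded with random
#'   sequence to this length otherwise.
#' @param pad_to Optional minimum contig length; the contig is padded with
#'   random sequence up to this size (useful for mapper stress tests).
#' @return A list of reference parameters for [build_reference()].
#' @export
reference_config <- function(contig_name = "chrSim",
                             n_pirna_loci = 2L, pirna_locus_length = 400L,
                             n_coding_loci = 3L, coding_locus_length = 600L,
                             n_ergo1_loci = 2L, n_alg34_loci = 2L,
                             sirna_locus_length = 400L,
                             n_mirna = 25L, mirna_mature_length = 22L,
                             n_motif_copies = 7L, motif_length = 26L,
                             include_xcluster = TRUE, include_trigger = TRUE,
                             trigger_locus_length = 300L,
                             gap_range = c(50L, 150L),
                             spacer_range = c(30L, 80L),
                             contig_length = NULL,
                             pad_to = NULL) {
  cfg <- list(contig_name = contig_name,
              n_pirna_loci = n_pirna_loci,
              pirna_locus_length = pirna_locus_length,
              n_coding_loci = n_coding_loci,
              coding_locus_length = coding_locus_length,
              n_ergo1_loci = n_ergo1_loci,
              n_alg34_loci = n_alg34_loci,
              sirna_locus_length = sirna_locus_length,
              n_mirna = n_mirna,
              mirna_mature_length = mirna_mature_length,
              n_motif_copies = n_motif_copies,
              motif_length = motif_length,
              include_xcluster = include_xcluster,
              include_trigger = include_trigger,
              trigger_locus_length = trigger_locus_length,
              gap_range = gap_range,
              spacer_range = spacer_range,
              contig_length = contig_length,
              pad_to = pad_to)
  if (cfg$include_xcluster && cfg$n_motif_copies < 1L) {
    .stopf("n_motif_copies must be >= 1 when the X-cluster locus is included")
  }
  if (cfg$motif_length < 26L) .stopf("motif_length must be >= 26")
  cfg
}

# Design the trigger guide / X-cluster motif pair. In "facing" space
# (r = reverse complement of the target window, aligned 5'->3' with the
# guide) a position pairs WC iff guide == r, and G:U iff (guide, r) is
# (G, A) or (T, C). The guide pairs Watson-Crick at positions 1-10 and
# 14-19, is mispaired at 11-13, and carries two G:U wobbles among
# otherwise mismatched 3' positions, giving 16 WC + 2 GU = 18 paired of 26
# positions (complementarity fraction ~0.692) for a 26-nt guide.
.design_guide_motif <- function(motif_length) {
  tail_pos <- 20:motif_length
  repeat {
    g <- c("G", sample(.BASES, motif_length - 1L, replace = TRUE))
    gu_ok <- intersect(tail_pos, which(g %in% c("G", "T")))
    if (length(gu_ok) >= 2L) break
  }
  gu_pos <- sort(sample(gu_ok, 2L))
  mm_pos <- setdiff(c(11:13, tail_pos), gu_pos)
  r <- g
  r[gu_pos] <- ifelse(g[gu_pos] == "G", "A", "C")
  for (i in mm_pos) {
    excl <- c(g[i], switch(g[i], G = "A", T = "C", NULL))
    r[i] <- sample(setdiff(.BASES, excl), 1L)
  }
  list(guide = paste(g, collapse = ""),
       motif = .revcomp(paste(r, collapse = "")))
}

# count occurrences of a pattern on both strands of a character genome
.count_both_strands <- function(pattern, contigs) {
  n <- 0L
  rc <- .revcomp(pattern)
  for (s in contigs) {
    for (p in unique(c(pattern, rc))) {
      m <- gregexpr(p, s, fixed = TRUE)[[1]]
      n <- n + sum(m > 0L)
    }
  }
  n
}

#' Build a synthetic reference genome with typed small RNA annotations
#'
#' Generates a random contig carrying the loci requested in `config`,
#' embeds the X-cluster motif copies and the trigger guide site, and
#' returns the sequences together with a 0-based, half-open, stranded
#' feature table. Deterministic given `(config, seed)`.
#'
#' @param config A list from [reference_config()].
#' @param seed Integer random seed.
#' @return An object of class `ReferenceSet`: a list with elements
#'   `sequences` (a [Biostrings::DNAStringSet]), `features` (a data.frame
#'   with columns `feature_id`, `contig`, `start`, `end`, `strand`,
#'   `class`, `mature_length`), `motif`, `guide`, `config`, and `seed`.
#' @export
build_reference <- function(config = reference_config(), seed = 1L) {
  set.seed(seed)
  gm <- if (config$include_xcluster) {
    .design_guide_motif(config$motif_length)
  } else {
    list(guide = NA_character_, motif = NA_character_)
  }

  blocks <- list()
  add <- function(class, id, len, tx = NULL) {
    blocks[[length(blocks) + 1L]] <<- list(class = class, id = id,
                                           len = len, tx = tx)
  }
  for (i in seq_len(config$n_pirna_loci)) {
    add("pirna_locus", sprintf("pirna_locus_%d", i), config$pirna_locus_length)
  }
  for (i in seq_len(config$n_coding_loci)) {
    add("coding_locus", sprintf("coding_locus_%d", i), config$coding_locus_length)
  }
  for (i in seq_len(config$n_ergo1_loci)) {
    add("sirna26g_ergo1_locus", sprintf("sirna26g_ergo1_locus_%d", i),
        config$sirna_locus_length)
  }
  for (i in seq_len(config$n_alg34_loci)) {
    add("sirna26g_alg34_locus", sprintf("sirna26g_alg34_locus_%d", i),
        config$sirna_locus_length)
  }
  for (i in seq_len(config$n_mirna)) {
    add("mirna_mature", sprintf("mir_sim_%d", i), config$mirna_mature_length)
  }

  for (attempt in seq_len(20L)) {
    blk <- blocks
    if (config$include_trigger) {
      # trigger transcript carries the reverse complement of the guide, so
      # the antisense 26G read off this locus IS the guide
      site <- .revcomp(gm$guide)
      flank <- config$trigger_locus_length - nchar(site)
      if (flank < 2L) .stopf("trigger_locus_length too small for the guide site")
      at <- sample(seq_len(flank - 1L), 1L)
      tx <- paste0(.rand_dna(at), site,
                   .rand_dna(flank - at))
      blk[[length(blk) + 1L]] <- list(class = "trigger_locus",
                                      id = "trigger_locus_1",
                                      len = nchar(tx), tx = tx)
    }
    if (config$include_xcluster) {
      nsp <- config$n_motif_copies + 1L
      spacers <- vapply(seq_len(nsp), function(i) {
        .rand_dna(sample(seq(config$spacer_range[1], config$spacer_range[2]), 1L))
      }, character(1))
      tx <- spacers[1L]
      for (i in seq_len(config$n_motif_copies)) {
        tx <- paste0(tx, gm$motif, spacers[i + 1L])
      }
      blk[[length(blk) + 1L]] <- list(class = "xcluster_locus",
                                      id = "xcluster_locus_1",
                                      len = nchar(tx), tx = tx)
    }

    blk <- blk[sample(seq_along(blk))]
    pieces <- character(0)
    pos <- 0L
    feat <- vector("list", length(blk))
    for (i in seq_along(blk)) {
      gap <- sample(seq(config$gap_range[1], config$gap_range[2]), 1L)
      pieces <- c(pieces, .rand_dna(gap))
      pos <- pos + gap
      b <- blk[[i]]
      strand <- sample(c("+", "-"), 1L)
      tx <- if (is.null(b$tx)) .rand_dna(b$len) else b$tx
      seg <- if (strand == "+") tx else .revcomp(tx)
      pieces <- c(pieces, seg)
      feat[[i]] <- data.frame(feature_id = b$id, contig = config$contig_name,
                              start = pos, end = pos + b$len, strand = strand,
                              class = b$class,
                              mature_length = if (b$class == "mirna_mature")
                                b$len else NA_integer_,
                              stringsAsFactors = FALSE)
      pos <- pos + b$len
    }
    gap <- sample(seq(config$gap_range[1], config$gap_range[2]), 1L)
    pieces <- c(pieces, .rand_dna(gap))
    contig <- paste(pieces, collapse = "")

    if (!is.null(config$contig_length)) {
      if (nchar(contig) > config$contig_length) {
        .stopf("requested loci (%d nt with gaps) exceed contig_length %d",
               nchar(contig), config$contig_length)
      }
      contig <- paste0(contig, .rand_dna(config$contig_length - nchar(contig)))
    }
    if (!is.null(config$pad_to) && nchar(contig) < config$pad_to) {
      contig <- paste0(contig, .rand_dna(config$pad_to - nchar(contig)))
    }

    ok <- TRUE
    motif_starts <- NULL
    if (config$include_xcluster) {
      ok <- .count_both_strands(gm$motif, contig) == config$n_motif_copies
      # the scan over the X-cluster transcript must recover exactly the
      # embedded motif placements: random spacer windows occasionally tie
      # the designed complementarity, in which case the layout is redrawn
      xtx <- vapply(blk, function(b) identical(b$class, "xcluster_locus"),
                    logical(1))
      xtx <- blk[[which(xtx)]]$tx
      motif_starts <- as.integer(gregexpr(gm$motif, xtx,
                                          fixed = TRUE)[[1]]) - 1L
      if (ok) {
        sc <- scan_transcript(gm$guide, xtx, min_complementarity = 0.69)
        starts <- vapply(sc, function(s) s$target_start, integer(1))
        ok <- length(sc) == config$n_motif_copies &&
          identical(sort(starts), sort(motif_starts))
      }
    }
    if (config$include_trigger) {
      ok <- ok && .count_both_strands(gm$guide, contig) == 1L
    }
    if (ok) {
      features <- do.call(rbind, feat)
      rownames(features) <- NULL
      seqs <- Biostrings::DNAStringSet(stats::setNames(contig, config$contig_name))
      ref <- structure(list(sequences = seqs, features = features,
                            motif = gm$motif, guide = gm$guide,
                            xcluster_motif_starts = motif_starts,
                            config = config, seed = seed),
                       class = "ReferenceSet")
      .validate_reference(ref)
      return(ref)
    }
  }
  .stopf("failed to assemble a reference without spurious motif copies")
}

.validate_reference <- function(ref) {
  f <- ref$features
  lens <- stats::setNames(Biostrings::width(ref$sequences), names(ref$sequences))
  stopifnot(all(f$start < f$end),
            all(f$start >= 0L),
            all(f$end <= lens[f$contig]),
            all(f$strand %in% c("+", "-")),
            all(f$class %in% c("mirna_mature", "pirna_locus",
                               "sirna26g_ergo1_locus", "sirna26g_alg34_locus",
                               "coding_locus", "xcluster_locus",
                               "trigger_locus")),
            all(is.na(f$mature_length) | f$mature_length <= f$end - f$start))
  invisible(ref)
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat(sprintf("ReferenceSet: %d contig(s), %d features (seed %d)\n",
              length(x$sequences), nrow(x$features), x$seed))
  print(table(x$features$class))
  invisible(x)
}

#' Transcript (sense-strand) sequence of a feature
#'
#' @param ref A `ReferenceSet`.
#' @param feature_id Feature identifier.
#' @return Character string: the feature sequence read 5'->3' on its
#'   annotated strand.
#' @export
feature_seq <- function(ref, feature_id) {
  f <- ref$features[ref$features$feature_id == feature_id, ]
  if (nrow(f) != 1L) .stopf("unknown feature_id '%s'", feature_id)
  s <- substr(as.character(ref$sequences[[f$contig]]), f$start + 1L, f$end)
  if (f$strand == "-") .revcomp(s) else s
}

.features_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand,
    type = features$class,
    ID = features$feature_id,
    mature_length = features$mature_length)
}

#' Write a reference to FASTA, GFF3, and BED
#'
#' @param ref A `ReferenceSet`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written (fasta, gff3, bed).
#' @export
write_reference <- function(ref, dir, prefix = "reference") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  bed <- file.path(dir, paste0(prefix, ".bed"))
  Biostrings::writeXStringSet(ref$sequences, fa)
  gr <- .features_granges(ref$features)
  rtracklayer::export(gr, gff, format = "gff3")
  bed_gr <- gr
  names(bed_gr) <- gr$ID
  rtracklayer::export(bed_gr, bed, format = "bed")
  invisible(c(fasta = fa, gff3 = gff, bed = bed))
}

#' Read a reference from FASTA + GFF3
#'
#' Counterpart of [write_reference()]; feature classes are read from the
#' GFF3 `type` column and coordinates converted back to 0-based half-open.
#'
#' @param fasta Path to the reference FASTA.
#' @param gff3 Path to the feature GFF3.
#' @return A `ReferenceSet` (without simulation metadata).
#' @export
read_reference <- function(fasta, gff3) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff3, format = "gff3")
  ml <- if ("mature_length" %in% names(GenomicRanges::mcols(gr))) {
    as.integer(gr$mature_length)
  } else {
    rep(NA_integer_, length(gr))
  }
  features <- data.frame(
    feature_id = as.character(gr$ID),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    class = as.character(gr$type),
    mature_length = ml,
    stringsAsFactors = FALSE)
  ref <- structure(list(sequences = seqs, features = features,
                        motif = NA_character_, guide = NA_character_,
                        config = NULL, seed = NA_integer_),
                   class = "ReferenceSet")
  .validate_reference(ref)
  ref
}
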