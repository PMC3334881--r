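# End-to-end run orchestration: generate -> treat -> map/classify ->
# enrich -> trim/tail -> target scan, with a manifest for reproducibility.

#' Default pipeline configuration
#'
#' @param seed Base random seed; stage seeds are fanned out from it.
#' @return Nested configuration list (reference, library, beta-elimination,
#'   mapping, enrichment, scanning sections).
#' @export
default_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       reference = reference_config(),
       library = library_config(),
       beta = list(p_meth = 1.0, p_unmeth = 0.1),
       map = list(min_prefix = 15L),
       enrich = list(threshold = 0, zero_epsilon = 1),
       scan = list(min_complementarity = 0.69, max_bulges = 0L))
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a (possibly partial) configuration list or a YAML file path;
#' missing fields are filled from [default_config()], unknown fields and
#' out-of-range probabilities are rejected.
#'
#' @param config Partial configuration list, YAML path, or `NULL`.
#' @return The normalized configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("config file '%s' does not exist", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- default_config()
  cfg <- .merge_config(defaults, config)
  # rebuild structured sections through their constructors so invariants
  # (probability ranges, motif sizing) are checked
  cfg$reference <- do.call(reference_config, cfg$reference)
  lc <- cfg$library
  cfg$library <- library_config(classes = lc$classes, p_meth = lc$p_meth,
                                p_unmeth = lc$p_unmeth,
                                size_range = lc$size_range,
                                copy_dispersion = lc$copy_dispersion,
                                tail_length_probs = lc$tail_length_probs,
                                trim_length_probs = lc$trim_length_probs)
  b <- unlist(cfg$beta)
  if (any(b < 0 | b > 1)) .stopf("beta survival probabilities must lie in [0, 1]")
  if (cfg$beta$p_unmeth > cfg$beta$p_meth) {
    .stopf("beta$p_unmeth > beta$p_meth: methylation must protect")
  }
  if (cfg$map$min_prefix < 1L) .stopf("map$min_prefix must be >= 1")
  cfg
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Builds the synthetic reference, simulates the untreated library,
#' applies beta-elimination, maps and classifies both libraries, computes
#' per-feature and per-class enrichment, 3' tail/trim summaries, and scans
#' the X-cluster transcript with the trigger guide. All stage tables are
#' written as TSV under `outdir` together with a JSON run manifest
#' (configuration snapshot, stage seeds, file digests, record counts,
#' package version). Deterministic given `(config, seed)`.
#'
#' @param config Configuration accepted by [validate_config()].
#' @param outdir Output directory (created; must be empty or absent unless
#'   `overwrite = TRUE`).
#' @param overwrite Allow writing into an existing directory.
#' @return Invisibly, `outdir`.
#' @export
run_pipeline <- function(config = NULL, outdir, overwrite = FALSE) {
  cfg <- validate_config(config)
  if (dir.exists(outdir) && length(dir(outdir)) && !overwrite) {
    .stopf("output directory '%s' is not empty (use overwrite = TRUE)", outdir)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(reference = cfg$seed, simulate = cfg$seed + 1L,
                beta = cfg$seed + 2L)

  ref <- build_reference(cfg$reference, seed = seeds$reference)
  write_reference(ref, outdir)

  untreated <- simulate_library(ref, cfg$library, seed = seeds$simulate)
  treated <- apply_beta_elimination(untreated, cfg$beta$p_meth,
                                    cfg$beta$p_unmeth, seed = seeds$beta)
  write_library(untreated, file.path(outdir, "untreated.fa"))
  write_library(treated, file.path(outdir, "treated.fa"))

  aln <- map_library(untreated, ref, min_prefix = cfg$map$min_prefix)
  assignments <- classify_library(untreated, aln, ref)
  .write_tsv(assignments, file.path(outdir, "class_assignments.tsv"))

  prof <- size_firstnt_profile(untreated)
  .write_tsv(data.frame(length = rownames(prof), prof, check.names = FALSE),
             file.path(outdir, "size_firstnt_matrix.tsv"))

  cls_of <- stats::setNames(assignments$class, assignments$read_id)
  total_u <- sum(untreated$count[cls_of[untreated$read_id] != "unmapped"])
  total_t <- sum(treated$count[cls_of[treated$read_id] != "unmapped"])
  aln_t <- aln[aln$read_id %in% treated$read_id, , drop = FALSE]
  fc_u <- feature_counts(untreated, aln, ref)
  fc_t <- feature_counts(treated, aln_t, ref)
  enr <- enrichment_table(fc_u, fc_t, total_u, total_t,
                          zero_epsilon = cfg$enrich$zero_epsilon,
                          threshold = cfg$enrich$threshold)
  .write_tsv(enr, file.path(outdir, "enrichment_features.tsv"))
  ratios <- class_ratio(treated, untreated, assignments,
                        threshold = cfg$enrich$threshold)
  .write_tsv(ratios, file.path(outdir, "class_ratios.tsv"))

  calls <- .annotate_anchor(aln, ref)
  attr(calls, "unplaced") <- setdiff(untreated$read_id, unique(calls$read_id))
  .write_tsv(calls, file.path(outdir, "tail_calls.tsv"))
  tails <- tailed_proportion(calls, untreated, assignments)
  trims <- trimmed_proportion(calls, untreated, assignments)
  .write_tsv(merge(tails, trims, by = "class", all = TRUE),
             file.path(outdir, "tailing_by_class.tsv"))
  .write_tsv(tail_composition(calls, untreated),
             file.path(outdir, "tail_composition.tsv"))

  if (cfg$reference$include_xcluster && cfg$reference$include_trigger) {
    sites <- scan_transcript(ref$guide, feature_seq(ref, "xcluster_locus_1"),
                             min_complementarity = cfg$scan$min_complementarity,
                             max_bulges = cfg$scan$max_bulges,
                             guide_id = "trigger_guide",
                             transcript_id = "xcluster_locus_1")
    .write_tsv(sites_table(sites), file.path(outdir, "target_sites.tsv"))
    xcov <- coverage_track(aln, untreated, ref, "xcluster_locus_1")
    .write_tsv(data.frame(position = seq_along(xcov) - 1L, coverage = xcov),
               file.path(outdir, "coverage_xcluster.tsv"))
  }

  files <- dir(outdir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("sRNAmethyl")),
    seeds = seeds,
    config = cfg,
    record_counts = list(
      untreated_species = nrow(untreated),
      untreated_copies = sum(untreated$count),
      treated_species = nrow(treated),
      treated_copies = sum(treated$count),
      placements = nrow(aln),
      unplaced_reads = length(attr(calls, "unplaced"))),
    file_md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(outdir)
}

#' Summarize a pipeline run from its stage tables
#'
#' Reads the stage TSVs written by [run_pipeline()] back in; every number
#' in the report is taken from a stage table (nothing is recomputed).
#'
#' @param outdir A [run_pipeline()] output directory.
#' @return List with `class_copies`, `class_ratios`, `enrichment`,
#'   `tailing`, `target_sites`, `manifest`.
#' @export
summarize_run <- function(outdir) {
  rd <- function(f) {
    p <- file.path(outdir, f)
    if (file.exists(p)) {
      utils::read.delim(p, stringsAsFactors = FALSE)
    } else {
      NULL
    }
  }
  ratios <- rd("class_ratios.tsv")
  list(class_copies = stats::setNames(ratios$rpm_untreated, ratios$class),
       class_ratios = ratios,
       enrichment = rd("enrichment_features.tsv"),
       tailing = rd("tailing_by_class.tsv"),
       target_sites = rd("target_sites.tsv"),
       manifest = jsonlite::read_json(file.path(outdir, "manifest.json")))
}
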