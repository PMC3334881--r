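# Normalized abundances, beta-elimination enrichment, and 2^-ddCt.

#' Reads per million
#'
#' @param count Copy count(s).
#' @param library_total Total mapped copies in the library (the documented
#'   normalization denominator).
#' @return `count * 1e6 / library_total`.
#' @export
rpm <- function(count, library_total) {
  if (length(library_total) != 1L || library_total <= 0) {
    .stopf("library_total must be a single positive number")
  }
  count * 1e6 / library_total
}

#' Log2 enrichment ratio of treated over untreated RPM
#'
#' Antisymmetric under swapping the two libraries; 0 when equal. A
#' pseudocount `epsilon` may be added to both terms for units observed at
#' zero in one library.
#'
#' @param rpm_treated,rpm_untreated RPM values.
#' @param epsilon Pseudocount in RPM units (default 0).
#' @return `log2((rpm_treated + epsilon) / (rpm_untreated + epsilon))`.
#' @export
feature_log2_ratio <- function(rpm_treated, rpm_untreated, epsilon = 0) {
  log2((rpm_treated + epsilon) / (rpm_untreated + epsilon))
}

#' Percent depletion of a species after treatment
#'
#' @param rpm_untreated RPM in the untreated library (must be > 0).
#' @param rpm_treated RPM in the treated library.
#' @return `100 * (1 - rpm_treated / rpm_untreated)`; negative values
#'   indicate enrichment.
#' @export
percent_depletion <- function(rpm_untreated, rpm_treated) {
  if (any(rpm_untreated <= 0)) .stopf("rpm_untreated must be positive")
  100 * (1 - rpm_treated / rpm_untreated)
}

#' Call enrichment status from a log2 ratio
#'
#' @param log2_ratio Log2 treated/untreated ratio(s).
#' @param threshold Non-negative threshold `t`; `enriched` if ratio > t,
#'   `depleted` if ratio < -t, else `unchanged` (ties at the threshold are
#'   unchanged).
#' @return Character vector of `enriched` / `depleted` / `unchanged`.
#' @export
call_status <- function(log2_ratio, threshold = 0) {
  ifelse(is.na(log2_ratio), NA_character_,
         ifelse(log2_ratio > threshold, "enriched",
                ifelse(log2_ratio < -threshold, "depleted", "unchanged")))
}

#' Per-feature beta-elimination enrichment table
#'
#' RPM values use each library's total mapped copies as denominator.
#' Features observed in both libraries use pseudocount 0; features at zero
#' in exactly one library use `zero_epsilon` (in RPM units) and are
#' flagged in the `epsilon` column; features absent from both yield `NA`.
#'
#' @param counts_untreated,counts_treated data.frames from
#'   [feature_counts()] (columns `feature_id`, `class`, `count`).
#' @param total_untreated,total_treated Library totals (mapped copies).
#' @param zero_epsilon Pseudocount (RPM) for features at zero in one
#'   library.
#' @param threshold Status threshold passed to [call_status()].
#' @return data.frame `feature_id`, `class`, `rpm_untreated`,
#'   `rpm_treated`, `epsilon`, `log2_ratio`, `status`.
#' @export
enrichment_table <- function(counts_untreated, counts_treated,
                             total_untreated, total_treated,
                             zero_epsilon = 1, threshold = 0) {
  stopifnot(identical(counts_untreated$feature_id, counts_treated$feature_id))
  ru <- rpm(counts_untreated$count, total_untreated)
  rt <- rpm(counts_treated$count, total_treated)
  eps <- ifelse(xor(ru == 0, rt == 0), zero_epsilon, 0)
  lr <- ifelse(ru == 0 & rt == 0, NA_real_, feature_log2_ratio(rt, ru, eps))
  data.frame(feature_id = counts_untreated$feature_id,
             class = counts_untreated$class,
             rpm_untreated = ru, rpm_treated = rt,
             epsilon = eps, log2_ratio = lr,
             status = call_status(lr, threshold),
             stringsAsFactors = FALSE)
}

#' Per-class ratio of normalized reads, treated vs untreated
#'
#' For each class, the ratio of summed RPM in the treated library to
#' summed RPM in the untreated library. Each library is normalized by its
#' own total mapped copies (reads with a class other than `unmapped`).
#' Classes with zero untreated signal are reported as missing.
#'
#' @param reads_treated,reads_untreated Library data.frames.
#' @param assignments data.frame `read_id`, `class` covering the union of
#'   both libraries (e.g. [classify_library()] on the untreated library
#'   when the treated one is its subset).
#' @param classes Optional class labels to report.
#' @param threshold Status threshold passed to [call_status()].
#' @return data.frame `class`, `rpm_untreated`, `rpm_treated`, `ratio`,
#'   `log2_ratio`, `status`.
#' @export
class_ratio <- function(reads_treated, reads_untreated, assignments,
                        classes = NULL, threshold = 0) {
  cls_of <- stats::setNames(assignments$class, assignments$read_id)
  .tally <- function(reads) {
    cl <- cls_of[reads$read_id]
    mapped <- !is.na(cl) & cl != "unmapped"
    total <- sum(reads$count[mapped])
    tapply_cl <- tapply(reads$count[mapped], cl[mapped], sum)
    list(total = total, by_class = tapply_cl)
  }
  u <- .tally(reads_untreated)
  t_ <- .tally(reads_treated)
  if (is.null(classes)) {
    classes <- sort(unique(c(names(u$by_class), names(t_$by_class))))
  }
  get0 <- function(tab, cl) if (cl %in% names(tab)) tab[[cl]] else 0
  out <- lapply(classes, function(cl) {
    ru <- if (u$total > 0) rpm(get0(u$by_class, cl), u$total) else NA_real_
    rt <- if (t_$total > 0) rpm(get0(t_$by_class, cl), t_$total) else 0
    ratio <- if (is.na(ru) || ru == 0) NA_real_ else rt / ru
    data.frame(class = cl, rpm_untreated = ru, rpm_treated = rt,
               ratio = ratio, log2_ratio = log2(ratio),
               status = call_status(log2(ratio), threshold),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative quantification by the 2^-ddCt method
#'
#' Fold change of a target species in a condition relative to a control,
#' each normalized to a reference species (e.g. miR-1 or miR-35 for small
#' RNAs):
#' `2^-((ct_target_cond - ct_ref_cond) - (ct_target_ctrl - ct_ref_ctrl))`.
#'
#' @param ct_target_cond,ct_ref_cond Ct of target and reference in the
#'   condition of interest.
#' @param ct_target_ctrl,ct_ref_ctrl Ct of target and reference in the
#'   control condition.
#' @return Fold change(s), strictly positive.
#' @export
ddct_fold_change <- function(ct_target_cond, ct_ref_cond,
                             ct_target_ctrl, ct_ref_ctrl) {
  ddct <- (ct_target_cond - ct_ref_cond) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' 2^-ddCt across replicates with a dispersion range
#'
#' Computes the mean ddCt over replicate Ct quadruples and reports the
#' fold change together with the range `[2^-(ddCt + SD), 2^-(ddCt - SD)]`
#' where SD is the standard deviation of the replicate ddCt values.
#'
#' @param ct_target_cond,ct_ref_cond,ct_target_ctrl,ct_ref_ctrl Numeric
#'   vectors of replicate Ct values (equal length).
#' @return List with `fold_change`, `ddct`, `sd`, `range` (length 2).
#' @export
ddct_summary <- function(ct_target_cond, ct_ref_cond,
                         ct_target_ctrl, ct_ref_ctrl) {
  ddct <- (ct_target_cond - ct_ref_cond) - (ct_target_ctrl - ct_ref_ctrl)
  m <- mean(ddct)
  s <- stats::sd(ddct)
  list(fold_change = 2^(-m), ddct = m, sd = s,
       range = c(2^(-(m + s)), 2^(-(m - s))))
}
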