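# Guide-target complementarity scoring and positional silencing rules.
#
# Positions are numbered from the guide 5' end (position 1 = 5' nt).
# Pairing states per guide position: W (Watson-Crick), G (G:U wobble),
# M (mismatch), D (guide bulge: the guide loops out over a deleted target
# nucleotide), I (target bulge: an inserted target nucleotide loops out).
# G:U wobbles count toward the complementarity fraction but are tracked
# separately.

#' Pairing state of one guide/target nucleotide pair
#'
#' @param guide_nt,target_nt Nucleotides (DNA or RNA alphabet), vectorized.
#' @return `"WC"` for A:U/U:A/G:C/C:G, `"GU"` for G:U/U:G, else `"MM"`.
#' @export
pair_state <- function(guide_nt, target_nt) {
  g <- .normalize_seq(guide_nt)
  t <- .normalize_seq(target_nt)
  wc <- (g == "A" & t == "T") | (g == "T" & t == "A") |
    (g == "G" & t == "C") | (g == "C" & t == "G")
  gu <- (g == "G" & t == "T") | (g == "T" & t == "G")
  ifelse(wc, "WC", ifelse(gu, "GU", "MM"))
}

.STATE_CODE <- c(WC = "W", GU = "G", MM = "M")

.new_site <- function(guide_id, target_id, guide, target_window, states,
                      bulge, target_start = NA_integer_, strand = "+",
                      threshold = 0.69) {
  site <- structure(list(
    guide_id = guide_id, target_id = target_id,
    guide = guide, target_window = target_window,
    target_start = target_start, strand = strand,
    states = states, state_string = paste(states, collapse = ""),
    complementarity = mean(states %in% c("W", "G")),
    gu_count = sum(states == "G"),
    wc_count = sum(states == "W"),
    bulge = bulge, call = NA_character_), class = "guide_target_site")
  site$call <- predict_silencing(site, threshold = threshold)
  site
}

#' @export
print.guide_target_site <- function(x, ...) {
  cat(sprintf("guide %s vs %s%s: %s  compl=%.3f (%d WC + %d GU)  call=%s\n",
              x$guide_id, x$target_id,
              if (is.na(x$target_start)) "" else sprintf(" @%d(%s)",
                                                         x$target_start,
                                                         x$strand),
              x$state_string, x$complementarity, x$wc_count, x$gu_count,
              x$call))
  invisible(x)
}

#' Align a guide against a target window
#'
#' The guide (5'->3') is paired antiparallel against the window (target
#' 5'->3'): guide position `i` faces window position `L - i + 1`. When
#' window and guide lengths are equal the alignment is ungapped. With one
#' bulge allowed, a window one nt shorter forces a guide bulge (one guide
#' position loops out) and a window one nt longer forces a target bulge
#' (one window nucleotide loops out); the placement maximizing the number
#' of paired (WC + GU) positions is chosen, with ties broken toward the
#' guide-3'-most bulge position.
#'
#' @param guide Guide sequence, 5'->3'.
#' @param target_window Target site sequence, 5'->3' on the target.
#' @param max_bulges 0 or 1 (at most one bulge per site).
#' @param guide_id,target_id Identifiers carried into the result.
#' @param threshold Complementarity threshold for [predict_silencing()].
#' @return A `guide_target_site`: per-position states over guide positions
#'   1..L, complementarity fraction `(#WC + #GU) / L`, and predicted call.
#' @export
align_guide <- function(guide, target_window, max_bulges = 1L,
                        guide_id = "guide", target_id = "target",
                        threshold = 0.69) {
  if (!max_bulges %in% c(0L, 1L)) .stopf("max_bulges must be 0 or 1")
  g <- .chars(.normalize_seq(guide))
  w <- .chars(.normalize_seq(target_window))
  d <- length(w) - length(g)
  if (abs(d) > max_bulges) {
    .stopf("window length differs from guide length by %d; at most %d bulge(s) allowed",
           abs(d), max_bulges)
  }
  tface <- rev(w)  # target bases facing guide positions 1..Lw
  Lg <- length(g)
  if (d == 0L) {
    states <- unname(.STATE_CODE[pair_state(g, tface)])
    bulge <- NA_integer_
  } else if (d == -1L) {
    best <- NULL
    for (j in seq_len(Lg)) {
      st <- unname(.STATE_CODE[pair_state(g[-j], tface)])
      sc <- sum(st != "M")
      if (is.null(best) || sc >= best$sc) best <- list(j = j, st = st, sc = sc)
    }
    states <- append(best$st, "D", after = best$j - 1L)
    bulge <- best$j
  } else {
    best <- NULL
    for (b in seq_len(Lg + 1L)) {
      st <- unname(.STATE_CODE[pair_state(g, tface[-b])])
      sc <- sum(st != "M")
      if (is.null(best) || sc >= best$sc) best <- list(b = b, st = st, sc = sc)
    }
    states <- best$st
    bulge <- min(best$b, Lg)
    states[bulge] <- "I"
  }
  .new_site(guide_id, target_id, paste(g, collapse = ""),
            paste(w, collapse = ""), states, bulge, threshold = threshold)
}

.as_state_vec <- function(x) {
  if (inherits(x, "guide_target_site")) return(x$states)
  if (is.character(x) && length(x) == 1L && nchar(x) > 1L) return(.chars(x))
  x
}

#' Predict the silencing outcome of a guide-target site
#'
#' A three-level abstraction of sensor fluorescence outcomes, evaluated on
#' the per-position state vector in priority order:
#' 1. any mismatch or bulge within guide positions 1-5 (the 5' region
#'    containing the seed) => `nonfunctional`;
#' 2. three contiguous mismatches within positions 12-14 => `nonfunctional`;
#' 3. three contiguous mismatches within positions 9-11 => `partial`;
#' 4. a single target bulge within positions 13-15 => `partial`;
#' 5. a single mismatch at 13, or a single guide bulge at 13, as the only
#'    defect => `functional`;
#' 6. mismatches confined to positions 20-22 (no bulges) => `functional`;
#' 7. otherwise `functional` iff the complementarity fraction (G:U counted
#'    as paired) reaches `threshold`.
#'
#' @param site A `guide_target_site`, a state string (e.g. `"WWWMM..."`),
#'   or a character vector of per-position state codes.
#' @param threshold Complementarity threshold for rule 7 (default 0.69).
#' @return `"functional"`, `"partial"`, or `"nonfunctional"`.
#' @export
predict_silencing <- function(site, threshold = 0.69) {
  s <- .as_state_vec(site)
  L <- length(s)
  mm <- s == "M"
  gb <- s == "D"
  tb <- s == "I"
  within <- function(v, pos) any(v[pos[pos <= L]])
  all_mm <- function(pos) {
    pos <- pos[pos <= L]
    length(pos) == 3L && all(mm[pos])
  }
  if (within(mm | gb | tb, 1:5)) return("nonfunctional")
  if (all_mm(12:14)) return("nonfunctional")
  if (all_mm(9:11)) return("partial")
  if (sum(tb) == 1L && within(tb, 13:15)) return("partial")
  n_defects <- sum(mm) + sum(gb) + sum(tb)
  if (n_defects == 1L && L >= 13L && (mm[13] || gb[13])) return("functional")
  if (!any(gb | tb) && any(mm) && all(which(mm) %in% 20:22)) {
    return("functional")
  }
  if (mean(s %in% c("W", "G")) >= threshold) "functional" else "nonfunctional"
}

#' Scan a transcript for guide target sites
#'
#' Slides the guide over every window of the transcript (ungapped by
#' default; windows one nt shorter/longer are also tried when
#' `max_bulges = 1`), keeps windows whose complementarity fraction reaches
#' `min_complementarity`, reduces overlapping candidate windows to local
#' maxima (highest complementarity; ties to the leftmost window), and
#' returns the surviving sites sorted by position.
#'
#' @param guide Guide sequence, 5'->3'.
#' @param transcript Transcript sequence, 5'->3' (the guide is paired
#'   antiparallel against it).
#' @param min_complementarity Minimum `(#WC + #GU) / L` to keep a window.
#' @param max_bulges 0 (default, ungapped scan) or 1.
#' @param guide_id,transcript_id Identifiers carried into the results.
#' @param threshold Complementarity threshold for the per-site call.
#' @return List of `guide_target_site` objects with 0-based `target_start`
#'   coordinates; see [sites_table()] for a tabular view.
#' @export
scan_transcript <- function(guide, transcript, min_complementarity = 0.69,
                            max_bulges = 0L, guide_id = "guide",
                            transcript_id = "transcript", threshold = 0.69) {
  g <- .chars(.normalize_seq(guide))
  tx <- .normalize_seq(transcript)
  t <- .chars(tx)
  Lg <- length(g)
  n <- length(t)
  cand <- list()
  if (n >= Lg) {
    nwin <- n - Lg + 1L
    score <- integer(nwin)
    for (i in seq_len(Lg)) {
      tb <- t[seq_len(nwin) + Lg - i]
      gi <- g[i]
      ok <- (gi == "A" & tb == "T") | (gi == "T" & (tb == "A" | tb == "G")) |
        (gi == "G" & (tb == "C" | tb == "T")) | (gi == "C" & tb == "G")
      score <- score + ok
    }
    for (j in which(score / Lg >= min_complementarity)) {
      cand[[length(cand) + 1L]] <- list(start = j - 1L, width = Lg,
                                        compl = score[j] / Lg)
    }
  }
  if (max_bulges >= 1L) {
    for (wd in c(Lg - 1L, Lg + 1L)) {
      if (n < wd) next
      for (j in seq_len(n - wd + 1L)) {
        site <- align_guide(paste(g, collapse = ""),
                            substr(tx, j, j + wd - 1L), max_bulges = 1L)
        if (site$complementarity >= min_complementarity) {
          cand[[length(cand) + 1L]] <- list(start = j - 1L, width = wd,
                                            compl = site$complementarity)
        }
      }
    }
  }
  if (!length(cand)) return(list())
  df <- do.call(rbind, lapply(cand, as.data.frame))
  df <- df[order(-df$compl, df$start), , drop = FALSE]
  kept <- df[0, ]
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]
    e <- s + df$width[i]
    if (!any(kept$start < e & s < kept$start + kept$width)) {
      kept <- rbind(kept, df[i, ])
    }
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  lapply(seq_len(nrow(kept)), function(i) {
    win <- substr(tx, kept$start[i] + 1L, kept$start[i] + kept$width[i])
    a <- align_guide(paste(g, collapse = ""), win,
                     max_bulges = if (kept$width[i] == Lg) 0L else 1L,
                     guide_id = guide_id, target_id = transcript_id,
                     threshold = threshold)
    a$target_start <- kept$start[i]
    a
  })
}

#' Tabulate a list of guide-target sites
#'
#' @param sites List of `guide_target_site` objects (e.g. from
#'   [scan_transcript()]).
#' @return data.frame with `guide_id`, `target_id`, `start`, `end`,
#'   `strand`, `complementarity`, `gu_count`, `state_string`, `call`.
#' @export
sites_table <- function(sites) {
  if (!length(sites)) {
    return(data.frame(guide_id = character(0), target_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), complementarity = numeric(0),
                      gu_count = integer(0), state_string = character(0),
                      call = character(0)))
  }
  out <- do.call(rbind, lapply(sites, function(s) {
    data.frame(guide_id = s$guide_id, target_id = s$target_id,
               start = s$target_start,
               end = s$target_start + nchar(s$target_window),
               strand = s$strand, complementarity = s$complementarity,
               gu_count = s$gu_count, state_string = s$state_string,
               call = s$call, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' State vectors of the siRNA sensor target-site variants
#'
#' Encodes the mutagenized single-site sensor series as per-position state
#' vectors over a 22-nt guide: the wild-type site, substitution blocks at
#' positions 1-3, 4-5, 9-11, 12-14, 20-22, a single substitution at 13, a
#' single target deletion at 4 or 13 (guide bulge), and a single target
#' insertion looping out between positions 13-15 (target bulge).
#'
#' @param guide_length Guide length in nt (default 22).
#' @return Named character vector of state strings, suitable for
#'   [predict_silencing()].
#' @export
sensor_variants <- function(guide_length = 22L) {
  wt <- function() rep("W", guide_length)
  set <- function(pos, code) {
    s <- wt()
    s[pos] <- code
    paste(s, collapse = "")
  }
  c(wild_type = paste(wt(), collapse = ""),
    sub_1_3 = set(1:3, "M"),
    sub_4_5 = set(4:5, "M"),
    del_4 = set(4, "D"),
    sub_9_11 = set(9:11, "M"),
    sub_12_14 = set(12:14, "M"),
    sub_13 = set(13, "M"),
    del_13 = set(13, "D"),
    ins_13 = set(14, "I"),
    sub_20_22 = set(20:22, "M"))
}
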