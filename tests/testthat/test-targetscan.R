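test_that("pairing states follow the Watson-Crick / G:U wobble table", {
  bases <- c("A", "C", "G", "T")
  wc <- c(AT = TRUE, TA = TRUE, GC = TRUE, CG = TRUE)
  gu <- c(GT = TRUE, TG = TRUE)
  for (g in bases) {
    for (t in bases) {
      want <- if (isTRUE(wc[paste0(g, t)])) "WC"
        else if (isTRUE(gu[paste0(g, t)])) "GU" else "MM"
      expect_equal(pair_state(g, t), want, info = paste0(g, ":", t))
    }
  }
  # RNA alphabet accepted
  expect_equal(pair_state("G", "U"), "GU")
  expect_equal(pair_state("A", "U"), "WC")
})

test_that("a guide aligned to its exact reverse complement is fully paired", {
  set.seed(60)
  g <- paste(sample(c("A", "C", "G", "T"), 26, replace = TRUE), collapse = "")
  site <- align_guide(g, oracle_rc(g), max_bulges = 0)
  expect_equal(site$complementarity, 1)
  expect_equal(site$state_string, strrep("W", 26))
  expect_equal(site$call, "functional")
})

test_that("the designed trigger guide pairs 18 of 26 positions against the motif", {
  ref <- build_reference(tiny_ref_config(), seed = 61)
  site <- align_guide(ref$guide, ref$motif, max_bulges = 0)
  expect_equal(site$complementarity, 18 / 26)
  s <- strsplit(site$state_string, "")[[1]]
  expect_true(all(s[c(1:10, 14:19)] == "W"))
  expect_true(all(s[11:13] == "M"))
  expect_equal(sum(s == "G"), 2)
  expect_true(all(which(s == "G") >= 20))
  expect_equal(site$call, "functional")
})

test_that("bulged alignments maximize pairing over all loop-out placements", {
  set.seed(62)
  for (rep in 1:10) {
    g <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
               collapse = "")
    w <- oracle_rc(g)
    # target insertion: one extra nt in the window -> target bulge
    j <- sample(2:21, 1)
    ins <- sample(c("A", "C", "G", "T"), 1)
    w_ins <- paste0(substr(w, 1, j), ins, substr(w, j + 1, 22))
    site <- align_guide(g, w_ins, max_bulges = 1)
    # brute force: best pairing over all single skips of the facing bases;
    # the reported vector spends one guide position on the bulge marker, so
    # its paired count sits within one of the optimum
    tface <- rev(strsplit(w_ins, "")[[1]])
    best <- max(vapply(1:23, function(b) {
      sum(pair_state(strsplit(g, "")[[1]], tface[-b]) != "MM")
    }, numeric(1)))
    paired <- site$wc_count + site$gu_count
    expect_true(paired == best - 1 || paired == best)
    expect_equal(sum(strsplit(site$state_string, "")[[1]] == "I"), 1)
    # target deletion: one missing nt -> guide bulge
    k <- sample(2:21, 1)
    w_del <- paste0(substr(w, 1, k - 1), substr(w, k + 1, 22))
    site_d <- align_guide(g, w_del, max_bulges = 1)
    tface_d <- rev(strsplit(w_del, "")[[1]])
    gch <- strsplit(g, "")[[1]]
    best_d <- max(vapply(1:22, function(b) {
      sum(pair_state(gch[-b], tface_d) != "MM")
    }, numeric(1)))
    expect_equal(site_d$wc_count + site_d$gu_count, best_d)
    expect_equal(sum(strsplit(site_d$state_string, "")[[1]] == "D"), 1)
  }
  expect_error(align_guide(strrep("A", 22), strrep("T", 25), max_bulges = 1),
               "bulge")
})

test_that("the sensor variant series reproduces the qualitative silencing outcomes", {
  v <- sensor_variants()
  expected <- c(wild_type = "functional",
                sub_1_3 = "nonfunctional",
                sub_4_5 = "nonfunctional",
                del_4 = "nonfunctional",
                sub_9_11 = "partial",
                sub_12_14 = "nonfunctional",
                sub_13 = "functional",
                del_13 = "functional",
                ins_13 = "partial",
                sub_20_22 = "functional")
  got <- vapply(v, predict_silencing, character(1))
  expect_equal(got[names(expected)], expected)
})

test_that("silencing calls respect the rule priority on edge cases", {
  # mismatches at 9-11 AND 12-14: the 12-14 block dominates (nonfunctional)
  s <- rep("W", 22); s[9:14] <- "M"
  expect_equal(predict_silencing(s), "nonfunctional")
  # single mismatch at 13 plus one at 21 is no longer the single-defect case,
  # but mismatches are not confined to 20-22 either; complementarity 20/22
  s <- rep("W", 22); s[c(13, 21)] <- "M"
  expect_equal(predict_silencing(s), "functional")
  # a bulge at position 2 dominates everything
  s <- rep("W", 22); s[2] <- "I"
  expect_equal(predict_silencing(s), "nonfunctional")
  # low-complementarity site with an intact 5' end is nonfunctional via rule 7
  s <- rep("M", 26); s[1:8] <- "W"
  expect_equal(predict_silencing(s), "nonfunctional")
})

test_that("duplex symmetries: role swap preserves states, revcomp preserves WC pairs", {
  set.seed(63)
  for (rep in 1:10) {
    g <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
               collapse = "")
    w <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
               collapse = "")
    a <- align_guide(g, w, max_bulges = 0)
    # the same duplex read from the target's side: identical state multiset
    b <- align_guide(w, g, max_bulges = 0)
    expect_equal(sort(strsplit(a$state_string, "")[[1]]),
                 sort(strsplit(b$state_string, "")[[1]]))
    expect_equal(a$complementarity, b$complementarity)
    # reverse-complementing both strands preserves Watson-Crick pairs
    # (G:U wobbles complement to A:C mismatches, so only WC is invariant)
    d <- align_guide(oracle_rc(g), oracle_rc(w), max_bulges = 0)
    expect_equal(d$wc_count, a$wc_count)
  }
})

test_that("transcript scanning finds the embedded motif sites and nothing else", {
  ref <- build_reference(tiny_ref_config(), seed = 64)
  xtx <- feature_seq(ref, "xcluster_locus_1")
  sites <- scan_transcript(ref$guide, xtx, min_complementarity = 0.69)
  expect_length(sites, tiny_ref_config()$n_motif_copies)
  st <- sites_table(sites)
  expect_equal(sort(st$start), sort(ref$xcluster_motif_starts))
  expect_true(all(st$complementarity >= 0.69))
  # an impossible threshold returns no sites
  expect_length(scan_transcript(ref$guide, xtx, min_complementarity = 1.01), 0)
})

test_that("scanning agrees with exhaustive window enumeration", {
  set.seed(65)
  ref <- build_reference(tiny_ref_config(), seed = 66)
  # shuffled transcript of the same composition as the X-cluster
  xtx <- feature_seq(ref, "xcluster_locus_1")
  shuf <- paste(sample(strsplit(xtx, "")[[1]]), collapse = "")
  thr <- 0.55  # low enough for background windows to qualify
  for (tx in c(substr(shuf, 1, 600), substr(xtx, 1, 600))) {
    sites <- scan_transcript(ref$guide, tx, min_complementarity = thr)
    st <- sites_table(sites)
    L <- nchar(ref$guide)
    compl <- vapply(seq_len(nchar(tx) - L + 1L), function(j) {
      oracle_window_compl(ref$guide, substr(tx, j, j + L - 1L))
    }, numeric(1))
    cand <- which(compl >= thr) - 1L  # 0-based starts
    # every reported site is a qualifying window with matching complementarity
    expect_true(all(st$start %in% cand))
    expect_equal(st$complementarity, compl[st$start + 1L])
    # reported sites are non-overlapping
    if (nrow(st) > 1L) {
      expect_true(all(diff(sort(st$start)) >= L))
    }
    # every qualifying window overlaps a reported site with >= complementarity
    for (j in cand) {
      over <- st[st$start < j + L & j < st$start + L, ]
      expect_gte(nrow(over), 1L)
      expect_true(max(over$complementarity) >= compl[j + 1L])
    }
  }
})
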