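prof_from_rpm <- function(...) {
  v <- c(...)
  fake_profile(data.frame(feature_id = names(v), sense_rpm = 0,
                          antisense_rpm = unname(v), stringsAsFactors = FALSE))
}

test_that("target calls honour the wild-type threshold and the 1/3 ratio with ties", {
  wt <- prof_from_rpm(a = 9.9, b = 100, c = 30, d = 15)
  mu1 <- prof_from_rpm(a = 0, b = 30, c = 10, d = 5)
  mu2 <- prof_from_rpm(a = 0, b = 50, c = 10, d = 5)
  calls <- call_targets(wt, list(`eri-7` = mu1, `eri-1` = mu2))
  by_id <- function(id) calls[calls$feature_id == id, ]
  ## a: fails the 10 RPM wild-type threshold despite total depletion
  expect_false(by_id("a")$called)
  ## b: eri-1 ratio 0.5 > 1/3, not called
  expect_false(by_id("b")$called)
  ## c: ratio exactly 1/3 in both mutants -> ties pass
  expect_true(by_id("c")$called)
  ## d: ratio 1/3, wt 15 >= 10 -> called
  expect_true(by_id("d")$called)
  ## sorted by wild-type RPM descending
  expect_equal(calls$feature_id, c("b", "c", "d", "a"))
})

test_that("an empty require set reduces to the wild-type threshold", {
  wt <- prof_from_rpm(a = 9.9, b = 100, c = 30)
  mu <- prof_from_rpm(a = 0, b = 100, c = 30)
  calls <- call_targets(wt, list(m = mu), require = character(0))
  expect_equal(sort(calls$feature_id[calls$called]), c("b", "c"))
})

test_that("a missing required genotype is an error", {
  wt <- prof_from_rpm(a = 100)
  expect_error(call_targets(wt, list(m = wt), require = c("m", "absent")),
               "absent")
})

test_that("raising thresholds never adds a target call", {
  set.seed(301)
  for (rep in 1:20) {
    ids <- paste0("f", 1:12)
    wt <- prof_from_rpm(stats::setNames(runif(12, 0, 50), ids))
    mu <- prof_from_rpm(stats::setNames(runif(12, 0, 50), ids))
    base <- call_targets(wt, list(m = mu), rpm_threshold = 5, depletion = 0.5)
    higher_rpm <- call_targets(wt, list(m = mu), rpm_threshold = 10, depletion = 0.5)
    higher_dep <- call_targets(wt, list(m = mu), rpm_threshold = 5, depletion = 0.8)
    expect_true(all(higher_rpm$feature_id[higher_rpm$called] %in%
                    base$feature_id[base$called]))
    expect_true(all(higher_dep$feature_id[higher_dep$called] %in%
                    base$feature_id[base$called]))
  }
})

test_that("individual siRNA calls use the 1 RPM threshold", {
  seqs <- c(a = "G1", b = "G2", c = "G3")
  mk <- function(rpms, is26 = TRUE) {
    fake_profile(data.frame(feature_id = character(0), sense_rpm = numeric(0),
                            antisense_rpm = numeric(0)),
                 seqs = data.frame(sequence = names(rpms), n_loci = 1L,
                                   count = unname(rpms), weight = unname(rpms),
                                   rpm = unname(rpms),
                                   length = 26L, first_nt = "G",
                                   is_26G = is26, stringsAsFactors = FALSE))
  }
  wt <- mk(c(s1 = 0.9, s2 = 5, s3 = 30))
  mu <- mk(c(s1 = 0, s2 = 0, s3 = 20))
  calls <- call_sirnas(wt, list(m = mu))
  expect_false(calls$called[calls$sequence == "s1"])  # below 1 RPM in wt
  expect_true(calls$called[calls$sequence == "s2"])   # ratio 0
  expect_equal(calls$m_ratio[calls$sequence == "s2"], 0)
  expect_false(calls$called[calls$sequence == "s3"])  # ratio 2/3 > 1/3
})

test_that("class depletion handles identity, total loss, and undefined cases", {
  mkp <- function(c26, c22) fake_profile(
    data.frame(feature_id = "f", sense_rpm = 0, antisense_rpm = c26 + c22),
    class_rpm = c(`26G` = c26, `22G` = c22, mirna = 0, pirna = 0, other = 0))
  wt <- mkp(100, 50)
  expect_equal(class_depletion(wt, wt, class = "26G"), 0)
  expect_equal(class_depletion(wt, mkp(0, 50), class = "26G"), 100)
  expect_equal(class_depletion(wt, mkp(150, 50), class = "26G"), -50)
  expect_error(class_depletion(wt, wt, class = "mirna"), "zero")
})

test_that("subset depletion sums per-feature antisense RPM", {
  mk <- function(a, b) fake_profile(
    data.frame(feature_id = c("a", "b"), sense_rpm = 0,
               antisense_rpm = c(a, b), stringsAsFactors = FALSE))
  wt <- mk(100, 40)
  mu <- mk(10, 40)
  expect_equal(class_depletion(wt, mu, subset = "a"), 90)
  expect_equal(class_depletion(wt, mu, subset = c("a", "b")),
               100 * (1 - 50 / 140))
})

test_that("window tracks tile a 10 kb chromosome into six 5 kb windows", {
  loci <- data.frame(chrom = "chrT", start = 2500L, end = 2526L, strand = "-",
                     length = 26L, first_nt = "G", rpm = 100,
                     stringsAsFactors = FALSE)
  p <- fake_profile(data.frame(feature_id = character(0), sense_rpm = numeric(0),
                               antisense_rpm = numeric(0)),
                    loci = loci, chrom_lengths = c(chrT = 10000L))
  tr <- window_track(p, p)
  expect_equal(nrow(tr), 6L)
  expect_equal(tr$start, seq(0L, 5000L, by = 1000L))
  expect_equal(unique(diff(tr$start)), 1000L)
  expect_equal(tr$end, tr$start + 5000L)
  ## identical libraries: all log2 ratios zero
  expect_true(all(tr$log2_ratio == 0))
  ## the locus at 2500 falls in windows starting 0..2000
  expect_equal(tr$wt_rpm > 0, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(tr$dominant_length[1], 26L)
})

test_that("a non-multiple chromosome length gets one truncated terminal window", {
  p <- fake_profile(data.frame(feature_id = character(0), sense_rpm = numeric(0),
                               antisense_rpm = numeric(0)),
                    loci = NULL, chrom_lengths = c(chrT = 10500L))
  p$loci <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       length = integer(0), first_nt = character(0),
                       rpm = numeric(0))
  tr <- window_track(p, p)
  expect_equal(tr$start[nrow(tr)], 6000L)
  expect_equal(tr$end[nrow(tr)], 10500L)
  expect_equal(unique(diff(tr$start)), 1000L)
})

test_that("windows over depleted target loci drop while background stays flat", {
  ds <- default_sim()
  tr <- window_track(ds$profiles$wt_embryo, ds$profiles$`eri-7_embryo`)
  feats <- ds$genome$features
  tgt <- feats[feats$class %in% "ergo1_target", ]
  hit <- rep(FALSE, nrow(tr))
  for (i in seq_len(nrow(tgt))) {
    hit <- hit | (tr$chrom == tgt$chrom[i] & tr$start < tgt$end[i] &
                  tr$end > tgt$start[i])
  }
  ## windows where the depleted 26G class dominates drop hard; windows that
  ## also span an abundant background locus (e.g. a miRNA gene) do not
  core <- hit & tr$wt_rpm > 1000 & tr$dominant_length == 26L
  expect_gt(sum(core, na.rm = TRUE), 0L)
  expect_true(all(tr$log2_ratio[which(core)] < -2))
  empty <- !hit & tr$wt_rpm > 1000
  expect_true(mean(abs(tr$log2_ratio[empty]) < 0.5) > 0.95)
})

test_that("target-set overlap is symmetric", {
  a <- c("x", "y", "z")
  b <- c("y", "z", "w")
  o1 <- target_overlap(a, b)
  o2 <- target_overlap(b, a)
  expect_equal(o1$n_shared, 2L)
  expect_equal(o1$n_union, 4L)
  expect_equal(o1$n_shared, o2$n_shared)
  expect_equal(o1$n_union, o2$n_union)
  expect_equal(o1$shared, o2$shared)
})
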