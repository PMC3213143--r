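## Build a toy genome with a minus-strand guide at [100, 126) and helpers to
## plant sense-strand reads around it.
duplex_fixture <- function(seed = 401, extra_reads = NULL) {
  set.seed(seed)
  s <- random_seq(400)
  g <- toy_genome(s)
  guide <- rc(substr(s, 101, 126))          # locus [100,126), strand "-"
  reads <- data.frame(sequence = guide, count = 100L, stringsAsFactors = FALSE)
  if (!is.null(extra_reads)) reads <- rbind(reads, extra_reads)
  list(genome = g, s = s, guide = guide,
       mapped = map_reads(reads, g))
}

sense_read <- function(s, start0, end0, count) {
  data.frame(sequence = substr(s, start0 + 1L, end0), count = count,
             stringsAsFactors = FALSE)
}

test_that("a sense read at [103,122) is the passenger with insets 3 and 4", {
  fx0 <- duplex_fixture()
  fx <- duplex_fixture(extra_reads = sense_read(fx0$s, 103L, 122L, 10L))
  rec <- find_passenger(list(sequence = fx$guide, chrom = "chrT", start = 100L,
                             strand = "-"), fx$mapped)
  expect_equal(rec$passenger_start, 103L)
  expect_equal(rec$passenger_end, 122L)
  expect_equal(rec$passenger_length, 19L)
  expect_equal(rec$inset3, 3L)
  expect_equal(rec$inset5, 4L)
  expect_equal(rec$ratio, 10 / 100)
  expect_equal(rec$window_start, 86L)
  expect_equal(rec$window_end, 140L)
})

test_that("no sense reads inside the 54 nt window means no passenger, ratio 0", {
  fx0 <- duplex_fixture()
  ## a sense read just outside the window does not qualify
  fx <- duplex_fixture(extra_reads = sense_read(fx0$s, 60L, 85L, 50L))
  rec <- find_passenger(list(sequence = fx$guide, chrom = "chrT", start = 100L,
                             strand = "-"), fx$mapped)
  expect_true(is.na(rec$passenger_seq))
  expect_equal(rec$ratio, 0)
})

test_that("count ties break toward the 3 nt 3' inset", {
  fx0 <- duplex_fixture()
  fx <- duplex_fixture(extra_reads = rbind(
    sense_read(fx0$s, 103L, 122L, 10L),   # inset3 = 3
    sense_read(fx0$s, 101L, 120L, 10L)))  # inset3 = 1
  rec <- find_passenger(list(sequence = fx$guide, chrom = "chrT", start = 100L,
                             strand = "-"), fx$mapped)
  expect_equal(rec$inset3, 3L)
  ## but a more abundant candidate wins regardless of inset
  fx <- duplex_fixture(extra_reads = rbind(
    sense_read(fx0$s, 103L, 122L, 10L),
    sense_read(fx0$s, 101L, 120L, 30L)))
  rec <- find_passenger(list(sequence = fx$guide, chrom = "chrT", start = 100L,
                             strand = "-"), fx$mapped)
  expect_equal(rec$inset3, 1L)
})

test_that("an unmapped guide is an error", {
  fx <- duplex_fixture()
  expect_error(find_passenger(list(sequence = fx$guide, chrom = "chrT",
                                   start = 50L, strand = "-"), fx$mapped),
               "not mapped")
})

test_that("geometry is strand-symmetric under genome reversal", {
  fx0 <- duplex_fixture()
  fx <- duplex_fixture(extra_reads = sense_read(fx0$s, 103L, 122L, 10L))
  rec <- find_passenger(list(sequence = fx$guide, chrom = "chrT", start = 100L,
                             strand = "-"), fx$mapped)
  ## reverse-complement the whole chromosome: the guide now maps to the plus
  ## strand at the mirrored locus; geometry must be unchanged
  L <- 400L
  g2 <- toy_genome(rc(fx$s))
  reads <- data.frame(sequence = c(fx$guide, substr(fx$s, 104L, 122L)),
                      count = c(100L, 10L), stringsAsFactors = FALSE)
  m2 <- map_reads(reads, g2)
  rec2 <- find_passenger(list(sequence = fx$guide, chrom = "chrT",
                              start = L - 126L, strand = "+"), m2)
  expect_equal(rec2$passenger_length, rec$passenger_length)
  expect_equal(rec2$inset3, rec$inset3)
  expect_equal(rec2$inset5, rec$inset5)
})

test_that("candidate selection matches a brute-force window scan", {
  ds <- default_sim()
  p <- ds$profiles$wt_embryo
  loci <- p$loci
  gidx <- which(loci$class == "26G")
  set.seed(402)
  gidx <- sample(gidx, 40L)
  for (i in gidx) {
    rec <- find_passenger(list(sequence = loci$sequence[i],
                               chrom = loci$chrom[i], start = loci$start[i],
                               strand = loci$strand[i]),
                          structure(list(loci = loci), class = "mapped_library"),
                          scale = p$scale)
    opp <- if (loci$strand[i] == "+") "-" else "+"
    cand <- loci[loci$chrom == loci$chrom[i] & loci$strand == opp &
                 loci$start >= loci$start[i] - 14L &
                 loci$end <= loci$end[i] + 14L, , drop = FALSE]
    if (nrow(cand) == 0L) {
      expect_true(is.na(rec$passenger_seq))
    } else {
      expect_equal(max(cand$weight),
                   rec$passenger_rpm / p$scale$rpm_factor)
    }
  }
})

test_that("consensus over uniform records returns that geometry", {
  recs <- data.frame(passenger_seq = "X", passenger_length = 19L,
                     inset3 = 3L, inset5 = 4L, guide_rpm = 5,
                     ratio = c(0.02, 0.05, 0.9), locus_weight = 1,
                     locus_frac = 1)
  cons <- duplex_consensus(recs)
  expect_equal(cons$modal_passenger_length, 19)
  expect_equal(cons$modal_inset3, 3)
  expect_equal(cons$modal_inset5, 4)
  expect_equal(cons$median_ratio, 0.05)
  expect_equal(cons$fraction_with_passenger, 1)
  expect_error(duplex_consensus(recs[0, ]), "empty")
})

test_that("passenger fold change is 1 for identical records and errors on zero", {
  recs <- data.frame(passenger_rpm = c(1, 2, 3))
  expect_equal(passenger_foldchange(recs, recs), 1)
  expect_error(passenger_foldchange(data.frame(passenger_rpm = 0), recs),
               "zero")
})

test_that("phasing intervals come from template-coordinate 5' positions", {
  ## feature on + strand [0, 200): guides are minus-strand loci whose 5' end
  ## (genomic end - 1) maps to template positions 0, 26, 52
  ann <- mini_annotation(list(id = "f1", chrom = "chrT", start = 0L,
                              end = 200L, strand = "+", biotype = "coding"))
  tpos <- c(100L, 126L, 152L)
  loci <- data.frame(chrom = "chrT", start = tpos + 1L - 26L,
                     end = tpos + 1L, strand = "-", length = 26L,
                     first_nt = "G", rpm = 1, class = "26G",
                     stringsAsFactors = FALSE)
  p <- fake_profile(data.frame(feature_id = character(0),
                               sense_rpm = numeric(0),
                               antisense_rpm = numeric(0)), loci = loci)
  ph <- phasing_profile("f1", p, ann)
  expect_equal(ph$positions, tpos)
  expect_equal(ph$intervals, c(26L, 26L))
  expect_equal(ph$fraction_in_range, 1)
  ## single guide: no intervals, fraction reported as absent
  p1 <- fake_profile(data.frame(feature_id = character(0),
                                sense_rpm = numeric(0),
                                antisense_rpm = numeric(0)),
                     loci = loci[1, , drop = FALSE])
  ph1 <- phasing_profile("f1", p1, ann)
  expect_length(ph1$intervals, 0L)
  expect_true(is.na(ph1$fraction_in_range))
})
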