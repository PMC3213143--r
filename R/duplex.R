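## duplex_phasing module: passenger-strand inference for 26G guides, duplex
## geometry consensus, passenger abundance comparisons, and 26G phasing
## intervals. All geometry is strand-aware: inset3 is measured on the
## guide's 3' side in duplex register (the genomic left end for a
## minus-strand guide), inset5 on its 5' side.

#' Infer the passenger strand of one 26G guide
#'
#' Searches the mapped library for reads on the strand opposite the guide
#' whose loci lie fully within the guide window (guide interval extended by
#' `flank` nt on each side; 54 nt total for a 26-nt guide with the default
#' 14-nt flank). The passenger is the most abundant candidate by fractional
#' locus weight; ties are broken by |inset3 - 3| ascending, then by longer
#' read, then lexicographically by sequence. If no candidate exists the
#' passenger is absent and the ratio is 0.
#'
#' Inset geometry: `inset3` is the distance between the guide 3' terminus
#' and the nearest passenger terminus in duplex register, `inset5` likewise
#' at the guide 5' end; negative values mean the passenger protrudes past
#' the guide (recorded, not clamped).
#'
#' @param guide List or one-row data.frame with `sequence`, `chrom`,
#'   `start`, `strand` (0-based start of the guide locus).
#' @param mapped A `mapped_library` covering both strands.
#' @param flank Window flank in nt (default 14).
#' @param scale Optional scale for RPM (defaults to the mapped library's).
#' @return One-row data.frame (`duplex_record`): guide fields, window
#'   bounds, passenger sequence/locus or NA, `passenger_length`, `inset3`,
#'   `inset5`, `guide_rpm`, `passenger_rpm`, `ratio`, `locus_weight`.
#' @export
find_passenger <- function(guide, mapped, flank = 14L, scale = NULL) {
  stopifnot(inherits(mapped, "mapped_library"))
  if (is.null(scale)) scale <- library_scale(mapped)
  glen <- nchar(guide$sequence)
  gstart <- as.integer(guide$start)
  gend <- gstart + glen
  gl <- mapped$loci
  gi <- which(gl$sequence == guide$sequence & gl$chrom == guide$chrom &
              gl$start == gstart & gl$strand == guide$strand)
  if (!length(gi)) {
    stopf("guide %s is not mapped at %s:%d(%s)", guide$sequence, guide$chrom,
          gstart, guide$strand)
  }
  win_start <- gstart - flank
  win_end <- gend + flank
  opp <- if (guide$strand == "+") "-" else "+"
  cand <- gl[gl$chrom == guide$chrom & gl$strand == opp &
             gl$start >= win_start & gl$end <= win_end, , drop = FALSE]
  geometry <- function(p_start, p_end) {
    if (guide$strand == "-") {
      ## guide 3' end at genomic left (gstart), 5' at genomic right (gend)
      list(inset3 = p_start - gstart, inset5 = gend - p_end)
    } else {
      list(inset3 = gend - p_end, inset5 = p_start - gstart)
    }
  }
  rec <- data.frame(guide_seq = guide$sequence, chrom = guide$chrom,
                    guide_start = gstart, guide_end = gend,
                    guide_strand = guide$strand,
                    window_start = win_start, window_end = win_end,
                    passenger_seq = NA_character_,
                    passenger_start = NA_integer_, passenger_end = NA_integer_,
                    passenger_length = NA_integer_,
                    inset3 = NA_integer_, inset5 = NA_integer_,
                    guide_rpm = rpm(gl$weight[gi[1L]], scale),
                    passenger_rpm = 0, ratio = 0,
                    locus_weight = gl$weight[gi[1L]],
                    locus_frac = 1 / gl$n_loci[gi[1L]],
                    stringsAsFactors = FALSE)
  if (!nrow(cand)) return(rec)
  g3 <- vapply(seq_len(nrow(cand)), function(i)
    geometry(cand$start[i], cand$end[i])$inset3, 0)
  o <- order(-cand$weight, abs(g3 - 3L), -cand$length, cand$sequence)
  best <- cand[o[1L], , drop = FALSE]
  gm <- geometry(best$start, best$end)
  rec$passenger_seq <- best$sequence
  rec$passenger_start <- best$start
  rec$passenger_end <- best$end
  rec$passenger_length <- best$length
  rec$inset3 <- as.integer(gm$inset3)
  rec$inset5 <- as.integer(gm$inset5)
  rec$passenger_rpm <- rpm(best$weight, scale)
  rec$ratio <- rec$passenger_rpm / rec$guide_rpm
  rec
}

#' Duplex records for every 26G guide locus in a library
#'
#' Runs [find_passenger()] on each locus of each 26G-class sequence (one
#' record per genomic locus of a multi-mapping guide; each record carries
#' its fractional locus weight).
#'
#' @param profile A `library_profile` (supplies classified loci and scale).
#' @param flank Window flank in nt.
#' @return data.frame of duplex records (class `duplex_records`).
#' @export
duplex_records <- function(profile, flank = 14L) {
  stopifnot(inherits(profile, "library_profile"))
  loci <- profile$loci
  gidx <- which(loci$class == "26G")
  scale <- profile$scale
  mapped <- structure(list(loci = loci, seqs = NULL,
                           total_mapped_reads = scale$total_mapped_reads,
                           rpm_factor = scale$rpm_factor),
                      class = "mapped_library")
  recs <- lapply(gidx, function(i) {
    find_passenger(list(sequence = loci$sequence[i], chrom = loci$chrom[i],
                        start = loci$start[i], strand = loci$strand[i]),
                   mapped, flank = flank, scale = scale)
  })
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(guide_seq = character(0), chrom = character(0),
               guide_start = integer(0), guide_end = integer(0),
               guide_strand = character(0), window_start = integer(0),
               window_end = integer(0), passenger_seq = character(0),
               passenger_start = integer(0), passenger_end = integer(0),
               passenger_length = integer(0), inset3 = integer(0),
               inset5 = integer(0), guide_rpm = numeric(0),
               passenger_rpm = numeric(0), ratio = numeric(0),
               locus_weight = numeric(0), locus_frac = numeric(0))
  class(out) <- c("duplex_records", class(out))
  out
}

#' Consensus duplex geometry and passenger:guide ratio
#'
#' Modal passenger length and inset geometry over guides with a passenger
#' found (locus-weighted; ties toward the smaller value), the
#' locus-weighted median passenger:guide RPM ratio over guides passing the
#' RPM threshold (guides without a passenger enter with ratio 0), and the
#' fraction of threshold-passing guides with a passenger.
#'
#' @param records `duplex_records` from one library.
#' @param guide_rpm_threshold Minimum guide RPM (default 1).
#' @return List (`duplex_consensus`): `modal_passenger_length`,
#'   `modal_inset3`, `modal_inset5`, `median_ratio`,
#'   `fraction_with_passenger`, `n_guides`.
#' @export
duplex_consensus <- function(records, guide_rpm_threshold = 1) {
  if (!nrow(records)) stopf("empty duplex record set")
  pass <- records[records$guide_rpm >= guide_rpm_threshold, , drop = FALSE]
  if (!nrow(pass)) stopf("no guide passes the %g RPM threshold", guide_rpm_threshold)
  found <- pass[!is.na(pass$passenger_seq), , drop = FALSE]
  ## each guide sequence contributes one unit, split over its loci, so
  ## multi-mapping guides are not over-counted and abundant guides do not
  ## dominate the median
  structure(list(
    modal_passenger_length = weighted_mode(found$passenger_length, found$locus_frac),
    modal_inset3 = weighted_mode(found$inset3, found$locus_frac),
    modal_inset5 = weighted_mode(found$inset5, found$locus_frac),
    median_ratio = weighted_median(pass$ratio, pass$locus_frac),
    fraction_with_passenger = sum(found$locus_frac) / sum(pass$locus_frac),
    n_guides = nrow(pass)), class = "duplex_consensus")
}

#' @export
print.duplex_consensus <- function(x, ...) {
  cat(sprintf("duplex consensus over %d guide loci: passenger %g nt, inset3 %g, inset5 %g; median passenger:guide ratio %.3f; passenger found for %.1f%%\n",
              x$n_guides, x$modal_passenger_length, x$modal_inset3,
              x$modal_inset5, x$median_ratio, 100 * x$fraction_with_passenger))
  invisible(x)
}

#' Fold change of total passenger-strand abundance
#'
#' `sum(passenger RPM, mutant) / sum(passenger RPM, wild type)` over duplex
#' records from matched stages; values above 1 indicate passenger
#' stabilisation (as when the slicer Argonaute that removes the passenger is
#' lost), values far below 1 co-depletion of both duplex strands.
#'
#' @param wt_records,mutant_records `duplex_records` tables.
#' @return Scalar fold change.
#' @export
passenger_foldchange <- function(wt_records, mutant_records) {
  wt <- sum(wt_records$passenger_rpm)
  if (!isTRUE(wt > 0)) stopf("wild-type passenger RPM total is zero; fold change undefined")
  sum(mutant_records$passenger_rpm) / wt
}

#' Phasing profile of 26G guides along one feature
#'
#' Collects the 5' positions of 26G-class guide loci antisense to the
#' feature, expresses them in template (mRNA sense) coordinates ascending
#' from the feature 5' end, and reports the successive intervals and the
#' fraction lying within `interval_range` (default 23-29 nt). A feature
#' with fewer than two distinct 5' positions has an empty interval list and
#' an NA fraction.
#'
#' @param feature_id Feature id.
#' @param profile A `library_profile`.
#' @param annotation Annotation list (`features` + `exons`).
#' @param interval_range Inclusive phasing interval window.
#' @return List (`phasing_profile`): `feature_id`, `positions` (template
#'   coordinates), `intervals`, `histogram` (table), `fraction_in_range`,
#'   `n_guides`.
#' @export
phasing_profile <- function(feature_id, profile, annotation,
                            interval_range = c(23L, 29L)) {
  feat <- annotation$features
  fr <- feat[feat$feature_id == feature_id, , drop = FALSE]
  if (!nrow(fr)) stopf("unknown feature '%s'", feature_id)
  loci <- profile$loci
  ov <- locus_feature_overlaps(loci, annotation)
  ov <- ov[ov$feature_id == feature_id & !ov$sense, , drop = FALSE]
  idx <- unique(ov$locus_idx)
  idx <- idx[loci$class[idx] == "26G"]
  ## template coordinate of the guide 5' nt
  tpos <- if (fr$strand == "+") {
    (loci$end[idx] - 1L) - fr$start
  } else {
    (fr$end - 1L) - loci$start[idx]
  }
  tpos <- sort(unique(tpos))
  intervals <- if (length(tpos) > 1L) diff(tpos) else integer(0)
  frac <- if (length(intervals)) {
    mean(intervals >= interval_range[1] & intervals <= interval_range[2])
  } else NA_real_
  structure(list(feature_id = feature_id, positions = tpos,
                 intervals = intervals,
                 histogram = if (length(intervals)) table(intervals) else table(integer(0)),
                 fraction_in_range = frac, n_guides = length(tpos)),
            class = "phasing_profile")
}

#' @export
print.phasing_profile <- function(x, ...) {
  cat(sprintf("phasing of %d 26G 5' positions on %s: %d intervals, %.0f%% in range\n",
              x$n_guides, x$feature_id, length(x$intervals),
              if (is.na(x$fraction_in_range)) NA else 100 * x$fraction_in_range))
  invisible(x)
}
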