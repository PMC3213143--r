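## depletion module: mutant vs wild-type comparison. Feature-level and
## individual-siRNA depletion calls use raw RPM ratios thresholded on the
## wild type first (no pseudocount); sliding-window genome tracks use a
## declared pseudocount because windows may be empty.

## "depleted by >= 67%" is implemented as ratio <= 1/3, ties passing, hence
## the default depletion fraction is exactly 2/3.
DEFAULT_DEPLETION <- 2 / 3

#' Call siRNA-depleted target features
#'
#' A feature is called iff its wild-type antisense RPM passes
#' `rpm_threshold` and its mutant/wild-type ratio is at most
#' `1 - depletion` in every genotype in `require` (ties pass; with the
#' default `depletion = 2/3` this is "depleted by >= 67%", i.e. ratio <=
#' 1/3). With `require = character(0)` the call reduces to the wild-type
#' threshold alone.
#'
#' @param wt_profile Wild-type `library_profile`.
#' @param mutant_profiles Named list of mutant `library_profile`s (names are
#'   genotypes).
#' @param rpm_threshold Minimum wild-type feature RPM (default 10).
#' @param depletion Required depletion fraction (default 2/3).
#' @param require Genotypes that must all show depletion (default: all in
#'   `mutant_profiles`).
#' @return data.frame sorted by wild-type RPM descending: `feature_id`,
#'   `wt_rpm`, per-genotype `<genotype>_rpm` and `<genotype>_ratio`,
#'   `passes_wt_threshold`, `depleted_in` (comma-separated genotypes),
#'   `called`.
#' @export
call_targets <- function(wt_profile, mutant_profiles,
                         rpm_threshold = 10, depletion = DEFAULT_DEPLETION,
                         require = names(mutant_profiles)) {
  missing_gt <- setdiff(require, names(mutant_profiles))
  if (length(missing_gt)) {
    stopf("required genotype(s) without a profile: %s",
          paste(missing_gt, collapse = ", "))
  }
  out <- data.frame(feature_id = wt_profile$feature_rpm$feature_id,
                    wt_rpm = wt_profile$feature_rpm$antisense_rpm,
                    stringsAsFactors = FALSE)
  ratio_max <- 1 - depletion
  depleted <- matrix(FALSE, nrow(out), length(mutant_profiles),
                     dimnames = list(NULL, names(mutant_profiles)))
  for (gt in names(mutant_profiles)) {
    mp <- mutant_profiles[[gt]]$feature_rpm
    m_rpm <- mp$antisense_rpm[match(out$feature_id, mp$feature_id)]
    m_rpm[is.na(m_rpm)] <- 0
    ratio <- ifelse(out$wt_rpm > 0, m_rpm / out$wt_rpm, NA_real_)
    out[[paste0(gt, "_rpm")]] <- m_rpm
    out[[paste0(gt, "_ratio")]] <- ratio
    depleted[, gt] <- !is.na(ratio) & ratio <= ratio_max + 1e-12
  }
  out$passes_wt_threshold <- out$wt_rpm >= rpm_threshold
  out$depleted_in <- apply(depleted, 1L, function(r)
    paste(colnames(depleted)[r], collapse = ","))
  req_ok <- if (length(require)) {
    apply(depleted[, require, drop = FALSE], 1L, all)
  } else rep(TRUE, nrow(out))
  out$called <- out$passes_wt_threshold & req_ok
  out <- out[order(-out$wt_rpm, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call depleted individual 26G siRNA sequences
#'
#' As [call_targets()] but at single-sequence resolution over 26G-class
#' sequences: a guide passes iff its wild-type RPM is at least
#' `rpm_threshold` (default 1) and its mutant/wild-type ratio is at most
#' `1 - depletion` in every required genotype.
#'
#' @inheritParams call_targets
#' @param rpm_threshold Minimum wild-type per-sequence RPM (default 1).
#' @return data.frame: `sequence`, `n_loci`, `wt_rpm`, per-genotype ratios,
#'   `called`, sorted by wild-type RPM descending.
#' @export
call_sirnas <- function(wt_profile, mutant_profiles,
                        rpm_threshold = 1, depletion = DEFAULT_DEPLETION,
                        require = names(mutant_profiles)) {
  missing_gt <- setdiff(require, names(mutant_profiles))
  if (length(missing_gt)) {
    stopf("required genotype(s) without a profile: %s",
          paste(missing_gt, collapse = ", "))
  }
  g <- wt_profile$seqs[wt_profile$seqs$is_26G %in% TRUE, , drop = FALSE]
  out <- data.frame(sequence = g$sequence, n_loci = g$n_loci, wt_rpm = g$rpm,
                    stringsAsFactors = FALSE)
  ratio_max <- 1 - depletion
  ok <- rep(TRUE, nrow(out))
  for (gt in names(mutant_profiles)) {
    ms <- mutant_profiles[[gt]]$seqs
    m_rpm <- ms$rpm[match(out$sequence, ms$sequence)]
    m_rpm[is.na(m_rpm)] <- 0
    ratio <- ifelse(out$wt_rpm > 0, m_rpm / out$wt_rpm, NA_real_)
    out[[paste0(gt, "_ratio")]] <- ratio
    if (gt %in% require) {
      ok <- ok & !is.na(ratio) & ratio <= ratio_max + 1e-12
    }
  }
  out$called <- out$wt_rpm >= rpm_threshold & ok
  out <- out[order(-out$wt_rpm, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent depletion of a class or feature subset
#'
#' `100 * (1 - sum(mutant RPM) / sum(wt RPM))` over a small-RNA class, a
#' feature-ID subset, or the intersection of both (e.g. 22G-class reads
#' restricted to a published target-gene set). Negative values indicate
#' enrichment. Errors when the wild-type total is zero.
#'
#' @param wt_profile,mutant_profile `library_profile`s from the same
#'   annotation.
#' @param class Optional class label (one of "26G", "22G", "mirna",
#'   "pirna", "other").
#' @param subset Optional character vector of feature ids; restricts to
#'   reads overlapping those features (antisense for siRNA classes).
#' @return Percent depletion (scalar).
#' @export
class_depletion <- function(wt_profile, mutant_profile, class = NULL,
                            subset = NULL) {
  tot <- function(p) {
    if (is.null(class) && is.null(subset)) return(sum(p$class_rpm))
    if (is.null(subset)) return(unname(p$class_rpm[class]))
    fc <- p$feature_class_rpm
    keep <- fc$feature_id %in% subset
    if (!is.null(class)) keep <- keep & fc$class == class
    if (is.null(class)) {
      fr <- p$feature_rpm
      return(sum(fr$antisense_rpm[fr$feature_id %in% subset]))
    }
    sum(fc$rpm[keep])
  }
  wt <- tot(wt_profile)
  if (!isTRUE(wt > 0)) {
    stopf("wild-type RPM total is zero for the requested class/subset; depletion undefined")
  }
  100 * (1 - tot(mutant_profile) / wt)
}

#' Sliding-window mutant/wild-type genome track
#'
#' Sums RPM in windows (default 5 kb, stepped every 1 kb) along each
#' chromosome in both libraries and reports the log2 mutant/wild-type ratio
#' with a pseudocount added to both sides, plus the dominant read-length
#' class per window. Window starts step by exactly `step`; a final
#' truncated window covers any remainder.
#'
#' @param wt_profile,mutant_profile `library_profile`s.
#' @param width,step Window width and step (nt).
#' @param pseudocount RPM pseudocount added to numerator and denominator.
#' @return data.frame: `chrom`, `start`, `end`, `wt_rpm`, `mut_rpm`,
#'   `log2_ratio`, `dominant_length`.
#' @export
window_track <- function(wt_profile, mutant_profile, width = 5000L,
                         step = 1000L, pseudocount = 1) {
  chrom_lengths <- wt_profile$chrom_lengths
  win <- do.call(rbind, lapply(names(chrom_lengths), function(cn) {
    L <- chrom_lengths[[cn]]
    n_full <- max(0L, (L - width) %/% step) + 1L
    starts <- seq(0L, by = step, length.out = n_full)
    if ((L - width) %% step != 0 && L > width) {
      starts <- c(starts, starts[length(starts)] + step)
    }
    data.frame(chrom = cn, start = starts, end = pmin(starts + width, L),
               stringsAsFactors = FALSE)
  }))
  sum_rpm <- function(profile) {
    loci <- profile$loci
    out <- numeric(nrow(win))
    lenmass <- vector("list", nrow(win))
    if (nrow(loci)) {
      wg <- GenomicRanges::GRanges(win$chrom,
                                   IRanges::IRanges(win$start + 1L, win$end))
      lg <- GenomicRanges::GRanges(loci$chrom,
                                   IRanges::IRanges(loci$start + 1L, loci$end))
      ov <- GenomicRanges::findOverlaps(wg, lg, ignore.strand = TRUE)
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      tt <- tapply(loci$rpm[sh], qh, sum)
      out[as.integer(names(tt))] <- tt
      for (w in unique(qh)) {
        idx <- sh[qh == w]
        lenmass[[w]] <- tapply(loci$rpm[idx], loci$length[idx], sum)
      }
    }
    list(rpm = out, lenmass = lenmass)
  }
  wtv <- sum_rpm(wt_profile)
  mtv <- sum_rpm(mutant_profile)
  dom <- vapply(seq_len(nrow(win)), function(w) {
    lm <- wtv$lenmass[[w]]
    mm <- mtv$lenmass[[w]]
    all_len <- union(names(lm), names(mm))
    if (!length(all_len)) return(NA_integer_)
    tot <- vapply(all_len, function(l) {
      s <- 0
      if (!is.null(lm) && l %in% names(lm)) s <- s + lm[[l]]
      if (!is.null(mm) && l %in% names(mm)) s <- s + mm[[l]]
      s
    }, 0)
    as.integer(all_len[which.max(tot)])
  }, 0L)
  win$wt_rpm <- wtv$rpm
  win$mut_rpm <- mtv$rpm
  win$log2_ratio <- log2((win$mut_rpm + pseudocount) / (win$wt_rpm + pseudocount))
  win$dominant_length <- dom
  rownames(win) <- NULL
  win
}

#' Overlap between two called target sets
#'
#' @param a,b Character vectors of feature ids (or `call_targets()` outputs,
#'   in which case called features are used).
#' @return List with `n_a`, `n_b`, `n_shared`, `n_union`, `shared`.
#' @export
target_overlap <- function(a, b) {
  ids <- function(x) if (is.data.frame(x)) x$feature_id[x$called] else as.character(x)
  a <- unique(ids(a)); b <- unique(ids(b))
  shared <- intersect(a, b)
  list(n_a = length(a), n_b = length(b), n_shared = length(shared),
       n_union = length(union(a, b)), shared = sort(shared))
}
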