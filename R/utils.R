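#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules. Coordinates are 0-based half-open
## everywhere inside the package; conversion to 1-based happens only at the
## GFF3/Biostrings boundaries.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character vectors
#' @noRd
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

#' Random DNA string of length n (uses the current RNG stream)
#' @noRd
random_dna <- function(n, prob = NULL) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

#' Deterministic substream seed derived from a root seed and a label.
#'
#' Small stable string hash so that adding one library never perturbs the
#' stream of another. Kept below 2^31 - 1.
#' @noRd
derive_seed <- function(root_seed, label) {
  codes <- utf8ToInt(label)
  h <- as.double(root_seed %% 2147483647L)
  for (cc in codes) {
    h <- (h * 131 + cc) %% 2147483629
  }
  as.integer(h)
}

#' Weighted mode; ties broken toward the smallest value.
#' @noRd
weighted_mode <- function(x, w = rep(1, length(x))) {
  if (length(x) == 0L) return(NA_real_)
  tot <- tapply(w, x, sum)
  vals <- as.numeric(names(tot))
  vals[order(-as.numeric(tot), vals)][1L]
}

#' Weighted median (lower weighted median; with unit weights this is the
#' usual lower median for even n).
#' @noRd
weighted_median <- function(x, w = rep(1, length(x))) {
  if (length(x) == 0L) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

#' Extract a 0-based half-open genomic slice as a character string.
#' @noRd
genome_slice <- function(genome, chrom, start0, end0) {
  as.character(Biostrings::subseq(genome[[chrom]], start = start0 + 1L, width = end0 - start0))
}

#' @noRd
first_nt <- function(seq) substr(seq, 1L, 1L)

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
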