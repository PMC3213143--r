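## mapper module: exact, full-length placement of collapsed reads on both
## genome strands, fractional multi-mapper weighting, RPM normalisation.
## Matching uses a Biostrings PDict per read length; no mismatches or gaps.

#' Map collapsed reads to a genome by exact matching
#'
#' Every reported locus is an exact full-length match of the read sequence
#' to the plus strand, or of its reverse complement to the plus strand
#' (recorded as a minus-strand locus). The count of a sequence matching
#' `n_loci` positions is divided equally over its loci (fractional
#' multi-mapper weighting), so summed locus weights conserve the mapped
#' read total exactly. Reads with no locus are dropped and reported.
#'
#' @param reads data.frame with columns `sequence`, `count` (e.g. from
#'   [read_collapsed_library()] or a simulated library).
#' @param genome A [Biostrings::DNAStringSet] or an `annotated_genome`.
#' @return Object of class `mapped_library`: list with
#'   \describe{
#'     \item{seqs}{per-sequence table: `sequence`, `count`, `n_loci`,
#'       `weight` (= count / n_loci)}
#'     \item{loci}{per-locus table: `sequence`, `chrom`, `start`, `end`
#'       (0-based half-open), `strand`, `length`, `first_nt`, `count`,
#'       `n_loci`, `weight`}
#'     \item{unmapped}{data.frame of unmapped sequences and counts}
#'     \item{total_mapped_reads}{sum of counts of mapped sequences}
#'     \item{rpm_factor}{1e6 / total_mapped_reads}
#'     \item{chrom_lengths}{named chromosome lengths}
#'   }
#' @export
map_reads <- function(reads, genome) {
  if (inherits(genome, "annotated_genome")) genome <- genome$genome
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (nrow(reads)) {
    reads <- stats::aggregate(list(count = reads$count),
                              by = list(sequence = reads$sequence), FUN = sum)
  }
  seqs <- reads$sequence
  counts <- reads$count
  hits <- vector("list", length(seqs))
  if (length(seqs)) {
    rc <- revcomp(seqs)
    for (L in sort(unique(nchar(seqs)))) {
      grp <- which(nchar(seqs) == L)
      fwd <- Biostrings::DNAStringSet(seqs[grp])
      rev <- Biostrings::DNAStringSet(rc[grp])
      pd_f <- Biostrings::PDict(fwd)
      pd_r <- Biostrings::PDict(rev)
      for (cn in names(genome)) {
        subject <- genome[[cn]]
        mf <- Biostrings::matchPDict(pd_f, subject)
        mr <- Biostrings::matchPDict(pd_r, subject)
        sf <- Biostrings::startIndex(mf)
        sr <- Biostrings::startIndex(mr)
        for (j in seq_along(grp)) {
          i <- grp[j]
          if (length(sf[[j]])) {
            hits[[i]] <- rbind(hits[[i]], data.frame(
              chrom = cn, start = sf[[j]] - 1L, strand = "+",
              stringsAsFactors = FALSE))
          }
          if (length(sr[[j]])) {
            hits[[i]] <- rbind(hits[[i]], data.frame(
              chrom = cn, start = sr[[j]] - 1L, strand = "-",
              stringsAsFactors = FALSE))
          }
        }
      }
    }
  }
  n_loci <- vapply(hits, function(h) if (is.null(h)) 0L else nrow(h), 0L)
  mapped_idx <- which(n_loci > 0L)
  loci <- NULL
  if (length(mapped_idx)) {
    loci <- do.call(rbind, lapply(mapped_idx, function(i) {
      h <- hits[[i]]
      L <- nchar(seqs[i])
      data.frame(sequence = seqs[i], chrom = h$chrom, start = h$start,
                 end = h$start + L, strand = h$strand, length = L,
                 first_nt = first_nt(seqs[i]), count = counts[i],
                 n_loci = n_loci[i], weight = counts[i] / n_loci[i],
                 stringsAsFactors = FALSE)
    }))
    loci <- loci[order(loci$chrom, loci$start, loci$strand, loci$sequence), ,
                 drop = FALSE]
    rownames(loci) <- NULL
  } else {
    loci <- data.frame(sequence = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), length = integer(0),
                       first_nt = character(0), count = numeric(0),
                       n_loci = integer(0), weight = numeric(0))
  }
  total <- sum(counts[mapped_idx])
  structure(list(
    seqs = data.frame(sequence = seqs[mapped_idx], count = counts[mapped_idx],
                      n_loci = n_loci[mapped_idx],
                      weight = counts[mapped_idx] / pmax(n_loci[mapped_idx], 1L),
                      stringsAsFactors = FALSE),
    loci = loci,
    unmapped = data.frame(sequence = seqs[n_loci == 0L],
                          count = counts[n_loci == 0L], stringsAsFactors = FALSE),
    total_mapped_reads = total,
    rpm_factor = if (total > 0) 1e6 / total else NA_real_,
    chrom_lengths = stats::setNames(Biostrings::width(genome), names(genome))),
    class = "mapped_library")
}

#' Library-size scale of a mapped library
#'
#' `total_mapped_reads` counts read copies (the summed counts of all mapped
#' sequences), not distinct sequences, so RPM reflects sequencing depth.
#'
#' @param mapped A `mapped_library`.
#' @return List with `total_mapped_reads` and `rpm_factor`.
#' @export
library_scale <- function(mapped) {
  stopifnot(inherits(mapped, "mapped_library"))
  if (mapped$total_mapped_reads <= 0) {
    stopf("library has zero mapped reads; RPM undefined")
  }
  list(total_mapped_reads = mapped$total_mapped_reads,
       rpm_factor = mapped$rpm_factor)
}

#' Reads-per-million normalisation
#'
#' @param weighted_count Numeric vector of (possibly fractional) read counts.
#' @param scale A scale from [library_scale()] or a `mapped_library`.
#' @return `weighted_count * 1e6 / total_mapped_reads`.
#' @export
rpm <- function(weighted_count, scale) {
  if (inherits(scale, "mapped_library")) scale <- library_scale(scale)
  if (is.null(scale$total_mapped_reads) || scale$total_mapped_reads <= 0) {
    stopf("library has zero mapped reads; RPM undefined")
  }
  weighted_count * 1e6 / scale$total_mapped_reads
}

#' @export
print.mapped_library <- function(x, ...) {
  cat(sprintf("mapped_library: %d sequences at %d loci; %s mapped reads (%d sequences unmapped)\n",
              nrow(x$seqs), nrow(x$loci),
              format(x$total_mapped_reads, big.mark = ","), nrow(x$unmapped)))
  invisible(x)
}
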