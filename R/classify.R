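## classify module: length x 5'-nt profiles, class assignment of each
## (read, locus) pair against the annotation, per-feature antisense/sense
## counts. Class definitions: 26G = 26 nt, 5'G, antisense overlap with a
## coding/pseudogene/transposon exon; 22G likewise at 22 nt; miRNA = sense
## overlap with a miRNA feature; piRNA (21U) = 21 nt, 5'U, sense within a
## piRNA locus. Precedence mirna > pirna > 26G > 22G > other.

SIRNA_CLASSES <- c("26G", "22G", "mirna", "pirna", "other")
TARGET_BIOTYPES <- c("coding", "pseudogene", "transposon")

## Overlaps of mapped loci with annotated exons (>= 1 nt of the exonic
## span). Returns a data.frame: locus_idx, feature_id, biotype, sense.
#' @noRd
locus_feature_overlaps <- function(loci, annotation) {
  ex <- annotation$exons
  feat <- annotation$features
  if (!nrow(loci) || !nrow(ex)) {
    return(data.frame(locus_idx = integer(0), feature_id = character(0),
                      biotype = character(0), sense = logical(0)))
  }
  lg <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start + 1L, loci$end))
  eg <- GenomicRanges::GRanges(ex$chrom,
                               IRanges::IRanges(ex$start + 1L, ex$end))
  ov <- GenomicRanges::findOverlaps(lg, eg, ignore.strand = TRUE)
  li <- S4Vectors::queryHits(ov)
  ei <- S4Vectors::subjectHits(ov)
  fid <- ex$feature_id[ei]
  out <- data.frame(locus_idx = li, feature_id = fid,
                    biotype = feat$biotype[match(fid, feat$feature_id)],
                    sense = loci$strand[li] == ex$strand[ei],
                    stringsAsFactors = FALSE)
  ## a read spanning two exons of one feature overlaps both exon rows;
  ## count the (locus, feature) pair once
  unique(out)
}

#' Classify mapped read loci against an annotation
#'
#' Assigns exactly one small-RNA class label to every (read, locus) pair:
#' `mirna` (sense overlap with a miRNA feature), `pirna` (21 nt, 5'U, sense
#' overlap with a piRNA locus), `26G` (26 nt, 5'G, antisense overlap with a
#' coding/pseudogene/transposon exon), `22G` (likewise at 22 nt), else
#' `other`, with precedence in that order.
#'
#' @param loci The `loci` data.frame of a `mapped_library` (or a compatible
#'   data.frame with `chrom`, `start`, `end`, `strand`, `length`,
#'   `first_nt`).
#' @param annotation A list with `features` and `exons` (e.g. from
#'   [read_annotation()] or an `annotated_genome`).
#' @return Character vector of class labels, one per locus row.
#' @export
classify_loci <- function(loci, annotation) {
  n <- nrow(loci)
  cls <- rep("other", n)
  if (!n) return(cls)
  ov <- locus_feature_overlaps(loci, annotation)
  if (!nrow(ov)) return(cls)
  hit_of <- function(cond) unique(ov$locus_idx[cond])
  i_mirna <- hit_of(ov$biotype == "mirna" & ov$sense)
  i_pirna <- hit_of(ov$biotype == "pirna_locus" & ov$sense)
  i_anti <- hit_of(ov$biotype %in% TARGET_BIOTYPES & !ov$sense)
  is26 <- loci$length == 26L & loci$first_nt == "G"
  is22 <- loci$length == 22L & loci$first_nt == "G"
  is21u <- loci$length == 21L & loci$first_nt %in% c("T", "U")
  cls[intersect(which(is22), i_anti)] <- "22G"
  cls[intersect(which(is26), i_anti)] <- "26G"
  cls[intersect(which(is21u), i_pirna)] <- "pirna"
  cls[i_mirna] <- "mirna"
  cls
}

#' Build a library profile
#'
#' Computes the length x 5'-nucleotide RPM matrix (rows 18-28 nt, columns
#' A/C/G/U), per-class RPM totals, per-feature sense and antisense RPM over
#' exonic spans, and per-(feature, class) antisense RPM. All counts use
#' fractional multi-mapper locus weights, so the matrix total equals 1e6 RPM
#' and class totals conserve it.
#'
#' @param mapped A `mapped_library` from [map_reads()].
#' @param annotation Annotation list (`features` + `exons`).
#' @param genotype,stage Optional labels stored in the profile.
#' @param size_range Row range of the length matrix.
#' @return Object of class `library_profile` with elements `matrix`,
#'   `class_rpm`, `feature_rpm` (feature_id, sense_rpm, antisense_rpm),
#'   `feature_class_rpm` (feature_id, class, rpm; antisense/sense per class
#'   definition), `seqs` (per-sequence total RPM with class flags), `loci`
#'   (the locus table with `rpm` and `class` columns), `scale`, `genotype`,
#'   `stage`, `chrom_lengths`.
#' @export
library_profile <- function(mapped, annotation, genotype = NA_character_,
                            stage = NA_character_, size_range = c(18L, 28L)) {
  stopifnot(inherits(mapped, "mapped_library"))
  scale <- library_scale(mapped)
  loci <- mapped$loci
  loci$rpm <- rpm(loci$weight, scale)
  loci$class <- classify_loci(loci, annotation)

  lens <- seq(size_range[1], size_range[2])
  nts <- c("A", "C", "G", "U")
  mat <- matrix(0, nrow = length(lens), ncol = 4L,
                dimnames = list(as.character(lens), nts))
  if (nrow(loci)) {
    nt <- chartr("T", "U", loci$first_nt)
    agg <- stats::aggregate(list(rpm = loci$rpm),
                            by = list(len = loci$length, nt = nt), FUN = sum)
    keep <- agg$len %in% lens & agg$nt %in% nts
    agg <- agg[keep, , drop = FALSE]
    mat[cbind(as.character(agg$len), agg$nt)] <- agg$rpm
  }

  class_rpm <- stats::setNames(numeric(length(SIRNA_CLASSES)), SIRNA_CLASSES)
  if (nrow(loci)) {
    tt <- tapply(loci$rpm, factor(loci$class, levels = SIRNA_CLASSES), sum,
                 default = 0)
    class_rpm[names(tt)] <- tt
  }

  ov <- locus_feature_overlaps(loci, annotation)
  feat_ids <- annotation$features$feature_id
  feature_rpm <- data.frame(feature_id = feat_ids,
                            sense_rpm = 0, antisense_rpm = 0,
                            stringsAsFactors = FALSE)
  fc <- NULL
  if (nrow(ov)) {
    ov$rpm <- loci$rpm[ov$locus_idx]
    ov$class <- loci$class[ov$locus_idx]
    a <- stats::aggregate(list(rpm = ov$rpm),
                          by = list(feature_id = ov$feature_id, sense = ov$sense),
                          FUN = sum)
    for (i in seq_len(nrow(a))) {
      r <- match(a$feature_id[i], feature_rpm$feature_id)
      col <- if (a$sense[i]) "sense_rpm" else "antisense_rpm"
      feature_rpm[r, col] <- feature_rpm[r, col] + a$rpm[i]
    }
    anti <- ov[!ov$sense | ov$class %in% c("mirna", "pirna"), , drop = FALSE]
    if (nrow(anti)) {
      fc <- stats::aggregate(list(rpm = anti$rpm),
                             by = list(feature_id = anti$feature_id,
                                       class = anti$class), FUN = sum)
    }
  }
  if (is.null(fc)) {
    fc <- data.frame(feature_id = character(0), class = character(0),
                     rpm = numeric(0))
  }

  seqs <- mapped$seqs
  seqs$rpm <- rpm(seqs$count, scale)
  seqs$length <- nchar(seqs$sequence)
  seqs$first_nt <- first_nt(seqs$sequence)
  if (nrow(seqs)) {
    cls26 <- tapply(loci$class == "26G", loci$sequence, any)
    seqs$is_26G <- unname(cls26[seqs$sequence])
  } else {
    seqs$is_26G <- logical(0)
  }

  structure(list(matrix = mat, class_rpm = class_rpm,
                 feature_rpm = feature_rpm, feature_class_rpm = fc,
                 seqs = seqs, loci = loci, scale = scale,
                 genotype = genotype, stage = stage,
                 chrom_lengths = mapped$chrom_lengths),
            class = "library_profile")
}

#' @export
print.library_profile <- function(x, ...) {
  cat(sprintf("library_profile%s: %s mapped reads\n",
              if (!is.na(x$genotype)) sprintf(" [%s %s]", x$genotype, x$stage) else "",
              format(x$scale$total_mapped_reads, big.mark = ",")))
  cat("class RPM:\n")
  print(round(x$class_rpm, 1))
  invisible(x)
}

#' Template nucleotide opposite a guide 5' end
#'
#' For a mapped antisense guide, returns the sense-strand (template, mRNA)
#' base paired with the guide's 5' nucleotide, read from the genome: for a
#' minus-strand locus this is the plus-strand base under the rightmost
#' position; for a plus-strand locus (guide antisense to a minus-strand
#' feature) the complement of the base at the leftmost position. A 5'G
#' guide therefore templates a C. Errors if the locus is not antisense to
#' any annotated coding/pseudogene/transposon exon.
#'
#' @param locus One-row data.frame (or list) with `chrom`, `start`, `end`,
#'   `strand`.
#' @param genome [Biostrings::DNAStringSet] or `annotated_genome`.
#' @param annotation Annotation list with `features` and `exons`.
#' @return Single character: the template base (one of A/C/G/T).
#' @export
five_prime_template <- function(locus, genome, annotation) {
  if (inherits(genome, "annotated_genome")) genome <- genome$genome
  ldf <- data.frame(chrom = locus$chrom, start = locus$start, end = locus$end,
                    strand = locus$strand, stringsAsFactors = FALSE)
  ov <- locus_feature_overlaps(ldf, annotation)
  ov <- ov[!ov$sense & ov$biotype %in% TARGET_BIOTYPES, , drop = FALSE]
  if (!nrow(ov)) {
    stopf("locus %s:%d-%d(%s) is not antisense to any annotated feature",
          locus$chrom, locus$start, locus$end, locus$strand)
  }
  if (locus$strand == "-") {
    ## guide 5' pairs with the plus-strand (sense) base at end-1
    genome_slice(genome, locus$chrom, locus$end - 1L, locus$end)
  } else {
    ## feature on minus strand: template base is the complement at start
    complement_base(genome_slice(genome, locus$chrom, locus$start, locus$start + 1L))
  }
}

#' Length profile of reads over a feature subset
#'
#' RPM by read length restricted to loci overlapping the exonic span of the
#' given features in the requested orientation. Used e.g. to ask which size
#' class dominates the small RNAs antisense to a target-gene set.
#'
#' @param profile A `library_profile`.
#' @param feature_ids Character vector of feature ids.
#' @param annotation Annotation list.
#' @param orientation `"antisense"`, `"sense"` or `"both"`.
#' @return Named numeric vector: RPM per read length (names are lengths).
#' @export
feature_length_profile <- function(profile, feature_ids, annotation,
                                   orientation = c("antisense", "sense", "both")) {
  orientation <- match.arg(orientation)
  loci <- profile$loci
  ov <- locus_feature_overlaps(loci, annotation)
  ov <- ov[ov$feature_id %in% feature_ids, , drop = FALSE]
  if (orientation == "antisense") ov <- ov[!ov$sense, , drop = FALSE]
  if (orientation == "sense") ov <- ov[ov$sense, , drop = FALSE]
  idx <- unique(ov$locus_idx)
  if (!length(idx)) return(stats::setNames(numeric(0), character(0)))
  tt <- tapply(loci$rpm[idx], loci$length[idx], sum)
  stats::setNames(as.numeric(tt), names(tt))
}
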