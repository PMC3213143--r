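## smallrna_io module: every on-disk format the pipeline touches, with strict
## validation. Internal coordinates are 0-based half-open; GFF3 (1-based
## inclusive) and Biostrings (1-based) conversions happen only here.

#' Read a collapsed small-RNA library from FASTA
#'
#' Collapsed FASTA holds one record per distinct sequence with the read count
#' in the header (`>id_xCOUNT`). Sequences are upper-cased and U is
#' normalised to T on read-in; records with characters outside ACGT(U) are
#' rejected with an error. Records outside the size-selection window
#' (default 18-28 nt, matching small-RNA library construction) are dropped
#' and counted in the `discarded` attribute.
#'
#' @param path FASTA file path.
#' @param size_range Length-2 integer vector of retained read lengths
#'   (inclusive).
#' @return data.frame with columns `read_id`, `sequence`, `count`; attribute
#'   `discarded` holds the number of size-filtered records. An empty file
#'   yields an empty data.frame.
#' @export
read_collapsed_library <- function(path, size_range = c(18L, 28L)) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  empty <- data.frame(read_id = character(0), sequence = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (file.size(path) == 0L) {
    attr(empty, "discarded") <- 0L
    return(empty)
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) {
    attr(empty, "discarded") <- 0L
    return(empty)
  }
  headers <- names(recs)
  m <- regmatches(headers, regexec("^(\\S+)_x(\\d+)\\s*$", headers))
  bad <- which(vapply(m, length, 0L) != 3L)
  if (length(bad)) {
    stopf("malformed collapsed-FASTA header (expected '>id_xCOUNT') at record %d: '%s'",
          bad[1L], headers[bad[1L]])
  }
  ids <- vapply(m, `[`, "", 2L)
  counts <- as.integer(vapply(m, `[`, "", 3L))
  if (any(counts < 1L)) stopf("read counts must be >= 1")
  seqs <- toupper(chartr("u", "t", as.character(recs)))
  seqs <- chartr("U", "T", seqs)
  ok <- grepl("^[ACGT]+$", seqs)
  if (!all(ok)) {
    stopf("sequence with characters outside ACGT/U at record %d ('%s')",
          which(!ok)[1L], ids[which(!ok)[1L]])
  }
  len <- nchar(seqs)
  keep <- len >= size_range[1] & len <= size_range[2]
  out <- data.frame(read_id = ids[keep], sequence = seqs[keep],
                    count = counts[keep], stringsAsFactors = FALSE)
  attr(out, "discarded") <- sum(!keep)
  out
}

#' Write a collapsed small-RNA library as FASTA
#'
#' @param reads data.frame with columns `sequence` and `count` (a `read_id`
#'   column is used if present, else ids are generated).
#' @param path Output path.
#' @export
write_collapsed_library <- function(reads, path) {
  ids <- if ("read_id" %in% names(reads)) reads$read_id
         else sprintf("read%d", seq_len(nrow(reads)))
  lines <- character(2L * nrow(reads))
  if (nrow(reads)) {
    lines[c(TRUE, FALSE)] <- sprintf(">%s_x%d", ids, reads$count)
    lines[c(FALSE, TRUE)] <- reads$sequence
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a genome FASTA
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_genome_fasta
#' @param genome A [Biostrings::DNAStringSet].
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a feature annotation from GFF3
#'
#' Expects gene rows (any of types gene/pseudogene/transposable_element/
#' miRNA/piRNA) carrying `ID` and `biotype` attributes (plus optional
#' `sim_class` ground-truth labels) and exon rows carrying `Parent`.
#' GFF3 1-based inclusive coordinates are converted to the package's
#' internal 0-based half-open convention. Exons are validated to lie within
#' their chromosome (when `##sequence-region` pragmas or `chrom_lengths` are
#' available), to be sorted and non-overlapping within a feature.
#'
#' @param path GFF3 path.
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   bounds validation.
#' @return List with data.frames `features` (feature_id, chrom, start, end,
#'   strand, biotype, class) and `exons` (feature_id, chrom, start, end,
#'   strand), 0-based half-open.
#' @export
read_annotation <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.null(chrom_lengths)) {
    sl <- GenomeInfoDb_seqlengths(GenomicRanges::seqinfo(gr))
    if (!all(is.na(sl))) {
      chrom_lengths <- sl
    } else {
      ## rtracklayer does not surface ##sequence-region pragmas as seqlengths
      prag <- grep("^##sequence-region", readLines(path), value = TRUE)
      if (length(prag)) {
        parts <- strsplit(trimws(prag), "\\s+")
        chrom_lengths <- stats::setNames(
          vapply(parts, function(p) as.integer(p[4]), 0L),
          vapply(parts, function(p) p[2], ""))
      }
    }
  }
  md <- S4Vectors::mcols(gr)
  is_exon <- md$type == "exon"
  genes <- gr[!is_exon]
  exons <- gr[is_exon]
  feat <- data.frame(
    feature_id = as.character(md$ID[!is_exon]),
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes) - 1L,
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    biotype = as.character(md$biotype[!is_exon]),
    class = if ("sim_class" %in% names(md)) as.character(md$sim_class[!is_exon])
            else NA_character_,
    stringsAsFactors = FALSE)
  parent <- md$Parent[is_exon]
  parent <- vapply(as.list(parent), function(p) as.character(p)[1L], "")
  exdf <- data.frame(
    feature_id = parent,
    chrom = as.character(GenomicRanges::seqnames(exons)),
    start = GenomicRanges::start(exons) - 1L,
    end = GenomicRanges::end(exons),
    strand = as.character(GenomicRanges::strand(exons)),
    stringsAsFactors = FALSE)
  exdf <- exdf[order(match(exdf$feature_id, feat$feature_id), exdf$start), ,
               drop = FALSE]
  rownames(exdf) <- NULL
  if (!is.null(chrom_lengths)) {
    bad <- exdf$end > chrom_lengths[exdf$chrom] | exdf$start < 0L
    if (any(bad, na.rm = TRUE)) {
      stopf("exon outside chromosome bounds for feature '%s'",
            exdf$feature_id[which(bad)[1L]])
    }
  }
  for (fid in unique(exdf$feature_id)) {
    e <- exdf[exdf$feature_id == fid, , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
      stopf("overlapping exons in feature '%s'", fid)
    }
  }
  list(features = feat, exons = exdf)
}

## GenomeInfoDb is pulled in by GenomicRanges; avoid a hard import for one
## accessor.
#' @noRd
GenomeInfoDb_seqlengths <- function(x) {
  getExportedValue("GenomeInfoDb", "seqlengths")(x)
}

#' Write a feature annotation as GFF3
#'
#' Inverse of [read_annotation()]; internal 0-based half-open intervals are
#' written as 1-based inclusive GFF3 with `biotype` and (when present)
#' `sim_class` attributes on gene rows and `Parent` on exon rows.
#'
#' @param features,exons Data frames as returned by [read_annotation()] (an
#'   `annotated_genome` also provides them).
#' @param path Output path.
#' @param chrom_lengths Optional named chromosome lengths, written as
#'   sequence-region pragmas.
#' @export
write_annotation <- function(features, exons, path, chrom_lengths = NULL) {
  type_of <- function(bt) {
    c(coding = "gene", pseudogene = "pseudogene",
      transposon = "transposable_element", mirna = "miRNA",
      pirna_locus = "piRNA")[bt]
  }
  g1 <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand)
  S4Vectors::mcols(g1)$type <- unname(type_of(features$biotype))
  S4Vectors::mcols(g1)$ID <- features$feature_id
  S4Vectors::mcols(g1)$biotype <- features$biotype
  if (!is.null(features$class)) S4Vectors::mcols(g1)$sim_class <- features$class
  g2 <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    strand = exons$strand)
  S4Vectors::mcols(g2)$type <- "exon"
  S4Vectors::mcols(g2)$Parent <- exons$feature_id
  gr <- suppressWarnings(c(g1, g2))
  if (!is.null(chrom_lengths)) {
    GenomeInfoDb_set_seqlengths(gr) <- chrom_lengths
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @noRd
`GenomeInfoDb_set_seqlengths<-` <- function(x, value) {
  f <- getExportedValue("GenomeInfoDb", "seqlengths<-")
  f(x, value[getExportedValue("GenomeInfoDb", "seqlevels")(x)])
}

#' Write mapped read loci as BED6
#'
#' BED is 0-based half-open, matching the internal convention; the name
#' column carries the read sequence and the score column the fractional
#' per-locus weight (count / number of loci).
#'
#' @param mapped A `mapped_library` from [map_reads()].
#' @param path Output path.
#' @export
write_bed <- function(mapped, path) {
  loci <- mapped$loci
  df <- data.frame(chrom = loci$chrom, start = loci$start, end = loci$end,
                   name = loci$sequence,
                   score = format(loci$weight, trim = TRUE, digits = 10),
                   strand = loci$strand)
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a complete simulated dataset to a directory
#'
#' Emits the genome FASTA, the GFF3 annotation (with ground-truth class
#' attributes), one collapsed FASTA per library, the ground-truth site and
#' count tables as TSV, and the configuration as YAML.
#'
#' @param genome An `annotated_genome`.
#' @param sim A `sim_libraries` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(genome, sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(genome$genome, file.path(dir, "genome.fa"))
  write_annotation(genome$features, genome$exons,
                   file.path(dir, "annotation.gff3"),
                   chrom_lengths = genome$chrom_lengths)
  for (nm in names(sim$libraries)) {
    write_collapsed_library(sim$libraries[[nm]],
                            file.path(dir, paste0("lib_", nm, ".fa")))
  }
  utils::write.table(sim$truth$sites, file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$counts, file.path(dir, "truth_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg$depletion_factors <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  utils::write.table(sim$config$depletion_factors,
                     file.path(dir, "depletion_factors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
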