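## homology module: sequence identity among target genes (with flanks),
## longest perfect stretches, proximity, single-linkage grouping, and the
## random-gene background. Local alignment scoring: match +1, mismatch -2,
## gap open -5, gap extend -2 (BLAST-like semantics without BLAST).

#' Gene sequence with flanking DNA
#'
#' Genomic span from (gene start - flank) to (gene end + flank), clipped at
#' the chromosome edges, returned in sense-strand orientation (reverse
#' complement for minus-strand genes). The `clipped` attribute flags edge
#' clipping.
#'
#' @param feature One-row data.frame (or list) with `chrom`, `start`,
#'   `end`, `strand` (0-based half-open), e.g. a row of
#'   `annotation$features`.
#' @param genome [Biostrings::DNAStringSet] or `annotated_genome`.
#' @param flank Flank size in nt (default 500).
#' @return Character sequence; attribute `clipped` (logical).
#' @export
flanked_sequence <- function(feature, genome, flank = 500L) {
  if (inherits(genome, "annotated_genome")) genome <- genome$genome
  chrom_len <- length(genome[[feature$chrom]])
  s <- max(0L, feature$start - flank)
  e <- min(chrom_len, feature$end + flank)
  seq <- genome_slice(genome, feature$chrom, s, e)
  if (feature$strand == "-") seq <- revcomp(seq)
  attr(seq, "clipped") <- (feature$start - flank < 0L) ||
    (feature$end + flank > chrom_len)
  seq
}

#' Longest common substring of two sequences
#'
#' Exact longest perfect-identity stretch shared by two sequences, found by
#' binary search over the shared-k-mer predicate (a length-k common
#' substring exists iff the k-mer sets intersect). Equivalent to the
#' dynamic-programming longest-common-substring but fast enough for
#' kilobase flanked genes.
#'
#' @param a,b Character sequences.
#' @return Integer length of the longest exact shared stretch.
#' @export
longest_common_substring <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) return(0L)
  kmers <- function(s, k, n) unique(substring(s, 1:(n - k + 1L), k:n))
  has_common <- function(k) {
    length(intersect(kmers(a, k, na), kmers(b, k, nb))) > 0L
  }
  lo <- 0L; hi <- min(na, nb)
  while (lo < hi) {
    mid <- as.integer((lo + hi + 1L) %/% 2L)
    if (has_common(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Pairwise identity and perfect-stretch statistics
#'
#' Aligns two sequences locally (match +1, mismatch -2, gap open -5, gap
#' extend -2) and reports percent identity over the aligned columns
#' (including gap columns), the alignment length, the exact longest common
#' substring, and optionally a proximity flag.
#'
#' @param seq_a,seq_b Non-empty character sequences.
#' @param a,b Optional feature ids recorded in the edge.
#' @param compute_identity Set FALSE to skip the alignment (stretch only);
#'   identity is then NA. Used for fast screening where the stretch
#'   criterion alone decides.
#' @return One-row data.frame (`homology_edge`): `a`, `b`,
#'   `percent_identity`, `aligned_length`, `longest_exact_stretch`.
#' @export
pair_identity <- function(seq_a, seq_b, a = "a", b = "b",
                          compute_identity = TRUE) {
  if (!nchar(seq_a) || !nchar(seq_b)) stopf("sequences must be non-empty")
  stretch <- longest_common_substring(seq_a, seq_b)
  pid <- NA_real_; alen <- NA_integer_
  if (compute_identity) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                    baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    alen <- Biostrings::nchar(aln)
    pid <- Biostrings::pid(aln, type = "PID1")
  }
  data.frame(a = a, b = b, percent_identity = pid,
             aligned_length = as.integer(alen),
             longest_exact_stretch = as.integer(stretch),
             stringsAsFactors = FALSE)
}

#' Does an edge qualify as homology?
#'
#' TRUE iff percent identity is strictly above `identity_threshold` (82
#' exactly does not qualify), the longest perfect stretch is at least
#' `stretch_threshold` nt (27 qualifies), and the alignment covers at least
#' `min_aligned` nt.
#'
#' @param edge A `pair_identity()` row (or data.frame of rows).
#' @param identity_threshold Percent identity lower bound (strict).
#' @param stretch_threshold Perfect-stretch lower bound (inclusive).
#' @param min_aligned Minimum alignment length (inclusive).
#' @return Logical vector.
#' @export
qualifying_edge <- function(edge, identity_threshold = 82,
                            stretch_threshold = 27L, min_aligned = 100L) {
  !is.na(edge$percent_identity) &
    edge$percent_identity > identity_threshold &
    edge$longest_exact_stretch >= stretch_threshold &
    edge$aligned_length >= min_aligned
}

#' All pairwise homology edges among a feature set
#'
#' Flanked sequences are extracted once; the exact-stretch screen runs on
#' every pair and the local alignment only where requested (always, or only
#' when the stretch passes, for speed). Adds the proximity flag: same
#' chromosome and flank-free gene-span gap strictly below `proximity_gap`.
#'
#' @param feature_ids Character vector of feature ids.
#' @param annotation Annotation list (`features` + `exons`).
#' @param genome Genome.
#' @param flank Flank used for [flanked_sequence()]; set 0 to disable.
#' @param stretch_threshold Passed to the screen when `screen = TRUE`.
#' @param screen If TRUE, skip the alignment for pairs failing the stretch
#'   criterion (their identity is NA and they can never qualify).
#' @param proximity_gap Proximity threshold in nt (strict <).
#' @return data.frame of edges with `proximal` flag.
#' @export
homology_edges <- function(feature_ids, annotation, genome, flank = 500L,
                           stretch_threshold = 27L, screen = FALSE,
                           proximity_gap = 5000L) {
  feat <- annotation$features
  rows <- feat[match(feature_ids, feat$feature_id), , drop = FALSE]
  if (anyNA(rows$feature_id)) stopf("unknown feature id(s)")
  seqs <- vapply(seq_len(nrow(rows)), function(i)
    as.character(flanked_sequence(rows[i, ], genome, flank = flank)), "")
  n <- length(feature_ids)
  out <- list()
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq((i + 1L), n)) {
      stretch <- longest_common_substring(seqs[i], seqs[j])
      do_aln <- !screen || stretch >= stretch_threshold
      e <- pair_identity(seqs[i], seqs[j], a = feature_ids[i], b = feature_ids[j],
                         compute_identity = do_aln)
      e$longest_exact_stretch <- as.integer(stretch)
      same_chrom <- rows$chrom[i] == rows$chrom[j]
      gp <- max(rows$start[i], rows$start[j]) - min(rows$end[i], rows$end[j])
      e$proximal <- same_chrom && gp < proximity_gap
      out[[length(out) + 1L]] <- e
    }
  }
  if (!length(out)) {
    return(data.frame(a = character(0), b = character(0),
                      percent_identity = numeric(0), aligned_length = integer(0),
                      longest_exact_stretch = integer(0), proximal = logical(0)))
  }
  do.call(rbind, out)
}

#' Single-linkage homology groups
#'
#' Connected components of the qualifying-edge graph: any two features
#' joined by a chain of qualifying edges fall in one group. Features with no
#' qualifying edge form no group.
#'
#' @param feature_ids Features considered.
#' @param edges Edge table from [homology_edges()] / [pair_identity()].
#' @param ... Thresholds passed to [qualifying_edge()].
#' @return List of character vectors (groups of >= 2 members), sorted by
#'   decreasing size then first member.
#' @export
homology_groups <- function(feature_ids, edges, ...) {
  q <- edges[qualifying_edge(edges, ...), , drop = FALSE]
  parent <- stats::setNames(seq_along(feature_ids), feature_ids)
  find <- function(x) {
    while (parent[[x]] != match(x, feature_ids)) {
      x <- feature_ids[parent[[x]]]
    }
    x
  }
  for (k in seq_len(nrow(q))) {
    ra <- find(q$a[k]); rb <- find(q$b[k])
    if (ra != rb) parent[[rb]] <- match(ra, feature_ids)
  }
  roots <- vapply(feature_ids, find, "")
  comps <- split(feature_ids, roots)
  comps <- comps[vapply(comps, length, 0L) >= 2L]
  comps <- lapply(comps, sort)
  comps <- unname(comps[order(-vapply(comps, length, 0L),
                              vapply(comps, `[`, "", 1L))])
  comps
}

#' Fraction of random background genes with a qualifying homology partner
#'
#' Repeatedly samples `n_genes` non-target genes whose combined (flanked)
#' sequence length matches the target set's within 10%, computes qualifying
#' edges within each sample, and returns the mean fraction of sampled genes
#' with at least one qualifying partner. This is the null expectation
#' against which the target set's homology excess is judged.
#'
#' @param annotation Annotation list.
#' @param genome Genome.
#' @param target_ids Target feature ids (excluded from sampling; their
#'   combined flanked length is the matching constraint).
#' @param n_genes Genes per draw (default: as many as needed to match the
#'   target combined length given the mean candidate gene length).
#' @param n_draws Number of draws (default 10).
#' @param seed Integer seed.
#' @param exclude_ids Further ids excluded from the sampling pool (e.g.
#'   known duplicate families when ground truth is available).
#' @param flank,... Passed to [homology_edges()]/[qualifying_edge()].
#' @return Mean fraction in \[0,1\].
#' @export
background_fraction <- function(annotation, genome, target_ids,
                                n_genes = NULL, n_draws = 10L, seed = 1L,
                                exclude_ids = character(0), flank = 500L, ...) {
  feat <- annotation$features
  pool <- feat[feat$biotype %in% TARGET_BIOTYPES &
               !(feat$feature_id %in% c(target_ids, exclude_ids)), , drop = FALSE]
  tgt <- feat[feat$feature_id %in% target_ids, , drop = FALSE]
  target_len <- sum(tgt$end - tgt$start + 2L * flank)
  pool_len <- pool$end - pool$start + 2L * flank
  if (is.null(n_genes)) n_genes <- max(2L, round(target_len / mean(pool_len)))
  if (nrow(pool) < n_genes) {
    stopf("insufficient non-target genes (%d) for draws of %d", nrow(pool), n_genes)
  }
  set.seed(seed)
  fracs <- numeric(n_draws)
  for (d in seq_len(n_draws)) {
    best <- NULL; best_diff <- Inf
    for (try in 1:200) {
      idx <- sample.int(nrow(pool), n_genes)
      diff <- abs(sum(pool_len[idx]) - target_len) / target_len
      if (diff < best_diff) { best <- idx; best_diff <- diff }
      if (diff <= 0.1) break
    }
    if (best_diff > 0.1) {
      warning(sprintf("draw %d: closest combined-length match is %.0f%% off target",
                      d, 100 * best_diff))
    }
    ids <- pool$feature_id[best]
    ed <- homology_edges(ids, annotation, genome, flank = flank, screen = TRUE)
    q <- ed[qualifying_edge(ed, ...), , drop = FALSE]
    with_partner <- unique(c(q$a, q$b))
    fracs[d] <- length(with_partner) / n_genes
  }
  mean(fracs)
}

#' Gene-structure summary of a feature set versus the whole annotation
#'
#' @param feature_ids Non-empty set of feature ids.
#' @param annotation Annotation list (features need `n_exons` or exon rows).
#' @return List with `set` and `genome`, each holding `median_exons` and
#'   `mean_length` (gene span, nt), plus `n` features summarised.
#' @export
gene_structure_stats <- function(feature_ids, annotation) {
  if (!length(feature_ids)) stopf("empty feature set")
  feat <- annotation$features
  exon_counts <- if ("n_exons" %in% names(feat)) {
    stats::setNames(feat$n_exons, feat$feature_id)
  } else {
    tt <- table(annotation$exons$feature_id)
    stats::setNames(as.integer(tt), names(tt))[feat$feature_id]
  }
  lens <- stats::setNames(feat$end - feat$start, feat$feature_id)
  genes <- feat$feature_id[feat$biotype %in% TARGET_BIOTYPES]
  sel <- intersect(feature_ids, names(lens))
  if (!length(sel)) stopf("no known features in the set")
  list(set = list(median_exons = stats::median(exon_counts[sel]),
                  mean_length = mean(lens[sel]), n = length(sel)),
       genome = list(median_exons = stats::median(exon_counts[genes]),
                     mean_length = mean(lens[genes]), n = length(genes)))
}
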