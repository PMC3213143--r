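## simdata module: toy genome + annotation + genotype/stage collapsed
## small-RNA libraries with ground truth, so every downstream stage is
## testable without external data.

#' Default per-(genotype, stage, class) depletion factors
#'
#' Multiplicative factors applied to wild-type species counts when a mutant
#' library is emitted. Wild type is always 1. The defaults encode the
#' class-level suppression magnitudes the analysis is designed to recover:
#' ERGO-1-class 26G siRNAs reduced to 0.002 of wild type in `eri-6`, `eri-7`
#' and `eri-1` embryos and to 0.04 in `ergo-1` embryos; ERGO-1-class 22G
#' siRNAs reduced to 0.1 in `eri-7` (embryo and adult); the 26G passenger
#' strand co-depleted with its guide in `eri` mutants but stabilised 2-fold
#' in `ergo-1`; ALG-3/4-class and CSR-1-class siRNAs, miRNAs and piRNAs
#' unaffected everywhere.
#'
#' @return A data.frame with columns `genotype`, `stage`, `class`, `factor`.
#' @export
default_depletion_factors <- function() {
  rows <- list(
    list("eri-6",  "embryo", "g26_ergo1", 0.002),
    list("eri-7",  "embryo", "g26_ergo1", 0.002),
    list("eri-1",  "embryo", "g26_ergo1", 0.002),
    list("ergo-1", "embryo", "g26_ergo1", 0.04),
    list("eri-6",  "embryo", "passenger", 0.002),
    list("eri-7",  "embryo", "passenger", 0.002),
    list("eri-1",  "embryo", "passenger", 0.002),
    list("ergo-1", "embryo", "passenger", 2.0),
    list("eri-6",  "embryo", "g22_ergo1", 0.1),
    list("eri-7",  "embryo", "g22_ergo1", 0.1),
    list("eri-1",  "embryo", "g22_ergo1", 0.1),
    list("eri-7",  "adult",  "g22_ergo1", 0.1)
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(genotype = r[[1]], stage = r[[2]], class = r[[3]],
               factor = r[[4]], stringsAsFactors = FALSE)
  }))
}

#' Default per-stage class composition of a wild-type library
#'
#' Fractions of `library_depth` allocated to each simulated read class.
#' Embryo libraries are dominated by the oocyte/embryo 26G pathway plus
#' miRNA/piRNA/CSR-1 background; adult libraries by 22G secondary siRNAs and
#' the sperm-specific ALG-3/4 26G class. Each stage sums to 1.
#'
#' @return Named list with numeric vectors `embryo` and `adult`.
#' @export
default_class_mix <- function() {
  list(
    embryo = c(g26_ergo1 = 0.10, g22_ergo1 = 0.04, g22_csr1 = 0.30,
               mirna = 0.36, pirna = 0.20),
    adult  = c(g26_alg34 = 0.10, g22_ergo1 = 0.03, g22_alg34 = 0.22,
               g22_csr1 = 0.30, mirna = 0.23, pirna = 0.12)
  )
}

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [simulate_genome()] and [simulate_libraries()]. Defaults define the study
#' conditions: 26-nt 5'G guide siRNAs phased at 23-29 nt intervals antisense
#' to target-gene exons, a 19-nt sense passenger inset 3 nt from the guide
#' 3' end and 4 nt from its 5' end, a population-median passenger:guide
#' ratio of 0.05, duplicated target-gene families diverged at 5%
#' substitutions per site, and class depletion factors per
#' [default_depletion_factors()].
#'
#' @param seed Integer root seed; one global stream drives genome
#'   construction, per-library substreams are derived from (genotype, stage).
#' @param n_chromosomes,chrom_length Toy genome dimensions (nt).
#' @param n_ergo1_targets,n_alg34_targets,n_csr1_targets Numbers of genes in
#'   each siRNA target class.
#' @param n_background Plain genes carrying no small RNAs (sampling pool for
#'   homology background estimation).
#' @param n_mirna,n_pirna Numbers of miRNA genes and piRNA (21U) loci.
#' @param duplication List: `n_families`, `copies_per_family`, `divergence`
#'   (substitution rate per nt in \[0,1\]). Duplicated families are drawn
#'   from the ERGO-1 target set; the first copy is the unmutated progenitor.
#' @param guide_length Guide siRNA length (nt).
#' @param phasing_interval Integer range (min, max) of successive guide
#'   5'-end spacings along the template.
#' @param duplex_geometry List: `passenger_length`, `inset3`, `inset5`,
#'   `jitter_prob` (probability that inset5 is jittered by +/-1 nt).
#' @param passenger_guide_ratio_median Median of the per-guide
#'   passenger:guide count ratio.
#' @param ratio_sdlog sdlog of the log-normal passenger:guide ratio.
#' @param abundance_model List `mu`, `sigma`: log-normal parameters for
#'   per-species relative abundance within a class.
#' @param depletion_factors Data frame per [default_depletion_factors()].
#' @param class_mix Per-stage class fractions per [default_class_mix()].
#' @param library_depth Wild-type reads per library (mutant libraries are
#'   thinned from wild-type counts by the depletion factors).
#' @param genotypes Named list mapping stage to the genotype roster.
#' @param target_gene,background_gene Gene-structure models: `n_exons`
#'   (candidate counts), `exon_length` and `intron_length` ranges (nt).
#' @param mirna_length,pirna_length Locus lengths (nt).
#' @param proximal_fraction Fraction of duplicated-family copies placed
#'   within 5 kb of another member of their family.
#' @param min_gene_gap Minimum spacing between placed features (nt). The
#'   default 1 kb keeps the 0.5 kb homology flanks of unrelated neighbours
#'   from sharing genomic sequence.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_chromosomes = 3L,
                       chrom_length = 100000L,
                       n_ergo1_targets = 12L,
                       n_alg34_targets = 6L,
                       n_csr1_targets = 6L,
                       n_background = 30L,
                       n_mirna = 8L,
                       n_pirna = 8L,
                       duplication = list(n_families = 3L, copies_per_family = 3L,
                                          divergence = 0.05),
                       guide_length = 26L,
                       phasing_interval = c(23L, 29L),
                       duplex_geometry = list(passenger_length = 19L, inset3 = 3L,
                                              inset5 = 4L, jitter_prob = 0),
                       passenger_guide_ratio_median = 0.05,
                       ratio_sdlog = 1.5,
                       abundance_model = list(mu = log(20), sigma = 1),
                       depletion_factors = default_depletion_factors(),
                       class_mix = default_class_mix(),
                       library_depth = 200000L,
                       genotypes = list(embryo = c("wt", "eri-6", "eri-7", "eri-1", "ergo-1"),
                                        adult = c("wt", "eri-7")),
                       target_gene = list(n_exons = 2:4, exon_length = c(300L, 500L),
                                          intron_length = c(40L, 80L)),
                       background_gene = list(n_exons = 4:6, exon_length = c(450L, 650L),
                                              intron_length = c(40L, 80L)),
                       mirna_length = 80L,
                       pirna_length = 30L,
                       proximal_fraction = 0.3,
                       min_gene_gap = 1000L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_ergo1_targets = as.integer(n_ergo1_targets),
              n_alg34_targets = as.integer(n_alg34_targets),
              n_csr1_targets = as.integer(n_csr1_targets),
              n_background = as.integer(n_background),
              n_mirna = as.integer(n_mirna), n_pirna = as.integer(n_pirna),
              duplication = duplication, guide_length = as.integer(guide_length),
              phasing_interval = as.integer(phasing_interval),
              duplex_geometry = duplex_geometry,
              passenger_guide_ratio_median = passenger_guide_ratio_median,
              ratio_sdlog = ratio_sdlog,
              abundance_model = abundance_model,
              depletion_factors = depletion_factors,
              class_mix = class_mix,
              library_depth = as.integer(library_depth),
              genotypes = genotypes,
              target_gene = target_gene, background_gene = background_gene,
              mirna_length = as.integer(mirna_length),
              pirna_length = as.integer(pirna_length),
              proximal_fraction = proximal_fraction,
              min_gene_gap = as.integer(min_gene_gap))
  ## the stock factor table covers the full genotype vocabulary; restrict it
  ## to the configured roster so wild-type-only or reduced rosters are valid
  if (missing(depletion_factors)) {
    roster <- unique(unlist(cfg$genotypes))
    cfg$depletion_factors <-
      cfg$depletion_factors[cfg$depletion_factors$genotype %in% roster, ,
                            drop = FALSE]
  }
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  g <- cfg$duplex_geometry
  if (g$jitter_prob == 0 &&
      cfg$guide_length != g$passenger_length + g$inset3 + g$inset5) {
    stopf("exact duplex geometry requires guide_length == passenger_length + inset3 + inset5 (%d != %d + %d + %d)",
          cfg$guide_length, g$passenger_length, g$inset3, g$inset5)
  }
  pi <- cfg$phasing_interval
  if (length(pi) != 2L || pi[1] < 1L || pi[1] > pi[2]) {
    stopf("phasing_interval must be (min, max) with 1 <= min <= max")
  }
  df <- cfg$depletion_factors
  if (any(df$factor < 0)) stopf("depletion factors must be >= 0")
  if (any(df$genotype == "wt" & df$factor != 1)) {
    stopf("wild-type depletion factors must equal 1")
  }
  roster <- unique(unlist(cfg$genotypes))
  unknown <- setdiff(unique(df$genotype), c(roster, "wt"))
  if (length(unknown)) {
    stopf("depletion_factors references genotype(s) not in the roster: %s",
          paste(unknown, collapse = ", "))
  }
  for (st in names(cfg$class_mix)) {
    if (abs(sum(cfg$class_mix[[st]]) - 1) > 1e-8) {
      stopf("class_mix for stage '%s' must sum to 1", st)
    }
  }
  dup <- cfg$duplication
  if (dup$n_families * dup$copies_per_family > cfg$n_ergo1_targets) {
    stopf("duplication demands %d family copies but only %d ergo1 targets requested",
          dup$n_families * dup$copies_per_family, cfg$n_ergo1_targets)
  }
  if (dup$divergence < 0 || dup$divergence > 1) stopf("divergence must be in [0,1]")
  invisible(cfg)
}

## ---- gene design in sense (template) coordinates --------------------------

#' @noRd
design_gene_structure <- function(model) {
  cand <- model$n_exons
  n_ex <- if (length(cand) == 1L) cand else sample(cand, 1L)
  ex_len <- sample(seq(model$exon_length[1], model$exon_length[2]), n_ex, replace = TRUE)
  in_len <- if (n_ex > 1L) {
    sample(seq(model$intron_length[1], model$intron_length[2]), n_ex - 1L, replace = TRUE)
  } else integer(0)
  starts <- cumsum(c(0L, ex_len[-n_ex] + in_len))
  data.frame(start = starts, end = starts + ex_len)
}

## Plan phased guide sites and sparse 22G sites within exons; coordinates are
## gene-relative sense positions of the covered template span.
#' @noRd
plan_walk_sites <- function(exons, read_len, step_range, offset_max = 6L) {
  out <- integer(0)
  for (i in seq_len(nrow(exons))) {
    a <- exons$start[i] + sample.int(offset_max + 1L, 1L) - 1L
    while (a + read_len <= exons$end[i]) {
      out <- c(out, a)
      a <- a + sample(seq(step_range[1], step_range[2]), 1L)
    }
  }
  out
}

## One gene "design": structure + site plan + sense sequence with planted
## 5'-anchor bases (template C under a guide/22G 5' end so the read starts
## with G; template T under a sense miRNA/piRNA 5' end so the read starts
## with U).
#' @noRd
design_gene <- function(cfg, kind) {
  gl <- cfg$guide_length
  geom <- cfg$duplex_geometry
  if (kind == "mirna") {
    len <- cfg$mirna_length
    exons <- data.frame(start = 0L, end = len)
    sites <- data.frame(type = "mirna", a = 20L, len = 22L)
  } else if (kind == "pirna") {
    len <- cfg$pirna_length
    exons <- data.frame(start = 0L, end = len)
    sites <- data.frame(type = "pirna", a = 4L, len = 21L)
  } else {
    model <- if (kind %in% c("ergo1", "alg34")) cfg$target_gene else cfg$background_gene
    exons <- design_gene_structure(model)
    len <- exons$end[nrow(exons)]
    sites <- NULL
    if (kind %in% c("ergo1", "alg34")) {
      a26 <- plan_walk_sites(exons, gl, cfg$phasing_interval)
      if (length(a26)) sites <- data.frame(type = "g26", a = a26, len = gl)
    }
    if (kind %in% c("ergo1", "alg34", "csr1")) {
      a22 <- plan_walk_sites(exons, 22L, c(60L, 120L), offset_max = 30L)
      if (length(a22)) sites <- rbind(sites, data.frame(type = "g22", a = a22, len = 22L))
    }
    if (is.null(sites)) sites <- data.frame(type = character(0), a = integer(0), len = integer(0))
  }
  seq <- random_dna(len)
  ## anchors: antisense reads (g26/g22) need template C opposite their 5' nt;
  ## sense reads (mirna/pirna) need template T at their 5' nt
  anchors <- integer(0)
  if (nrow(sites)) {
    anti <- sites$type %in% c("g26", "g22")
    pos <- ifelse(anti, sites$a + sites$len - 1L, sites$a)
    base <- ifelse(anti, "C", "T")
    for (i in seq_along(pos)) substr(seq, pos[i] + 1L, pos[i] + 1L) <- base[i]
    anchors <- pos
  }
  list(exons = exons, sites = sites, seq = seq, anchors = anchors, length = len)
}

#' @noRd
mutate_copy <- function(seq, divergence, protected) {
  if (divergence <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < divergence
  hit[protected + 1L] <- FALSE
  idx <- which(hit)
  if (length(idx)) {
    alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
    pick <- sample.int(3L, length(idx), replace = TRUE)
    chars[idx] <- alt[cbind(match(chars[idx], rownames(alt)), pick)]
  }
  paste(chars, collapse = "")
}

## ---- genome assembly ------------------------------------------------------

#' Simulate a toy annotated genome
#'
#' Generates random chromosome sequences and places non-overlapping gene
#' features on random strands: ERGO-1 26G target genes (including duplicated
#' families copied from a progenitor and mutated at the configured divergence
#' rate), ALG-3/4 26G target genes, CSR-1 22G genes, plain background genes,
#' miRNA genes and piRNA loci. Guide and secondary-siRNA sites are planned
#' along target exons during construction, with the template base under each
#' planned 5' end planted (C for antisense 5'G reads, T for sense 5'U reads)
#' and protected from family-copy mutation, so emitted reads are exact
#' genomic matches with the correct 5' nucleotide. A configured fraction of
#' family copies is placed within 5 kb of another member of its family.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `annotated_genome`: list with `genome`
#'   (a [Biostrings::DNAStringSet]), `features`, `exons` and `sites` data
#'   frames (0-based half-open coordinates), `chrom_lengths`, and the
#'   `config` used.
#' @export
simulate_genome <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "genome"))
  chrom_names <- paste0("chr", as.character(utils::as.roman(seq_len(config$n_chromosomes))))
  chrom_len <- stats::setNames(rep(config$chrom_length, config$n_chromosomes), chrom_names)
  chrom_seq <- lapply(chrom_names, function(cn) {
    sample(DNA_BASES, config$chrom_length, replace = TRUE)
  })
  names(chrom_seq) <- chrom_names

  occupied <- stats::setNames(vector("list", length(chrom_names)), chrom_names)
  gap <- config$min_gene_gap
  is_free <- function(cn, s, e) {
    occ <- occupied[[cn]]
    if (is.null(occ) || !nrow(occ)) return(TRUE)
    !any(s < occ$end + gap & e > occ$start - gap)
  }
  place <- function(len, near = NULL) {
    if (!is.null(near)) {
      for (i in 1:50) {
        g <- sample(seq(gap, 4800L), 1L)
        s <- near$end + g
        e <- s + len
        if (e <= chrom_len[near$chrom] && is_free(near$chrom, s, e)) {
          occupied[[near$chrom]] <<- rbind(occupied[[near$chrom]],
                                           data.frame(start = s, end = e))
          return(list(chrom = near$chrom, start = s, end = e))
        }
      }
    }
    for (i in 1:500) {
      cn <- sample(chrom_names, 1L)
      if (chrom_len[cn] <= len) next
      s <- sample.int(chrom_len[cn] - len, 1L) - 1L
      e <- s + len
      if (is_free(cn, s, e)) {
        occupied[[cn]] <<- rbind(occupied[[cn]], data.frame(start = s, end = e))
        return(list(chrom = cn, start = s, end = e))
      }
    }
    stopf("capacity exceeded: cannot place a feature of %d nt on %d chromosome(s) of %d nt",
          len, config$n_chromosomes, config$chrom_length)
  }

  features <- list(); exons <- list(); sites <- list()
  geom <- config$duplex_geometry
  gl <- config$guide_length
  add_instance <- function(id, design, kind, class, biotype, family, near = NULL) {
    loc <- place(design$length, near = near)
    strand <- sample(c("+", "-"), 1L)
    gseq <- if (strand == "+") design$seq else revcomp(design$seq)
    chrom_seq[[loc$chrom]][(loc$start + 1L):loc$end] <<- strsplit(gseq, "", fixed = TRUE)[[1]]
    features[[length(features) + 1L]] <<- data.frame(
      feature_id = id, chrom = loc$chrom, start = loc$start, end = loc$end,
      strand = strand, biotype = biotype, class = class, family = family,
      n_exons = nrow(design$exons), length = design$length,
      stringsAsFactors = FALSE)
    ## sense [a,b) -> genomic: '+' [start+a, start+b); '-' [end-b, end-a)
    s2g <- function(a, b) {
      if (strand == "+") cbind(loc$start + a, loc$start + b)
      else cbind(loc$end - b, loc$end - a)
    }
    eg <- s2g(design$exons$start, design$exons$end)
    exons[[length(exons) + 1L]] <<- data.frame(
      feature_id = id, chrom = loc$chrom, start = eg[, 1], end = eg[, 2],
      strand = strand, stringsAsFactors = FALSE)
    if (nrow(design$sites)) {
      st <- design$sites
      plan_prefix <- if (!is.na(family)) family else id
      plan_id <- sprintf("%s_s%03d", plan_prefix, seq_len(nrow(st)))
      anti <- st$type %in% c("g26", "g22")
      sg <- s2g(st$a, st$a + st$len)
      read_strand <- ifelse(anti, setdiff(c("+", "-"), strand), strand)
      mix_class <- ifelse(st$type == "g26", paste0("g26_", class),
                   ifelse(st$type == "g22", paste0("g22_", class), st$type))
      mix_class <- sub("_ergo1_target$", "_ergo1", mix_class)
      pass <- st$type == "g26"
      pa <- st$a + geom$inset3
      pb <- st$a + st$len - geom$inset5
      pg <- s2g(pa, pb)
      sites[[length(sites) + 1L]] <<- data.frame(
        feature_id = id, plan_id = plan_id, type = st$type, mix_class = mix_class,
        chrom = loc$chrom, start = sg[, 1], end = sg[, 2],
        strand = read_strand, gene_strand = strand,
        t5 = ifelse(anti, st$a + st$len - 1L, st$a),
        pass_start = ifelse(pass, pg[, 1], NA_integer_),
        pass_end = ifelse(pass, pg[, 2], NA_integer_),
        pass_strand = ifelse(pass, strand, NA_character_),
        stringsAsFactors = FALSE)
    }
  }

  target_biotype <- function() sample(c("coding", "pseudogene", "transposon"), 1L,
                                      prob = c(0.6, 0.3, 0.1))
  dup <- config$duplication
  n_family_copies <- dup$n_families * dup$copies_per_family
  fam_count <- 0L
  ## duplicated families among the ergo1 targets; first copy = progenitor
  for (f in seq_len(dup$n_families)) {
    progenitor <- design_gene(config, "ergo1")
    bt <- target_biotype()
    prev <- NULL
    for (k in seq_len(dup$copies_per_family)) {
      fam_count <- fam_count + 1L
      d <- progenitor
      if (k > 1L) d$seq <- mutate_copy(progenitor$seq, dup$divergence, progenitor$anchors)
      id <- sprintf("etgt%02d", fam_count)
      near <- NULL
      if (k > 1L && stats::runif(1) < config$proximal_fraction && !is.null(prev)) near <- prev
      add_instance(id, d, "ergo1", "ergo1_target", bt, sprintf("fam%02d", f), near = near)
      fr <- features[[length(features)]]
      prev <- list(chrom = fr$chrom, end = fr$end)
    }
  }
  for (k in seq_len(config$n_ergo1_targets - n_family_copies)) {
    fam_count <- fam_count + 1L
    add_instance(sprintf("etgt%02d", fam_count), design_gene(config, "ergo1"),
                 "ergo1", "ergo1_target", target_biotype(), NA_character_)
  }
  for (k in seq_len(config$n_alg34_targets)) {
    add_instance(sprintf("atgt%02d", k), design_gene(config, "alg34"),
                 "alg34", "alg34_target", "coding", NA_character_)
  }
  for (k in seq_len(config$n_csr1_targets)) {
    add_instance(sprintf("csrg%02d", k), design_gene(config, "csr1"),
                 "csr1", "csr1_wago", "coding", NA_character_)
  }
  for (k in seq_len(config$n_background)) {
    add_instance(sprintf("bkgg%02d", k), design_gene(config, "background"),
                 "background", NA_character_, "coding", NA_character_)
  }
  for (k in seq_len(config$n_mirna)) {
    add_instance(sprintf("mir%02d", k), design_gene(config, "mirna"),
                 "mirna", "mirna", "mirna", NA_character_)
  }
  for (k in seq_len(config$n_pirna)) {
    add_instance(sprintf("21ur%02d", k), design_gene(config, "pirna"),
                 "pirna", "pirna", "pirna_locus", NA_character_)
  }

  features <- do.call(rbind, features)
  exons <- do.call(rbind, exons)
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(feature_id = character(0), plan_id = character(0),
               type = character(0),
               mix_class = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               gene_strand = character(0), t5 = integer(0),
               pass_start = integer(0), pass_end = integer(0),
               pass_strand = character(0))
  ## normalise mix_class labels for non-ergo1 site classes
  sites$mix_class <- sub("_alg34_target$", "_alg34", sites$mix_class)
  sites$mix_class <- sub("_csr1_wago$", "_csr1", sites$mix_class)
  if (nrow(sites)) sites$site_id <- sprintf("site%04d", seq_len(nrow(sites)))
  genome <- Biostrings::DNAStringSet(vapply(chrom_seq, paste, "", collapse = ""))
  names(genome) <- chrom_names
  structure(list(genome = genome, features = features, exons = exons,
                 sites = sites, chrom_lengths = chrom_len, config = config),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome: %d chromosome(s), %d nt total; %d features (%d siRNA sites)\n",
              length(x$genome), sum(x$chrom_lengths), nrow(x$features), nrow(x$sites)))
  print(table(x$features$class, useNA = "ifany"))
  invisible(x)
}

## ---- library emission -----------------------------------------------------

## integer allocation of `total` over `weights`, largest-remainder rule
#' @noRd
allocate_counts <- function(total, weights) {
  if (length(weights) == 0L) return(integer(0))
  if (sum(weights) <= 0) weights <- rep(1, length(weights))
  x <- total * weights / sum(weights)
  fl <- floor(x)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0L) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

#' @noRd
lookup_factor <- function(factors, genotype, stage, class) {
  hit <- factors$genotype == genotype & factors$stage == stage & factors$class == class
  if (any(hit)) factors$factor[which(hit)[1L]] else 1
}

#' Emit collapsed small-RNA libraries and the ground-truth table
#'
#' For each configured (genotype, stage) the generator emits a collapsed
#' read library: guide 26G reads at the planned phased sites, their sense
#' passenger reads with the configured inset geometry, 22G secondary reads,
#' and miRNA/piRNA background. Wild-type counts are a largest-remainder
#' allocation of `library_depth` over classes (per the stage class mix) and
#' over species within a class (log-normal weights), so each wild-type
#' library total equals `library_depth` exactly; passenger reads are emitted
#' on top of the guide allocation at per-guide ratios whose population
#' median is `passenger_guide_ratio_median`. Mutant counts are Poisson
#' thinnings/scalings of the wild-type counts by the per-(genotype, stage,
#' class) depletion factors, so class-level mutant/wild-type count ratios
#' are unbiased estimates of the configured factors.
#'
#' @param genome An `annotated_genome` from [simulate_genome()].
#' @param config The same [sim_config()] used to build the genome (defaults
#'   to the one stored in `genome`).
#' @return An object of class `sim_libraries`: list with `libraries` (named
#'   list of data.frames `sequence`, `count`; names `<genotype>_<stage>`)
#'   and `truth` (list of `features`, `sites` with per-stage wild-type
#'   counts, and `counts`, a long data.frame of per-library per-site guide
#'   and passenger counts).
#' @export
simulate_libraries <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "annotated_genome"))
  validate_sim_config(config)
  sites <- genome$sites
  geom <- config$duplex_geometry
  ## root stream: per-species latent abundances and passenger ratios
  set.seed(derive_seed(config$seed, "abundance"))
  ## per-site abundances and passenger:guide ratios are properties of the
  ## duplex-processing site and are shared by homologous sites of a
  ## duplicated family (one draw per site plan): homologous loci are
  ## processed equivalently, and only sequence divergence distinguishes
  ## family copies
  plan <- unique(sites$plan_id)
  plan_weight <- stats::setNames(
    stats::rlnorm(length(plan), config$abundance_model$mu,
                  config$abundance_model$sigma), plan)
  plan_ratio <- stats::setNames(
    stats::rlnorm(length(plan), log(config$passenger_guide_ratio_median),
                  config$ratio_sdlog), plan)
  sites$weight <- plan_weight[sites$plan_id]
  sites$pass_ratio <- ifelse(sites$type == "g26",
                             plan_ratio[sites$plan_id], NA_real_)
  ## read sequences (guides/22G antisense, mirna/pirna sense)
  sites$sequence <- site_sequences(genome$genome, sites$chrom, sites$start,
                                   sites$end, sites$strand)

  ## per-stage wild-type counts
  for (st in names(config$class_mix)) {
    mix <- config$class_mix[[st]]
    class_budget <- allocate_counts(config$library_depth, mix)
    names(class_budget) <- names(mix)
    cnt <- integer(nrow(sites))
    for (cl in names(mix)) {
      idx <- which(sites$mix_class == cl)
      if (length(idx)) cnt[idx] <- allocate_counts(class_budget[[cl]], sites$weight[idx])
    }
    sites[[paste0("wt_", st)]] <- cnt
  }
  ## wild-type passenger counts: stochastic rounding of guide_count * ratio
  ## (floor plus a Bernoulli remainder), so E[passenger] = count * ratio
  ## exactly, matching the Poisson thinning used for mutant libraries
  set.seed(derive_seed(config$seed, "passenger-rounding"))
  for (st in names(config$class_mix)) {
    g <- sites$type == "g26"
    x <- sites[[paste0("wt_", st)]] * sites$pass_ratio
    cnt <- floor(x) + (stats::runif(nrow(sites)) < (x - floor(x)))
    sites[[paste0("wt_pass_", st)]] <- ifelse(g, as.integer(cnt), NA_integer_)
  }

  libraries <- list(); truth_counts <- list()
  for (st in names(config$genotypes)) {
    if (!st %in% names(config$class_mix)) {
      stopf("no class_mix defined for stage '%s'", st)
    }
    for (gt in config$genotypes[[st]]) {
      lib_name <- paste(gt, st, sep = "_")
      set.seed(derive_seed(config$seed, paste0("lib:", lib_name)))
      wt_cnt <- sites[[paste0("wt_", st)]]
      wt_pass <- sites[[paste0("wt_pass_", st)]]
      if (gt == "wt") {
        cnt <- wt_cnt
        pass_cnt <- wt_pass
      } else {
        fac <- vapply(sites$mix_class, function(cl)
          lookup_factor(config$depletion_factors, gt, st, cl), 0)
        cnt <- stats::rpois(nrow(sites), wt_cnt * fac)
        pfac <- lookup_factor(config$depletion_factors, gt, st, "passenger")
        pass_cnt <- ifelse(sites$type == "g26",
                           stats::rpois(nrow(sites), ifelse(is.na(wt_pass), 0, wt_pass) * pfac),
                           NA_integer_)
      }
      ## inset5 jitter on the passenger 3' end (sense high side)
      jit <- integer(nrow(sites))
      if (geom$jitter_prob > 0) {
        g <- which(sites$type == "g26")
        jit[g] <- sample(c(-1L, 0L, 1L), length(g), replace = TRUE,
                         prob = c(geom$jitter_prob / 2, 1 - geom$jitter_prob,
                                  geom$jitter_prob / 2))
      }
      ## assemble reads
      keep <- which(cnt > 0L)
      seqs <- sites$sequence[keep]
      cts <- cnt[keep]
      pkeep <- which(!is.na(pass_cnt) & pass_cnt > 0L)
      if (length(pkeep)) {
        ps <- sites$pass_start[pkeep]
        pe <- sites$pass_end[pkeep]
        ## jitter j shifts inset5: sense-high end moves by -j
        plus <- sites$pass_strand[pkeep] == "+"
        pe2 <- ifelse(plus, pe - jit[pkeep], pe)
        ps2 <- ifelse(plus, ps, ps + jit[pkeep])
        pseq <- site_sequences(genome$genome, sites$chrom[pkeep], ps2, pe2,
                               sites$pass_strand[pkeep])
        seqs <- c(seqs, pseq)
        cts <- c(cts, pass_cnt[pkeep])
      }
      agg <- stats::aggregate(list(count = cts), by = list(sequence = seqs), FUN = sum)
      agg <- agg[order(-agg$count, agg$sequence), , drop = FALSE]
      rownames(agg) <- NULL
      libraries[[lib_name]] <- agg
      truth_counts[[lib_name]] <- data.frame(
        library = lib_name, genotype = gt, stage = st,
        site_id = sites$site_id, feature_id = sites$feature_id,
        type = sites$type, mix_class = sites$mix_class,
        count = cnt, passenger_count = pass_cnt, inset5_jitter = jit,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(libraries = libraries,
                 truth = list(features = genome$features, sites = sites,
                              counts = do.call(rbind, truth_counts)),
                 config = config),
            class = "sim_libraries")
}

#' @noRd
site_sequences <- function(genome, chrom, start, end, strand) {
  if (length(chrom) == 0L) return(character(0))
  seqs <- character(length(chrom))
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    v <- Biostrings::extractAt(genome[[cn]],
                               IRanges::IRanges(start = start[i] + 1L, end = end[i]))
    seqs[i] <- as.character(v)
  }
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  seqs
}

#' @export
print.sim_libraries <- function(x, ...) {
  cat(sprintf("sim_libraries: %d libraries\n", length(x$libraries)))
  for (nm in names(x$libraries)) {
    cat(sprintf("  %-16s %6d distinct sequences, %8d reads\n", nm,
                nrow(x$libraries[[nm]]), sum(x$libraries[[nm]]$count)))
  }
  invisible(x)
}
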