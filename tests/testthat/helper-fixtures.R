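## Shared fixtures and independent oracles. The default-scale dataset
## (library depth 2e5, seed 42) is built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

## Default study-condition dataset: genome, libraries, mapped profiles.
default_sim <- function() {
  if (!is.null(.fixture_cache$default)) return(.fixture_cache$default)
  cfg <- sim_config()
  genome <- simulate_genome(cfg)
  sim <- simulate_libraries(genome, cfg)
  profiles <- lapply(names(sim$libraries), function(nm) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    library_profile(map_reads(sim$libraries[[nm]], genome), genome,
                    genotype = paste(parts[-length(parts)], collapse = "_"),
                    stage = parts[length(parts)])
  })
  names(profiles) <- names(sim$libraries)
  .fixture_cache$default <- list(cfg = cfg, genome = genome, sim = sim,
                                 profiles = profiles)
  .fixture_cache$default
}

## A small, fast configuration for unit tests.
small_config <- function(seed = 11L, ...) {
  defaults <- list(seed = seed, chrom_length = 40000L,
                   n_ergo1_targets = 6L, n_alg34_targets = 2L,
                   n_csr1_targets = 2L, n_background = 8L,
                   n_mirna = 3L, n_pirna = 3L,
                   duplication = list(n_families = 2L, copies_per_family = 2L,
                                      divergence = 0.05),
                   library_depth = 20000L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_sim <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  cfg <- small_config()
  genome <- simulate_genome(cfg)
  sim <- simulate_libraries(genome, cfg)
  .fixture_cache$small <- list(cfg = cfg, genome = genome, sim = sim)
  .fixture_cache$small
}

## Hand-built toy genome: one chromosome from a fixed base string.
toy_genome <- function(seq, name = "chrT") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- name
  g
}

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

## Independent mapping oracle: scan every position of both strands by direct
## substring comparison.
brute_map <- function(read, genome) {
  out <- NULL
  k <- nchar(read)
  read_rc <- rc(read)
  for (cn in names(genome)) {
    s <- as.character(genome[[cn]])
    n <- nchar(s)
    if (n < k) next
    subs <- substring(s, 1:(n - k + 1L), k:n)
    fwd <- which(subs == read) - 1L
    rev <- which(subs == read_rc) - 1L
    if (length(fwd)) out <- rbind(out, data.frame(chrom = cn, start = fwd,
                                                  strand = "+"))
    if (length(rev)) out <- rbind(out, data.frame(chrom = cn, start = rev,
                                                  strand = "-"))
  }
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      strand = character(0))
  }
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

## Independent longest-common-substring oracle: dynamic programming over a
## rolling row.
lcs_dp <- function(a, b) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  n <- length(av); m <- length(bv)
  if (n == 0L || m == 0L) return(0L)
  prev <- integer(m)
  best <- 0L
  for (i in seq_len(n)) {
    cur <- integer(m)
    hit <- which(bv == av[i])
    if (length(hit)) {
      cur[hit] <- 1L
      h2 <- hit[hit > 1L]
      cur[h2] <- prev[h2 - 1L] + 1L
      best <- max(best, cur[hit])
    }
    prev <- cur
  }
  as.integer(best)
}

## Minimal annotation builder (0-based half-open; single-exon features).
mini_annotation <- function(...) {
  rows <- list(...)
  feat <- do.call(rbind, lapply(rows, function(r)
    data.frame(feature_id = r$id, chrom = r$chrom, start = r$start,
               end = r$end, strand = r$strand, biotype = r$biotype,
               class = if (!is.null(r$class)) r$class else NA_character_,
               stringsAsFactors = FALSE)))
  list(features = feat,
       exons = feat[, c("feature_id", "chrom", "start", "end", "strand")])
}

## Fabricate a minimal library_profile for threshold-logic tests.
fake_profile <- function(feature_rpm, class_rpm = NULL, loci = NULL,
                         chrom_lengths = c(chrT = 10000L), seqs = NULL) {
  structure(list(
    matrix = NULL,
    class_rpm = class_rpm,
    feature_rpm = feature_rpm,
    feature_class_rpm = data.frame(feature_id = character(0),
                                   class = character(0), rpm = numeric(0)),
    seqs = seqs, loci = loci,
    scale = list(total_mapped_reads = 1e6, rpm_factor = 1),
    genotype = "x", stage = "embryo", chrom_lengths = chrom_lengths),
    class = "library_profile")
}
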