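mutate_at_rate <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  idx <- which(stats::runif(length(chars)) < rate)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (i in idx) chars[i] <- sample(alt[[chars[i]]], 1L)
  paste(chars, collapse = "")
}

test_that("identical sequences score 100% identity and a full-length stretch", {
  set.seed(501)
  a <- random_seq(1000)
  e <- pair_identity(a, a)
  expect_equal(e$percent_identity, 100)
  expect_equal(e$longest_exact_stretch, 1000L)
  expect_equal(e$aligned_length, 1000L)
})

test_that("a 5% mutated copy shows ~95% identity and a long perfect stretch", {
  set.seed(502)
  a <- random_seq(1000)
  b <- mutate_at_rate(a, 0.05)
  e <- pair_identity(a, b)
  expect_gte(e$percent_identity, 92)
  expect_lte(e$percent_identity, 98)
  expect_gte(e$longest_exact_stretch, 27L)
  ## ungapped pair: identity from the alignment tracks the direct Hamming count
  hamming <- 100 * mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  expect_equal(e$percent_identity, hamming, tolerance = 0.03)
})

test_that("independent random kilobase sequences share no 27 nt stretch", {
  set.seed(503)
  for (rep in 1:3) {
    e <- pair_identity(random_seq(1000), random_seq(1000))
    expect_lt(e$longest_exact_stretch, 27L)
  }
})

test_that("longest_common_substring equals the dynamic-programming oracle", {
  set.seed(504)
  cases <- list()
  a <- random_seq(600); cases[[1]] <- c(a, mutate_at_rate(a, 0.05))
  cases[[2]] <- c(random_seq(500), random_seq(700))
  b <- random_seq(300); cases[[3]] <- c(paste0(random_seq(50), b),
                                        paste0(b, random_seq(40)))
  cases[[4]] <- c("ACGT", "TTTT")
  cases[[5]] <- c("ACGTACGT", "ACGTACGT")
  for (cs in cases) {
    expect_equal(longest_common_substring(cs[1], cs[2]), lcs_dp(cs[1], cs[2]))
  }
  ## a 2 kb diverged pair, the scale the screen runs at
  a2 <- random_seq(2000)
  b2 <- mutate_at_rate(a2, 0.08)
  expect_equal(longest_common_substring(a2, b2), lcs_dp(a2, b2))
})

test_that("pair identity and stretch are symmetric in their arguments", {
  set.seed(505)
  a <- random_seq(800)
  b <- mutate_at_rate(a, 0.1)
  e1 <- pair_identity(a, b)
  e2 <- pair_identity(b, a)
  expect_equal(e1$percent_identity, e2$percent_identity, tolerance = 1e-6)
  expect_equal(e1$longest_exact_stretch, e2$longest_exact_stretch)
})

test_that("qualifying edges use strict >82% identity and inclusive >=27 nt stretch", {
  edge <- function(pid, stretch, alen = 1000L) {
    data.frame(a = "x", b = "y", percent_identity = pid,
               aligned_length = alen, longest_exact_stretch = stretch)
  }
  expect_false(qualifying_edge(edge(82, 100)))
  expect_true(qualifying_edge(edge(82.001, 100)))
  expect_false(qualifying_edge(edge(95, 26)))
  expect_true(qualifying_edge(edge(95, 27)))
  expect_false(qualifying_edge(edge(95, 100, alen = 50L)))  # coverage filter
  expect_false(qualifying_edge(edge(NA, 100)))
})

test_that("raising either threshold never adds a qualifying edge", {
  set.seed(506)
  edges <- data.frame(a = "x", b = "y",
                      percent_identity = runif(50, 60, 100),
                      aligned_length = 1000L,
                      longest_exact_stretch = sample(10:60, 50, replace = TRUE))
  base <- qualifying_edge(edges)
  expect_true(all(qualifying_edge(edges, identity_threshold = 90) <= base))
  expect_true(all(qualifying_edge(edges, stretch_threshold = 40) <= base))
})

test_that("single-linkage groups are transitive closures of qualifying edges", {
  edges <- data.frame(a = c("a", "b"), b = c("b", "c"),
                      percent_identity = c(95, 95), aligned_length = 1000L,
                      longest_exact_stretch = c(50L, 50L))
  grp <- homology_groups(c("a", "b", "c", "d"), edges)
  expect_equal(grp, list(c("a", "b", "c")))
  ## no qualifying edges: no groups
  none <- homology_groups(c("a", "b"), edges[0, ])
  expect_equal(none, list())
})

test_that("flanked sequences clip at chromosome edges and respect strand", {
  set.seed(507)
  s <- random_seq(3000)
  g <- toy_genome(s)
  feat <- list(chrom = "chrT", start = 1000L, end = 2000L, strand = "+")
  fs <- flanked_sequence(feat, g)
  expect_equal(as.character(fs), substr(s, 501, 2500))
  expect_false(attr(fs, "clipped"))
  feat2 <- list(chrom = "chrT", start = 100L, end = 600L, strand = "+")
  fs2 <- flanked_sequence(feat2, g)
  expect_equal(as.character(fs2), substr(s, 1, 1100))
  expect_true(attr(fs2, "clipped"))
  feat3 <- list(chrom = "chrT", start = 1000L, end = 2000L, strand = "-")
  expect_equal(as.character(flanked_sequence(feat3, g)), rc(substr(s, 501, 2500)))
})

test_that("simulated duplicate families are recovered as exact groups", {
  ss <- small_sim()
  g <- ss$genome
  tgt <- g$features$feature_id[g$features$class %in% "ergo1_target"]
  edges <- homology_edges(tgt, g, g$genome, screen = TRUE)
  groups <- homology_groups(tgt, edges)
  fams <- split(g$features$feature_id[!is.na(g$features$family)],
                g$features$family[!is.na(g$features$family)])
  fams <- unname(lapply(fams, sort))
  expect_equal(length(groups), length(fams))
  expect_setequal(vapply(groups, paste, "", collapse = ","),
                  vapply(fams, paste, "", collapse = ","))
})

test_that("proximity flags mark same-chromosome neighbours under 5 kb", {
  ann <- mini_annotation(
    list(id = "a", chrom = "chrT", start = 0L, end = 1000L, strand = "+",
         biotype = "coding"),
    list(id = "b", chrom = "chrT", start = 3000L, end = 4000L, strand = "+",
         biotype = "coding"),
    list(id = "c", chrom = "chrT", start = 9500L, end = 10500L, strand = "+",
         biotype = "coding"))
  set.seed(508)
  g <- toy_genome(random_seq(12000))
  ed <- homology_edges(c("a", "b", "c"), ann, g, flank = 0L, screen = TRUE)
  pick <- function(x, y) ed$proximal[ed$a == x & ed$b == y]
  expect_true(pick("a", "b"))    # gap 2000
  expect_false(pick("a", "c"))   # gap 8500
  expect_false(pick("b", "c"))   # gap 5500
})

test_that("gene structure stats summarise the set against the annotation", {
  ann <- mini_annotation(
    list(id = "t1", chrom = "chrT", start = 0L, end = 1300L, strand = "+",
         biotype = "coding"),
    list(id = "b1", chrom = "chrT", start = 2000L, end = 4800L, strand = "+",
         biotype = "coding"))
  ann$features$n_exons <- c(3L, 5L)
  st <- gene_structure_stats("t1", ann)
  expect_equal(st$set$median_exons, 3L)
  expect_equal(st$set$mean_length, 1300)
  expect_error(gene_structure_stats(character(0), ann), "empty")
  ## simulated targets are shorter than the background genes
  ss <- small_sim()
  tgt <- ss$genome$features$feature_id[ss$genome$features$class %in% "ergo1_target"]
  st2 <- gene_structure_stats(tgt, ss$genome)
  expect_lt(st2$set$mean_length, st2$genome$mean_length)
  expect_lte(st2$set$median_exons, st2$genome$median_exons)
})

test_that("background sampling rejects an undersized pool", {
  ss <- small_sim()
  g <- ss$genome
  tgt <- g$features$feature_id[g$features$class %in% "ergo1_target"]
  expect_error(background_fraction(g, g$genome, tgt, n_genes = 1000L,
                                   n_draws = 1L),
               "insufficient")
})
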