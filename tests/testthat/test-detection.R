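# Cluster detection: density windows, dynamic cutoff, chaining, the minimum
# rule, extension, classification, and end-to-end recovery of planted loci.

test_that("local gene density covers the ten nearest genes", {
  # 10 genes of 1 kb each, starts every 5 kb: span 46 kb exactly
  g <- make_test_genome(layout_genes(10, 5000L, 1000L))
  ctx <- local_gene_density("g005", g)
  expect_equal(length(ctx$window_genes), 10L)
  expect_equal(ctx$window_span_kb, 46.0)
  expect_equal(ctx$local_density, 10 / 46)

  # a 3-gene contig gives a 3-gene window
  g3 <- make_test_genome(layout_genes(3, 5000L, 1000L))
  expect_equal(length(local_gene_density("g002", g3)$window_genes), 3L)

  # tie for the last window slot goes to the lower-coordinate gene
  g11 <- make_test_genome(layout_genes(11, 5000L, 1000L))
  ctx11 <- local_gene_density("g006", g11)  # g001 and g011 equidistant
  expect_true("g001" %in% ctx11$window_genes)
  expect_false("g011" %in% ctx11$window_genes)
})

test_that("the dynamic cutoff is linear in mean spacing and clamps", {
  ctx <- list(window_genes = paste0("g", 1:10), window_span_kb = 50)
  expect_equal(dynamic_cutoff_kb(ctx, multiplier = 2), 10)      # 2 * 5 kb
  # doubling density (halving spacing) halves the raw cutoff
  ctx2 <- list(window_genes = paste0("g", 1:10), window_span_kb = 25)
  expect_equal(dynamic_cutoff_kb(ctx2, multiplier = 2, min_kb = 0),
               dynamic_cutoff_kb(ctx, multiplier = 2, min_kb = 0) / 2)
  # sparse contig clamps at max_kb
  sparse <- list(window_genes = paste0("g", 1:2), window_span_kb = 900)
  expect_equal(dynamic_cutoff_kb(sparse, multiplier = 5, max_kb = 100), 100)
  expect_equal(dynamic_cutoff_kb(ctx2, multiplier = 0.1, min_kb = 10), 10)
})

test_that("chaining merges within the larger cutoff, transitively", {
  g <- make_test_genome(data.frame(
    gene_id = c("h1", "h2", "h3"), record_id = "chr1",
    start = c(1, 4001, 12001), end = c(1000, 5000, 13000),
    strand = "+", stringsAsFactors = FALSE))
  cut <- c(h1 = 10, h2 = 10, h3 = 10)
  cfg <- detection_config()
  # 3 kb and 7 kb gaps: all merge into one locus even though h1-h3 alone
  # are 11 kb apart (> 10 kb)
  expect_equal(chain_candidate_loci(g, c("h1", "h2", "h3"), cut, cfg),
               list(c("h1", "h2", "h3")))
  # 200 kb apart: two loci
  g2 <- make_test_genome(data.frame(
    gene_id = c("h1", "h2"), record_id = "chr1",
    start = c(1, 201001), end = c(1000, 202000), strand = "+",
    stringsAsFactors = FALSE))
  expect_equal(length(chain_candidate_loci(g2, c("h1", "h2"),
                                           cut[1:2], cfg)), 2L)
})

test_that("chaining equals brute-force union-find merging on random layouts", {
  set.seed(5)
  cfg <- detection_config()
  for (rep in 1:6) {
    n <- sample(10:50, 1)
    start <- cumsum(sample(500:30000, n, replace = TRUE))
    genes <- data.frame(gene_id = sprintf("g%03d", 1:n), record_id = "chr1",
                        start = start, end = start + 999L, strand = "+",
                        stringsAsFactors = FALSE)
    g <- make_test_genome(genes)
    hits <- sort(sample(genes$gene_id, sample(3:8, 1)))
    cut <- stats::setNames(sample(c(5, 10, 20), length(hits), replace = TRUE),
                           hits)
    got <- chain_candidate_loci(g, hits, cut, cfg)
    want <- bf_chain(genes, hits, cut)
    expect_equal(lapply(got, sort), lapply(want, sort))
  }
})

test_that("genecount mode chains by intervening gene count", {
  genes <- layout_genes(12, 50000L, 1000L)  # 49 kb gaps: density mode splits
  g <- make_test_genome(genes)
  cfg <- detection_config(cutoff_mode = "genecount", max_gene_gap = 3L)
  loci <- chain_candidate_loci(g, c("g001", "g004", "g012"), NULL, cfg)
  expect_equal(loci, list(c("g001", "g004"), "g012"))
})

test_that("the minimum rule needs 3 subclasses from 2 classes and collapses tandems", {
  lib <- load_profile_library()
  mkhits <- function(genes, profs) data.frame(
    gene_id = genes, profile_id = profs, bitscore = 150, evalue = 1e-30,
    ali_start = 1L, ali_end = 100L, stringsAsFactors = FALSE)
  cfg <- detection_config()

  # three dissimilar enzymes of three classes: accepted (3 subclasses, 3 classes)
  prot3 <- stats::setNames(unrelated_proteins(3), c("a", "b", "c"))
  ann3 <- annotate_genes(mkhits(c("a", "b", "c"),
                                c("PF01397", "PF00067", "PF00201")), lib)
  r3 <- evaluate_minimum_rule(c("a", "b", "c"), ann3, prot3, cfg)
  expect_true(r3$accept)
  expect_equal(r3$subclass_count, 3L)
  expect_equal(r3$class_count, 3L)

  # five near-identical P450s: one subclass, one class -> rejected
  prot5 <- stats::setNames(rep(protein_pair_identity(20L)[1], 5),
                           paste0("p", 1:5))
  ann5 <- annotate_genes(mkhits(names(prot5), rep("PF00067", 5)), lib)
  r5 <- evaluate_minimum_rule(names(prot5), ann5, prot5, cfg)
  expect_false(r5$accept)
  expect_equal(r5$subclass_count, 1L)
  expect_equal(r5$class_count, 1L)

  # three dissimilar P450s: 3 subclasses but 1 class -> rejected
  annP <- annotate_genes(mkhits(c("a", "b", "c"), rep("PF00067", 3)), lib)
  rP <- evaluate_minimum_rule(c("a", "b", "c"), annP, prot3, cfg)
  expect_false(rP$accept)
  expect_equal(rP$subclass_count, 3L)
  expect_equal(rP$class_count, 1L)
})

test_that("extension takes in sandwiched genes and near flanks only", {
  genes <- data.frame(
    gene_id = c("far", "near", "hitA", "mid", "hitB", "out"),
    record_id = "chr1",
    start = c(1, 38001, 50001, 53001, 56001, 120001),
    end = c(1000, 39000, 51000, 54000, 57000, 121000),
    strand = "+", stringsAsFactors = FALSE)
  g <- make_test_genome(genes)
  cut <- c(hitA = 12, hitB = 12)
  ext <- extend_cluster(c("hitA", "hitB"), g, cut)
  expect_setequal(ext$gene_ids, c("near", "hitA", "mid", "hitB"))
  expect_equal(ext$start, 38001)
  expect_equal(ext$end, 57000)
})

test_that("product classification follows signature classes with Hybrid and Putative", {
  lib <- load_profile_library()
  mkann <- function(profs) annotate_genes(data.frame(
    gene_id = paste0("g", seq_along(profs)), profile_id = profs,
    bitscore = 150, evalue = 1e-30, ali_start = 1L, ali_end = 100L,
    stringsAsFactors = FALSE), lib)
  expect_equal(classify_cluster("g1", mkann("PF01397")), "Terpene")
  expect_setequal(classify_cluster(c("g1", "g2"), mkann(c("PF01397", "PF00195"))),
                  c("Terpene", "Polyketide", "Hybrid"))
  # only tailoring enzymes: Putative
  expect_equal(classify_cluster(c("g1", "g2"), mkann(c("PF00067", "PF03171"))),
               "Putative")
})

test_that("detection recovers a planted locus and rejects tandem arrays and spread loci", {
  spec <- genome_spec(
    seed = 31,
    records = data.frame(record_id = "chr1", n_genes = 45L,
                         mean_spacing_kb = 5, spacing_dispersion = 0.6),
    planted_loci = list(
      list(record = "chr1", position = 10L,
           classes = data.frame(
             enzyme_class = c("terpene synthase", "cytochrome P450",
                              "glycosyltransferase"),
             n_copies = c(1L, 2L, 1L), mutual_identity = c(1, 0.3, 1))),
      # spread beyond every cutoff: must not chain
      list(record = "chr1", position = 35L, spacing_kb = 150,
           classes = data.frame(
             enzyme_class = c("terpene synthase", "cytochrome P450",
                              "dioxygenase"),
             n_copies = 1L, mutual_identity = 1))),
    tandem_arrays = list(list(record = "chr1", position = 25L,
                              enzyme_class = "cytochrome P450",
                              n_copies = 5L)))
  fx <- make_toy_genome(spec)
  cl <- detect_clusters(fx$genome, fx$hits)
  expect_equal(nrow(cl), 1L)
  truth <- fx$truth$elements[[1]]
  expect_setequal(cl$hit_gene_ids[[1]], truth$genes)
  hg <- fx$genome$genes[fx$genome$genes$gene_id %in% cl$hit_gene_ids[[1]], ]
  expect_equal(min(hg$start), truth$start)
  expect_equal(max(hg$end), truth$end)
  expect_true(cl$subclass_count[1] >= 3 && cl$class_count[1] >= 2)
  expect_true("Terpene" %in% cl$product_classes[[1]])
})

test_that("lowering the rule thresholds never loses clusters, and reported clusters never overlap", {
  spec <- genome_spec(
    seed = 8,
    records = data.frame(record_id = "chr1", n_genes = 50L,
                         mean_spacing_kb = 4, spacing_dispersion = 0.7),
    planted_loci = list(
      list(record = "chr1", position = 10L,
           classes = data.frame(
             enzyme_class = c("terpene synthase", "cytochrome P450"),
             n_copies = c(1L, 2L), mutual_identity = c(1, 0.95))),
      list(record = "chr1", position = 30L,
           classes = data.frame(
             enzyme_class = c("polyketide synthase", "methyltransferase",
                              "dioxygenase"),
             n_copies = 1L, mutual_identity = 1))))
  fx <- make_toy_genome(spec)
  strict <- detect_clusters(fx$genome, fx$hits,
                            config = detection_config(min_subclasses = 3,
                                                      min_classes = 2))
  loose <- detect_clusters(fx$genome, fx$hits,
                           config = detection_config(min_subclasses = 2,
                                                     min_classes = 1))
  expect_gte(nrow(loose), nrow(strict))
  if (nrow(loose) > 1) {
    for (rec in unique(loose$record_id)) {
      d <- loose[loose$record_id == rec, ]
      d <- d[order(d$start), ]
      if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)]))
    }
  }
  # hit genes of accepted loci are exactly the union over reported clusters
  expect_setequal(unlist(strict$hit_gene_ids),
                  fx$truth$elements[[2]]$genes)
})

test_that("cluster exports are well-formed BED and GFF3", {
  spec <- genome_spec(seed = 31,
                      records = data.frame(record_id = "chr1", n_genes = 30L,
                                           mean_spacing_kb = 5,
                                           spacing_dispersion = 0.5),
                      planted_loci = list(list(
                        record = "chr1", position = 10L,
                        classes = data.frame(
                          enzyme_class = c("terpene synthase",
                                           "cytochrome P450",
                                           "glycosyltransferase"),
                          n_copies = 1L, mutual_identity = 1))))
  fx <- make_toy_genome(spec)
  cl <- detect_clusters(fx$genome, fx$hits)
  bed <- tempfile(fileext = ".bed"); gff <- tempfile(fileext = ".gff3")
  write_clusters_bed(cl, bed)
  write_clusters_gff3(cl, gff)
  b <- read.delim(bed, header = FALSE)
  expect_equal(nrow(b), nrow(cl))
  expect_equal(b$V2 + 1, cl$start)   # BED is 0-based half-open
  expect_equal(b$V3, as.integer(cl$end))
  g <- rtracklayer::import(gff)
  expect_equal(length(g), nrow(cl))
  expect_equal(GenomicRanges::start(g), as.integer(cl$start))
})
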