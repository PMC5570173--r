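# Expression IO, the distance transform, heatmap ordering/normalization,
# networks, ego networks and inter-cluster linkage.

toy_matrix <- function() {
  set.seed(42)
  f <- rnorm(20)
  m <- rbind(a = f, b = f + rnorm(20, sd = 0.05),       # strongly correlated
             c = -f + rnorm(20, sd = 0.05),             # anti-correlated
             d = rnorm(20), e = rnorm(20))              # noise
  colnames(m) <- sprintf("s%02d", 1:20)
  as_expression_matrix(m, "toy")
}

test_that("expression CSV round-trips and rejects malformed inputs", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("gene_id,s1,s2,s3,s4", "g1,1,2,3,4", "g2,4,3,2,1",
               "g3,0,0,1,1"), p)
  m <- read_expression_csv(p)
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(rownames(m), c("g1", "g2", "g3"))
  expect_equal(unname(m["g1", ]), c(1, 2, 3, 4))

  dup <- tempfile(fileext = ".csv")
  writeLines(c("gene_id,s1,s2", "g1,1,2", "g1,3,4"), dup)
  expect_error(read_expression_csv(dup), "g1")

  one <- tempfile(fileext = ".csv")
  writeLines(c("gene_id,s1", "g1,1"), one)
  expect_error(read_expression_csv(one), "sample")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("gene_id,s1,s2", "g1,1,x"), bad)
  expect_error(read_expression_csv(bad), "g1")
})

test_that("SOFT tables parse, drop null-containing genes, and error without a table", {
  p <- tempfile(fileext = ".soft")
  writeLines(c("^DATASET = GDS_toy", "!dataset_title = toy",
               "!dataset_table_begin",
               "ID_REF\tIDENTIFIER\tGSM1\tGSM2\tGSM3",
               "1007_s_at\tgeneA\t1.0\t2.0\t3.0",
               "1053_at\tgeneB\t4.0\t5.0\t6.0",
               "117_at\tgeneC\tnull\t1.0\t2.0",
               "!dataset_table_end"), p)
  m <- read_soft(p)
  expect_equal(dim(m), c(2L, 3L))
  expect_setequal(rownames(m), c("geneA", "geneB"))

  noTable <- tempfile(fileext = ".soft")
  writeLines(c("^PLATFORM = GPL1", "!platform_title = x"), noTable)
  expect_error(read_soft(noTable), "table")
})

test_that("the distance transform is the linear map 100*(1-PCC)", {
  expect_equal(coexpression_distance(1), 0)
  expect_equal(coexpression_distance(-1), 200)
  expect_equal(coexpression_distance(0), 100)
  expect_error(coexpression_distance(1.5), "outside")
  grid <- seq(-1, 1, length.out = 21)
  expect_equal(coexpression_distance(grid), 100 * (1 - grid))
  # antisymmetry around PCC 0
  expect_equal(coexpression_distance(grid) + coexpression_distance(-grid),
               rep(200, 21))
})

test_that("complete-linkage ordering merges the correlated pair first", {
  m <- toy_matrix()
  ord <- hierarchical_order(c("a", "b", "c"), m)
  merged_first <- ord$hclust$merge[1, ]
  expect_setequal(ord$hclust$labels[-merged_first], c("a", "b"))
  # all-identical genes chain at distance ~0
  m2 <- as_expression_matrix(rbind(x = m["a", ], y = m["a", ], z = m["a", ]),
                             "toy")
  ord2 <- hierarchical_order(c("x", "y", "z"), m2)
  expect_true(all(ord2$hclust$height < 1e-8))
  # zero-variance genes are excluded with a warning
  m3 <- as_expression_matrix(rbind(m[c("a", "b"), ], flat = rep(1, 20)), "toy")
  expect_warning(ord3 <- hierarchical_order(c("a", "b", "flat"), m3), "flat")
  expect_equal(ord3$excluded, "flat")
})

test_that("merge heights match a brute-force complete-linkage oracle", {
  set.seed(9)
  m <- matrix(rnorm(5 * 15), nrow = 5,
              dimnames = list(paste0("g", 1:5), sprintf("s%02d", 1:15)))
  em <- as_expression_matrix(m, "toy")
  ord <- hierarchical_order(rownames(m), em)
  d <- coexpression_distance(stats::cor(t(m)))
  diag(d) <- 0
  expect_equal(sort(ord$hclust$height),
               sort(bf_complete_linkage_heights(stats::as.dist(d))),
               tolerance = 1e-10)
})

test_that("heatmap normalization min-max scales with the 0.5 constant convention", {
  m <- rbind(r1 = c(2, 4, 6), r2 = c(3, 3, 3))
  n <- normalize_heatmap(m, "row")
  expect_equal(unname(n["r1", ]), c(0, 0.5, 1))
  expect_equal(unname(n["r2", ]), c(0.5, 0.5, 0.5))
  # column mode on the transpose equals row mode on the original
  expect_equal(unname(t(normalize_heatmap(t(m), "column"))), unname(n))
})

test_that("network edges appear exactly below the distance cutoff", {
  m <- toy_matrix()
  net <- build_cluster_network(c("a", "b", "c", "d"), m, 50)
  e <- igraph::as_edgelist(net)
  expect_equal(nrow(e), 1L)
  expect_setequal(as.vector(e), c("a", "b"))
  # widening the cutoff can only add edges; edge sets match brute force
  for (cut in c(30, 50, 70, 110)) {
    net2 <- build_cluster_network(rownames(m), m, cut)
    want <- bf_edges(m, rownames(m), 1 - cut / 100)
    expect_equal(igraph::ecount(net2), ncol(want))
  }
})

test_that("local transitivity follows the neighbor-pair definition", {
  tri <- igraph::make_graph(~ a - b, b - c, a - c)
  expect_equal(local_transitivity("a", tri), 1)
  star <- igraph::make_graph(~ hub - l1, hub - l2, hub - l3)
  expect_equal(local_transitivity("hub", star), 0)
  expect_equal(local_transitivity("l1", star), 0)   # degree < 2
  g <- igraph::make_graph(~ x - a, x - b, x - c, a - b)
  expect_equal(local_transitivity("x", g), 1 / 3)
})

# A deterministic scenario for ego-network rules: focal cluster f1..f3,
# another cluster o1..o3, plus unclustered genes.
ego_fixture <- function() {
  set.seed(4)
  f <- rnorm(30)
  noise <- function() rnorm(30)
  jitter <- function(sd = 0.01) f + rnorm(30, sd = sd)
  m <- rbind(f1 = jitter(), f2 = jitter(), f3 = noise(),
             o1 = jitter(), o2 = noise(), o3 = noise(),
             ub1 = jitter(), ub2 = noise(), un1 = jitter())
  colnames(m) <- sprintf("s%02d", 1:30)
  lib <- load_profile_library()
  # biosynthetic: f1 (P450), f2 (terpene synthase), o1, ub1, ub2
  hits <- data.frame(
    gene_id = c("f1", "f2", "o1", "ub1", "ub2"),
    profile_id = c("PF00067", "PF01397", "PF00201", "PF03171", "PF00891"),
    bitscore = 150, evalue = 1e-30, ali_start = 1L, ali_end = 100L,
    stringsAsFactors = FALSE)
  clusters <- data.frame(cluster_id = 1:2, record_id = "chr1",
                         start = c(1, 100000), end = c(50000, 150000),
                         stringsAsFactors = FALSE)
  clusters$gene_ids <- list(c("f1", "f2", "f3"), c("o1", "o2", "o3"))
  clusters$hit_gene_ids <- clusters$gene_ids
  class(clusters) <- c("bgc_clusters", "data.frame")
  list(m = as_expression_matrix(m, "toy"),
       ann = annotate_genes(hits, lib), clusters = clusters)
}

test_that("ego admission follows rules (i) and (ii)", {
  fx <- ego_fixture()
  ego <- build_ego_network(1, fx$clusters, fx$ann, fx$m, 0.9)
  roles <- stats::setNames(igraph::V(ego)$role, igraph::V(ego)$name)
  # o1: member of another cluster, correlated with >= 1 focal gene
  expect_equal(unname(roles["o1"]), "other-cluster")
  # ub1: biosynthetic, correlated with f1 and f2, f1 biosynthetic
  expect_equal(unname(roles["ub1"]), "unclustered-biosynthetic")
  # ub2: biosynthetic but uncorrelated -> absent; un1: correlated but not
  # biosynthetic and not in a cluster -> absent
  expect_false("ub2" %in% names(roles))
  expect_false("un1" %in% names(roles))
  expect_setequal(names(roles)[roles == "in-cluster"], c("f1", "f2", "f3"))
})

test_that("rule (ii) requires a biosynthetic partner among the correlated focal genes", {
  fx <- ego_fixture()
  # rebuild with f1/f2 NOT biosynthetic (annotation lacks them): ub1 must drop
  lib <- load_profile_library()
  ann2 <- annotate_genes(data.frame(
    gene_id = c("o1", "ub1"), profile_id = c("PF00201", "PF03171"),
    bitscore = 150, evalue = 1e-30, ali_start = 1L, ali_end = 100L,
    stringsAsFactors = FALSE), lib)
  ego <- build_ego_network(1, fx$clusters, ann2, fx$m, 0.9)
  expect_false("ub1" %in% igraph::V(ego)$name)
})

# Two 4-gene clusters sharing one latent signal: a near-clique across both.
link_fixture <- function(correlated = TRUE) {
  set.seed(12)
  f <- rnorm(40)
  val <- function(corr) if (corr) f + rnorm(40, sd = 0.05) else rnorm(40)
  m <- rbind(a1 = val(correlated), a2 = val(correlated), a3 = val(correlated),
             a4 = rnorm(40),
             b1 = val(correlated), b2 = val(correlated), b3 = val(correlated),
             b4 = rnorm(40))
  colnames(m) <- sprintf("s%02d", 1:40)
  lib <- load_profile_library()
  hits <- data.frame(
    gene_id = c("a1", "a2", "b1", "b2"),
    profile_id = c("PF00067", "PF01397", "PF00201", "PF03171"),
    bitscore = 150, evalue = 1e-30, ali_start = 1L, ali_end = 100L,
    stringsAsFactors = FALSE)
  clusters <- data.frame(cluster_id = 1:2, record_id = "chr1",
                         start = c(1, 100000), end = c(50000, 150000),
                         stringsAsFactors = FALSE)
  clusters$gene_ids <- list(paste0("a", 1:4), paste0("b", 1:4))
  clusters$hit_gene_ids <- clusters$gene_ids
  class(clusters) <- c("bgc_clusters", "data.frame")
  list(m = as_expression_matrix(m, "toy"),
       ann = annotate_genes(hits, lib), clusters = clusters)
}

test_that("block-correlated cluster pairs are linked; unlinked otherwise", {
  fx <- link_fixture(TRUE)
  li <- intercluster_links(fx$clusters, fx$ann, fx$m)
  expect_equal(nrow(li), 1L)
  expect_equal(sort(c(li$cluster_a, li$cluster_b)), c(1L, 2L))
  wit <- li$witness[[1]]
  expect_gte(sum(grepl("^a", wit)), 2L)
  expect_gte(sum(grepl("^b", wit)), 2L)
  # determinism across repeated runs
  li2 <- intercluster_links(fx$clusters, fx$ann, fx$m)
  expect_identical(li, li2)

  none <- link_fixture(FALSE)
  expect_equal(nrow(intercluster_links(none$clusters, none$ann, none$m)), 0L)
})

test_that("a single correlated gene per cluster, or a star, cannot witness a link", {
  set.seed(3)
  f <- rnorm(40)
  m <- rbind(a1 = f + rnorm(40, sd = 0.05), a2 = rnorm(40), a3 = rnorm(40),
             b1 = f + rnorm(40, sd = 0.05), b2 = rnorm(40), b3 = rnorm(40))
  colnames(m) <- sprintf("s%02d", 1:40)
  lib <- load_profile_library()
  hits <- data.frame(gene_id = c("a1", "a2", "b1", "b2"),
                     profile_id = c("PF00067", "PF01397", "PF00201", "PF03171"),
                     bitscore = 150, evalue = 1e-30, ali_start = 1L,
                     ali_end = 100L, stringsAsFactors = FALSE)
  clusters <- data.frame(cluster_id = 1:2, record_id = "chr1",
                         start = c(1, 2), end = c(3, 4),
                         stringsAsFactors = FALSE)
  clusters$gene_ids <- list(paste0("a", 1:3), paste0("b", 1:3))
  clusters$hit_gene_ids <- clusters$gene_ids
  class(clusters) <- c("bgc_clusters", "data.frame")
  ann <- annotate_genes(hits, lib)
  li <- intercluster_links(clusters, ann, as_expression_matrix(m, "toy"))
  expect_equal(nrow(li), 0L)  # only one correlated gene per cluster (iii)
})

test_that("ego admission is monotone in the PCC threshold", {
  fx <- ego_fixture()
  hi <- igraph::V(build_ego_network(1, fx$clusters, fx$ann, fx$m, 0.95))$name
  lo <- igraph::V(build_ego_network(1, fx$clusters, fx$ann, fx$m, 0.8))$name
  expect_true(all(hi %in% lo))
})
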