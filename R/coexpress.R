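# Expression input and coexpression structure: the PCC -> [0,200] distance
# transform, heatmap ordering, cluster networks, ego networks, and
# Louvain-based inter-cluster linkage.

#' Read a genes x samples expression CSV
#'
#' First column: gene identifiers; header row: sample identifiers; cells:
#' normalized expression values.
#'
#' @param path Path to the CSV file.
#' @param experiment_id Experiment label; default the file base name.
#' @return An `expression_matrix`: numeric matrix (genes x samples) with
#'   attribute `experiment_id`.
#' @export
read_expression_csv <- function(path, experiment_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expression matrix needs >= 2 sample columns (PCC undefined on 1)")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene id(s) in expression CSV: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) & vals[[j]] != "")
    if (length(bad)) {
      stop("non-numeric expression value at gene '", genes[bad[1L]],
           "', sample '", names(vals)[j], "'")
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  as_expression_matrix(m, experiment_id %||%
                            tools::file_path_sans_ext(basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an expression matrix object
#'
#' @param m Numeric matrix, genes as rows (rownames) and samples as columns.
#' @param experiment_id Experiment label.
#' @return An `expression_matrix`.
#' @export
as_expression_matrix <- function(m, experiment_id = "experiment") {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (ncol(m) < 2L) stop("expression matrix needs >= 2 samples")
  attr(m, "experiment_id") <- experiment_id
  class(m) <- c("expression_matrix", class(m))
  m
}

#' Read a GEO SOFT expression table
#'
#' Minimal reader for the SOFT subset carrying a value table between
#' `!*_table_begin` / `!*_table_end` markers (GEO DataSet or Series matrix
#' style).  Rows are keyed on the `IDENTIFIER` column when present, else on
#' the first column; literal `"null"` values are treated as missing and any
#' gene with a missing value is dropped.
#'
#' @param path Path to a SOFT file.
#' @param experiment_id Experiment label; default the file base name.
#' @return An `expression_matrix`.
#' @export
read_soft <- function(path, experiment_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!\\w*[Tt]able_begin", lines)
  fin <- grep("^!\\w*[Tt]able_end", lines)
  if (length(beg) == 0L || length(fin) == 0L || fin[1L] <= beg[1L] + 1L) {
    stop("SOFT file '", path, "' has no value table (missing table delimiters)")
  }
  tab <- lines[(beg[1L] + 1L):(fin[1L] - 1L)]
  df <- utils::read.delim(text = paste(tab, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  key_col <- if ("IDENTIFIER" %in% names(df)) "IDENTIFIER" else names(df)[1L]
  meta_cols <- unique(c(names(df)[1L], "IDENTIFIER", "ID_REF"))
  val_cols <- setdiff(names(df), meta_cols)
  if (length(val_cols) < 2L) stop("SOFT table has fewer than 2 sample columns")
  vals <- df[, val_cols, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    v[v %in% c("null", "NULL", "NA", "")] <- NA
    vals[[j]] <- suppressWarnings(as.numeric(v))
  }
  m <- as.matrix(vals)
  rownames(m) <- as.character(df[[key_col]])
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  if (anyDuplicated(rownames(m))) {
    stop("duplicate gene identifier(s) in SOFT table: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  as_expression_matrix(m, experiment_id %||%
                            tools::file_path_sans_ext(basename(path)))
}

#' Coexpression distance from a Pearson correlation
#'
#' Linear transform `100 * (1 - pcc)`: 0 for PCC = +1 (perfectly positively
#' correlated), 100 for PCC = 0, 200 for PCC = -1.
#'
#' @param pcc Pearson correlation value(s) in `[-1, 1]`.
#' @return Distance value(s) in `[0, 200]`.
#' @export
coexpression_distance <- function(pcc) {
  if (any(is.na(pcc)) || any(pcc < -1 - 1e-12) || any(pcc > 1 + 1e-12)) {
    stop("pcc outside [-1, 1]")
  }
  100 * (1 - pmin(pmax(pcc, -1), 1))  # pcc first: keeps dim attributes
}

# Pairwise PCC matrix over the given genes (rows of the matrix).
# Pairwise-complete; pairs sharing < 3 samples and zero-variance genes -> NA.
.pcc_matrix <- function(matrix, genes = rownames(matrix)) {
  genes <- intersect(genes, rownames(matrix))
  v <- matrix[genes, , drop = FALSE]
  sds <- apply(v, 1L, stats::sd, na.rm = TRUE)
  p <- suppressWarnings(stats::cor(t(v), use = "pairwise.complete.obs"))
  ok <- !is.na(v)
  shared <- tcrossprod(ok * 1)
  p[shared < 3L] <- NA
  p[is.na(sds) | sds == 0, ] <- NA
  p[, is.na(sds) | sds == 0] <- NA
  diag(p) <- 1
  p
}

#' Complete-linkage hierarchical ordering of cluster genes
#'
#' Agglomerates genes on the coexpression distance (`100 * (1 - PCC)`) with
#' complete linkage; the leaf order is the heatmap row order.  Zero-variance
#' genes are excluded with a warning (their PCC is undefined).
#'
#' @param gene_ids Genes to order (must be rows of `matrix`).
#' @param matrix An `expression_matrix`.
#' @return List: `hclust` (the tree), `order` (leaf gene ids), `excluded`.
#' @export
hierarchical_order <- function(gene_ids, matrix) {
  gene_ids <- intersect(gene_ids, rownames(matrix))
  sds <- apply(matrix[gene_ids, , drop = FALSE], 1L, stats::sd, na.rm = TRUE)
  excluded <- gene_ids[is.na(sds) | sds == 0]
  if (length(excluded)) {
    warning("excluding zero-variance gene(s): ", paste(excluded, collapse = ", "))
  }
  keep <- setdiff(gene_ids, excluded)
  if (length(keep) < 2L) stop("need >= 2 genes with defined correlations")
  p <- .pcc_matrix(matrix, keep)
  d <- stats::as.dist(coexpression_distance(p))
  hc <- stats::hclust(d, method = "complete")
  list(hclust = hc, order = keep[hc$order], excluded = excluded)
}

#' Normalize expression values for heatmap display
#'
#' Min-max scales each row (default) or column to `[0, 1]`; constant rows or
#' columns map to 0.5.
#'
#' @param matrix Numeric matrix.
#' @param mode `"row"` or `"column"`.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
normalize_heatmap <- function(matrix, mode = c("row", "column")) {
  mode <- match.arg(mode)
  scale1 <- function(x) {
    r <- range(x, na.rm = TRUE)
    if (r[1L] == r[2L]) return(rep(0.5, length(x)))
    (x - r[1L]) / (r[2L] - r[1L])
  }
  if (mode == "row") {
    t(apply(matrix, 1L, scale1))
  } else {
    apply(matrix, 2L, scale1)
  }
}

#' Cluster-specific coexpression network
#'
#' Nodes are the cluster's genes (those present in the matrix); an
#' undirected edge joins two genes when their coexpression distance is below
#' the cutoff (default < 50, i.e. PCC > 0.5).
#'
#' @param gene_ids Cluster gene ids.
#' @param matrix An `expression_matrix`.
#' @param distance_cutoff Edge threshold on the 0-200 distance; default 50.
#' @return An [igraph][igraph::igraph-package] graph with edge attributes
#'   `pcc` and `distance`.
#' @export
build_cluster_network <- function(gene_ids, matrix, distance_cutoff = 50) {
  gene_ids <- intersect(gene_ids, rownames(matrix))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(gene_ids), name = gene_ids)
  if (length(gene_ids) < 2L) return(g)
  p <- .pcc_matrix(matrix, gene_ids)
  idx <- which(upper.tri(p) & !is.na(p) & coexpression_distance(p) < distance_cutoff,
               arr.ind = TRUE)
  if (nrow(idx)) {
    ends <- rbind(gene_ids[idx[, 1L]], gene_ids[idx[, 2L]])
    g <- igraph::add_edges(g, as.vector(ends),
                           pcc = p[idx],
                           distance = coexpression_distance(p[idx]))
  }
  g
}

#' Local transitivity (clustering coefficient) of a node
#'
#' Fraction of a node's neighbor pairs that are themselves connected; nodes
#' of degree < 2 have transitivity 0.
#'
#' @param node Vertex name.
#' @param network An igraph graph.
#' @return Fraction in `[0, 1]`.
#' @export
local_transitivity <- function(node, network) {
  unname(igraph::transitivity(network, type = "localundirected", vids = node,
                              isolates = "zero"))
}

#' First-order ego network of a candidate cluster
#'
#' Extends the cluster's coexpression network with genes from elsewhere on
#' the genome that either (i) belong to another candidate cluster and
#' correlate above the PCC threshold with at least one focal gene, or (ii)
#' carry a biosynthetic domain and correlate above the threshold with at
#' least two focal genes, at least one of which is itself biosynthetic.
#' Edges join any two member genes whose PCC exceeds the threshold.
#'
#' @param focal_cluster_id Cluster id of the focal cluster.
#' @param clusters A `bgc_clusters` data frame.
#' @param annotations An `enzyme_annotation` data frame (genome-wide).
#' @param matrix An `expression_matrix`.
#' @param pcc_threshold Admission/edge threshold; default 0.9.
#' @return igraph graph; vertex attribute `role` tags nodes as
#'   `"in-cluster"`, `"other-cluster"` or `"unclustered-biosynthetic"`.
#' @export
build_ego_network <- function(focal_cluster_id, clusters, annotations, matrix,
                              pcc_threshold = 0.9) {
  fi <- match(focal_cluster_id, clusters$cluster_id)
  if (is.na(fi)) stop("unknown cluster id: ", focal_cluster_id)
  focal <- intersect(clusters$gene_ids[[fi]], rownames(matrix))
  other_cluster_genes <- setdiff(unlist(clusters$gene_ids[-fi]), focal)
  bio <- annotations$gene_id[annotations$is_biosynthetic]
  focal_bio <- intersect(focal, bio)
  outside <- setdiff(rownames(matrix), focal)
  cand <- union(intersect(outside, other_cluster_genes),
                intersect(outside, bio))
  admitted <- character(); role <- character()
  if (length(cand) && length(focal)) {
    p <- .pcc_matrix(matrix, c(focal, cand))
    for (g in cand) {
      cors <- p[g, focal]
      high <- names(cors)[!is.na(cors) & cors > pcc_threshold]
      if (g %in% other_cluster_genes) {
        if (length(high) >= 1L) { admitted <- c(admitted, g); role <- c(role, "other-cluster") }
      } else if (length(high) >= 2L && length(intersect(high, focal_bio)) >= 1L) {
        admitted <- c(admitted, g); role <- c(role, "unclustered-biosynthetic")
      }
    }
  }
  nodes <- c(focal, admitted)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes,
                            role = c(rep("in-cluster", length(focal)), role))
  if (length(nodes) >= 2L) {
    p <- .pcc_matrix(matrix, nodes)
    p <- p[nodes, nodes]
    idx <- which(upper.tri(p) & !is.na(p) & p > pcc_threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      ends <- rbind(nodes[idx[, 1L]], nodes[idx[, 2L]])
      g <- igraph::add_edges(g, as.vector(ends), pcc = p[idx],
                             distance = coexpression_distance(p[idx]))
    }
  }
  g
}

#' Inter-cluster linkage via Louvain communities
#'
#' Builds the full coexpression network over all candidate clusters' genes
#' (edges at PCC above `pcc_threshold`), partitions it with Louvain, and
#' declares a pair of clusters linked when some subnetwork satisfies: (i)
#' one community, (ii) every node has local transitivity > 0, (iii) at least
#' two genes from each cluster, (iv) at least one biosynthetic gene per
#' cluster, (v) at least three biosynthetic genes in total.  Candidate
#' subnetworks are the connected components of the pair's genes within a
#' community, pruned of zero-transitivity nodes to a fixed point when needed.
#'
#' @param clusters A `bgc_clusters` data frame.
#' @param annotations An `enzyme_annotation` data frame.
#' @param matrix An `expression_matrix`.
#' @param pcc_threshold Edge threshold; default 0.9.
#' @param seed RNG seed for the Louvain pass; default 42.
#' @return Data frame: cluster_a, cluster_b, witness (list of gene-id
#'   vectors), community.
#' @export
intercluster_links <- function(clusters, annotations, matrix,
                               pcc_threshold = 0.9, seed = 42L) {
  empty <- data.frame(cluster_a = integer(), cluster_b = integer(),
                      community = integer(), stringsAsFactors = FALSE)
  empty$witness <- list()
  if (nrow(clusters) < 2L) return(empty)
  gene_cluster <- stats::setNames(
    rep(clusters$cluster_id, lengths(clusters$gene_ids)),
    unlist(clusters$gene_ids))
  genes <- intersect(names(gene_cluster), rownames(matrix))
  if (length(genes) < 4L) return(empty)
  p <- .pcc_matrix(matrix, genes)
  idx <- which(upper.tri(p) & !is.na(p) & p > pcc_threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, as.vector(rbind(genes[idx[, 1L]], genes[idx[, 2L]])),
                           pcc = p[idx])
  }
  comm <- withr::with_seed(seed, igraph::cluster_louvain(g, resolution = 1))
  memb <- igraph::membership(comm)
  bio <- annotations$gene_id[annotations$is_biosynthetic]
  links <- list()
  for (cm in sort(unique(memb))) {
    cgenes <- names(memb)[memb == cm]
    cl_present <- sort(unique(gene_cluster[cgenes]))
    if (length(cl_present) < 2L) next
    pairs <- utils::combn(cl_present, 2L)
    for (k in seq_len(ncol(pairs))) {
      ca <- pairs[1L, k]; cb <- pairs[2L, k]
      pg <- cgenes[gene_cluster[cgenes] %in% c(ca, cb)]
      sub <- igraph::induced_subgraph(g, pg)
      wit <- .find_witness(sub, gene_cluster, bio, ca, cb)
      if (!is.null(wit)) {
        links[[length(links) + 1L]] <- list(cluster_a = ca, cluster_b = cb,
                                            community = as.integer(cm),
                                            witness = wit)
      }
    }
  }
  if (length(links) == 0L) return(empty)
  out <- data.frame(cluster_a = vapply(links, `[[`, numeric(1), "cluster_a"),
                    cluster_b = vapply(links, `[[`, numeric(1), "cluster_b"),
                    community = vapply(links, `[[`, integer(1), "community"),
                    stringsAsFactors = FALSE)
  out$witness <- lapply(links, `[[`, "witness")
  # one witness per qualifying cluster pair
  out <- out[!duplicated(out[, c("cluster_a", "cluster_b")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Search one community-restricted cluster-pair graph for a node set meeting
# criteria (ii)-(v); returns the witness gene ids or NULL.
.find_witness <- function(sub, gene_cluster, bio, ca, cb) {
  check <- function(nodes, graph) {
    if (length(nodes) < 4L) return(FALSE)
    s <- igraph::induced_subgraph(graph, nodes)
    tr <- igraph::transitivity(s, type = "localundirected", isolates = "zero")
    if (any(tr <= 0)) return(FALSE)
    cl <- gene_cluster[nodes]
    nb <- sum(nodes %in% bio)
    sum(cl == ca) >= 2L && sum(cl == cb) >= 2L && nb >= 3L &&
      any(nodes[cl == ca] %in% bio) && any(nodes[cl == cb] %in% bio)
  }
  comps <- igraph::components(sub)
  for (ci in seq_len(comps$no)) {
    nodes <- names(comps$membership)[comps$membership == ci]
    if (check(nodes, sub)) return(sort(nodes))
    # prune zero-transitivity nodes to a fixed point, then re-test components
    cur <- nodes
    repeat {
      if (length(cur) < 4L) break
      s <- igraph::induced_subgraph(sub, cur)
      tr <- igraph::transitivity(s, type = "localundirected", isolates = "zero")
      drop <- igraph::V(s)$name[tr <= 0]
      if (length(drop) == 0L) break
      cur <- setdiff(cur, drop)
    }
    if (length(cur) >= 4L) {
      s <- igraph::induced_subgraph(sub, cur)
      sc <- igraph::components(s)
      for (cj in seq_len(sc$no)) {
        nn <- names(sc$membership)[sc$membership == cj]
        if (check(nn, s)) return(sort(nn))
      }
    }
  }
  NULL
}

#' Export a coexpression network
#'
#' @param network An igraph graph.
#' @param path Output path; format from extension (`.graphml` or `.json`).
#' @export
write_network <- function(network, path) {
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(network, what = "both")
    jsonlite::write_json(list(nodes = el$vertices, edges = el$edges), path,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
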