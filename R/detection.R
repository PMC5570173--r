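# Candidate cluster detection: dynamic gene-density cutoff, chaining of
# biosynthetic genes, the minimum subclass/class rule, extension with
# flanking genes, and product classification.

#' Default detection configuration
#'
#' @param min_subclasses Minimum distinct enzyme subclasses (identity groups)
#'   in a cluster; default 3.
#' @param min_classes Minimum distinct enzyme classes; default 2.
#' @param cdhit_threshold Identity threshold for subclass grouping; default
#'   0.5 (>50% identity merges).
#' @param density_multiplier Multiplier applied to the mean per-gene spacing
#'   of the 10-gene window to obtain the chaining cutoff in kb; default 5.
#' @param cutoff_mode One of `"density"` (dynamic, default), `"distance"`
#'   (fixed kb) or `"genecount"` (max intervening genes).
#' @param fixed_kb Cutoff for `"distance"` mode; default 20 kb.
#' @param max_gene_gap Max intervening genes for `"genecount"` mode; default 10.
#' @param min_kb,max_kb Clamp for the dynamic cutoff; defaults 10 and 100 kb.
#' @return Named list of settings.
#' @export
detection_config <- function(min_subclasses = 3L, min_classes = 2L,
                             cdhit_threshold = 0.5, density_multiplier = 5,
                             cutoff_mode = c("density", "distance", "genecount"),
                             fixed_kb = 20, max_gene_gap = 10L,
                             min_kb = 10, max_kb = 100) {
  list(min_subclasses = as.integer(min_subclasses),
       min_classes = as.integer(min_classes),
       cdhit_threshold = cdhit_threshold,
       density_multiplier = density_multiplier,
       cutoff_mode = match.arg(cutoff_mode),
       fixed_kb = fixed_kb, max_gene_gap = as.integer(max_gene_gap),
       min_kb = min_kb, max_kb = max_kb)
}

#' Local gene density around a hit gene
#'
#' Density of the ten genes nearest to the hit (the hit gene included),
#' nearest by midpoint distance; ties go to the lower-coordinate gene.  On a
#' record with fewer than ten genes the whole record forms the window.
#'
#' @param gene_id Hit gene.
#' @param genome An `annotated_genome`.
#' @param window_size Window size in genes; default 10.
#' @return List: gene_id, window_genes (ids), window_span_kb, local_density
#'   (genes/kb).
#' @export
local_gene_density <- function(gene_id, genome, window_size = 10L) {
  g <- genome$genes
  i <- match(gene_id, g$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id)
  rec <- g[g$record_id == g$record_id[i], , drop = FALSE]
  mid <- (rec$start + rec$end) / 2
  d <- abs(mid - mid[match(gene_id, rec$gene_id)])
  ord <- order(d, rec$start)
  w <- rec[ord[seq_len(min(window_size, nrow(rec)))], , drop = FALSE]
  span_kb <- (max(w$end) - min(w$start) + 1) / 1000
  list(gene_id = gene_id, window_genes = w$gene_id[order(w$start)],
       window_span_kb = span_kb, local_density = nrow(w) / span_kb)
}

#' Dynamic chaining cutoff from local gene density
#'
#' The cutoff in kb is a linear function of local density:
#' `multiplier * mean per-gene spacing` of the window (span / window genes),
#' clamped to `[min_kb, max_kb]` -- dense regions get tight cutoffs, sparse
#' regions generous ones.
#'
#' @param context Result of [local_gene_density()].
#' @param multiplier Positive multiplier; default 5.
#' @param min_kb,max_kb Clamp bounds; defaults 10 and 100 kb.
#' @return Cutoff in kilobases.
#' @export
dynamic_cutoff_kb <- function(context, multiplier = 5, min_kb = 10, max_kb = 100) {
  stopifnot(multiplier > 0)
  raw <- multiplier * context$window_span_kb / length(context$window_genes)
  min(max(raw, min_kb), max_kb)
}

# Per-hit cutoff in kb under the configured mode.
.hit_cutoffs_kb <- function(genome, hit_ids, config) {
  switch(config$cutoff_mode,
    density = vapply(hit_ids, function(h)
      dynamic_cutoff_kb(local_gene_density(h, genome),
                        config$density_multiplier, config$min_kb,
                        config$max_kb), numeric(1)),
    distance = stats::setNames(rep(config$fixed_kb, length(hit_ids)), hit_ids),
    genecount = stats::setNames(rep(NA_real_, length(hit_ids)), hit_ids))
}

#' Chain nearby biosynthetic genes into seed loci
#'
#' Consecutive hit genes on a record merge into one locus when the gap
#' between gene bodies (end of one to start of the next) does not exceed the
#' larger of their two cutoffs; chaining is transitive.  In `"genecount"`
#' mode the gap criterion is the number of intervening genes instead.
#'
#' @param genome An `annotated_genome`.
#' @param hit_ids Biosynthetic (hit) gene ids.
#' @param cutoffs_kb Named numeric, per-hit cutoff in kb (ignored for
#'   genecount mode).
#' @param config Detection configuration.
#' @return List of character vectors (hit gene ids per locus), in genome order.
#' @export
chain_candidate_loci <- function(genome, hit_ids, cutoffs_kb,
                                 config = detection_config()) {
  g <- genome$genes
  hits <- g[g$gene_id %in% hit_ids, , drop = FALSE]
  loci <- list()
  for (rec in unique(hits$record_id)) {
    h <- hits[hits$record_id == rec, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    cur <- h$gene_id[1L]
    for (i in seq_len(nrow(h) - 1L)) {
      a <- h[i, ]; b <- h[i + 1L, ]
      merge <- if (config$cutoff_mode == "genecount") {
        rec_genes <- g[g$record_id == rec, , drop = FALSE]
        ia <- match(a$gene_id, rec_genes$gene_id)
        ib <- match(b$gene_id, rec_genes$gene_id)
        (ib - ia - 1L) <= config$max_gene_gap
      } else {
        gap_bp <- b$start - a$end - 1L
        gap_bp <= 1000 * max(cutoffs_kb[[a$gene_id]], cutoffs_kb[[b$gene_id]])
      }
      if (merge) {
        cur <- c(cur, b$gene_id)
      } else {
        loci <- c(loci, list(cur))
        cur <- b$gene_id
      }
    }
    loci <- c(loci, list(cur))
  }
  loci
}

#' Apply the minimum subclass/class rule to a seed locus
#'
#' Within each enzyme class present at the locus, proteins are grouped by
#' identity ([greedy_cluster()]); the subclass count is the total number of
#' identity groups across classes, so tandem arrays of near-identical genes
#' count once.  A locus is accepted when it holds at least `min_subclasses`
#' subclasses from at least `min_classes` classes.
#'
#' @param locus_hit_ids Hit gene ids of the locus.
#' @param annotations An `enzyme_annotation` data frame.
#' @param proteins Named character vector gene_id -> protein.
#' @param config Detection configuration.
#' @return List: accept (logical), subclass_count, class_count,
#'   groups_by_class.
#' @export
evaluate_minimum_rule <- function(locus_hit_ids, annotations, proteins,
                                  config = detection_config()) {
  ann <- annotations[annotations$gene_id %in% locus_hit_ids, , drop = FALSE]
  classes <- sort(unique(unlist(ann$enzyme_classes)))
  groups_by_class <- list()
  n_sub <- 0L
  for (cl in classes) {
    in_cl <- ann$gene_id[vapply(ann$enzyme_classes, function(x) cl %in% x,
                                logical(1))]
    prot <- proteins[in_cl]
    missing <- is.na(prot) | !nzchar(prot) | is.na(names(prot))
    grp <- greedy_cluster(prot[!missing], config$cdhit_threshold, cl)
    # genes without a protein cannot be aligned: each is its own subclass
    n_cl <- nrow(grp) + sum(missing)
    groups_by_class[[cl]] <- grp
    n_sub <- n_sub + n_cl
  }
  list(accept = n_sub >= config$min_subclasses &&
         length(classes) >= config$min_classes,
       subclass_count = n_sub, class_count = length(classes),
       groups_by_class = groups_by_class)
}

#' Extend an accepted locus with flanking genes
#'
#' The cluster takes in every gene (biosynthetic or not) lying between its
#' outermost hit genes, plus flanking genes whose nearest edge is within the
#' outermost hit gene's cutoff.
#'
#' @param locus_hit_ids Hit gene ids.
#' @param genome An `annotated_genome`.
#' @param cutoffs_kb Named per-hit cutoffs in kb; `NA` entries (genecount
#'   mode) disable flank extension beyond the hit span.
#' @return List: record_id, start, end, gene_ids (position-ordered).
#' @export
extend_cluster <- function(locus_hit_ids, genome, cutoffs_kb) {
  g <- genome$genes
  hits <- g[g$gene_id %in% locus_hit_ids, , drop = FALSE]
  rec <- hits$record_id[1L]
  rec_genes <- g[g$record_id == rec, , drop = FALSE]
  rec_genes <- rec_genes[order(rec_genes$start), , drop = FALSE]
  first <- hits[which.min(hits$start), ]
  last <- hits[which.max(hits$end), ]
  left_kb <- cutoffs_kb[[first$gene_id]]
  right_kb <- cutoffs_kb[[last$gene_id]]
  lo <- first$start - if (is.na(left_kb)) 0 else 1000 * left_kb
  hi <- last$end + if (is.na(right_kb)) 0 else 1000 * right_kb
  inside <- rec_genes$start <= last$end & rec_genes$end >= first$start
  flank <- rec_genes$end >= lo & rec_genes$start <= hi
  keep <- rec_genes[inside | flank, , drop = FALSE]
  list(record_id = rec, start = min(keep$start), end = max(keep$end),
       gene_ids = keep$gene_id)
}

#' Classify a cluster by its signature enzymes
#'
#' Signature enzyme classes present among the cluster's genes are mapped to
#' product class labels via the rule table; two or more distinct products
#' additionally label the cluster `"Hybrid"`, none labels it `"Putative"`.
#'
#' @param cluster_gene_ids Gene ids of the cluster.
#' @param annotations An `enzyme_annotation` data frame.
#' @param rule_table Data frame (enzyme_class, product_class); default the
#'   shipped rules.
#' @return Character vector of product class labels.
#' @export
classify_cluster <- function(cluster_gene_ids, annotations, rule_table = NULL) {
  if (is.null(rule_table)) rule_table <- load_product_rules()
  ann <- annotations[annotations$gene_id %in% cluster_gene_ids, , drop = FALSE]
  sig_classes <- unique(unlist(ann$signature_classes))
  products <- unique(rule_table$product_class[rule_table$enzyme_class %in% sig_classes])
  if (length(products) == 0L) return("Putative")
  if (length(products) >= 2L) products <- c(sort(products), "Hybrid")
  products
}

#' Load the product classification rule table
#'
#' @param path Optional path to a rules TSV (enzyme_class, product_class);
#'   default the shipped table.
#' @return Data frame.
#' @export
load_product_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "product_rules.tsv", package = "plantbgc")
  }
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Detect candidate biosynthetic gene clusters
#'
#' Full detection pass: filter domain hits, annotate genes, compute per-hit
#' chaining cutoffs, chain hits into seed loci, apply the minimum
#' subclass/class rule, extend accepted loci with flanking genes, and
#' classify products.  Clusters are numbered sequentially (1-based) in
#' record order.
#'
#' @param genome An `annotated_genome`.
#' @param hits Domain hit data frame (raw; filtering is applied here).
#' @param library A `domain_library`; default the shipped one.
#' @param config Detection configuration from [detection_config()].
#' @param rule_table Product rules; default shipped.
#' @return Data frame of class `bgc_clusters`: cluster_id, record_id, start,
#'   end, product_classes (list), subclass_count, class_count, n_genes,
#'   gene_ids (list), hit_gene_ids (list).
#' @export
detect_clusters <- function(genome, hits, library = load_profile_library(),
                            config = detection_config(), rule_table = NULL) {
  kept <- filter_hits(hits, library)
  ann <- annotate_genes(kept, library)
  proteins <- stats::setNames(genome$genes$protein, genome$genes$gene_id)
  hit_ids <- intersect(genome$genes$gene_id, ann$gene_id[ann$is_biosynthetic])
  empty <- data.frame(cluster_id = integer(), record_id = character(),
                      start = numeric(), end = numeric(),
                      subclass_count = integer(), class_count = integer(),
                      n_genes = integer(), stringsAsFactors = FALSE)
  empty$product_classes <- list(); empty$gene_ids <- list()
  empty$hit_gene_ids <- list()
  class(empty) <- c("bgc_clusters", "data.frame")
  if (length(hit_ids) == 0L) return(empty)
  cutoffs <- .hit_cutoffs_kb(genome, hit_ids, config)
  loci <- chain_candidate_loci(genome, hit_ids, cutoffs, config)
  rows <- list()
  for (locus in loci) {
    rule <- evaluate_minimum_rule(locus, ann, proteins, config)
    if (!rule$accept) next
    ext <- extend_cluster(locus, genome, cutoffs)
    rows[[length(rows) + 1L]] <- list(
      record_id = ext$record_id, start = ext$start, end = ext$end,
      subclass_count = rule$subclass_count, class_count = rule$class_count,
      gene_ids = ext$gene_ids, hit_gene_ids = locus,
      product_classes = classify_cluster(ext$gene_ids, ann, rule_table))
  }
  if (length(rows) == 0L) return(empty)
  out <- data.frame(
    record_id = vapply(rows, `[[`, character(1), "record_id"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    subclass_count = vapply(rows, `[[`, integer(1), "subclass_count"),
    class_count = vapply(rows, `[[`, integer(1), "class_count"),
    stringsAsFactors = FALSE)
  out$gene_ids <- lapply(rows, `[[`, "gene_ids")
  out$hit_gene_ids <- lapply(rows, `[[`, "hit_gene_ids")
  out$product_classes <- lapply(rows, `[[`, "product_classes")
  out <- out[order(out$record_id, out$start), , drop = FALSE]
  # neighboring clusters must not overlap: trim extensions at the gene-index
  # midpoint between adjacent hit spans
  gsorted <- genome$genes
  for (rec in unique(out$record_id)) {
    idx <- which(out$record_id == rec)
    if (length(idx) < 2L) next
    rg <- gsorted[gsorted$record_id == rec, , drop = FALSE]
    rg <- rg[order(rg$start), , drop = FALSE]
    for (k in seq_len(length(idx) - 1L)) {
      a <- idx[k]; b <- idx[k + 1L]
      if (out$end[a] < out$start[b]) next
      a_last_hit <- max(match(out$hit_gene_ids[[a]], rg$gene_id))
      b_first_hit <- min(match(out$hit_gene_ids[[b]], rg$gene_id))
      cutpt <- floor((a_last_hit + b_first_hit) / 2)
      a_keep <- rg$gene_id[seq_len(cutpt)]
      b_keep <- rg$gene_id[(cutpt + 1L):nrow(rg)]
      out$gene_ids[[a]] <- intersect(out$gene_ids[[a]], a_keep)
      out$gene_ids[[b]] <- intersect(out$gene_ids[[b]], b_keep)
      out$start[a] <- min(rg$start[rg$gene_id %in% out$gene_ids[[a]]])
      out$end[a] <- max(rg$end[rg$gene_id %in% out$gene_ids[[a]]])
      out$start[b] <- min(rg$start[rg$gene_id %in% out$gene_ids[[b]]])
      out$end[b] <- max(rg$end[rg$gene_id %in% out$gene_ids[[b]]])
    }
  }
  out$cluster_id <- seq_len(nrow(out))
  out$n_genes <- lengths(out$gene_ids)
  rownames(out) <- NULL
  out <- out[, c("cluster_id", "record_id", "start", "end", "product_classes",
                 "subclass_count", "class_count", "n_genes", "gene_ids",
                 "hit_gene_ids")]
  class(out) <- c("bgc_clusters", "data.frame")
  out
}

#' @export
print.bgc_clusters <- function(x, ...) {
  cat(nrow(x), "candidate cluster(s)\n")
  if (nrow(x) > 0L) {
    show <- data.frame(cluster_id = x$cluster_id, record = x$record_id,
                       start = x$start, end = x$end,
                       product = vapply(x$product_classes, paste,
                                        character(1), collapse = ","),
                       subclasses = x$subclass_count, classes = x$class_count,
                       genes = x$n_genes)
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.bgc_clusters <- function(object, ...) {
  cat(nrow(object), "candidate cluster(s);",
      sum(lengths(object$gene_ids)), "genes included\n")
  tab <- table(unlist(object$product_classes))
  if (length(tab)) print(tab)
  invisible(object)
}

#' Write detected clusters as BED
#'
#' @param clusters A `bgc_clusters` data frame.
#' @param path Output path.  BED is 0-based half-open; conversion happens
#'   here at the boundary.
#' @export
write_clusters_bed <- function(clusters, path) {
  lines <- sprintf("%s\t%d\t%d\tcluster%d_%s\t%d\t.",
                   clusters$record_id, as.integer(clusters$start) - 1L,
                   as.integer(clusters$end), clusters$cluster_id,
                   vapply(clusters$product_classes, paste, character(1),
                          collapse = ";"),
                   pmin(1000L, clusters$subclass_count * 100L))
  writeLines(lines, path)
  invisible(path)
}

#' Write detected clusters as GFF3
#'
#' @param clusters A `bgc_clusters` data frame.
#' @param path Output path.
#' @export
write_clusters_gff3 <- function(clusters, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(clusters))) {
    writeLines(sprintf(
      "%s\tplantbgc\tbiosynthetic_gene_cluster\t%d\t%d\t.\t.\t.\tID=cluster%d;product=%s;subclasses=%d;classes=%d",
      clusters$record_id[i], as.integer(clusters$start[i]),
      as.integer(clusters$end[i]), clusters$cluster_id[i],
      paste(clusters$product_classes[[i]], collapse = ","),
      clusters$subclass_count[i], clusters$class_count[i]), con)
  }
  invisible(path)
}
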