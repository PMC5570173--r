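# Orchestration: run the full pass (annotate -> group -> detect -> classify
# -> coexpress -> prioritize -> compare) and write machine-readable outputs.

#' Assemble a run configuration
#'
#' @param fasta,gff3,genbank Input genome (FASTA+GFF3, or GenBank).
#' @param hits Path to a domain hit table (domtblout or TSV); alternatively
#'   `hmm_db` + `hmmer_bin` to scan proteins externally.
#' @param hmm_db,hmmer_bin Optional external HMMER scan inputs.
#' @param expression Character vector of expression file paths (CSV or SOFT;
#'   one experiment per file).
#' @param outdir Output directory.
#' @param min_subclasses,min_classes,cdhit_threshold,density_multiplier,cutoff_mode,fixed_kb,max_gene_gap,min_kb,max_kb
#'   Detection thresholds; see [detection_config()].
#' @param network_cutoff Coexpression network distance cutoff; default 50.
#' @param ego_pcc Ego-network / linkage PCC threshold; default 0.9.
#' @param alpha Prioritization significance level; default 0.05.
#' @param seed RNG seed; default 42.
#' @param compare_db Optional path to a locus database directory.
#' @return A `run_config` list.
#' @export
run_config <- function(fasta = NULL, gff3 = NULL, genbank = NULL, hits = NULL,
                       hmm_db = NULL, hmmer_bin = "hmmscan",
                       expression = character(), outdir = "plantbgc_out",
                       min_subclasses = 3L, min_classes = 2L,
                       cdhit_threshold = 0.5, density_multiplier = 5,
                       cutoff_mode = "density", fixed_kb = 20,
                       max_gene_gap = 10L, min_kb = 10, max_kb = 100,
                       network_cutoff = 50, ego_pcc = 0.9, alpha = 0.05,
                       seed = 42L, compare_db = NULL) {
  structure(list(
    fasta = fasta, gff3 = gff3, genbank = genbank, hits = hits,
    hmm_db = hmm_db, hmmer_bin = hmmer_bin, expression = expression,
    outdir = outdir,
    detection = detection_config(min_subclasses, min_classes, cdhit_threshold,
                                 density_multiplier, cutoff_mode, fixed_kb,
                                 max_gene_gap, min_kb, max_kb),
    network_cutoff = network_cutoff, ego_pcc = ego_pcc, alpha = alpha,
    seed = as.integer(seed), compare_db = compare_db), class = "run_config")
}

.stage_log <- function(stage, ...) {
  message(sprintf("[plantbgc] %s: %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' Stages run in order: input parsing, domain filtering and annotation,
#' cluster detection and classification, then (when expression data is
#' supplied) per-experiment coexpression artifacts, inter-cluster linkage
#' and Mann-Whitney prioritization, then (when a locus database is
#' supplied) comparative ranking.  All outputs are written under
#' `config$outdir`; a stage failure aborts with the stage name.
#'
#' @param config A `run_config`.
#' @return A `run_result` list: clusters, prioritization, links, matches,
#'   and provenance (config hash, seed, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      at <- conditionCall(e)
      stop("stage '", name, "' failed",
           if (!is.null(at)) paste0(" in ", deparse(at)[1L]), ": ",
           conditionMessage(e), call. = FALSE)
    })
  }
  genome <- stage("genome_io", {
    if (!is.null(config$genbank)) {
      read_genbank(config$genbank)
    } else {
      seqs <- if (!is.null(config$fasta)) read_genome_fasta(config$fasta) else NULL
      if (is.null(config$gff3)) stop("need --gff3 (or --genbank)")
      merge_annotations(seqs, read_gff3(config$gff3))
    }
  })
  .stage_log("genome_io", "%d record(s), %d gene(s)",
             nrow(genome$records), nrow(genome$genes))
  library <- load_profile_library()
  hits <- stage("domain_model", {
    if (!is.null(config$hits)) {
      parse_domain_table(config$hits)
    } else if (!is.null(config$hmm_db)) {
      prot <- stats::setNames(genome$genes$protein, genome$genes$gene_id)
      run_hmmscan(prot[!is.na(prot)], config$hmm_db, config$hmmer_bin)
    } else stop("need --hits or --hmm-db")
  })
  kept <- filter_hits(hits, library)
  ann <- annotate_genes(kept, library)
  .stage_log("domain_model", "%d hit(s) parsed, %d kept, %d gene(s) annotated",
             nrow(hits), nrow(kept), nrow(ann))
  clusters <- stage("detection",
                    detect_clusters(genome, hits, library, config$detection))
  .stage_log("detection", "%d cluster(s) accepted", nrow(clusters))
  write_clusters_bed(clusters, file.path(config$outdir, "clusters.bed"))
  write_clusters_gff3(clusters, file.path(config$outdir, "clusters.gff3"))
  cl_tab <- data.frame(cluster_id = clusters$cluster_id,
                       record_id = clusters$record_id,
                       start = clusters$start, end = clusters$end,
                       product = vapply(clusters$product_classes, paste,
                                        character(1), collapse = ";"),
                       subclass_count = clusters$subclass_count,
                       class_count = clusters$class_count,
                       n_genes = clusters$n_genes,
                       genes = vapply(clusters$gene_ids, paste, character(1),
                                      collapse = ";"))
  utils::write.table(cl_tab, file.path(config$outdir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  prioritization <- NULL; links <- NULL; matrices <- NULL
  if (length(config$expression) > 0L && nrow(clusters) > 0L) {
    matrices <- stage("coexpress_io", lapply(config$expression, function(p) {
      if (grepl("\\.soft(\\.txt)?$", p, ignore.case = TRUE)) read_soft(p)
      else read_expression_csv(p)
    }))
    stage("coexpress", {
      for (m in matrices) {
        eid <- attr(m, "experiment_id")
        for (i in seq_len(nrow(clusters))) {
          genes <- intersect(clusters$gene_ids[[i]], rownames(m))
          if (length(genes) < 3L) next
          net <- build_cluster_network(genes, m, config$network_cutoff)
          write_network(net, file.path(config$outdir,
                                       sprintf("network_%s_cluster%d.graphml",
                                               eid, clusters$cluster_id[i])))
          ord <- tryCatch(hierarchical_order(genes, m), error = function(e) NULL)
          if (!is.null(ord)) {
            jsonlite::write_json(
              list(order = ord$order, merge = ord$hclust$merge,
                   height = ord$hclust$height,
                   heatmap = normalize_heatmap(m[ord$order, , drop = FALSE])),
              file.path(config$outdir,
                        sprintf("heatmap_%s_cluster%d.json", eid,
                                clusters$cluster_id[i])),
              auto_unbox = TRUE, digits = NA)
          }
          ego <- build_ego_network(clusters$cluster_id[i], clusters, ann, m,
                                   config$ego_pcc)
          write_network(ego, file.path(config$outdir,
                                       sprintf("ego_%s_cluster%d.graphml",
                                               eid, clusters$cluster_id[i])))
        }
      }
      links <- intercluster_links(clusters, ann, matrices[[1L]],
                                  config$ego_pcc, config$seed)
      if (nrow(links)) {
        ltab <- data.frame(cluster_a = links$cluster_a,
                           cluster_b = links$cluster_b,
                           witness = vapply(links$witness, paste, character(1),
                                            collapse = ";"))
        utils::write.table(ltab, file.path(config$outdir, "hive_links.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
    .stage_log("coexpress", "%d experiment(s), %d inter-cluster link(s)",
               length(matrices), if (is.null(links)) 0L else nrow(links))
    prioritization <- stage("prioritize", {
      prot <- stats::setNames(genome$genes$protein, genome$genes$gene_id)
      prot <- prot[!is.na(prot) & nzchar(prot)]
      gmap <- if (length(prot) > 1L && length(prot) <= 500L) {
        identity_group_map(prot, config$detection$cdhit_threshold)
      } else NULL
      prioritize(clusters, genome, matrices, config$alpha, gmap)
    })
    utils::write.table(as.data.frame(prioritization),
                       file.path(config$outdir, "prioritization.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .stage_log("prioritize", "%d cluster(s) tested, %d significant at alpha=%g",
               sum(!is.na(prioritization$p)), sum(prioritization$significant),
               config$alpha)
  } else if (length(config$expression) == 0L) {
    .stage_log("coexpress", "skipped (no expression data supplied)")
  }

  matches <- NULL
  if (!is.null(config$compare_db) && nrow(clusters) > 0L) {
    matches <- stage("compare", {
      db <- read_locus_db(config$compare_db)
      res <- list()
      for (i in seq_len(nrow(clusters))) {
        idx <- match(clusters$gene_ids[[i]], genome$genes$gene_id)
        q <- data.frame(gene_id = clusters$gene_ids[[i]],
                        protein = genome$genes$protein[idx],
                        stringsAsFactors = FALSE)
        h <- search_homologs(q, db)
        r <- rank_loci(h, db)
        if (nrow(r)) r$query_cluster <- clusters$cluster_id[i]
        res[[i]] <- r
      }
      do.call(rbind, res)
    })
    if (!is.null(matches) && nrow(matches)) {
      utils::write.table(matches, file.path(config$outdir, "compare.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .stage_log("compare", "%d locus match(es)",
               if (is.null(matches)) 0L else nrow(matches))
  }

  cfg_plain <- unclass(config)
  provenance <- list(
    package = "plantbgc",
    version = as.character(utils::packageVersion("plantbgc")),
    seed = config$seed,
    config = cfg_plain,
    config_hash = .config_hash(cfg_plain))
  result <- structure(list(clusters = clusters, prioritization = prioritization,
                           links = links, matches = matches,
                           provenance = provenance), class = "run_result")
  jsonlite::write_json(
    list(provenance = provenance, clusters = cl_tab,
         prioritization = if (!is.null(prioritization))
           as.data.frame(prioritization) else NULL),
    file.path(config$outdir, "run.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null",
    force = TRUE)
  result
}

.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE,
                        null = "null")
  # small polynomial rolling hash over the serialized config: stable,
  # dependency-free provenance fingerprint (not cryptographic)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.run_result <- function(x, ...) {
  cat("plantbgc run:", nrow(x$clusters), "cluster(s)")
  if (!is.null(x$prioritization)) {
    cat(";", sum(x$prioritization$significant), "significant by coexpression")
  }
  cat("\n")
  invisible(x)
}
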