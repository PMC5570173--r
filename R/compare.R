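# ClusterBlast-style comparative search: a relaxed-threshold locus database
# and synteny-aware ranking of homologous loci for a query cluster.

#' Build a relaxed-threshold locus database
#'
#' Re-runs detection with the inclusive settings used for homology search:
#' at least two distinct identity groups, no class-count requirement, and a
#' generous 0.9 identity threshold so near-duplicates still collapse but
#' diverged homologous loci are retained.
#'
#' @param genomes Named list of `annotated_genome` objects (name = source
#'   genome label).
#' @param hits_list List of hit data frames, parallel to `genomes`.
#' @param library A `domain_library`; default shipped.
#' @param config Base detection config; the relaxed thresholds are applied
#'   on top.
#' @return Object of class `locus_db`: list of locus records, each a list
#'   with locus_id, source_genome and a gene data frame (gene_id, protein,
#'   enzyme_class).
#' @export
build_locus_db <- function(genomes, hits_list,
                           library = load_profile_library(),
                           config = detection_config()) {
  config$min_subclasses <- 2L
  config$min_classes <- 1L
  config$cdhit_threshold <- 0.9
  loci <- list()
  for (gn in names(genomes)) {
    genome <- genomes[[gn]]
    cl <- detect_clusters(genome, hits_list[[gn]], library, config)
    kept <- filter_hits(hits_list[[gn]], library)
    ann <- annotate_genes(kept, library)
    for (i in seq_len(nrow(cl))) {
      ids <- cl$gene_ids[[i]]
      gidx <- match(ids, genome$genes$gene_id)
      classes <- vapply(ids, function(g) {
        j <- match(g, ann$gene_id)
        if (is.na(j)) NA_character_ else paste(ann$enzyme_classes[[j]], collapse = ";")
      }, character(1))
      loci[[length(loci) + 1L]] <- list(
        locus_id = sprintf("%s_locus%d", gn, cl$cluster_id[i]),
        source_genome = gn,
        genes = data.frame(gene_id = ids,
                           protein = genome$genes$protein[gidx],
                           enzyme_class = unname(classes),
                           stringsAsFactors = FALSE))
    }
  }
  structure(loci, class = "locus_db")
}

#' @export
print.locus_db <- function(x, ...) {
  cat("Locus database:", length(x), "locus record(s)\n")
  invisible(x)
}

#' Write / read a locus database as plain text
#'
#' The on-disk form is a directory holding `loci.tsv` (locus_id,
#' source_genome, gene_id, position) and `proteins.faa`.
#'
#' @param db A `locus_db`.
#' @param dir Directory path.
#' @export
write_locus_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(db, function(l) {
    data.frame(locus_id = l$locus_id, source_genome = l$source_genome,
               gene_id = l$genes$gene_id,
               position = seq_len(nrow(l$genes)),
               enzyme_class = l$genes$enzyme_class,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, file.path(dir, "loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prot <- unlist(lapply(db, function(l)
    stats::setNames(l$genes$protein, paste0(l$locus_id, "|", l$genes$gene_id))))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(prot),
                              file.path(dir, "proteins.faa"))
  invisible(dir)
}

#' @rdname write_locus_db
#' @export
read_locus_db <- function(dir) {
  rows <- utils::read.delim(file.path(dir, "loci.tsv"), stringsAsFactors = FALSE)
  prot <- Biostrings::readAAStringSet(file.path(dir, "proteins.faa"))
  pmap <- stats::setNames(as.character(prot), names(prot))
  db <- lapply(split(rows, rows$locus_id), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    list(locus_id = d$locus_id[1L], source_genome = d$source_genome[1L],
         genes = data.frame(gene_id = d$gene_id,
                            protein = unname(pmap[paste0(d$locus_id, "|", d$gene_id)]),
                            enzyme_class = d$enzyme_class,
                            stringsAsFactors = FALSE))
  })
  structure(unname(db[order(names(db))]), class = "locus_db")
}

# Gapped BLOSUM62 Karlin-Altschul constants for the bitscore approximation.
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

# Local BLOSUM62 alignment of two proteins -> list(raw, bits, identity).
.align_pair <- function(q, s) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  raw <- Biostrings::score(aln)
  bits <- (.KA_LAMBDA * raw - log(.KA_K)) / log(2)
  w <- Biostrings::nchar(aln)
  list(raw = raw, bits = bits,
       identity = if (w > 0) Biostrings::nmatch(aln) / w else 0)
}

#' Search a query cluster's proteins against a locus database
#'
#' Internal backend: exact local protein alignment (BLOSUM62) with a
#' bitscore approximation; per query gene the best hit in each locus above
#' the identity and bitscore floors is reported.
#'
#' @param query Data frame with columns gene_id and protein (e.g. the gene
#'   table of a detected cluster).
#' @param db A `locus_db`.
#' @param min_identity Identity floor on the aligned region; default 0.3.
#' @param min_bits Bitscore floor; default 30.
#' @return Data frame: query_gene, query_pos, locus_id, subject_gene,
#'   subject_pos, identity, bitscore.
#' @export
search_homologs <- function(query, db, min_identity = 0.3, min_bits = 30) {
  stopifnot(all(c("gene_id", "protein") %in% names(query)))
  rows <- list()
  for (l in db) {
    for (qi in seq_len(nrow(query))) {
      qp <- query$protein[qi]
      if (is.na(qp) || !nzchar(qp)) next
      best <- NULL
      for (si in seq_len(nrow(l$genes))) {
        sp <- l$genes$protein[si]
        if (is.na(sp) || !nzchar(sp)) next
        a <- .align_pair(qp, sp)
        if (a$identity < min_identity || a$bits < min_bits) next
        if (is.null(best) || a$bits > best$bits) {
          best <- list(bits = a$bits, identity = a$identity, si = si)
        }
      }
      if (!is.null(best)) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_gene = query$gene_id[qi], query_pos = qi,
          locus_id = l$locus_id, subject_gene = l$genes$gene_id[best$si],
          subject_pos = best$si, identity = best$identity,
          bitscore = best$bits, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(query_gene = character(), query_pos = integer(),
                      locus_id = character(), subject_gene = character(),
                      subject_pos = integer(), identity = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Longest increasing subsequence length (O(n^2); hit lists are short).
.lis_length <- function(v) {
  n <- length(v)
  if (n == 0L) return(0L)
  best <- rep(1L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (v[j] < v[i] && best[j] + 1L > best[i]) best[i] <- best[j] + 1L
    }
  }
  max(best)
}

#' Rank database loci against a query cluster
#'
#' Loci are sorted lexicographically by number of query genes hit, then
#' conserved synteny (length of the longest common ordered run of hit
#' positions, orientation-insensitive), then cumulative bitscore; final
#' tie-break is the locus id, making the order total and deterministic.
#'
#' @param hits Result of [search_homologs()].
#' @param db A `locus_db` (for the full locus listing; loci without hits are
#'   omitted).
#' @return Data frame of class `locus_matches`: locus_id, source_genome,
#'   n_hits, synteny_score, cumulative_bitscore.
#' @export
rank_loci <- function(hits, db) {
  src <- stats::setNames(vapply(db, `[[`, character(1), "source_genome"),
                         vapply(db, `[[`, character(1), "locus_id"))
  sp <- split(hits, hits$locus_id)
  out <- do.call(rbind, lapply(sp, function(h) {
    h <- h[order(h$query_pos), , drop = FALSE]
    syn <- max(.lis_length(h$subject_pos), .lis_length(rev(h$subject_pos)))
    data.frame(locus_id = h$locus_id[1L],
               source_genome = unname(src[h$locus_id[1L]]),
               n_hits = length(unique(h$query_gene)),
               synteny_score = syn,
               cumulative_bitscore = sum(h$bitscore),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(locus_id = character(), source_genome = character(),
                      n_hits = integer(), synteny_score = integer(),
                      cumulative_bitscore = numeric(), stringsAsFactors = FALSE)
  } else {
    out <- out[order(-out$n_hits, -out$synteny_score,
                     -out$cumulative_bitscore, out$locus_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("locus_matches", "data.frame")
  out
}
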