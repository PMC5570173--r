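# Test-side helpers: minimal object constructors and independent brute-force
# oracles, deliberately written without reference to the package internals.

# Minimal annotated genome from a gene table (no sequences needed for
# order/distance logic).
make_test_genome <- function(genes, cds = NULL) {
  genes <- genes[order(genes$record_id, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  if (is.null(genes$protein)) genes$protein <- NA_character_
  rec <- unique(genes$record_id)
  structure(list(
    records = data.frame(record_id = rec,
                         length = vapply(rec, function(r)
                           max(genes$end[genes$record_id == r]) + 1000,
                           numeric(1))),
    seqs = NULL, genes = genes,
    cds = cds %||% data.frame(gene_id = genes$gene_id, start = genes$start,
                              end = genes$end, phase = 0L)),
    class = "annotated_genome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evenly spaced gene table: gene i occupies [ (i-1)*spacing_bp + 1, ... + len ].
layout_genes <- function(n, spacing_bp, len_bp, record = "chr1",
                         prefix = "g") {
  start <- (seq_len(n) - 1L) * spacing_bp + 1L
  data.frame(gene_id = sprintf("%s%03d", prefix, seq_len(n)),
             record_id = record, start = start, end = start + len_bp - 1L,
             strand = "+", stringsAsFactors = FALSE)
}

# Two expression vectors with Pearson correlation exactly rho (up to FP):
# v2 = rho * x + sqrt(1-rho^2) * y with x, y standardized and orthogonal.
exact_corr_vectors <- function(rho, n = 12L) {
  x <- seq_len(n)
  x <- (x - mean(x)) / stats::sd(x)
  y0 <- rep(c(1, -1), length.out = n)
  y <- stats::residuals(stats::lm(y0 ~ x))
  y <- (y - mean(y)) / stats::sd(y)
  list(a = x, b = rho * x + sqrt(1 - rho^2) * y)
}

# Matrix whose row `b` has correlation ~rho with row `a`, rows named.
corr_pair_matrix <- function(rho, n = 12L, names = c("a", "b")) {
  v <- exact_corr_vectors(rho, n)
  m <- rbind(v$a, v$b)
  rownames(m) <- names
  colnames(m) <- sprintf("s%02d", seq_len(n))
  as_expression_matrix(m, "toy")
}

# Proteins sharing exactly k identical positions out of len (diagonal
# alignment is optimal: mismatches use letters absent from the partner).
protein_pair_identity <- function(k, len = 20L) {
  base <- strsplit(paste(rep(c("M", "A", "T", "E", "K"), length.out = len),
                         collapse = ""), "")[[1]]
  other <- base
  if (k < len) other[(k + 1L):len] <- rep(c("W", "Y", "F", "H"),
                                          length.out = len - k)
  c(paste(base, collapse = ""), paste(other, collapse = ""))
}

# Mutually unrelated proteins (shared positions ~ 1/len).
unrelated_proteins <- function(n, len = 30L) {
  letters_pool <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i) {
    paste0("M", paste(rep(letters_pool[(i - 1L) %% 19L + 1L], len - 1L),
                      collapse = ""))
  }, character(1))
}

# Brute-force greedy clustering straight from a full pairwise identity
# matrix (independent re-derivation of the CD-HIT greedy rule).
bf_greedy <- function(proteins, threshold) {
  ord <- order(-nchar(proteins), names(proteins))
  proteins <- proteins[ord]
  idm <- outer(seq_along(proteins), seq_along(proteins),
               Vectorize(function(i, j)
                 plantbgc::pairwise_identity(proteins[[i]], proteins[[j]])))
  groups <- list()
  rep_idx <- integer()
  for (i in seq_along(proteins)) {
    placed <- FALSE
    for (g in seq_along(rep_idx)) {
      if (idm[i, rep_idx[g]] > threshold) {
        groups[[g]] <- c(groups[[g]], names(proteins)[i]); placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      groups[[length(groups) + 1L]] <- names(proteins)[i]
    }
  }
  groups
}

# Brute-force transitive interval chaining: merge any consecutive hit pair
# whose gap satisfies the rule, using union-find.
bf_chain <- function(genes, hit_ids, cutoffs_kb) {
  h <- genes[genes$gene_id %in% hit_ids, , drop = FALSE]
  out <- list()
  for (rec in unique(h$record_id)) {
    hr <- h[h$record_id == rec, , drop = FALSE]
    hr <- hr[order(hr$start), , drop = FALSE]
    parent <- seq_len(nrow(hr))
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(nrow(hr) - 1L)) {
      gap <- hr$start[i + 1L] - hr$end[i] - 1L
      lim <- 1000 * max(cutoffs_kb[[hr$gene_id[i]]],
                        cutoffs_kb[[hr$gene_id[i + 1L]]])
      if (gap <= lim) parent[find(i + 1L)] <- find(i)
    }
    roots <- vapply(seq_len(nrow(hr)), find, integer(1))
    out <- c(out, unname(split(hr$gene_id, roots)))
  }
  out
}

# Brute-force complete-linkage merge heights from a distance matrix.
bf_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  active <- lapply(seq_len(nrow(d)), identity)
  heights <- numeric()
  while (length(active) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (i >= j) next
        h <- max(d[active[[i]], active[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    active[[bi]] <- c(active[[bi]], active[[bj]])
    active[[bj]] <- NULL
  }
  heights
}

# Exhaustive one-sided Mann-Whitney permutation p-value: enumerate every
# assignment of the pooled values to the "within" role.
bf_mwu_p <- function(within, background) {
  pooled <- c(within, background)
  n1 <- length(within)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2L, u_of)
  mean(us >= obs - 1e-9)
}

# All-pairs brute-force edge list at a PCC threshold.
bf_edges <- function(mat, genes, pcc_gt) {
  pairs <- utils::combn(genes, 2L)
  keep <- vapply(seq_len(ncol(pairs)), function(k)
    stats::cor(mat[pairs[1L, k], ], mat[pairs[2L, k], ]) > pcc_gt,
    logical(1))
  pairs[, keep, drop = FALSE]
}

# Write a small GFF3 from row text; returns the path.
write_gff3_text <- function(lines) {
  p <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), p)
  p
}

write_fasta_text <- function(named_seqs) {
  p <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(named_seqs), function(n)
    c(paste0(">", n), named_seqs[[n]]))), p)
  p
}
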