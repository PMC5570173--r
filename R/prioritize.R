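# Cluster prioritization: one-sided Mann-Whitney test of the within-cluster
# PCC distribution against a distance-matched genomic background, with MAD
# eligibility filtering and an identity-group-exclusion variant.

#' Median absolute deviation (unscaled)
#'
#' Median of absolute deviations from the median, without the normal
#' consistency constant; genes with MAD = 0 are ineligible for the test.
#'
#' @param values Numeric vector (non-empty).
#' @return The MAD.
#' @export
median_absolute_deviation <- function(values) {
  if (length(values) == 0L) stop("median_absolute_deviation: empty input")
  stats::mad(values, constant = 1, na.rm = TRUE)
}

#' Assemble the statistics matrix from one or more experiments
#'
#' Genes must be observed in every experiment and have MAD > 0 in each to be
#' eligible.  Samples are concatenated across experiments after
#' per-experiment row standardization (so experiments with different scales
#' pool without one dominating the correlation).
#'
#' @param matrices List of `expression_matrix` objects.
#' @return List: `values` (eligible genes x pooled samples), `eligible`
#'   (gene ids), `mad` (per-gene, per-experiment MAD matrix).
#' @export
build_stat_matrix <- function(matrices) {
  if (!is.list(matrices) || inherits(matrices, "expression_matrix")) {
    matrices <- list(matrices)
  }
  common <- Reduce(intersect, lapply(matrices, rownames))
  mads <- vapply(matrices, function(m)
    apply(m[common, , drop = FALSE], 1L, median_absolute_deviation),
    numeric(length(common)))
  mads <- matrix(mads, nrow = length(common),
                 dimnames = list(common, vapply(matrices, attr, character(1),
                                                "experiment_id")))
  eligible <- common[apply(mads > 0, 1L, all)]
  zrow <- function(m) {
    v <- m[eligible, , drop = FALSE]
    mu <- rowMeans(v, na.rm = TRUE)
    sd <- apply(v, 1L, stats::sd, na.rm = TRUE)
    sd[sd == 0 | is.na(sd)] <- 1
    (v - mu) / sd
  }
  values <- do.call(cbind, lapply(matrices, zrow))
  list(values = values, eligible = eligible, mad = mads)
}

#' Within-cluster PCC distribution
#'
#' Pearson correlations of every unordered pair of eligible cluster genes;
#' when `group_map` is given and `exclude_same_group` is set, pairs whose
#' genes fall in the same identity group are discarded (the variant that
#' removes coexpression driven by near-identical duplicates).
#'
#' @param cluster_genes Gene ids of the cluster.
#' @param stat Result of [build_stat_matrix()].
#' @param group_map Named integer vector gene_id -> identity group
#'   (proteome-wide clustering), or `NULL`.
#' @param exclude_same_group Drop same-group pairs; default `FALSE`.
#' @return Numeric vector of PCCs (possibly empty, with a warning).
#' @export
within_cluster_pccs <- function(cluster_genes, stat, group_map = NULL,
                                exclude_same_group = FALSE) {
  genes <- intersect(cluster_genes, stat$eligible)
  if (length(genes) < 2L) {
    warning("fewer than 2 eligible genes in cluster; empty PCC list")
    return(numeric())
  }
  pr <- utils::combn(genes, 2L)
  if (exclude_same_group && !is.null(group_map)) {
    ga <- group_map[pr[1L, ]]; gb <- group_map[pr[2L, ]]
    keep <- is.na(ga) | is.na(gb) | ga != gb
    pr <- pr[, keep, drop = FALSE]
  }
  if (ncol(pr) == 0L) return(numeric())
  .pair_pccs(stat$values, pr[1L, ], pr[2L, ])
}

# Vectorized per-pair Pearson correlation between rows a[i] and b[i].
.pair_pccs <- function(values, a, b) {
  va <- values[a, , drop = FALSE]
  vb <- values[b, , drop = FALSE]
  if (anyNA(va) || anyNA(vb)) {
    return(vapply(seq_along(a), function(i)
      suppressWarnings(stats::cor(va[i, ], vb[i, ],
                                  use = "pairwise.complete.obs")),
      numeric(1)))
  }
  n <- ncol(values)
  ma <- rowMeans(va); mb <- rowMeans(vb)
  ca <- va - ma; cb <- vb - mb
  num <- rowSums(ca * cb)
  den <- sqrt(rowSums(ca * ca) * rowSums(cb * cb))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Distance-matched background PCC distribution
#'
#' For a cluster of `x` genes, the background holds the PCC of every
#' eligible gene pair separated by 0 to `x - 2` intervening genes (adjacent
#' pairs up to the widest separation occurring inside an x-gene cluster),
#' collected across the whole genome but excluding pairs where either gene
#' lies in any predicted cluster.
#'
#' @param x Cluster size in genes (>= 2).
#' @param genome An `annotated_genome` (supplies gene order).
#' @param stat Result of [build_stat_matrix()].
#' @param clusters A `bgc_clusters` data frame of predicted clusters whose
#'   genes are excluded, or `NULL`.
#' @param group_map,exclude_same_group As in [within_cluster_pccs()].
#' @return Numeric vector of PCCs; attribute `offsets` records the number of
#'   intervening genes for each pair.
#' @export
background_pccs <- function(x, genome, stat, clusters = NULL,
                            group_map = NULL, exclude_same_group = FALSE) {
  stopifnot(x >= 2L)
  in_cluster <- if (!is.null(clusters) && nrow(clusters)) {
    unique(unlist(clusters$gene_ids))
  } else character()
  g <- genome$genes[order(genome$genes$record_id, genome$genes$start), ]
  a_all <- character(); b_all <- character(); off_all <- integer()
  for (rec in unique(g$record_id)) {
    ids <- g$gene_id[g$record_id == rec]
    n <- length(ids)
    for (k in 0:(x - 2L)) {          # k intervening genes; 0 = adjacent
      d <- k + 1L                    # index difference
      if (n <= d) next
      a <- ids[seq_len(n - d)]
      b <- ids[seq_len(n - d) + d]
      keep <- a %in% stat$eligible & b %in% stat$eligible &
        !(a %in% in_cluster) & !(b %in% in_cluster)
      a_all <- c(a_all, a[keep]); b_all <- c(b_all, b[keep])
      off_all <- c(off_all, rep(k, sum(keep)))
    }
  }
  if (exclude_same_group && !is.null(group_map)) {
    ga <- group_map[a_all]; gb <- group_map[b_all]
    keep <- is.na(ga) | is.na(gb) | ga != gb
    a_all <- a_all[keep]; b_all <- b_all[keep]; off_all <- off_all[keep]
  }
  if (length(a_all) == 0L) stop("empty background distribution; test undefined")
  out <- .pair_pccs(stat$values, a_all, b_all)
  ok <- !is.na(out)
  structure(out[ok], offsets = off_all[ok])
}

#' One-sided Mann-Whitney U test (within stochastically greater)
#'
#' U is computed from midrank sums.  For small samples (both sizes at most
#' `exact_max`) the p-value is exact, from the permutation distribution of
#' the rank sum computed by dynamic programming over the observed midranks
#' (valid under ties); otherwise the normal approximation with tie and
#' continuity correction is used.
#'
#' @param within Numeric vector (the within-cluster PCCs).
#' @param background Numeric vector (the matched background PCCs).
#' @param exact_max Size bound for the exact path; default 12.
#' @return List of class `mwu_result`: U, p, n_within, n_background, method.
#' @export
mwu_one_sided <- function(within, background, exact_max = 12L) {
  n1 <- length(within); n2 <- length(background)
  if (n1 == 0L || n2 == 0L) stop("mwu_one_sided: empty sample")
  all_r <- rank(c(within, background))
  r1 <- sum(all_r[seq_len(n1)])
  U <- r1 - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    p <- .mwu_exact_p(all_r, n1, r1)
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(all_r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    mu <- n1 * n2 / 2
    if (sigma2 <= 0) {
      p <- 1  # all values tied: no evidence of shift
    } else {
      z <- (U - mu - 0.5) / sqrt(sigma2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
    method <- "normal"
  }
  structure(list(U = U, p = max(p, .Machine$double.xmin),
                 n_within = n1, n_background = n2, method = method),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n_within = %d, n_background = %d), one-sided p = %.4g [%s]\n",
              x$U, x$n_within, x$n_background, x$p, x$method))
  invisible(x)
}

# Exact one-sided p = P(rank sum of a random n1-subset >= r1_obs), by DP over
# doubled midranks (integers even under .5 midranks).
.mwu_exact_p <- function(all_r, n1, r1_obs) {
  r2 <- as.integer(round(2 * all_r))
  N <- length(r2)
  target <- as.integer(round(2 * r1_obs))
  maxsum <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # ways[k+1, s+1] = number of k-subsets with doubled rank sum s
  ways <- matrix(0, nrow = n1 + 1L, ncol = maxsum + 1L)
  ways[1L, 1L] <- 1
  for (r in r2) {
    kmax <- n1
    for (k in kmax:1L) {
      src <- ways[k, ]
      if (all(src == 0)) next
      shifted <- c(rep(0, r), src)[seq_len(maxsum + 1L)]
      ways[k + 1L, ] <- ways[k + 1L, ] + shifted
    }
  }
  counts <- ways[n1 + 1L, ]
  total <- sum(counts)
  sum(counts[(target:maxsum) + 1L]) / total
}

#' Prioritize candidate clusters by within-cluster coexpression
#'
#' Runs the distance-matched one-sided Mann-Whitney test for every cluster,
#' in the plain form and (when a `group_map` is supplied) the variant that
#' discards PCCs between genes of the same identity group.  Clusters are
#' ranked by ascending p-value; a Benjamini-Hochberg adjusted column is
#' reported alongside the raw significance flag.
#'
#' @param clusters A `bgc_clusters` data frame.
#' @param genome An `annotated_genome`.
#' @param matrices One `expression_matrix` or a list of them (samples pooled
#'   after per-experiment standardization).
#' @param alpha Significance level; default 0.05 (raw p, as the procedure
#'   prescribes).
#' @param group_map Proteome-wide identity group map, or `NULL` to skip the
#'   variant.
#' @return Data frame of class `bgc_prioritization`: cluster_id, n_within,
#'   n_background, U, p, p_bh, significant, and the `_variant` columns when
#'   applicable; sorted by p.
#' @export
prioritize <- function(clusters, genome, matrices, alpha = 0.05,
                       group_map = NULL) {
  stat <- build_stat_matrix(matrices)
  bg_cache <- list()
  get_bg <- function(x, excl) {
    key <- paste0(x, "_", excl)
    if (is.null(bg_cache[[key]])) {
      bg_cache[[key]] <<- background_pccs(x, genome, stat, clusters,
                                          group_map, excl)
    }
    bg_cache[[key]]
  }
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    genes <- clusters$gene_ids[[i]]
    x <- length(intersect(genes, stat$eligible))
    row <- list(cluster_id = clusters$cluster_id[i], n_within = NA_integer_,
                n_background = NA_integer_, U = NA_real_, p = NA_real_,
                U_variant = NA_real_, p_variant = NA_real_)
    if (x < 2L) return(row)
    w <- suppressWarnings(within_cluster_pccs(genes, stat))
    if (length(w) == 0L) return(row)
    bg <- get_bg(x, FALSE)
    res <- mwu_one_sided(w, bg)
    row$n_within <- res$n_within; row$n_background <- res$n_background
    row$U <- res$U; row$p <- res$p
    if (!is.null(group_map)) {
      wv <- suppressWarnings(within_cluster_pccs(genes, stat, group_map, TRUE))
      if (length(wv) > 0L) {
        bgv <- get_bg(x, TRUE)
        resv <- mwu_one_sided(wv, bgv)
        row$U_variant <- resv$U; row$p_variant <- resv$p
      }
    }
    row
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p) & out$p < alpha
  if (!is.null(group_map)) {
    out$significant_variant <- !is.na(out$p_variant) & out$p_variant < alpha
  } else {
    out$U_variant <- NULL; out$p_variant <- NULL
  }
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("bgc_prioritization", "data.frame")
  out
}

#' @export
print.bgc_prioritization <- function(x, ...) {
  cat("Cluster prioritization by within-cluster coexpression (alpha = ",
      attr(x, "alpha"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
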