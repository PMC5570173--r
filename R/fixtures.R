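# Synthetic data with planted, truth-tracked structure: genomes with
# plant-like variable gene spacing, planted biosynthetic loci and tandem
# arrays; expression matrices with block-correlated planted clusters.

# Fixed back-translation table (one codon per amino acid).
.codon_of <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
               Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
               L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
               S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

.random_protein <- function(len) {
  paste0("M", paste(sample(names(.codon_of), len - 1L, replace = TRUE),
                    collapse = ""))
}

# Mutate a protein so that two independently mutated copies have expected
# pairwise identity ~ target: per-copy substitution rate r = 1 - sqrt(target).
.mutate_protein <- function(protein, target_identity) {
  aa <- strsplit(protein, "")[[1L]]
  r <- 1 - sqrt(target_identity)
  n_mut <- round(r * (length(aa) - 1L))
  if (n_mut > 0L) {
    pos <- sample(2:length(aa), n_mut)   # keep the initial M
    aa[pos] <- vapply(aa[pos], function(x)
      sample(setdiff(names(.codon_of), x), 1L), character(1))
  }
  paste(aa, collapse = "")
}

.back_translate <- function(protein) {
  paste0(paste(.codon_of[strsplit(protein, "")[[1L]]], collapse = ""), "TAA")
}

.random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Specify a synthetic genome
#'
#' @param seed RNG seed (output is deterministic given the spec).
#' @param records Data frame: record_id, n_genes (background genes),
#'   mean_spacing_kb, spacing_dispersion (log-normal sdlog of intergenic
#'   gaps).
#' @param planted_loci List of planted biosynthetic loci; each a list with
#'   `record`, `position` (background gene index after which the block is
#'   inserted), `classes` (data frame: enzyme_class, n_copies,
#'   mutual_identity) and optional `spacing_kb` (fixed intra-locus gap).
#' @param tandem_arrays List of tandem arrays; each a list with `record`,
#'   `position`, `enzyme_class`, `n_copies` and optional `mutual_identity`
#'   (default 0.95) and `spacing_kb`.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(seed = 1L,
                        records = data.frame(record_id = "chr1", n_genes = 30L,
                                             mean_spacing_kb = 5,
                                             spacing_dispersion = 0.6),
                        planted_loci = list(), tandem_arrays = list()) {
  tandem_as_locus <- lapply(tandem_arrays, function(t) {
    list(record = t$record, position = t$position,
         classes = data.frame(enzyme_class = t$enzyme_class,
                              n_copies = t$n_copies,
                              mutual_identity = t$mutual_identity %||% 0.95,
                              stringsAsFactors = FALSE),
         spacing_kb = t$spacing_kb, tandem = TRUE)
  })
  elements <- c(lapply(planted_loci, function(l) { l$tandem <- FALSE; l }),
                tandem_as_locus)
  key <- vapply(elements, function(e) paste(e$record, e$position), character(1))
  if (anyDuplicated(key)) stop("overlapping planted elements (same record and position)")
  structure(list(seed = as.integer(seed), records = records,
                 elements = elements), class = "genome_spec")
}

#' Generate a synthetic annotated genome with planted structure
#'
#' Writes FASTA, GFF3, a domain hit table and a truth table; intergenic
#' spacing is log-normal (plant-like: large and variable), planted enzymes
#' of one class descend from a shared ancestor mutated to the requested
#' mutual identity, and every planted gene gets a hit on a library profile
#' of its class.
#'
#' @param spec A `genome_spec`.
#' @param dir Output directory.
#' @param library Domain library used to pick hit profiles; default shipped.
#' @param hit_mode `"strong"` (default: E = 1e-30) or `"borderline"`
#'   (planted hits exactly at the default E cutoff 1e-5, plus decoy hits at
#'   1e-4 on background genes that filtering must drop).
#' @return List: genome (`annotated_genome`), hits (data frame), truth
#'   (list), paths (named character).
#' @export
make_toy_genome <- function(spec, dir = tempfile("toygenome"),
                            library = load_profile_library(),
                            hit_mode = c("strong", "borderline")) {
  hit_mode <- match.arg(hit_mode)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(spec$seed, {
    seqs <- character(); gene_rows <- list(); cds_rows <- list()
    hit_rows <- list(); truth_elems <- list()
    for (ri in seq_len(nrow(spec$records))) {
      rec <- spec$records$record_id[ri]
      n_bg <- spec$records$n_genes[ri]
      mu_kb <- spec$records$mean_spacing_kb[ri]
      disp <- spec$records$spacing_dispersion[ri]
      elems <- Filter(function(e) e$record == rec, spec$elements)
      elems <- elems[order(vapply(elems, `[[`, numeric(1), "position"))]
      # assemble the gene plan: background genes with planted blocks inserted
      plan <- list()
      add_bg <- function(i) {
        len_codons <- sample(100:400, 1L)
        list(kind = "bg", protein = .random_protein(len_codons),
             class = NA_character_, gap_kb = NA_real_, element = NA_integer_)
      }
      ei <- 1L
      for (i in seq_len(n_bg)) {
        plan[[length(plan) + 1L]] <- add_bg(i)
        while (ei <= length(elems) && elems[[ei]]$position == i) {
          e <- elems[[ei]]
          for (ci in seq_len(nrow(e$classes))) {
            cls <- e$classes$enzyme_class[ci]
            anc <- .random_protein(300L)
            for (cp in seq_len(e$classes$n_copies[ci])) {
              plan[[length(plan) + 1L]] <- list(
                kind = "planted",
                protein = .mutate_protein(anc, e$classes$mutual_identity[ci]),
                class = cls, gap_kb = e$spacing_kb %||% NA_real_,
                element = ei)
            }
          }
          ei <- ei + 1L
        }
      }
      # lay the genes down; pos = bases emitted so far
      pos <- 0L; seq_parts <- character(); elem_span <- list()
      for (gi in seq_along(plan)) {
        p <- plan[[gi]]
        gap_bp <- if (!is.na(p$gap_kb)) {
          as.integer(round(1000 * p$gap_kb))
        } else {
          as.integer(round(stats::rlnorm(1, log(mu_kb * 1000) - disp^2 / 2, disp)))
        }
        gap_bp <- max(gap_bp, 50L)
        cds <- .back_translate(p$protein)
        strand <- sample(c("+", "-"), 1L)
        start <- pos + gap_bp + 1L
        end <- start + nchar(cds) - 1L
        gid <- sprintf("%s_g%04d", rec, gi)
        genomic <- if (strand == "-") {
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
        } else cds
        seq_parts <- c(seq_parts, .random_dna(gap_bp), genomic)
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = gid, record_id = rec, start = start, end = end,
          strand = strand, stringsAsFactors = FALSE)
        cds_rows[[length(cds_rows) + 1L]] <- data.frame(
          gene_id = gid, start = start, end = end, phase = 0L,
          stringsAsFactors = FALSE)
        if (p$kind == "planted") {
          prof <- library$profile_id[library$enzyme_class == p$class]
          if (length(prof) == 0L) stop("no library profile for class: ", p$class)
          ev <- if (hit_mode == "strong") 1e-30 else 1e-5
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            gene_id = gid, profile_id = prof[1L], bitscore = 150, evalue = ev,
            ali_start = 5L, ali_end = 250L, stringsAsFactors = FALSE)
          es <- as.character(p$element)
          sp <- elem_span[[es]] %||% list(start = start, end = end, genes = character())
          sp$start <- min(sp$start, start); sp$end <- max(sp$end, end)
          sp$genes <- c(sp$genes, gid)
          elem_span[[es]] <- sp
        } else if (hit_mode == "borderline" && stats::runif(1) < 0.1) {
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            gene_id = gid, profile_id = library$profile_id[1L], bitscore = 10,
            evalue = 1e-4, ali_start = 5L, ali_end = 50L,
            stringsAsFactors = FALSE)
        }
        pos <- end
      }
      seqs[rec] <- paste0(paste(seq_parts, collapse = ""), .random_dna(500L))
      for (es in names(elem_span)) {
        e <- elems[[as.integer(es)]]
        n_sub <- sum(ifelse(e$classes$mutual_identity > 0.5, 1L,
                            e$classes$n_copies))
        n_cls <- length(unique(e$classes$enzyme_class))
        chained <- is.null(e$spacing_kb) || is.na(e$spacing_kb %||% NA_real_) ||
          (e$spacing_kb %||% 0) <= 100
        truth_elems[[length(truth_elems) + 1L]] <- list(
          record = rec, start = elem_span[[es]]$start,
          end = elem_span[[es]]$end, genes = elem_span[[es]]$genes,
          tandem = isTRUE(e$tandem),
          expected_subclasses = n_sub, expected_classes = n_cls,
          expected_detected = n_sub >= 3L && n_cls >= 2L && chained)
      }
    }
    genes <- do.call(rbind, gene_rows)
    cds <- do.call(rbind, cds_rows)
    hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
      data.frame(gene_id = character(), profile_id = character(),
                 bitscore = numeric(), evalue = numeric(),
                 ali_start = integer(), ali_end = integer(),
                 stringsAsFactors = FALSE)
    dna <- Biostrings::DNAStringSet(seqs)
    genome <- merge_annotations(dna, list(genes = genes, cds = cds))
    paths <- c(fasta = file.path(dir, "genome.fasta"),
               gff3 = file.path(dir, "genome.gff3"),
               hits = file.path(dir, "hits.tsv"),
               truth = file.path(dir, "truth.json"))
    Biostrings::writeXStringSet(dna, paths[["fasta"]])
    write_gff3(genome, paths[["gff3"]])
    utils::write.table(hits, paths[["hits"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth <- list(elements = truth_elems)
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
    list(genome = genome, hits = hits, truth = truth, paths = paths)
  })
}

#' Specify a synthetic expression matrix
#'
#' @param seed RNG seed.
#' @param n_samples Number of samples (>= 3).
#' @param planted_blocks List of blocks; each a list with `genes`
#'   (character), `target_pcc` in (0, 1], and optional `pattern` (numeric
#'   length n_samples added to the block's shared signal).
#' @param noise_sd Standard deviation of unplanted genes' values; default 1.
#' @return An `expression_spec` list.
#' @export
expression_spec <- function(seed = 1L, n_samples = 50L, planted_blocks = list(),
                            noise_sd = 1) {
  stopifnot(n_samples >= 3L)
  for (b in planted_blocks) {
    stopifnot(b$target_pcc > 0, b$target_pcc <= 1)
    if (b$target_pcc == 1 && noise_sd > 0) {
      stop("infeasible block: target PCC 1 with noise_sd > 0")
    }
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 planted_blocks = planted_blocks, noise_sd = noise_sd),
            class = "expression_spec")
}

#' Generate a synthetic expression matrix with planted coexpression blocks
#'
#' Block genes share a latent standard-normal factor with weight
#' `sqrt(target_pcc)` plus an independent residual of weight
#' `sqrt(1 - target_pcc)`, so the expected pairwise PCC within a block
#' equals the target; all other genes are independent noise.
#'
#' @param spec An `expression_spec`.
#' @param gene_ids All genes the matrix should cover (planted block genes
#'   must be a subset).
#' @param path Optional CSV output path.
#' @param experiment_id Experiment label; default "synthetic".
#' @return An `expression_matrix`.
#' @export
make_expression <- function(spec, gene_ids, path = NULL,
                            experiment_id = "synthetic") {
  planted <- unlist(lapply(spec$planted_blocks, `[[`, "genes"))
  if (!all(planted %in% gene_ids)) {
    stop("planted block gene(s) absent from gene_ids: ",
         paste(setdiff(planted, gene_ids), collapse = ", "))
  }
  withr::with_seed(spec$seed, {
    ns <- spec$n_samples
    m <- matrix(stats::rnorm(length(gene_ids) * ns, sd = spec$noise_sd),
                nrow = length(gene_ids), dimnames = list(gene_ids, NULL))
    for (b in spec$planted_blocks) {
      f <- stats::rnorm(ns)
      if (!is.null(b$pattern)) f <- f + b$pattern
      rho <- b$target_pcc
      for (g in b$genes) {
        m[g, ] <- sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(ns)
      }
    }
    colnames(m) <- sprintf("sample%03d", seq_len(ns))
    em <- as_expression_matrix(m, experiment_id)
    if (!is.null(path)) {
      df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    }
    em
  })
}
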