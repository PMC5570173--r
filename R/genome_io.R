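# Genome input: FASTA + GFF3 (or GenBank) -> annotated genome with proteins.
# Internal coordinates are 1-based inclusive throughout (GFF3-native), so no
# conversion happens at the I/O boundary; all gap/span arithmetic is explicit.

#' Read a nucleotide FASTA file
#'
#' Each entry becomes one sequence record; the record identifier is the first
#' whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record identifier.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file '", path, "' contains no sequences")
  ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA record identifier(s): ", paste(dup, collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Read a GFF3 annotation file
#'
#' CDS features are grouped into genes by following `Parent` chains
#' (CDS -> mRNA -> gene).  When a gene has several mRNAs the mRNA with the
#' longest summed CDS length is kept, so each gene yields one protein.  A CDS
#' without any parent is grouped under its own `ID` with a warning.
#'
#' @param path Path to a GFF3 file.  An embedded `##FASTA` section is
#'   tolerated (and ignored).
#' @return A list with elements `genes` (data frame: gene_id, record_id,
#'   start, end, strand) and `cds` (data frame: gene_id, start, end, phase),
#'   both 1-based inclusive.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fasta_at <- which(lines == "##FASTA")
  body_end <- if (length(fasta_at)) fasta_at[1L] - 1L else length(lines)
  body <- lines[seq_len(body_end)]
  is_data <- !startsWith(body, "#") & nzchar(trimws(body))
  nfield <- lengths(strsplit(body[is_data], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(is_data)[which(nfield != 9L)[1L]]
    stop("malformed GFF3 line ", bad, ": expected 9 tab-separated columns, got ",
         nfield[which(nfield != 9L)[1L]])
  }
  src <- path
  if (length(fasta_at)) {
    src <- tempfile(fileext = ".gff3")
    on.exit(unlink(src), add = TRUE)
    writeLines(body, src)
  }
  gr <- rtracklayer::import(src, format = "gff3")
  .group_gff_features(gr)
}

# Build gene table from an imported GFF3 GRanges.
.group_gff_features <- function(gr) {
  type <- as.character(gr$type)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))

  feat_type <- stats::setNames(type, id)
  feat_parent <- stats::setNames(parent, id)

  cds_idx <- which(type == "CDS")
  if (length(cds_idx) == 0L) {
    return(list(
      genes = data.frame(gene_id = character(), record_id = character(),
                         start = integer(), end = integer(),
                         strand = character(), stringsAsFactors = FALSE),
      cds = data.frame(gene_id = character(), start = integer(),
                       end = integer(), phase = integer(),
                       stringsAsFactors = FALSE)))
  }

  # transcript id for each CDS: its Parent, else its own ID (orphan)
  tx <- parent[cds_idx]
  orphan <- is.na(tx)
  if (any(orphan)) {
    own <- id[cds_idx][orphan]
    if (anyNA(own)) stop("CDS feature with neither Parent nor ID")
    warning("CDS feature(s) without a Parent; grouped by their own ID: ",
            paste(unique(own), collapse = ", "))
    tx[orphan] <- own
  }
  # gene id for a transcript: walk Parent chain up to a 'gene'-typed ancestor
  tx_gene <- function(t) {
    seen <- character()
    cur <- t
    while (!is.na(cur) && !cur %in% seen) {
      seen <- c(seen, cur)
      ty <- feat_type[cur]
      if (!is.na(ty) && ty == "gene") return(cur)
      nxt <- feat_parent[cur]
      if (is.na(nxt) || is.null(nxt)) break
      cur <- nxt
    }
    t  # no gene ancestor: the transcript stands for the gene
  }
  utx <- unique(tx)
  gene_of_tx <- stats::setNames(vapply(utx, tx_gene, character(1)), utx)

  cds_df <- data.frame(
    tx = tx,
    gene_id = unname(gene_of_tx[tx]),
    record_id = as.character(GenomicRanges::seqnames(gr))[cds_idx],
    start = GenomicRanges::start(gr)[cds_idx],
    end = GenomicRanges::end(gr)[cds_idx],
    strand = as.character(GenomicRanges::strand(gr))[cds_idx],
    phase = {
      ph <- if (!is.null(gr$phase)) as.integer(gr$phase)[cds_idx] else rep(0L, length(cds_idx))
      ph[is.na(ph)] <- 0L
      ph
    },
    stringsAsFactors = FALSE)

  # one transcript per gene: longest summed CDS
  cds_len <- tapply(cds_df$end - cds_df$start + 1L, cds_df$tx, sum)
  keep_tx <- vapply(split(names(cds_len), unname(gene_of_tx[names(cds_len)])),
                    function(txs) {
                      l <- cds_len[txs]
                      txs[order(-l, txs)][1L]  # ties: lexicographic
                    }, character(1))
  cds_df <- cds_df[cds_df$tx %in% keep_tx, , drop = FALSE]
  cds_df <- cds_df[order(cds_df$gene_id, cds_df$start), , drop = FALSE]

  # gene body: the gene feature's own coords when present, else CDS extremes
  genes <- do.call(rbind, lapply(split(cds_df, cds_df$gene_id), function(d) {
    g <- d$gene_id[1L]
    gs <- min(d$start); ge <- max(d$end)
    if (!is.na(feat_type[g]) && feat_type[g] == "gene") {
      i <- match(g, id)
      gs <- GenomicRanges::start(gr)[i]; ge <- GenomicRanges::end(gr)[i]
    }
    data.frame(gene_id = g, record_id = d$record_id[1L], start = gs, end = ge,
               strand = d$strand[1L], stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  list(genes = genes[order(genes$record_id, genes$start), , drop = FALSE],
       cds = cds_df[, c("gene_id", "start", "end", "phase")])
}

#' Merge sequences and annotation into an annotated genome
#'
#' Record names must match exactly between the two inputs.  The single
#' exception: when both inputs contain exactly one record, a name mismatch is
#' accepted provided no feature lies outside the sequence range.
#'
#' @param seqs A named [Biostrings::DNAStringSet] (from [read_genome_fasta()]),
#'   or `NULL` for annotation-only mode (proteins must then be supplied to
#'   downstream steps separately).
#' @param features Annotation as returned by [read_gff3()].
#' @param proteins Optional named character vector of protein sequences
#'   (gene_id -> amino acids); used instead of translation when given.
#' @return An object of class `annotated_genome`: list with `records`
#'   (data frame record_id, length), `seqs`, `genes` (sorted by record and
#'   start, with a `protein` column), `cds`.
#' @export
merge_annotations <- function(seqs, features, proteins = NULL) {
  genes <- features$genes
  cds <- features$cds
  if (!is.null(seqs)) {
    ann_rec <- unique(genes$record_id)
    if (length(seqs) == 1L && length(ann_rec) == 1L) {
      if (ann_rec != names(seqs)) {
        # single-record exception: adopt the sequence's name
        genes$record_id <- names(seqs)
      }
      too_far <- genes$end > Biostrings::width(seqs)[1L] | genes$start < 1L
      if (any(too_far)) {
        stop("single-record inputs: feature(s) outside sequence range: ",
             paste(genes$gene_id[too_far], collapse = ", "))
      }
    } else {
      unmatched <- setdiff(ann_rec, names(seqs))
      if (length(unmatched) > 0L) {
        stop("annotation record(s) absent from sequence input: ",
             paste(unmatched, collapse = ", "))
      }
    }
    records <- data.frame(record_id = names(seqs),
                          length = Biostrings::width(seqs),
                          stringsAsFactors = FALSE)
  } else {
    rec <- unique(genes$record_id)
    records <- data.frame(record_id = rec,
                          length = vapply(rec, function(r)
                            max(genes$end[genes$record_id == r]), numeric(1)),
                          stringsAsFactors = FALSE)
  }
  genes <- genes[order(genes$record_id, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id(s): ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  genome <- structure(list(records = records, seqs = seqs,
                           genes = genes, cds = cds),
                      class = "annotated_genome")
  if (!is.null(proteins)) {
    genome$genes$protein <- unname(proteins[genome$genes$gene_id])
  } else if (!is.null(seqs)) {
    prot <- extract_proteins(genome)
    genome$genes$protein <- unname(prot[genome$genes$gene_id])
  } else {
    genome$genes$protein <- NA_character_
  }
  genome
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("Annotated genome: ", nrow(x$records), " record(s), ",
      nrow(x$genes), " gene(s)\n", sep = "")
  invisible(x)
}

#' Translate every gene's CDS into protein
#'
#' CDS segments are concatenated in transcription order (reverse-complemented
#' on the minus strand), the 5' phase of the first segment is trimmed, a
#' length not divisible by three is truncated with a warning, and translation
#' uses the standard genetic code.  A trailing stop is removed; an internal
#' stop triggers a warning and translation stops there.
#'
#' @param genome An `annotated_genome` with sequences present.
#' @return Named character vector, gene_id -> protein.
#' @export
extract_proteins <- function(genome) {
  if (is.null(genome$seqs)) stop("genome has no sequences; cannot translate")
  cds_by_gene <- split(genome$cds, genome$cds$gene_id)
  out <- vapply(genome$genes$gene_id, function(g) {
    d <- cds_by_gene[[g]]
    if (is.null(d)) return(NA_character_)
    i <- match(g, genome$genes$gene_id)
    rec <- genome$genes$record_id[i]
    strand <- genome$genes$strand[i]
    d <- d[order(d$start), , drop = FALSE]
    segs <- lapply(seq_len(nrow(d)), function(k)
      Biostrings::subseq(genome$seqs[[rec]], d$start[k], d$end[k]))
    nt <- do.call(Biostrings::xscat, segs)
    first_phase <- d$phase[1L]
    if (strand == "-") {
      nt <- Biostrings::reverseComplement(nt)
      first_phase <- d$phase[nrow(d)]
    }
    if (first_phase > 0L) nt <- Biostrings::subseq(nt, first_phase + 1L)
    rem <- length(nt) %% 3L
    if (rem != 0L) {
      warning("gene ", g, ": CDS length not a multiple of 3; trailing ",
              rem, " base(s) dropped")
      nt <- Biostrings::subseq(nt, 1L, length(nt) - rem)
    }
    aa <- as.character(Biostrings::translate(nt, if.fuzzy.codon = "X"))
    aa <- sub("\\*$", "", aa)
    if (grepl("*", aa, fixed = TRUE)) {
      warning("gene ", g, ": internal stop codon; translated up to first stop")
      aa <- sub("\\*.*$", "", aa)
    }
    aa
  }, character(1))
  stats::setNames(out, genome$genes$gene_id)
}

#' Write an annotation back to GFF3
#'
#' Emits gene and CDS rows (one transcript per gene, mirroring the internal
#' model), suitable for round-tripping through [read_gff3()].
#'
#' @param genome An `annotated_genome`.
#' @param path Output path.
#' @export
write_gff3 <- function(genome, path) {
  g <- genome$genes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(g))) {
    writeLines(sprintf("%s\tplantbgc\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$record_id[i], g$start[i], g$end[i], g$strand[i],
                       g$gene_id[i]), con)
    d <- genome$cds[genome$cds$gene_id == g$gene_id[i], , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    for (k in seq_len(nrow(d))) {
      writeLines(sprintf("%s\tplantbgc\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                         g$record_id[i], d$start[k], d$end[k], g$strand[i],
                         d$phase[k], g$gene_id[i], g$gene_id[i]), con)
    }
  }
  invisible(path)
}

#' Read a GenBank flat file into an annotated genome
#'
#' Minimal reader for the common subset: LOCUS name, CDS features with
#' `join()`/`complement()` locations, `/locus_tag` or `/gene` identifiers and
#' optional `/translation` (used when present, otherwise the CDS is
#' translated from the ORIGIN sequence).
#'
#' @param path Path to a GenBank flat file.
#' @return An `annotated_genome`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loci <- grep("^LOCUS", lines)
  if (length(loci) == 0L) stop("not a GenBank flat file: no LOCUS line")
  ends <- c(loci[-1L] - 1L, length(lines))
  all_genes <- list(); all_cds <- list(); seq_list <- list()
  for (li in seq_along(loci)) {
    block <- lines[loci[li]:ends[li]]
    rec_id <- strsplit(trimws(sub("^LOCUS", "", block[1L])), "[ \t]+")[[1L]][1L]
    ori <- grep("^ORIGIN", block)
    seq_str <- ""
    if (length(ori)) {
      seq_lines <- block[(ori[1L] + 1L):length(block)]
      seq_lines <- seq_lines[!grepl("^//", seq_lines)]
      seq_str <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    }
    feat_start <- grep("^FEATURES", block)
    feat_end <- if (length(ori)) ori[1L] - 1L else length(block)
    genes <- list(); cds <- list()
    if (length(feat_start)) {
      fb <- block[(feat_start[1L] + 1L):feat_end]
      is_key <- grepl("^ {5}\\S", fb)
      key_at <- which(is_key)
      for (ki in seq_along(key_at)) {
        ln <- fb[key_at[ki]]
        key <- sub("^ +(\\S+).*$", "\\1", ln)
        if (key != "CDS") next
        stop_at <- if (ki < length(key_at)) key_at[ki + 1L] - 1L else length(fb)
        body <- fb[key_at[ki]:stop_at]
        body[1L] <- sub("^ +CDS +", "", body[1L])
        # location may continue on lines before the first qualifier
        qual_at <- grep("^ +/", body)
        loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(body)
        loc <- gsub("[ \t]", "", paste(trimws(body[1:loc_end]), collapse = ""))
        quals <- paste(trimws(body[-(1:loc_end)]), collapse = " ")
        gid <- .gb_qualifier(quals, "locus_tag")
        if (is.na(gid)) gid <- .gb_qualifier(quals, "gene")
        if (is.na(gid)) gid <- .gb_qualifier(quals, "protein_id")
        if (is.na(gid)) gid <- paste0(rec_id, "_cds", length(cds) + 1L)
        transl <- .gb_qualifier(quals, "translation")
        if (!is.na(transl)) transl <- gsub(" ", "", transl)
        p <- .parse_gb_location(loc)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, record_id = rec_id,
          start = min(p$start), end = max(p$end),
          strand = if (p$complement) "-" else "+",
          protein = if (is.na(transl)) NA_character_ else transl,
          stringsAsFactors = FALSE)
        cds[[length(cds) + 1L]] <- data.frame(
          gene_id = gid, start = p$start, end = p$end,
          phase = rep(0L, length(p$start)), stringsAsFactors = FALSE)
      }
    }
    seq_list[[rec_id]] <- seq_str
    all_genes <- c(all_genes, genes)
    all_cds <- c(all_cds, cds)
  }
  genes <- do.call(rbind, all_genes)
  cds <- do.call(rbind, all_cds)
  seqs <- NULL
  if (any(nzchar(unlist(seq_list)))) {
    seqs <- Biostrings::DNAStringSet(unlist(seq_list))
  }
  genome <- merge_annotations(seqs, list(genes = genes[, 1:5], cds = cds))
  # prefer /translation where present
  has_tr <- !is.na(genes$protein)
  if (any(has_tr)) {
    idx <- match(genes$gene_id[has_tr], genome$genes$gene_id)
    genome$genes$protein[idx] <- genes$protein[has_tr]
  }
  genome
}

.gb_qualifier <- function(quals, name) {
  pat <- paste0("/", name, '="([^"]*)"')
  m <- regmatches(quals, regexec(pat, quals))[[1L]]
  if (length(m) >= 2L) return(m[2L])
  pat2 <- paste0("/", name, "=([^ /]+)")
  m2 <- regmatches(quals, regexec(pat2, quals))[[1L]]
  if (length(m2) >= 2L) return(m2[2L])
  NA_character_
}

.parse_gb_location <- function(loc) {
  complement <- grepl("complement", loc)
  inner <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
  inner <- gsub("[<>]", "", inner)
  parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
  se <- do.call(rbind, lapply(parts, function(p) {
    xs <- as.integer(strsplit(p, "\\.\\.")[[1L]])
    if (length(xs) == 1L) xs <- c(xs, xs)
    xs
  }))
  list(start = se[, 1L], end = se[, 2L], complement = complement)
}
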