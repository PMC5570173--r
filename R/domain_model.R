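# Biosynthetic domain library, hit-table parsing, and gene annotation.

#' Load the biosynthetic domain profile library
#'
#' The shipped default library describes 62 profiles (57 Pfam-sourced, 5
#' custom) covering enzyme families recurrently found in plant specialized
#' metabolic pathways, each tagged with an enzyme class, a signature flag
#' (scaffold-generating enzymes that determine a product class) and an
#' optional per-profile E-value cutoff.
#'
#' @param path Path to a library TSV (columns: profile_id, name,
#'   enzyme_class, is_signature, source, cutoff).  Default: the shipped
#'   library.
#' @return Data frame of class `domain_library`.
#' @export
load_profile_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "domain_library.tsv", package = "plantbgc")
  }
  lib <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("profile_id", "name", "enzyme_class", "is_signature", "source")
  miss <- setdiff(need, names(lib))
  if (length(miss)) stop("library config lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(lib$profile_id)) {
    stop("duplicate profile_id in library: ",
         paste(unique(lib$profile_id[duplicated(lib$profile_id)]), collapse = ", "))
  }
  if (any(!nzchar(lib$enzyme_class))) {
    stop("profile(s) with empty enzyme_class: ",
         paste(lib$profile_id[!nzchar(lib$enzyme_class)], collapse = ", "))
  }
  lib$is_signature <- as.logical(lib$is_signature)
  if (!"cutoff" %in% names(lib)) lib$cutoff <- NA_real_
  lib$cutoff <- suppressWarnings(as.numeric(lib$cutoff))
  class(lib) <- c("domain_library", "data.frame")
  lib
}

#' Parse a domain hit table
#'
#' Accepts either HMMER3 per-domain tabular output (`hmmscan --domtblout`,
#' whitespace columns, profile as target and gene as query) or the package's
#' own tab-separated hit format with a header line
#' `gene_id profile_id bitscore evalue ali_start ali_end`.
#'
#' @param path Path to the hit table.
#' @return Data frame with columns gene_id, profile_id, bitscore, evalue,
#'   ali_start, ali_end.
#' @export
parse_domain_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  empty <- data.frame(gene_id = character(), profile_id = character(),
                      bitscore = numeric(), evalue = numeric(),
                      ali_start = integer(), ali_end = integer(),
                      stringsAsFactors = FALSE)
  if (length(keep) == 0L) return(empty)
  first <- lines[keep[1L]]
  if (grepl("\t", first) && grepl("gene_id", first)) {
    hits <- utils::read.delim(text = paste(lines[keep], collapse = "\n"),
                              stringsAsFactors = FALSE)
    need <- c("gene_id", "profile_id", "bitscore", "evalue")
    miss <- setdiff(need, names(hits))
    if (length(miss)) stop("hit table lacks column(s): ", paste(miss, collapse = ", "))
    if (!"ali_start" %in% names(hits)) hits$ali_start <- NA_integer_
    if (!"ali_end" %in% names(hits)) hits$ali_end <- NA_integer_
    if (!is.numeric(hits$bitscore) || !is.numeric(hits$evalue)) {
      bad <- which(is.na(suppressWarnings(as.numeric(hits$bitscore))) |
                   is.na(suppressWarnings(as.numeric(hits$evalue))))[1L]
      stop("non-numeric score in hit table near data row ", bad)
    }
    return(hits[, c("gene_id", "profile_id", "bitscore", "evalue",
                    "ali_start", "ali_end")])
  }
  # domtblout: 22 fixed whitespace-separated fields + free-text description
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) < 22L) {
      stop("unparseable domtblout row at line ", i, ": expected >= 22 fields, got ",
           length(f))
    }
    ev <- suppressWarnings(as.numeric(f[13L]))
    sc <- suppressWarnings(as.numeric(f[14L]))
    a1 <- suppressWarnings(as.integer(f[18L]))
    a2 <- suppressWarnings(as.integer(f[19L]))
    if (is.na(ev) || is.na(sc)) stop("non-numeric score at line ", i)
    pid <- if (f[2L] != "-") sub("\\.\\d+$", "", f[2L]) else f[1L]
    data.frame(gene_id = f[4L], profile_id = pid, bitscore = sc, evalue = ev,
               ali_start = a1, ali_end = a2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Filter domain hits by profile significance cutoffs
#'
#' Keeps hits whose E-value is at or below the profile's cutoff; profiles
#' without a configured cutoff use the global default.  Hits on profiles
#' absent from the library are dropped with a warning.
#'
#' @param hits Data frame from [parse_domain_table()].
#' @param library A `domain_library`.
#' @param default_evalue Global E-value cutoff (default `1e-5`).
#' @return Filtered hit data frame.
#' @export
filter_hits <- function(hits, library, default_evalue = 1e-5) {
  if (nrow(hits) == 0L) return(hits)
  idx <- match(hits$profile_id, library$profile_id)
  unknown <- is.na(idx)
  if (any(unknown)) {
    warning("dropping hit(s) on unknown profile(s): ",
            paste(unique(hits$profile_id[unknown]), collapse = ", "))
    hits <- hits[!unknown, , drop = FALSE]
    idx <- idx[!unknown]
  }
  cut <- library$cutoff[idx]
  cut[is.na(cut)] <- default_evalue
  hits[hits$evalue <= cut, , drop = FALSE]
}

#' Annotate genes with enzyme classes from filtered domain hits
#'
#' Per gene, the enzyme classes are the union over its hit profiles; a gene
#' is a signature carrier if any hit profile is flagged as signature.  Genes
#' without hits are absent from the output.
#'
#' @param hits Filtered hit data frame.
#' @param library A `domain_library`.
#' @return Data frame (class `enzyme_annotation`): gene_id, enzyme_classes
#'   (list column of sorted unique labels), is_biosynthetic,
#'   is_signature_carrier.
#' @export
annotate_genes <- function(hits, library) {
  if (nrow(hits) == 0L) {
    out <- data.frame(gene_id = character(), stringsAsFactors = FALSE)
    out$enzyme_classes <- list()
    out$signature_classes <- list()
    out$is_biosynthetic <- logical()
    out$is_signature_carrier <- logical()
    class(out) <- c("enzyme_annotation", "data.frame")
    return(out)
  }
  idx <- match(hits$profile_id, library$profile_id)
  if (anyNA(idx)) stop("annotate_genes: hits reference unknown profiles; filter first")
  d <- data.frame(gene_id = hits$gene_id,
                  class = library$enzyme_class[idx],
                  sig = library$is_signature[idx],
                  stringsAsFactors = FALSE)
  sp <- split(d, d$gene_id)
  out <- data.frame(gene_id = names(sp), stringsAsFactors = FALSE)
  out$enzyme_classes <- lapply(sp, function(x) sort(unique(x$class)))
  out$signature_classes <- lapply(sp, function(x) sort(unique(x$class[x$sig])))
  out$is_biosynthetic <- lengths(out$enzyme_classes) > 0L
  out$is_signature_carrier <- vapply(sp, function(x) any(x$sig), logical(1))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enzyme_annotation", "data.frame")
  out
}

#' Run hmmscan against a profile HMM database (optional adapter)
#'
#' Thin wrapper over an external HMMER3 `hmmscan` binary; writes and parses a
#' domtblout table.  All core logic consumes hit tables, so this adapter is
#' only needed when starting from raw proteins and a profile database.
#'
#' @param proteins Named character vector, gene_id -> amino acids.
#' @param hmm_db Path to a pressed HMM database.
#' @param hmmscan Path to the `hmmscan` executable.
#' @return Hit data frame as from [parse_domain_table()].
#' @export
run_hmmscan <- function(proteins, hmm_db, hmmscan = "hmmscan") {
  if (Sys.which(hmmscan) == "" && !file.exists(hmmscan)) {
    stop("hmmscan binary not found: ", hmmscan)
  }
  fa <- tempfile(fileext = ".faa")
  out <- tempfile(fileext = ".domtblout")
  on.exit(unlink(c(fa, out)), add = TRUE)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), fa)
  status <- system2(hmmscan, c("--domtblout", out, "--noali", shQuote(hmm_db),
                               shQuote(fa)), stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("hmmscan exited with status ", status)
  parse_domain_table(out)
}
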