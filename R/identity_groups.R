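# Sequence-identity subclass grouping (CD-HIT semantics): same-class enzymes
# above the identity threshold collapse into one subclass, so tandem arrays
# of near-identical genes count once toward the cluster rule.

.aa_match_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters <- c(LETTERS, "*")
      mm <- diag(1, length(letters))
      dimnames(mm) <- list(letters, letters)
      m <<- mm
    }
    m
  }
})

#' Pairwise protein identity (CD-HIT convention)
#'
#' Global alignment with free end gaps (semi-global; match +1, mismatch 0,
#' gaps penalized for path choice only); identity is the number of identical
#' aligned positions divided by the length of the shorter sequence, so a
#' short sequence fully contained in a longer one has identity 1.
#'
#' @param a,b Protein sequences (non-empty character strings).
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("pairwise_identity: empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "overlap", substitutionMatrix = .aa_match_matrix(),
    gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Greedy incremental identity clustering
#'
#' CD-HIT-style: sequences are sorted by length descending (ties broken
#' lexicographically by identifier for determinism), the first unassigned
#' sequence seeds a group and becomes its representative, and each following
#' sequence joins the first existing group whose representative it exceeds
#' `threshold` identity with, else seeds a new group.
#'
#' @param proteins Named character vector (gene_id -> protein).
#' @param threshold Identity threshold in (0, 1); default 0.5, i.e. >50%
#'   mutual identity merges.
#' @param enzyme_class Optional class label attached to every group.
#' @return Data frame of class `identity_groups`: group_id, enzyme_class,
#'   representative, members (list column), n_members.
#' @export
greedy_cluster <- function(proteins, threshold = 0.5, enzyme_class = NA_character_) {
  stopifnot(threshold > 0, threshold < 1)
  if (length(proteins) == 0L) {
    out <- data.frame(group_id = integer(), enzyme_class = character(),
                      representative = character(), n_members = integer(),
                      stringsAsFactors = FALSE)
    out$members <- list()
    class(out) <- c("identity_groups", "data.frame")
    return(out[, c("group_id", "enzyme_class", "representative", "members",
                   "n_members")])
  }
  if (is.null(names(proteins)) || any(!nzchar(names(proteins)))) {
    stop("greedy_cluster: proteins must be named by gene_id")
  }
  ord <- order(-nchar(proteins), names(proteins))
  proteins <- proteins[ord]
  reps <- character()       # representative sequences, in group order
  rep_ids <- character()
  members <- list()
  for (i in seq_along(proteins)) {
    s <- proteins[[i]]
    assigned <- FALSE
    for (g in seq_along(reps)) {
      if (pairwise_identity(s, reps[g]) > threshold) {
        members[[g]] <- c(members[[g]], names(proteins)[i])
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, s)
      rep_ids <- c(rep_ids, names(proteins)[i])
      members <- c(members, list(names(proteins)[i]))
    }
  }
  out <- data.frame(group_id = seq_along(reps),
                    enzyme_class = rep(enzyme_class, length(reps)),
                    representative = rep_ids,
                    n_members = lengths(members),
                    stringsAsFactors = FALSE)
  out$members <- members
  out <- out[, c("group_id", "enzyme_class", "representative", "members",
                 "n_members")]
  class(out) <- c("identity_groups", "data.frame")
  out
}

#' Map each gene to its identity group
#'
#' Convenience for the proteome-wide clustering mode used by the
#' prioritization statistics (all proteins clustered together at one
#' threshold, regardless of enzyme class).
#'
#' @param proteins Named character vector.
#' @param threshold Identity threshold; default 0.5.
#' @return Named integer vector gene_id -> group_id.
#' @export
identity_group_map <- function(proteins, threshold = 0.5) {
  grp <- greedy_cluster(proteins, threshold)
  if (nrow(grp) == 0L) return(stats::setNames(integer(), character()))
  ids <- rep(grp$group_id, lengths(grp$members))
  stats::setNames(ids, unlist(grp$members))
}
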