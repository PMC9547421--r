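# Redundancy reduction (greedy identity clustering in the CD-HIT idiom) and
# neighbor-joining tree construction with bootstrap support.

pairwise_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                       Biostrings::AAString(b),
                                       type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5)
  # CD-HIT convention: identical positions over the shorter sequence length
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Greedy identity clustering of near-redundant sequences
#'
#' Sequences are sorted by decreasing length (ties broken by id) and each
#' joins the first existing representative whose global pairwise identity
#' -- matched positions divided by the shorter sequence's length, the
#' CD-HIT convention -- strictly exceeds the cutoff; otherwise it founds a
#' new cluster. Deterministic given the inputs.
#'
#' @param records Protein data frame (columns `id`, `sequence`).
#' @param identity_cutoff Identity fraction in (0, 1]; default 0.95.
#' @return List with `representatives` (character vector of ids) and
#'   `clusters` (data frame `id`, `representative`).
#' @export
cluster_redundant <- function(records, identity_cutoff = 0.95) {
  stopifnot(identity_cutoff > 0, identity_cutoff <= 1)
  ord <- order(-nchar(records$sequence), records$id)
  records <- records[ord, , drop = FALSE]
  reps <- character(0)
  rep_seqs <- character(0)
  assign <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    joined <- NA_character_
    for (j in seq_along(reps)) {
      if (pairwise_identity(records$sequence[i], rep_seqs[j]) >
          identity_cutoff) {
        joined <- reps[j]
        break
      }
    }
    if (is.na(joined)) {
      reps <- c(reps, records$id[i])
      rep_seqs <- c(rep_seqs, records$sequence[i])
      joined <- records$id[i]
    }
    assign[i] <- joined
  }
  list(representatives = reps,
       clusters = data.frame(id = records$id, representative = assign))
}

#' Pairwise p-distance matrix of an alignment
#'
#' `d(i, j)` is the proportion of mismatches over columns where neither row
#' carries a gap.
#'
#' @param aln Named character vector of equal-length aligned sequences
#'   (gap `"-"`).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aln) {
  n <- length(aln)
  stopifnot(n >= 2L)
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows must have equal length")
  ids <- names(aln)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  m <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok))
        stop("no comparable sites between ", ids[i], " and ", ids[j])
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) with negative branch-length
#' estimates clamped to zero; the number of clamped edges is recorded in the
#' `clamped_edges` attribute of the returned tree.
#'
#' @param d Square symmetric distance matrix with zero diagonal,
#'   `n >= 3` taxa.
#' @return An [ape::phylo] object.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || nrow(d) < 3L)
    stop("distance matrix must be square with at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-9)
    stop("distance matrix is asymmetric beyond tolerance")
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix must have a zero diagonal")
  tree <- ape::nj(d)
  clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped_edges") <- clamped
  tree
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the full-data p-distance NJ tree, then resamples alignment
#' columns with replacement `n_reps` times; the support of each internal
#' bipartition of the full-data tree is the percentage of replicate trees
#' containing it, written into the tree's node labels.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return An [ape::phylo] tree whose `node.label` holds supports in
#'   `[0, 100]` (the root label is empty).
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  tree <- neighbor_joining(p_distance_matrix(aln))
  cols <- nchar(aln[[1]])
  m <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  rep_trees <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      idx <- sample.int(cols, cols, replace = TRUE)
      rows <- apply(m[, idx, drop = FALSE], 1, paste, collapse = "")
      neighbor_joining(p_distance_matrix(rows))
    })
  })
  counts <- ape::prop.clades(tree, rep_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps, 1)
  # first internal node is the (unrooted) basal node; leave it unlabeled
  lab <- as.character(support)
  lab[1] <- ""
  tree$node.label <- lab
  attr(tree, "support") <- support
  attr(tree, "n_reps") <- n_reps
  tree
}
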