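# Independent oracles used to validate the package's algorithms. Each is a
# deliberately brute-force re-derivation that shares no code path with the
# implementation it checks.

# --- exhaustive ligand-assignment enumeration ------------------------------

# Enumerate every spacer combination of `rule` at every candidate start
# position and keep, per first-ligand position, the assignment with the
# lexicographically smallest spacer vector. Returns a list of 0-based
# ligand-position vectors.
oracle_scan_rule <- function(seq, rule) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  ranges <- rule$spacers
  combos <- as.matrix(expand.grid(lapply(ranges, function(r) r[1]:r[2]),
                                  KEEP.OUT.ATTRS = FALSE))
  combos <- combos[do.call(order, as.data.frame(combos)), , drop = FALSE]
  offs <- cbind(0L, t(apply(combos + 1L, 1, cumsum)))
  starts <- which(ch %in% rule$allowed[[1]])
  hits <- list()
  for (p in starts) {
    pos <- p + offs  # 1-based positions, rows = combos
    valid <- pos[, ncol(pos)] <= L
    for (j in seq_along(rule$allowed)) {
      idx <- which(valid)
      if (!length(idx)) break
      valid[idx] <- ch[pos[idx, j]] %in% rule$allowed[[j]]
    }
    w <- which(valid)
    if (length(w))
      hits[[length(hits) + 1L]] <- unname(pos[w[1], ]) - 1L
  }
  hits
}

random_protein <- function(n, alphabet = c(ringzf:::AA_STANDARD, "X")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- NG86 pathway enumeration ----------------------------------------------

# Average synonymous/nonsynonymous step counts over all orderings of the
# differing codon positions, excluding orderings through stop codons.
# Independent recursive implementation.
oracle_codon_paths <- function(ca, cb) {
  gc <- Biostrings::GENETIC_CODE
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  if (!length(pos)) return(c(sd = 0, nd = 0, paths = 1))
  acc <- new.env()
  acc$sd <- 0; acc$nd <- 0; acc$paths <- 0
  recurse <- function(cur, remaining, sd, nd) {
    if (!length(remaining)) {
      acc$sd <- acc$sd + sd; acc$nd <- acc$nd + nd
      acc$paths <- acc$paths + 1
      return(invisible())
    }
    for (i in seq_along(remaining)) {
      p <- remaining[i]
      nxt <- cur; nxt[p] <- b[p]
      if (gc[[paste(nxt, collapse = "")]] == "*") next
      syn <- gc[[paste(nxt, collapse = "")]] == gc[[paste(cur, collapse = "")]]
      recurse(nxt, remaining[-i], sd + syn, nd + !syn)
    }
  }
  recurse(a, pos, 0, 0)
  if (acc$paths == 0) return(c(sd = NA_real_, nd = NA_real_, paths = 0))
  c(sd = acc$sd / acc$paths, nd = acc$nd / acc$paths, paths = acc$paths)
}

# --- brute-force IUPAC scan ------------------------------------------------

iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

iupac_revcomp <- function(pat) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(comp[rev(strsplit(pat, "")[[1]])], collapse = "")
}

# Test every (position, strand) against the IUPAC expansion; subject N
# matches nothing. Returns data frame motif/start(0-based)/strand.
oracle_scan_motifs <- function(seq, motif_table) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  res <- list()
  for (i in seq_len(nrow(motif_table))) {
    for (strand in c("+", "-")) {
      pat <- motif_table$pattern[i]
      if (strand == "-") pat <- iupac_revcomp(pat)
      sets <- lapply(strsplit(pat, "")[[1]], function(c_) iupac_sets[[c_]])
      m <- length(sets)
      if (m > L) next
      n_pos <- L - m + 1L
      ok <- rep(TRUE, n_pos)
      for (j in seq_len(m))
        ok <- ok & (ch[j:(j + n_pos - 1L)] %in% sets[[j]])
      w <- which(ok)
      if (length(w))
        res[[length(res) + 1L]] <- data.frame(motif = motif_table$name[i],
                                              start = w - 1L,
                                              strand = strand)
    }
  }
  if (!length(res))
    return(data.frame(motif = character(), start = integer(),
                      strand = character()))
  out <- do.call(rbind, res)
  out[order(out$start, out$motif, out$strand), , drop = FALSE]
}

# --- exhaustive unrooted topology enumeration + least-squares fit ----------

# Enumerate all unrooted binary topologies on n leaves as edge matrices
# (leaves 1..n, internal nodes n+1, ...). (2n-5)!! topologies.
enumerate_topologies <- function(n) {
  stopifnot(n >= 3)
  base <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), ncol = 2,
                 byrow = TRUE)
  tops <- list(list(edges = base, next_node = n + 2L))
  for (k in 4:n) {
    if (n < 4) break
    new_tops <- list()
    for (tp in tops) {
      for (e in seq_len(nrow(tp$edges))) {
        ed <- tp$edges
        u <- ed[e, 1]; v <- ed[e, 2]
        w <- tp$next_node
        ed <- ed[-e, , drop = FALSE]
        ed <- rbind(ed, c(u, w), c(w, v), c(w, k))
        new_tops[[length(new_tops) + 1L]] <-
          list(edges = ed, next_node = w + 1L)
      }
    }
    tops <- new_tops
  }
  lapply(tops, `[[`, "edges")
}

# Path-edge incidence matrix: rows = leaf pairs (i<j), cols = edges.
topology_incidence <- function(edges, n) {
  nodes <- max(edges)
  adj <- vector("list", nodes)
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- rbind(adj[[edges[e, 1]]], c(edges[e, 2], e))
    adj[[edges[e, 2]]] <- rbind(adj[[edges[e, 2]]], c(edges[e, 1], e))
  }
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (r in seq_len(nrow(pairs))) {
    # BFS from pairs[r,1] to pairs[r,2] recording edge path
    src <- pairs[r, 1]; dst <- pairs[r, 2]
    prev <- rep(NA_integer_, nodes); prev_edge <- rep(NA_integer_, nodes)
    queue <- src; seen <- rep(FALSE, nodes); seen[src] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (u == dst) break
      for (row in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][row, 1]
        if (!seen[v]) {
          seen[v] <- TRUE; prev[v] <- u; prev_edge[v] <- adj[[u]][row, 2]
          queue <- c(queue, v)
        }
      }
    }
    u <- dst
    while (u != src) { A[r, prev_edge[u]] <- 1; u <- prev[u] }
  }
  A
}

# Non-trivial bipartitions of a topology, as canonical strings over leaf
# labels 1..n (the side containing leaf 1).
topology_bipartitions <- function(edges, n) {
  nodes <- max(edges)
  out <- character(0)
  for (e in seq_len(nrow(edges))) {
    if (edges[e, 1] <= n || edges[e, 2] <= n) next  # pendant edge
    # leaves on the side of edges[e,1], cutting edge e
    adj <- vector("list", nodes)
    for (k in seq_len(nrow(edges))) {
      if (k == e) next
      adj[[edges[k, 1]]] <- c(adj[[edges[k, 1]]], edges[k, 2])
      adj[[edges[k, 2]]] <- c(adj[[edges[k, 2]]], edges[k, 1])
    }
    seen <- rep(FALSE, nodes); queue <- edges[e, 1]; seen[queue] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (!seen[v]) { seen[v] <- TRUE
        queue <- c(queue, v) }
    }
    side <- which(seen[seq_len(n)])
    if (!(1 %in% side)) side <- setdiff(seq_len(n), side)
    out <- c(out, paste(sort(side), collapse = ","))
  }
  sort(out)
}

# Bipartitions of an ape::phylo tree with integer-coded tip labels "t1".."tn"
phylo_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  tips <- as.integer(sub("^t", "", tree$tip.label))
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (p in pp) {
    side <- sort(tips[p])
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (!(1 %in% side)) side <- sort(setdiff(seq_len(n), side))
    out <- c(out, paste(side, collapse = ","))
  }
  sort(unique(out))
}

# Random unrooted binary tree with positive branch lengths; returns the
# ape tree and its additive (cophenetic) distance matrix.
random_additive_tree <- function(n) {
  tree <- ape::rtree(n, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.1, 1))
  tree$tip.label <- paste0("t", sample(n))
  d <- ape::cophenetic.phylo(tree)
  ord <- paste0("t", seq_len(n))
  list(tree = tree, d = d[ord, ord])
}

# --- independent net-charge grid for pI ------------------------------------

oracle_pi_grid <- function(seq, step = 1e-4) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pkas <- list(Nterm = c(8.6, +1), Cterm = c(3.6, -1), C = c(8.5, -1),
               D = c(3.9, -1), E = c(4.1, -1), H = c(6.5, +1),
               K = c(10.8, +1), R = c(12.5, +1), Y = c(10.1, -1))
  counts <- c(Nterm = 1, Cterm = 1,
              vapply(c("C", "D", "E", "H", "K", "R", "Y"),
                     function(a) sum(ch == a), numeric(1)))
  grid <- seq(0, 14, by = step)
  q <- rep(0, length(grid))
  for (g in names(pkas)) {
    n <- counts[[g]]
    if (n == 0) next
    pka <- pkas[[g]][1]; sgn <- pkas[[g]][2]
    q <- q + if (sgn > 0) n / (1 + 10^(grid - pka))
             else -n / (1 + 10^(pka - grid))
  }
  grid[which.min(abs(q))]
}
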