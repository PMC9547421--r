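test_that("identity clustering merges duplicates and splits divergents", {
  recs <- data.frame(id = c("a", "b"),
                     sequence = rep("MKCRAAAGGLLSTV", 2))
  cl <- cluster_redundant(recs)
  expect_length(cl$representatives, 1L)
  expect_equal(sort(cl$clusters$id), c("a", "b"))

  # 18/20 identical positions = 0.90 identity: below the 0.95 cutoff
  recs2 <- data.frame(id = c("a", "b"),
                      sequence = c("MKCRAAAGGLLSTVPPEEQN",
                                   "MKCRAAAGGLLSTVPPEEVV"))
  expect_length(cluster_redundant(recs2)$representatives, 2L)
  expect_length(cluster_redundant(recs2, identity_cutoff = 0.85)$representatives,
                1L)
})

test_that("clustering output is a partition covering every input", {
  set.seed(61)
  recs <- make_protein_set(c("RING-H2" = 6, "RING-M" = 3), n_decoys = 4,
                           seed = 62)$records
  cl <- cluster_redundant(recs)
  expect_setequal(cl$clusters$id, recs$id)
  expect_true(all(cl$clusters$representative %in% cl$representatives))
  expect_equal(anyDuplicated(cl$clusters$id), 0L)
})

test_that("planted identity classes give the planted number of clusters", {
  set.seed(63)
  n_classes <- 20
  bases <- replicate(n_classes, random_protein(60, ringzf:::AA_STANDARD))
  recs <- list(); k <- 0
  for (i in seq_len(n_classes)) {
    copies <- sample(1:3, 1)
    for (j in seq_len(copies)) {
      k <- k + 1
      s <- strsplit(bases[i], "")[[1]]
      if (j > 1) {  # at most 2 substitutions: identity >= 58/60 > 0.95
        pos <- sample(60, 2)
        s[pos] <- sample(ringzf:::AA_STANDARD, 2, replace = TRUE)
      }
      recs[[k]] <- data.frame(id = sprintf("c%02d_%d", i, j),
                              sequence = paste(s, collapse = ""))
    }
  }
  recs <- do.call(rbind, recs)
  cl <- cluster_redundant(recs)
  expect_length(cl$representatives, n_classes)
  # members of one class share a representative
  cls <- sub("_.*", "", cl$clusters$id)
  rep_of <- tapply(cl$clusters$representative, cls,
                   function(x) length(unique(x)))
  expect_true(all(rep_of == 1))
})

test_that("p-distance excludes gap columns and validates input", {
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  expect_equal(p_distance_matrix(c(a = "A-AA", b = "ATAA"))["a", "b"], 0)
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_error(p_distance_matrix(c(a = "A-", b = "-A")), "no comparable")
  expect_error(p_distance_matrix(c(a = "AA", b = "AAA")), "equal length")
})

test_that("three taxa give the unique closed-form branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("t1", "t2", "t3"), c("t1", "t2", "t3")))
  tree <- neighbor_joining(d)
  expect_equal(length(tree$tip.label), 3L)
  # x = (d12 + d13 - d23)/2 etc.
  lens <- tree$edge.length[match(1:3, tree$edge[, 2])]
  expect_equal(sort(lens), sort(c((3 + 4 - 5) / 2, (3 + 5 - 4) / 2,
                                  (4 + 5 - 3) / 2)))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  dd <- d; dd[1, 2] <- 3.5
  expect_error(neighbor_joining(dd), "asymmetric")
})

test_that("NJ recovers random additive trees exactly (enumeration oracle)", {
  set.seed(71)
  for (i in 1:12) {
    n <- sample(4:6, 1)
    ra <- random_additive_tree(n)
    tree <- neighbor_joining(ra$d)
    # distances reproduced exactly
    cd <- ape::cophenetic.phylo(tree)[rownames(ra$d), colnames(ra$d)]
    expect_equal(cd, ra$d, tolerance = 1e-8)
    # the generating topology is the unique additive fit among all
    # unrooted topologies
    tops <- enumerate_topologies(n)
    fits <- vapply(tops, function(ed) {
      A <- topology_incidence(ed, n)
      dv <- as.vector(ra$d[t(combn(n, 2))])
      x <- qr.solve(A, dv)
      sqrt(sum((A %*% x - dv)^2))
    }, numeric(1))
    hit <- which(fits < 1e-8)
    expect_length(hit, 1L)
    expect_equal(topology_bipartitions(tops[[hit]], n),
                 phylo_bipartitions(tree))
  }
})

test_that("NJ reproduces distances for larger additive trees", {
  set.seed(72)
  for (n in 7:8) {
    ra <- random_additive_tree(n)
    tree <- neighbor_joining(ra$d)
    cd <- ape::cophenetic.phylo(tree)[rownames(ra$d), colnames(ra$d)]
    expect_equal(cd, ra$d, tolerance = 1e-8)
  }
})

test_that("an ultrametric matrix yields its single-linkage hierarchy", {
  # two clades {a,b} and {c,d,e} at heights 0.1/0.2 within, 1 between
  labs <- c("a", "b", "c", "d", "e")
  d <- matrix(1, 5, 5, dimnames = list(labs, labs))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0.1
  d["c", "d"] <- d["d", "c"] <- 0.2
  d["c", "e"] <- d["e", "c"] <- 0.2
  d["d", "e"] <- d["e", "d"] <- 0.2
  tree <- neighbor_joining(d)
  pp <- ape::prop.part(tree)
  sides <- lapply(pp, function(p) sort(tree$tip.label[p]))
  has_ab <- any(vapply(sides, function(s) identical(s, c("a", "b")),
                       logical(1))) ||
    any(vapply(sides, function(s) identical(s, c("c", "d", "e")),
               logical(1)))
  expect_true(has_ab)
})

test_that("bootstrap supports are deterministic, bounded, and high for
           well-separated clades", {
  set.seed(81)
  blockA <- paste0(strrep("A", 30), strrep("C", 30))
  blockB <- paste0(strrep("T", 30), strrep("G", 30))
  jitter <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(60, k)
    ch[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  aln <- c(a1 = jitter(blockA, 2), a2 = jitter(blockA, 2),
           a3 = jitter(blockA, 2), b1 = jitter(blockB, 2),
           b2 = jitter(blockB, 2), b3 = jitter(blockB, 2))
  t1 <- bootstrap_support(aln, n_reps = 200, seed = 5)
  t2 <- bootstrap_support(aln, n_reps = 200, seed = 5)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  sup <- attr(t1, "support")
  expect_true(all(sup >= 0 & sup <= 100))
  # the edge separating the two planted clades has near-full support
  pp <- ape::prop.part(t1)
  sides <- lapply(pp, function(p) sort(t1$tip.label[p]))
  sep <- which(vapply(sides, function(s)
    identical(s, c("a1", "a2", "a3")) ||
      identical(s, c("b1", "b2", "b3")), logical(1)))
  expect_true(length(sep) >= 1)
  expect_true(any(sup[sep] >= 95))
})

test_that("degenerate identical-row alignments still build a tree", {
  aln <- c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA")
  tree <- bootstrap_support(aln, n_reps = 20, seed = 1)
  expect_equal(sort(tree$tip.label), c("a", "b", "c", "d"))
  expect_true(all(tree$edge.length == 0))
})

test_that("trees serialize to and re-parse from newick losslessly", {
  set.seed(91)
  ra <- random_additive_tree(6)
  tree <- neighbor_joining(ra$d)
  nwk <- ape::write.tree(tree)
  back <- ape::read.tree(text = nwk)
  expect_setequal(back$tip.label, tree$tip.label)
  cd1 <- ape::cophenetic.phylo(tree)
  cd2 <- ape::cophenetic.phylo(back)[rownames(cd1), colnames(cd1)]
  expect_equal(cd1, cd2, tolerance = 1e-6)
})
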