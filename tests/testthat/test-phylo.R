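# distance phylogenetics: p-distance, Poisson correction, NJ, bootstrap

test_that("p-distances use pairwise deletion of gaps and X", {
  aln <- c(a = "WRKY", b = "WRKF")
  expect_equal(pdistance(aln, "a", "b"), 0.25)
  expect_equal(pdistance(c(a = "WR-Y", b = "WRKY"), "a", "b"), 0)
  expect_equal(pdistance(c(a = "WRKY", b = "WRKY"), "a", "b"), 0)
  expect_true(is.na(pdistance(c(a = "--XX", b = "AC--"), "a", "b")))
  # appending a column gapped in one row changes no distance involving it
  aln3 <- c(a = "WRKYA", b = "WRKFA", c = "WAKYA")
  aln3g <- c(a = "WRKYA-", b = "WRKFAT", c = "WAKYAT")
  for (p in list(c("a", "b"), c("a", "c"))) {
    expect_equal(pdistance(aln3g, p[1L], p[2L]),
                 pdistance(aln3, p[1L], p[2L]))
  }
})

test_that("Poisson correction matches the closed form and its limits", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.5), -log(0.5))
  p <- seq(0, 0.9, by = 0.1)
  d <- poisson_correct(p)
  expect_true(all(diff(d) > 0))       # monotone
  expect_true(all(d >= p))            # correction only inflates
  expect_lt(abs(poisson_correct(1e-6) - 1e-6), 1e-9)
  expect_warning(ds <- poisson_correct(c(0.2, 1)), "saturated")
  expect_true(is.na(ds[2L]))
})

test_that("NJ recovers additive trees exactly (path lengths to 1e-9)", {
  set.seed(61)
  for (n in c(4L, 6L, 8L)) {
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    D <- cophenetic(tr)
    mine <- nj_tree(D)
    expect_lt(max(abs(cophenetic(mine)[rownames(D), colnames(D)] - D)), 1e-9)
    # independent implementation agrees on topology
    expect_equal(phangorn::RF.dist(ape::unroot(tr), mine), 0)
    expect_equal(phangorn::RF.dist(ape::nj(D), mine), 0)
  }
})

test_that("NJ topology matches exhaustive least-squares over all trees", {
  set.seed(67)
  tr <- ape::rtree(6L, br = function(k) runif(k, 0.1, 1))
  D <- cophenetic(tr)
  mine <- nj_tree(D)
  all_tops <- phangorn::allTrees(6L, rooted = FALSE,
                                 tip.label = rownames(D))
  resid <- vapply(all_tops, ls_residual, numeric(1L), D = D)
  best <- all_tops[[which.min(resid)]]
  expect_lt(min(resid), 1e-12)
  expect_equal(phangorn::RF.dist(best, mine), 0)
})

test_that("3-taxon trees use the closed three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2L]])
  expect_equal(unname(len[c("A", "B", "C")]), c(1, 2, 3))
})

test_that("missing distances are a hard error naming the remedy", {
  D <- matrix(0, 3L, 3L, dimnames = list(letters[1:3], letters[1:3]))
  D[1L, 2L] <- D[2L, 1L] <- NA
  expect_error(nj_tree(D), "trim the alignment")
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("negative branch lengths are clamped with the deficit moved", {
  # a non-additive matrix known to produce a negative NJ branch
  D <- matrix(c(0, 2, 2, 6,
                2, 0, 0.1, 6,
                2, 0.1, 0, 0.2,
                6, 6, 0.2, 0), 4L,
              dimnames = list(letters[1:4], letters[1:4]))
  clamped <- nj_tree(D, clamp_negative = TRUE)
  raw <- nj_tree(D, clamp_negative = FALSE)
  expect_true(all(clamped$edge.length >= 0))
  expect_true(any(raw$edge.length < 0))
  expect_equal(phangorn::RF.dist(clamped, raw), 0)
  # the deficit moves to the sister, so the tip carrying the negative
  # branch keeps its path length to that sister
  neg_tip <- raw$tip.label[raw$edge[raw$edge.length < 0, 2L]]
  cr <- cophenetic(raw)
  cc <- cophenetic(clamped)[rownames(cr), colnames(cr)]
  expect_true(any(abs(cc[neg_tip, colnames(cc) != neg_tip] -
                        cr[neg_tip, colnames(cr) != neg_tip]) < 1e-12))
})

test_that("bootstrap supports are seeded, quantized and order-invariant", {
  aln <- clean_pair_alignment(k = 4L)
  t1 <- bootstrap_consensus(aln, replicates = 50, seed = 7)
  t2 <- bootstrap_consensus(aln, replicates = 50, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  q <- bootstrap_consensus(aln, replicates = 1, seed = 7)
  expect_true(all(as.numeric(q$node.label) %in% c(0, 100)))

  set.seed(3)
  perm <- sample(length(aln))
  t3 <- bootstrap_consensus(aln[perm], replicates = 50, seed = 7)
  expect_equal(phangorn::RF.dist(t1, t3), 0)
  expect_equal(sort(as.numeric(t1$node.label)),
               sort(as.numeric(t3$node.label)))
})

test_that("well-separated clean clades earn near-unanimous support", {
  aln <- clean_pair_alignment(k = 4L)
  tr <- bootstrap_consensus(aln, replicates = 200, seed = 11)
  ntip <- length(tr$tip.label)
  sup <- as.numeric(tr$node.label)
  # locate the internal node holding each of the four true pairs
  kids <- split(tr$edge[, 2L], tr$edge[, 1L])
  tips_under <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(kids[[as.character(node)]], tips_under))
  }
  for (p in 1:4) {
    pair <- paste0("t", p, 1:2)
    node <- which(vapply((ntip + 1L):(ntip + tr$Nnode), function(nd) {
      setequal(tr$tip.label[tips_under(nd)], pair)
    }, logical(1L)))
    expect_length(node, 1L)
    expect_gte(sup[node], 95)
  }
})

test_that("consensus sequences follow majority rule with documented ties", {
  aln <- c(a = "WRKYGQK", b = "WRKYGQK", c = "WRKYGQK")
  expect_equal(consensus_sequence(aln), "WRKYGQK")
  # 2/2 tie at threshold 0.5 breaks alphabetically
  tie <- c(a = "AK", b = "AK", c = "CK", d = "CK")
  expect_equal(consensus_sequence(tie), "AK")
  # sub-threshold columns become x; majority-gap columns are dropped
  mixed <- c(a = "AR-", b = "AK-", c = "CY-", d = "GWT")
  expect_equal(consensus_sequence(mixed), "Ax")
  # a fixture subfamily alignment keeps its invariant heptapeptide
  set.seed(71)
  doms <- vapply(1:4, function(i) {
    h <- wrkyminer:::.domain_halves(wrky_gene_template("IIc"), 0.1)
    paste0(h$part1, h$part2)
  }, character(1L))
  names(doms) <- paste0("d", 1:4)
  expect_match(consensus_sequence(doms), "WRKYGQK")
})

test_that("newick writing validates labels and round-trips topology", {
  aln <- clean_pair_alignment(k = 3L)
  tr <- bootstrap_consensus(aln, replicates = 20, seed = 13)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_equal(phangorn::RF.dist(back, tr), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
  expect_true(all(as.numeric(back$node.label) >= 0 &
                    as.numeric(back$node.label) <= 100))

  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  write_newick(star, path)
  expect_match(readLines(path), "A:1")

  bad <- star
  bad$tip.label[2L] <- ""
  expect_error(write_newick(bad, path), "unlabeled")
  bad2 <- star
  bad2$node.label <- "150"
  expect_error(write_newick(bad2, path), "0, 100")
})
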