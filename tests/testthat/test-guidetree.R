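# helper: similarity matrix from a named full matrix
sim_from <- function(M, method = "F") {
  structure(M, method = method, class = c("sim_matrix", class(M)))
}

sim3 <- function(ab, ac, bc) {
  M <- matrix(100, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  M["A", "B"] <- M["B", "A"] <- ab
  M["A", "C"] <- M["C", "A"] <- ac
  M["B", "C"] <- M["C", "B"] <- bc
  sim_from(M)
}

topology <- function(gt) ape::write.tree(ape::compute.brlen(gt$phylo, 1))

test_that("UPGMA joins the most similar pair and averages removed scores", {
  gt <- build_upgma(sim3(90, 50, 50))
  expect_identical(sort(msaframe:::leaves_below(gt$phylo,
                     setdiff(gt$phylo$edge[, 2], 1:3)[1])), c("A", "B"))
  # the merged (AB) cluster sits at similarity 50 to C -> root height 0.25
  depths <- ape::node.depth.edgelength(gt$phylo)
  expect_equal(max(depths), (100 - 50) / 200)
})

test_that("two sequences give the single-join tree", {
  M <- matrix(c(100, 80, 80, 100), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  gt <- build_upgma(sim_from(M))
  expect_equal(length(gt$phylo$tip.label), 2)
  expect_equal(gt$phylo$Nnode, 1)
})

test_that("SLMIN keeps the max removed score and SLMAX the min", {
  # after joining (A,B): SLMIN -> sim((AB),C) = 70, SLMAX -> 30.
  # root height reveals which: (100 - s)/200.
  gmin <- build_slink(sim3(90, 70, 30), "SLMIN")
  gmax <- build_slink(sim3(90, 70, 30), "SLMAX")
  expect_equal(max(ape::node.depth.edgelength(gmin$phylo)), (100 - 70) / 200)
  expect_equal(max(ape::node.depth.edgelength(gmax$phylo)), (100 - 30) / 200)
})

test_that("all-equal similarities produce the deterministic caterpillar", {
  M <- matrix(50, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(M) <- 100
  for (m in c("UPGMA", "SLMIN", "SLMAX")) {
    gt <- build_guide_tree(sim_from(M), m)
    expect_identical(topology(gt), "(((a:1,b:1):1,c:1):1,d:1);", info = m)
  }
})

test_that("n=3 with equal removed scores: UPGMA, SLMIN, SLMAX agree", {
  s <- sim3(90, 60, 60)
  expect_identical(topology(build_upgma(s)),
                   topology(build_slink(s, "SLMIN")))
  expect_identical(topology(build_upgma(s)),
                   topology(build_slink(s, "SLMAX")))
})

test_that("agglomerative builders match hclust on random matrices", {
  # UPGMA-as-described = mcquitty, SLMIN = single, SLMAX = complete,
  # all on the distance transform d = 100 - M (merge heights x 1/200)
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    d <- matrix(runif(n * n, 5, 95), n)
    d <- (d + t(d)) / 2
    ids <- paste0("t", seq_len(n))
    dimnames(d) <- list(ids, ids)
    M <- 100 - d; diag(M) <- 100
    for (pair in list(c("UPGMA", "mcquitty"), c("SLMIN", "single"),
                      c("SLMAX", "complete"))) {
      gt <- build_guide_tree(sim_from(M), pair[1])
      hc <- stats::hclust(stats::as.dist(d), method = pair[2])
      expect_equal(max(ape::node.depth.edgelength(gt$phylo)),
                   max(hc$height) / 200, tolerance = 1e-9, info = pair[1])
      got <- ape::unroot(ape::compute.brlen(gt$phylo, 1))
      want <- ape::unroot(ape::compute.brlen(ape::as.phylo(hc), 1))
      expect_equal(ape::dist.topo(got, want)[1], 0, info = pair[1])
    }
  }
})

test_that("UPGMA recovers the topology behind an ultrametric similarity matrix", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    phy <- ape::rcoal(n, tip.label = paste0("u", seq_len(n)))
    d <- ape::cophenetic.phylo(phy)
    d <- 95 * d / max(d)
    M <- 100 - d; diag(M) <- 100
    gt <- build_upgma(sim_from(M[sort(rownames(M)), sort(rownames(M))]))
    expect_equal(ape::dist.topo(ape::unroot(ape::compute.brlen(gt$phylo, 1)),
                                ape::unroot(ape::compute.brlen(phy, 1)))[1], 0)
  }
})

test_that("NJ recovers additive topologies and matches ape::nj", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    phy <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
    phy$edge.length <- runif(nrow(phy$edge), 0.05, 0.3)
    d <- ape::cophenetic.phylo(phy)
    d <- pmin(d, 0.99)
    M <- 100 * (1 - d); diag(M) <- 100
    ord <- sort(rownames(M))
    gt <- build_nj(sim_from(M[ord, ord]))
    got <- ape::unroot(ape::compute.brlen(gt$phylo, 1))
    want <- ape::unroot(ape::compute.brlen(
      ape::nj(stats::as.dist(d[ord, ord])), 1))
    expect_equal(ape::dist.topo(got, want)[1], 0)
  }
})

test_that("NJ with three leaves uses the closed-form branch lengths", {
  s <- sim3(80, 60, 70)  # d: AB .2, AC .4, BC .3
  gt <- build_nj(s)
  # closed form: lA = (dAB + dAC - dBC)/2 = .15, lB = .05, lC = .25
  phy <- gt$phylo
  tipedge <- setNames(phy$edge.length[match(1:3, phy$edge[, 2])],
                      phy$tip.label)
  expect_equal(unname(tipedge["A"]), 0.15, tolerance = 1e-9)
  expect_equal(unname(tipedge["B"]), 0.05, tolerance = 1e-9)
  # d((AB),C) = (dAC + dBC - dAB)/2 = 0.25, rooted at its midpoint
  expect_equal(unname(tipedge["C"]), 0.125, tolerance = 1e-9)
})

test_that("identical sequences give a zero-length star-like NJ tree", {
  M <- matrix(100, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  gt <- build_nj(sim_from(M))
  expect_equal(sum(gt$phylo$edge.length), 0)
  expect_equal(length(gt$phylo$tip.label), 4)
})

test_that("newick round-trips preserve topology and labels", {
  expect_identical(to_newick(from_newick("((A:1,B:1):1,C:2);")),
                   "((A:1,B:1):1,C:2);")
  gt <- from_newick("((x_1:1,x_2:1):1,y_3:1);")
  expect_setequal(gt$phylo$tip.label, c("x_1", "x_2", "y_3"))
  set.seed(24)
  for (rep in 1:20) {
    n <- sample(4:16, 1)
    phy <- ape::rtree(n)
    txt <- ape::write.tree(phy)
    expect_equal(ape::dist.topo(ape::unroot(from_newick(txt)$phylo),
                                ape::unroot(phy))[1], 0)
  }
  expect_error(from_newick("((A,B"), "malformed")
})

test_that("every builder yields a valid rooted binary guide tree", {
  set.seed(25)
  n <- 7
  seqs <- aa_seqs(setNames(replicate(n, rand_seq(12)), paste0("s", 1:n)))
  sim <- build_similarity_matrix(seqs, "K", k = 2)
  for (m in c("UPGMA", "SLMIN", "SLMAX", "NJ")) {
    gt <- build_guide_tree(sim, m)
    expect_equal(length(gt$phylo$tip.label), n, info = m)
    expect_equal(gt$phylo$Nnode, n - 1, info = m)
    expect_setequal(gt$phylo$tip.label, names(seqs))
  }
})
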