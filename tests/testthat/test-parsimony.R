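test_that("Fitch length reproduces textbook cases", {
  taxa4 <- paste0("t", 1:4)
  m <- matrix("A", 4, 3, dimnames = list(taxa4, NULL))
  good <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  bad <- ape::read.tree(text = "((t1,t3),(t2,t4));")
  expect_equal(fitch_length(good, m), 0L)   # invariant matrix

  m[, 1] <- c("A", "A", "T", "T")
  expect_equal(fitch_length(good, m), 1L)
  expect_equal(fitch_length(bad, m), 2L)

  m3 <- matrix(c("A", "C", "G"), 3, 1,
               dimnames = list(paste0("t", 1:3), NULL))
  expect_equal(fitch_length(ape::read.tree(text = "(t1,t2,t3);"), m3), 2L)

  expect_error(fitch_length(good, m3), "leaf set")
})

test_that("Fitch equals exhaustive state-assignment minimisation", {
  set.seed(101)
  for (rep in 1:10) {
    m <- random_charmatrix(5, 8, p_missing = 0.1)
    tr <- ape::rtree(5, tip.label = rownames(m))
    expect_equal(fitch_length(tr, m), oracle_fitch(tr, m))
  }
})

test_that("Fitch length is invariant under re-rooting", {
  set.seed(102)
  m <- random_charmatrix(6, 30)
  tr <- ape::rtree(6, tip.label = rownames(m))
  l0 <- fitch_length(tr, m)
  for (tx in rownames(m)) {
    expect_equal(fitch_length(ape::root(tr, outgroup = tx), m), l0)
  }
})

test_that("a duplicated column adds exactly its per-column steps", {
  set.seed(103)
  m <- random_charmatrix(6, 10)
  tr <- ape::rtree(6, tip.label = rownames(m))
  l0 <- fitch_length(tr, m)
  lc <- fitch_length(tr, m[, 3, drop = FALSE])
  expect_equal(fitch_length(tr, cbind(m, m[, 3])), l0 + lc)
})

test_that("exhaustive search enumerates (2n-5)!! topologies", {
  m4 <- matrix(c("A", "A", "T", "T"), 4, 1,
               dimnames = list(paste0("t", 1:4), NULL))
  ex <- exhaustive_search(m4)
  expect_equal(ex$n_topologies, 3L)
  expect_equal(ex$length, 1L)
  expect_equal(length(ex$trees), 1L)
  # the unique MP tree groups the shared-state pairs
  expect_identical(plastocomp:::splits_of(ex$trees[[1]]), "t3,t4")

  set.seed(104)
  m8 <- random_charmatrix(8, 4)
  expect_equal(exhaustive_search(m8)$n_topologies, 10395L)
  expect_error(exhaustive_search(random_charmatrix(12, 4)), "heuristic")
})

test_that("exhaustive MP set equals brute force over all 15 topologies", {
  set.seed(105)
  m <- matrix(sample(c("0", "1"), 5 * 6, TRUE), 5, 6,
              dimnames = list(paste0("t", 1:5), NULL))
  ex <- exhaustive_search(m)
  # independent enumeration and scoring through phangorn
  all15 <- phangorn::allTrees(5, rooted = FALSE,
                              tip.label = paste0("t", 1:5))
  pd <- phangorn::phyDat(m, type = "USER", levels = c("0", "1"))
  plens <- vapply(all15, function(tr) {
    as.integer(phangorn::parsimony(tr, pd))
  }, integer(1))
  expect_equal(ex$length, min(plens))
  expect_equal(length(ex$trees), sum(plens == min(plens)))
  got <- sort(vapply(ex$trees, plastocomp:::topology_key, character(1)))
  want <- sort(vapply(all15[plens == min(plens)],
                      plastocomp:::topology_key, character(1)))
  expect_identical(got, want)
})

test_that("heuristic search attains the exhaustive optimum", {
  set.seed(106)
  for (rep in 1:6) {
    m <- random_charmatrix(7, 40)
    ex <- exhaustive_search(m)
    for (swap in c("NNI", "SPR")) {
      h <- heuristic_search(m, n_addition = 8, swap = swap, seed = rep)
      expect_equal(h$length, ex$length)
    }
  }
})

test_that("more addition replicates never find a worse tree", {
  set.seed(107)
  m <- random_charmatrix(8, 25)
  l1 <- heuristic_search(m, n_addition = 1, seed = 9)$length
  l100 <- heuristic_search(m, n_addition = 100, seed = 9)$length
  expect_true(l100 <= l1)
})

test_that("heuristic best length never exceeds a user tree's length", {
  set.seed(108)
  for (rep in 1:5) {
    m <- random_charmatrix(7, 30)
    h <- heuristic_search(m, n_addition = 10, seed = rep)
    user <- ape::rtree(7, tip.label = rownames(m))
    expect_true(h$length <= fitch_length(user, m))
  }
})

test_that("bootstrap support is 100 when every column backs one split", {
  taxa <- paste0("t", 1:6)
  m <- matrix("A", 6, 40, dimnames = list(taxa, NULL))
  m[c("t1", "t2"), 1:20] <- "T"
  m[c("t1", "t2", "t3"), 21:40] <- "G"
  bs <- bootstrap_support(m, replicates = 30, seed = 5)
  sup <- bs$support
  # splits are keyed by the side not containing the first taxon
  expect_equal(sup$support[sup$split == "t3,t4,t5,t6"], 100)
  expect_equal(sup$support[sup$split == "t4,t5,t6"], 100)
})

test_that("bootstrap support is invariant to taxon order", {
  set.seed(109)
  taxa <- paste0("t", 1:6)
  m <- matrix(sample(c("A", "C", "G", "T"), 6 * 60, TRUE), 6, 60,
              dimnames = list(taxa, NULL))
  m[c("t1", "t2"), 1:12] <- "T"; m[c("t5", "t6"), 13:24] <- "G"
  b1 <- bootstrap_support(m, replicates = 25, seed = 11)
  b2 <- bootstrap_support(m[rev(taxa), ], replicates = 25, seed = 11)
  s1 <- b1$support[order(b1$support$split), ]
  s2 <- b2$support[order(b2$support$split), ]
  expect_identical(s1$split, s2$split)
  expect_true(all(abs(s1$support - s2$support) <= 20))
})

test_that("majority-rule consensus equals the split tally", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,b),(c,e),d);")
  cons <- majority_consensus(list(t1, t2, t1))
  # identical trees: consensus is the tree itself, all frequencies 100
  same <- majority_consensus(list(t1, t1, t1))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(same), ape::unroot(t1))), 0)
  expect_true(all(as.numeric(same$node.label[same$node.label != ""]) == 100))
  # a split in 2 of 3 trees is kept at 66.7
  key <- plastocomp:::splits_of(cons)
  expect_true("c,d" %in% key)
  expect_true("66.7" %in% cons$node.label)

  set.seed(110)
  for (rep in 1:5) {
    # a majority backbone plus random noise trees
    backbone <- ape::rtree(6, tip.label = paste0("t", 1:6))
    noise <- ape::rmtree(3, 6, tip.label = paste0("t", 1:6))
    trees <- c(list(backbone, backbone, backbone, backbone),
               as.list(noise))
    mine <- majority_consensus(trees)
    ref <- ape::consensus(trees, p = 0.5)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine),
                                           ape::unroot(ref))), 0)
  }
  expect_error(majority_consensus(list(t1, ape::rtree(4))), "leaf set")
})

test_that("homoplasy indices match hand computation and stay bounded", {
  taxa4 <- paste0("t", 1:4)
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  clean <- matrix(c("A", "A", "T", "T"), 4, 1,
                  dimnames = list(taxa4, NULL))
  expect_equal(ci_ri(tr, clean)$ci, 1)

  # A/T/A/T on the 'wrong' tree: 2 steps, min 1 -> column CI = 0.5
  conflict <- matrix(c("A", "T", "A", "T"), 4, 1,
                     dimnames = list(taxa4, NULL))
  h <- ci_ri(tr, conflict)
  expect_equal(h$ci, 0.5)
  expect_equal(h$ri, 0)

  # no informative variation: RI undefined
  auta <- matrix(c("A", "T", "G", "C"), 4, 1,
                 dimnames = list(taxa4, NULL))
  expect_true(is.na(ci_ri(tr, auta)$ri))

  set.seed(111)
  for (rep in 1:15) {
    m <- random_charmatrix(6, 15)
    tr <- ape::rtree(6, tip.label = rownames(m))
    h <- ci_ri(tr, m)
    expect_true(h$ci <= 1 + 1e-12)
    if (!is.na(h$ri)) expect_true(h$ri >= -1e-12 && h$ri <= 1 + 1e-12)
    # cross-check against the established implementation
    pd <- phangorn::phyDat(m, type = "DNA")
    expect_equal(h$ci, phangorn::CI(tr, pd))
    if (!is.na(h$ri)) expect_equal(h$ri, phangorn::RI(tr, pd))
  }
  # bounds also hold with missing data
  for (rep in 1:5) {
    m <- random_charmatrix(6, 15, p_missing = 0.1)
    tr <- ape::rtree(6, tip.label = rownames(m))
    h <- ci_ri(tr, m)
    expect_true(h$ci <= 1 + 1e-12)
    if (!is.na(h$ri)) expect_true(h$ri >= -1e-12 && h$ri <= 1 + 1e-12)
  }
})
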