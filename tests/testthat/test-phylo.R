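test_that("three-taxon branch lengths follow the closed form", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(d)
  len <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(len[["A"]], (2 + 3 - 4) / 2)  # 0.5
  expect_equal(len[["B"]], (2 + 4 - 3) / 2)  # 1.5
  expect_equal(len[["C"]], (3 + 4 - 2) / 2)  # 2.5
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("an additive 4-taxon matrix recovers its split and branch lengths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):0);")
  d <- ape::cophenetic.phylo(tr)
  d <- d[c("A", "B", "C", "D"), c("A", "B", "C", "D")]
  tree <- nj_tree(d)
  keys <- names(madswalk:::bipartition_keys(tree))
  expect_identical(keys, "C|D")
  # classical NJ resolves the final three clusters as a star, so the
  # zero-length half of the internal path folds into five unit edges
  expect_equal(sort(tree$edge.length), rep(1, 5))
})

test_that("equal distances resolve deterministically by the index tie-break", {
  d <- matrix(1, 5, 5, dimnames = list(paste0("t", 1:5), paste0("t", 1:5)))
  diag(d) <- 0
  t1 <- ape::write.tree(nj_tree(d))
  t2 <- ape::write.tree(nj_tree(d))
  expect_identical(t1, t2)
})

test_that("NJ recovers generating topologies from additive matrices", {
  set.seed(71)
  ok <- 0
  for (i in 1:30) {
    tt <- ape::rtree(5, rooted = FALSE)
    tt$edge.length <- runif(length(tt$edge.length), 0.1, 2)
    d <- ape::cophenetic.phylo(tt)
    got <- nj_tree(d)
    ok <- ok + (ape::dist.topo(ape::unroot(got), ape::unroot(tt)) == 0)
  }
  expect_equal(ok, 30)
})

test_that("4-taxon NJ agrees with brute-force minimum evolution", {
  set.seed(72)
  for (i in 1:25) {
    tt <- ape::rtree(4, rooted = FALSE)
    tt$edge.length <- runif(length(tt$edge.length), 0.1, 2)
    d <- ape::cophenetic.phylo(tt)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    got <- nj4_split(nj_tree(d))
    expect_identical(got, oracle_me_topology(d), label = paste("case", i))
  }
})

test_that("NJ matches the independent reference implementation", {
  set.seed(73)
  for (i in 1:10) {
    m <- matrix(runif(49, 0.05, 1), 7)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    rownames(m) <- colnames(m) <- paste0("t", 1:7)
    d1 <- ape::dist.topo(ape::unroot(nj_tree(m)), ape::unroot(ape::nj(m)))
    expect_equal(as.numeric(d1), 0)
  }
})

test_that("bootstrap supports a planted split and is seed-stable", {
  set.seed(74)
  alpha <- c("A", "R", "N", "D", "K", "L")
  base <- paste(sample(alpha, 80, replace = TRUE), collapse = "")
  mut <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    for (i in sample(length(ch), n)) ch[i] <- sample(setdiff(alpha, ch[i]), 1)
    paste(ch, collapse = "")
  }
  # C near-identical to D, both far from the near-identical A/B pair
  other <- mut(base, 48)
  aln <- msa(c(A = base, B = mut(base, 2), C = other, D = mut(other, 2)))
  bt <- bootstrap_support(aln, n_reps = 100, seed = 9)
  sup <- attr(bt, "bipartition_support")
  expect_gte(sup[["C|D"]], 95)
  bt2 <- bootstrap_support(aln, n_reps = 100, seed = 9)
  expect_identical(attr(bt2, "bipartition_support"), sup)
  # a single replicate gives supports of exactly 0 or 100
  b1 <- attr(bootstrap_support(aln, n_reps = 1, seed = 10),
             "bipartition_support")
  expect_true(all(b1 %in% c(0, 100)))
})

test_that("supports are invariant to row order of the alignment", {
  set.seed(76)
  rows <- setNames(vapply(1:5, function(i) random_protein_str(60),
                          character(1)), paste0("s", 1:5))
  aln1 <- msa(rows)
  aln2 <- msa(rows[c(3, 1, 5, 2, 4)])
  s1 <- attr(bootstrap_support(aln1, n_reps = 30, seed = 3),
             "bipartition_support")
  s2 <- attr(bootstrap_support(aln2, n_reps = 30, seed = 3),
             "bipartition_support")
  expect_identical(s1[sort(names(s1))], s2[sort(names(s2))])
})

test_that("collapse contracts below-threshold edges and keeps the boundary", {
  t49 <- ape::read.tree(text = "((A:1,B:1)49:0.5,(C:1,D:1)75:0.5,E:1);")
  c49 <- collapse_low_support(t49, 50)
  expect_identical(ape::write.tree(c49), "(A:1,B:1,(C:1,D:1)75:0.5,E:1);")
  t50 <- ape::read.tree(text = "((A:1,B:1)50:0.5,(C:1,D:1)75:0.5,E:1);")
  c50 <- collapse_low_support(t50, 50)
  expect_identical(ape::write.tree(c50),
                   "((A:1,B:1)50:0.5,(C:1,D:1)75:0.5,E:1);")
  t100 <- ape::read.tree(text = "((A:1,B:1)100:0.5,(C:1,D:1)100:0.5,E:1);")
  expect_identical(ape::write.tree(collapse_low_support(t100, 50)),
                   ape::write.tree(t100))
  expect_setequal(c49$tip.label, t49$tip.label)
})

test_that("clade assignment uses the smallest reference-bearing group", {
  tr <- ape::read.tree(text = "((q1:1,ref1:1):1,(ref2:1,q2:1):1,ref3:1);")
  labs <- c(ref1 = "SVP-like", ref2 = "TM3-like", ref3 = "AG-like")
  got <- assign_clade(tr, labs)
  expect_identical(got$clade[got$query == "q1"], "SVP-like")
  expect_identical(got$clade[got$query == "q2"], "TM3-like")
  # polytomy with conflicting references
  tr2 <- ape::read.tree(text = "((q:1,ref1:1,ref2:1):1,ref3:1,ref4:1);")
  labs2 <- c(ref1 = "X", ref2 = "Y", ref3 = "X", ref4 = "Y")
  expect_identical(assign_clade(tr2, labs2)$clade, "unresolved")
  expect_error(assign_clade(tr, character(0)), "empty")
})

test_that("planted clades are assigned perfectly from held-out references", {
  fam <- gen_gene_family(18, 3, seed = 77)
  aln <- progressive_align(fam$proteins)
  cropped <- crop_to_conserved(aln, 0.5)
  tree <- bootstrap_support(cropped, n_reps = 30, seed = 4)
  collapsed <- collapse_low_support(tree, 50)
  ref_ids <- names(fam$clade_labels)[c(TRUE, FALSE)]
  got <- assign_clade(collapsed, fam$clade_labels[ref_ids])
  expect_identical(unname(fam$clade_labels[got$query]), got$clade)
})
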