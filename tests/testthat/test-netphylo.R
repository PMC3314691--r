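test_that("presence/absence matrix is binary with duplications collapsed", {
  arch <- data.frame(protein = c("p1", "p1", "p1", "p2", "p2"),
                     slot = c(1, 2, 3, 1, 2),
                     family = c("N1", "Ami", "C1", "GH19", "GH19"),
                     class = c("N", "CAT", "C", "CAT", "CAT"),
                     start = c(1, 150, 350, 1, 200),
                     end = c(100, 300, 430, 150, 340))
  attr(arch, "proteins") <- c("p1", "p2", "p3")
  M <- presence_absence(arch)
  expect_equal(dim(M), c(3, 4))
  expect_equal(sum(M["p1", ]), 3)
  expect_equal(unname(M["p2", "GH19"]), 1)  # two copies still one
  expect_equal(sum(M["p3", ]), 0)
  M15 <- presence_absence(arch, family_types = c(colnames(M), paste0("Z", 1:11)))
  expect_equal(ncol(M15), 15)
  expect_equal(sum(M15["p1", ]), 3)
})

test_that("binary distances follow the hamming and jaccard definitions", {
  M <- rbind(a = c(1, 0, 1), b = c(0, 1, 1), c = c(1, 0, 1))
  expect_equal(binary_distance(M, "hamming")["a", "b"], 2 / 3)
  expect_equal(binary_distance(M, "jaccard")["a", "b"], 2 / 3)
  expect_equal(binary_distance(M, "hamming")["a", "c"], 0)
  M2 <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(binary_distance(M2, "jaccard")["a", "b"], 1)
  M3 <- rbind(a = c(0, 0), b = c(0, 0))
  expect_equal(binary_distance(M3, "jaccard")["a", "b"], 0)
  D <- binary_distance(M, "hamming")
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
})

test_that("neighbor joining realizes additive metrics exactly", {
  set.seed(14)
  for (rep in 1:30) {
    am <- random_additive_metric(sample(5:8, 1))
    tr <- nj_tree(am$D)
    expect_equal(rf_distance(tr, am$tree), 0)
    expect_equal(stats::cophenetic(tr)[rownames(am$D), colnames(am$D)],
                 am$D, tolerance = 1e-8)
  }
  # 3 taxa: closed-form star branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(D3)
  bl <- setNames(tr3$edge.length,
                 tr3$tip.label[tr3$edge[, 2]])
  expect_equal(unname(bl["A"]), (3 + 4 - 5) / 2)
  expect_error(nj_tree(D3[1:2, 1:2]), "at least 3")
  # zero matrix: all branch lengths zero
  D0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(nj_tree(D0)$edge.length == 0))
})

test_that("Robinson-Foulds distance counts unshared bipartitions", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  expect_equal(rf_distance(t2, t1), 2)
  t5a <- ape::read.tree(text = "(((A,B),C),(D,E));")
  t5b <- ape::read.tree(text = "(((A,D),B),(C,E));")
  expect_equal(rf_distance(t5a, t5b), 4)
  expect_error(rf_distance(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "leaf sets")
  # agreement with an independent implementation on random trees
  set.seed(6)
  for (rep in 1:10) {
    x <- ape::rtree(7); y <- ape::rtree(7)
    expect_equal(rf_distance(x, y),
                 as.integer(phangorn::RF.dist(ape::unroot(x),
                                              ape::unroot(y))))
  }
})

test_that("progressive alignment preserves sequences and matches pairwise DP", {
  s <- scoring_model()
  seqs <- c(a = "MKVLWAAG", b = "MKVLWAAG", c = "MKVLWAAG")
  msa <- progressive_msa(seqs, s)
  expect_equal(msa$ncol, 8)
  expect_false(any(grepl("-", msa$aln)))
  # two sequences equal the pairwise global alignment
  two <- c(x = "MKVLWAAGRR", y = "MKVWAAGRR")
  msa2 <- progressive_msa(two, s)
  ga <- global_align(two[["x"]], two[["y"]], s)
  expect_equal(unname(msa2$aln), c(ga$a_aln, ga$b_aln))
  # de-gapping reproduces every input (random sets)
  set.seed(8)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    sq <- setNames(replicate(n, rand_seq(sample(30:60, 1), aa20)),
                   paste0("s", 1:n))
    mm <- progressive_msa(sq, s)
    expect_equal(unname(nchar(mm$aln)), rep(mm$ncol, n))
    expect_identical(gsub("-", "", mm$aln), sq)
    expect_gte(mm$ncol, max(nchar(sq)))
  }
})

test_that("a deletion shows up as a gap block in the carrier row", {
  s <- scoring_model()
  set.seed(12)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- rand_seq(40, aa20)
  del <- paste0(substr(base, 1, 17), substr(base, 21, 40))
  msa <- progressive_msa(c(f1 = base, f2 = base, f3 = del), s)
  expect_equal(msa$ncol, 40)
  expect_equal(unname(vapply(msa$aln, function(x)
    sum(strsplit(x, "")[[1]] == "-"), 1)), c(0, 0, 3))
})

test_that("bootstrap support is reproducible and finds a planted clade", {
  s <- scoring_model()
  set.seed(23)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  # two clades differing at 50% of sites
  anc1 <- strsplit(rand_seq(80, aa20), "")[[1]]
  anc2 <- anc1
  flip <- sample(80, 40)
  anc2[flip] <- vapply(anc2[flip], function(ch)
    sample(setdiff(aa20, ch), 1), "")
  mut <- function(v) {
    hit <- stats::runif(80) < 0.05
    v[hit] <- vapply(v[hit], function(ch) sample(setdiff(aa20, ch), 1), "")
    paste(v, collapse = "")
  }
  seqs <- c(a1 = mut(anc1), a2 = mut(anc1), a3 = mut(anc1),
            b1 = mut(anc2), b2 = mut(anc2), b3 = mut(anc2))
  msa <- progressive_msa(seqs, s)
  bs <- bootstrap_support(msa, n_reps = 100, seed = 41)
  clade <- bs$supports[bs$supports$split %in%
                         c("b1,b2,b3", "a2,a3"), , drop = FALSE]
  split_ab <- bs$supports$support[bs$supports$split == "b1,b2,b3"]
  expect_gte(split_ab, 95)
  bs2 <- bootstrap_support(msa, n_reps = 100, seed = 41)
  expect_identical(bs$supports, bs2$supports)
  # identical sequences: star tree, no internal splits to support
  same <- c(x = mut(anc1), y = NA, z = NA)
  same[] <- same[["x"]]
  bs3 <- bootstrap_support(progressive_msa(same, s), n_reps = 10, seed = 1)
  expect_equal(nrow(bs3$supports), 0)
})

test_that("neighbor_net reproduces additive trees and mixed signals", {
  am <- random_additive_metric(6)
  net <- neighbor_net(am$D)
  expect_lte(net$residual, 1e-8)
  # split set equals the tree splits (non-trivial ones) plus pendant edges
  tree_splits <- tree_bipartitions(am$tree)
  net_keys <- vapply(net$splits, function(side) {
    labs <- net$labels
    if (sort(labs)[1] %in% side) side <- setdiff(labs, side)
    if (length(side) < 2 || length(side) > length(labs) - 2)
      return(NA_character_)
    paste(sort(side), collapse = ",")
  }, "")
  expect_setequal(stats::na.omit(net_keys), names(tree_splits))
  # all-equal distances: perfect fit by equal pendant weights
  De <- matrix(2, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(De) <- 0
  nete <- neighbor_net(De)
  expect_lte(nete$residual, 1e-8)
  pend <- lengths(nete$splits) %in% c(1, 4)
  expect_true(all(abs(nete$weights[pend] - 1) < 1e-6))
})

test_that("neighbor_net weights match a brute-force NNLS oracle", {
  skip_if_not_installed("pracma")
  D2 <- matrix(c(0, 2, 4, 4, 2, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D3 <- matrix(c(0, 4, 2, 4, 4, 0, 4, 2, 2, 4, 0, 4, 4, 2, 4, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  Dm <- (D2 + D3) / 2
  net <- neighbor_net(Dm)
  # both conflicting 2|2 splits get positive weight
  two_sided <- net$splits[lengths(net$splits) == 2]
  expect_gte(length(two_sided), 2)
  orc <- nnls_circular_oracle(Dm, net$order)
  expect_equal(net$residual, orc$residual, tolerance = 1e-6)
  # weights agree split by split (bipartitions compared up to complement)
  canon <- function(side, labs, anchor) {
    if (anchor %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = ",")
  }
  anchor <- net$order[1]
  okey <- vapply(orc$splits, canon, "", labs = net$labels, anchor = anchor)
  nkey <- vapply(net$splits, canon, "", labs = net$labels, anchor = anchor)
  for (k in seq_along(nkey)) {
    expect_equal(net$weights[k],
                 sum(orc$weights[okey == nkey[k]]), tolerance = 1e-6)
  }
})

test_that("splits networks handle tiny taxon sets and write Nexus", {
  D <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  net2 <- neighbor_net(D)
  expect_equal(length(net2$splits), 1)
  expect_equal(net2$weights, 3)
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  net3 <- neighbor_net(D3)
  expect_equal(sort(net3$weights), c(1, 2, 3))
  expect_lte(net3$residual, 1e-8)
  path <- withr::local_tempfile(fileext = ".nex")
  write_splits_nexus(net3, path, comment = "seed=1")
  txt <- readLines(path)
  expect_equal(txt[1], "#NEXUS")
  expect_true(any(grepl("BEGIN Splits;", txt)))
  expect_true(any(grepl("nsplits=3", txt)))
})

test_that("incongruence scan skips class pairs with too few shared proteins", {
  cs <- list(N = c(p1 = "MKVLW"), CAT = c(p1 = "MKVLW", p2 = "MKVLW"))
  expect_message(out <- incongruence_scan(cs, n_reps = 5, seed = 1),
                 "only 1 shared")
  expect_equal(nrow(out), 0)
})

test_that("a four-taxon conflicting pattern is flagged", {
  # N-domain tree pairs {w,x}{y,z}; CAT tree pairs {w,y}{x,z}
  set.seed(33)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mk <- function(anc, d = 0.03) {
    v <- strsplit(anc, "")[[1]]
    hit <- stats::runif(length(v)) < d
    v[hit] <- vapply(v[hit], function(ch) sample(setdiff(aa20, ch), 1), "")
    paste(v, collapse = "")
  }
  nA <- rand_seq(90, aa20); nB <- rand_seq(90, aa20)
  cA <- rand_seq(90, aa20); cB <- rand_seq(90, aa20)
  cs <- list(
    N = c(w = mk(nA), x = mk(nA), y = mk(nB), z = mk(nB)),
    CAT = c(w = mk(cA), y = mk(cA), x = mk(cB), z = mk(cB)))
  out <- incongruence_scan(cs, n_reps = 100, seed = 7)
  row <- out[out$class1 == "N" & out$class2 == "CAT", ]
  expect_equal(row$rf, 2)
  expect_true(row$flagged)
})
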