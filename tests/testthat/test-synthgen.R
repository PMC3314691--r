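test_that("generator config validates probability mass and ranges", {
  expect_error(generator_config(org_distribution = c("N+CAT+C" = 0.5)),
               "sum to 1")
  expect_error(generator_config(divergence = 1.5), "divergence")
  expect_error(generator_config(org_distribution = c("N+Q" = 1)),
               "N, CAT, C")
  cfg <- generator_config()
  expect_s3_class(cfg, "generator_config")
  expect_equal(sum(cfg$org_distribution), 1)
})

test_that("generation is deterministic and zero divergence reproduces ancestors", {
  cfg <- generator_config(n_proteins = 8, divergence = 0, seed = 5)
  p1 <- generate_proteome(cfg)
  p2 <- generate_proteome(cfg)
  expect_identical(p1$proteins, p2$proteins)
  expect_identical(p1$truth$instances, p2$truth$instances)
  ti <- p1$truth$instances
  for (k in seq_len(nrow(ti))) {
    expect_identical(
      substr(p1$proteins[[ti$protein[k]]], ti$start[k], ti$end[k]),
      unname(p1$truth$ancestors[ti$family[k]]))
  }
})

test_that("truth intervals plus linkers compose the protein exactly", {
  pr <- generate_proteome(generator_config(n_proteins = 10, seed = 3))
  pieces <- pr$truth$pieces
  for (pp in names(pr$proteins)) {
    expect_identical(paste(pieces$seq[pieces$protein == pp], collapse = ""),
                     unname(pr$proteins[[pp]]))
  }
  # intervals are non-overlapping and within bounds
  ti <- pr$truth$instances
  expect_true(all(ti$start >= 1))
  expect_true(all(ti$end <= nchar(pr$proteins[ti$protein])))
  by_prot <- split(ti, ti$protein)
  for (df in by_prot) {
    df <- df[order(df$start), ]
    if (nrow(df) > 1)
      expect_true(all(df$start[-1] > df$end[-nrow(df)]))
  }
})

test_that("canonical organization fraction follows the binomial", {
  cfg <- generator_config(n_proteins = 600, divergence = 0, seed = 9)
  pr <- generate_proteome(cfg)
  frac <- mean(pr$truth$proteins$template == "N+CAT+C")
  se <- sqrt(0.9 * 0.1 / 600)
  expect_lt(abs(frac - 0.9), 3 * se)
})

test_that("within-family identity matches the substitution model expectation", {
  for (d in c(0.1, 0.3)) {
    cfg <- generator_config(n_proteins = 30, divergence = d, seed = 13)
    pr <- generate_proteome(cfg)
    ti <- pr$truth$instances
    idents <- c()
    for (f in unique(ti$family)) {
      members <- ti[ti$family == f, ]
      if (nrow(members) < 2) next
      seqs <- substr(pr$proteins[members$protein], members$start,
                     members$end)
      pairs <- utils::combn(seq_along(seqs), 2)
      for (k in seq_len(ncol(pairs))) {
        a <- strsplit(seqs[pairs[1, k]], "")[[1]]
        b <- strsplit(seqs[pairs[2, k]], "")[[1]]
        idents <- c(idents, mean(a == b))
      }
    }
    exp_id <- expected_family_identity(d)
    # pairs sharing an ancestor are correlated, so the plain SE of the
    # pair identities underestimates the sampling error; allow a small
    # absolute slack on top
    se <- stats::sd(idents) / sqrt(length(idents))
    expect_lt(abs(mean(idents) - exp_id), 3 * se + 5e-3)
  }
})

test_that("recovery score is exact on identity and on the hand pair-count case", {
  pr <- generate_proteome(generator_config(n_proteins = 10, seed = 2))
  ti <- pr$truth$instances
  inferred <- ti[, c("protein", "family", "start", "end")]
  rep <- family_recovery_score(inferred, pr$truth)
  expect_equal(rep$ari, 1.0)
  expect_true(all(rep$per_family$precision == 1))
  expect_true(all(rep$per_family$recall == 1))
  # two equal-size true families collapsed into one inferred cluster:
  # pair counting gives ARI (2 - 2) / (4 - 2) = 0
  truth <- data.frame(protein = c("p1", "p1", "p2", "p2"),
                      family = c("A", "B", "A", "B"),
                      class = "CAT",
                      start = c(1, 200, 1, 200),
                      end = c(100, 300, 100, 300))
  inf1 <- truth[, c("protein", "family", "start", "end")]
  inf1$family <- "X"
  expect_equal(family_recovery_score(inf1, truth)$ari, 0)
})

test_that("random relabelling of instances has near-zero mean ARI", {
  truth <- data.frame(protein = rep(sprintf("p%02d", 1:12), each = 3),
                      family = rep(c("A", "B", "C"), 12),
                      class = rep(c("N", "CAT", "C"), 12),
                      start = rep(c(1, 200, 400), 12),
                      end = rep(c(100, 300, 500), 12))
  inferred <- truth[, c("protein", "family", "start", "end")]
  set.seed(4)
  aris <- replicate(100, {
    inferred$family <- sample(inferred$family)
    family_recovery_score(inferred, truth)$ari
  })
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("architecture accuracy counts exact ordered matches under the best bijection", {
  truth <- data.frame(protein = rep(sprintf("p%02d", 1:10), each = 3),
                      family = rep(c("N1", "A1", "C1"), 10),
                      class = rep(c("N", "CAT", "C"), 10),
                      start = rep(c(1, 200, 400), 10),
                      end = rep(c(100, 300, 500), 10))
  inferred <- truth[, c("protein", "family", "start", "end")]
  inferred$family <- paste0("F", match(inferred$family, c("N1", "A1", "C1")))
  expect_equal(architecture_accuracy(inferred, truth), 1.0)
  # one protein's central domain assigned to a different family
  inferred$family[inferred$protein == "p03" &
                    inferred$start == 200] <- "F9"
  expect_equal(architecture_accuracy(inferred, truth), 0.9)
  expect_error(architecture_accuracy(
    transform(inferred, protein = "zz"), truth), "no protein")
})

test_that("maximum-weight assignment agrees with brute force", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    W <- matrix(stats::runif(n * m, 0, 10), n, m)
    asn <- lysmod:::max_weight_assignment(W)
    got <- sum(W[cbind(which(!is.na(asn)), asn[!is.na(asn)])])
    k <- min(n, m)
    best <- 0
    rows <- utils::combn(seq_len(n), k)
    for (ci in seq_len(ncol(rows))) {
      # enumerate column permutations over all k-subsets of columns
      cols <- utils::combn(seq_len(m), k)
      for (cj in seq_len(ncol(cols))) {
        pm <- function(v) {
          if (length(v) == 1) return(list(v))
          out <- list()
          for (i in seq_along(v))
            for (rest in pm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
          out
        }
        for (pp in pm(cols[, cj])) {
          best <- max(best, sum(W[cbind(rows[, ci], pp)]))
        }
      }
    }
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("engineered swap updates sequence, coordinates and swap table", {
  pr <- generate_proteome(generator_config(
    n_proteins = 8, n_lineages = 4, swap_rate = 0,
    preference_scheme = "disjoint", seed = 6))
  before <- pr$truth$instances
  pr2 <- apply_domain_swap(pr, "Phage001_gp1", 2, 2, seed = 1)
  after <- pr2$truth$instances
  sw <- pr2$truth$swaps
  expect_equal(nrow(sw), 1)
  expect_equal(sw$protein, "Phage001_gp1")
  expect_equal(sw$donor_lineage, 2)
  k <- which(after$protein == "Phage001_gp1")[2]
  expect_identical(
    substr(pr2$proteins[["Phage001_gp1"]], after$start[k], after$end[k]),
    substr(pr2$proteins[["Phage001_gp1"]], after$start[k], after$end[k]))
  expect_false(identical(pr$proteins[["Phage001_gp1"]],
                         pr2$proteins[["Phage001_gp1"]]))
  # untouched proteins unchanged
  expect_identical(pr$proteins[-1], pr2$proteins[-1])
})

test_that("proteome writer emits FASTA and truth tables that read back", {
  pr <- generate_proteome(generator_config(n_proteins = 6, seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_proteome(pr, dir)
  expect_true(all(file.exists(paths)))
  back <- read_fasta(file.path(dir, "proteome.fasta"))
  expect_identical(back, pr$proteins)
  ti <- read_tsv(file.path(dir, "truth_instances.tsv"))
  expect_equal(nrow(ti), nrow(pr$truth$instances))
  expect_true(any(grepl("seed", readLines(file.path(dir, "proteome.fasta"),
                                          n = 1))))
})
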