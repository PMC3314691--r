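test_that("link predicate applies the dual threshold with strict inequalities", {
  p <- cluster_params()
  expect_true(link_predicate(list(evalue = 1e-6, gident = 15), p))
  expect_false(link_predicate(list(evalue = 1e-5, gident = 20), p))
  expect_true(link_predicate(list(evalue = 0.01, gident = 25), p))
  pa <- cluster_params(link_rule = "AND")
  expect_false(link_predicate(list(evalue = 0.01, gident = 25), pa))
  expect_true(link_predicate(list(evalue = 1e-7, gident = 30), pa))
  # populated flags take precedence over stored values
  expect_false(link_predicate(list(evalue = 1e-9, gident = 99,
                                   passes_evalue = FALSE,
                                   passes_identity = FALSE), p))
})

test_that("interval consolidation merges by fraction of the shorter interval", {
  p <- cluster_params()
  iv <- data.frame(protein = "p", start = c(10, 20), end = c(100, 110))
  out <- consolidate_segments(iv, p)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(10, 110))

  iv2 <- data.frame(protein = "p", start = c(10, 100), end = c(60, 150))
  expect_equal(nrow(consolidate_segments(iv2, p)), 2)

  # overlap 6 < 0.5 * 91: kept separate
  iv3 <- data.frame(protein = "p", start = c(10, 95), end = c(100, 200))
  expect_equal(nrow(consolidate_segments(iv3, p)), 2)

  # order independence
  iv4 <- iv[c(2, 1), ]
  expect_identical(consolidate_segments(iv4, p),
                   consolidate_segments(iv, p))
})

test_that("single linkage recovers planted single-domain families", {
  pl <- planted_single_domain_proteome(n_fam = 3, per_fam = 3,
                                       divergence = 0.2, seed = 2)
  m <- all_vs_all(pl$proteins)
  fams <- cluster_families(m, pl$proteins)
  expect_equal(nrow(fams$families), 3)
  # inferred partition of proteins equals the planted families
  byfam <- split(fams$instances$protein, fams$instances$family)
  planted <- split(names(pl$family), pl$family)
  key <- function(part) sort(unname(vapply(part, function(x)
    paste(sort(x), collapse = ","), "")))
  expect_setequal(key(byfam), key(planted))
})

test_that("no matches means every interval is its own family", {
  set.seed(5)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  prot <- setNames(replicate(3, rand_seq(150, aa20)), c("a", "b", "c"))
  m <- all_vs_all(prot)
  fams <- cluster_families(m, prot)
  # unrelated random proteins: no linked matches survive, or only
  # singleton fragments that the fragment filter removes
  expect_true(nrow(fams$instances) == 0 ||
                all(table(fams$instances$family) <= 1))
})

test_that("relaxing thresholds only merges families, never splits them", {
  pr <- generate_proteome(generator_config(n_proteins = 24,
                                           divergence = 0.2, seed = 19))
  m <- all_vs_all(pr$proteins)
  strict <- cluster_families(m, pr$proteins,
                             cluster_params(evalue_max = 1e-5))
  relaxed <- cluster_families(m, pr$proteins,
                              cluster_params(evalue_max = 1e-2))
  # map each strict instance to its relaxed family; a strict family must
  # land inside exactly one relaxed family
  key <- paste(relaxed$instances$protein, relaxed$instances$start)
  for (f in unique(strict$instances$family)) {
    sub <- strict$instances[strict$instances$family == f, ]
    hit <- relaxed$instances$family[match(paste(sub$protein, sub$start),
                                          key)]
    hit <- hit[!is.na(hit)]
    if (length(hit)) expect_equal(length(unique(hit)), 1)
  }
})

test_that("positional class assignment votes on normalized midpoints", {
  prot <- c(p1 = paste(rep("A", 400), collapse = ""),
            p2 = paste(rep("A", 400), collapse = ""),
            p3 = paste(rep("A", 400), collapse = ""))
  early <- data.frame(protein = c("p1", "p2", "p3"),
                      start = 20, end = 100)
  expect_equal(assign_class(early, prot), "N")
  late <- data.frame(protein = c("p1", "p2", "p3"),
                     start = 300, end = 380)
  expect_equal(assign_class(late, prot), "C")
  mid <- data.frame(protein = c("p1", "p2", "p3"),
                    start = 150, end = 260)
  expect_equal(assign_class(mid, prot), "CAT")
  # annotation wins over position
  expect_equal(assign_class(late, prot, family = "F001",
                            annotation = c(F001 = "CAT")), "CAT")
  # a 2-way tie is unassigned
  tie <- data.frame(protein = c("p1", "p2"),
                    start = c(20, 300), end = c(100, 380))
  expect_equal(assign_class(tie, prot), "UNASSIGNED")
})

test_that("unknown annotation families trigger a warning and are ignored", {
  pl <- planted_single_domain_proteome(n_fam = 2, per_fam = 3, seed = 3)
  m <- all_vs_all(pl$proteins)
  expect_warning(
    cluster_families(m, pl$proteins,
                     annotation = c(NOPE = "CAT")),
    "unknown")
})

test_that("planted families recover with high ARI at divergence 0.3", {
  cfg <- generator_config(n_proteins = 36, divergence = 0.3, seed = 8)
  pr <- generate_proteome(cfg)
  m <- all_vs_all(pr$proteins)
  fams <- cluster_families(m, pr$proteins)
  rec <- family_recovery_score(fams$instances, pr$truth)
  expect_gte(rec$ari, 0.95)
  # inferred classes match the generator classes via instance matching
  ti <- pr$truth$instances
  for (k in sample(nrow(ti), 10)) {
    cand <- fams$instances[fams$instances$protein == ti$protein[k], ]
    ov <- pmin(cand$end, ti$end[k]) - pmax(cand$start, ti$start[k]) + 1
    best <- which.max(ov)
    if (length(best) && ov[best] > 0)
      expect_equal(cand$class[best], ti$class[k])
  }
})
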