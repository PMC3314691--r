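mk_arch <- function(...) {
  # build an architectures table from named lists of (family, class)
  specs <- list(...)
  rows <- list()
  for (pname in names(specs)) {
    sp <- specs[[pname]]
    for (k in seq_along(sp)) {
      rows[[length(rows) + 1]] <- data.frame(
        protein = pname, slot = k, family = sp[[k]][1],
        class = sp[[k]][2],
        start = 100 * k, end = 100 * k + 80, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein = character(0), slot = integer(0),
               family = character(0), class = character(0),
               start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  attr(res, "proteins") <- names(specs)
  class(res) <- c("architectures", "data.frame")
  res
}

test_that("architectures are ordered by start and keep duplications", {
  prot <- c(px = paste(rep("A", 500), collapse = ""))
  inst <- data.frame(protein = "px",
                     family = c("Ami", "N1", "C1"),
                     class = c("CAT", "N", "C"),
                     start = c(150, 5, 350), end = c(320, 120, 430))
  arch <- build_architectures(inst, prot)
  expect_equal(arch$family, c("N1", "Ami", "C1"))
  expect_equal(arch$slot, 1:3)
  # input order must not matter
  arch2 <- build_architectures(inst[c(3, 1, 2), ], prot)
  expect_identical(as.data.frame(arch), as.data.frame(arch2))
  # duplicated family retained in order
  inst3 <- data.frame(protein = "px",
                      family = c("GH19", "Ami"), class = c("CAT", "CAT"),
                      start = c(10, 200), end = c(150, 340))
  arch3 <- build_architectures(inst3, prot)
  expect_equal(arch3$family, c("GH19", "Ami"))
  # domainless proteins yield empty architectures but stay recorded
  arch4 <- build_architectures(inst, c(prot, py = "AAAA"))
  expect_setequal(attr(arch4, "proteins"), c("px", "py"))
  expect_false("py" %in% arch4$protein)
})

test_that("organizations group identical signatures with deterministic labels", {
  arch <- mk_arch(
    a1 = list(c("N1", "N"), c("Ami", "CAT"), c("C1", "C")),
    a2 = list(c("N1", "N"), c("Ami", "CAT"), c("C1", "C")),
    b1 = list(c("N2", "N"), c("Ami", "CAT"), c("C1", "C")))
  orgs <- assign_organizations(arch)
  expect_equal(nrow(orgs), 2)
  expect_equal(orgs$label, c("Org-A", "Org-B"))
  expect_equal(orgs$size, c(2, 1))
  expect_equal(orgs$members[1], "a1,a2")
  # empty input
  e <- assign_organizations(mk_arch())
  expect_equal(nrow(e), 0)
  # shuffling protein order changes nothing
  orgs2 <- assign_organizations(arch[sample(nrow(arch)), ])
  expect_identical(as.data.frame(orgs), as.data.frame(orgs2))
})

test_that("organization labels continue beyond 26 groups", {
  labs <- vapply(1:30, lysmod:::org_label, "")
  expect_equal(labs[1], "Org-A")
  expect_equal(labs[26], "Org-Z")
  expect_equal(labs[27], "Org-AA")
  expect_equal(labs[28], "Org-AB")
})

test_that("combinatorial enumeration is an exact product", {
  expect_equal(enumerate_combinations(6, 5, 4), 120)
  expect_equal(enumerate_combinations(1, 1, 1), 1)
  expect_equal(enumerate_combinations(0, 5, 4), 0)
  set.seed(2)
  for (i in 1:20) {
    v <- sample(0:9, 3, replace = TRUE)
    expect_equal(enumerate_combinations(v[1], v[2], v[3]), prod(v))
  }
})

test_that("coverage statistics count canonical three-domain proteins", {
  arch <- mk_arch(
    a = list(c("N1", "N"), c("Ami", "CAT"), c("C1", "C")),
    b = list(c("N1", "N"), c("Ami", "CAT"), c("C1", "C")),
    c = list(c("Ami", "CAT"), c("C1", "C")))
  orgs <- assign_organizations(arch)
  cov <- coverage_stats(orgs, class_menu(6, 5, 4))
  expect_equal(cov$canonical_n, 2)
  expect_equal(cov$canonical_fraction, 2 / 3)
  expect_equal(cov$possible_combinations, 120)
  cov2 <- coverage_stats(orgs, n_total = 10)
  expect_equal(cov2$canonical_fraction, 0.2)
})

test_that("prevalence of the top organizations matches the published counts", {
  expect_equal(org_prevalence(c(47, 38, 31, 26), 224), 142 / 224)
  expect_gte(org_prevalence(c(47, 38, 31, 26), 224), 0.60)
  expect_equal(org_prevalence(c(5, 1, 1), 10, k = 1), 0.5)
})

test_that("domain swaps are detected symmetrically between near-identical architectures", {
  arch <- mk_arch(
    w = list(c("N2", "N"), c("AmiA", "CAT"), c("C2", "C")),
    x = list(c("N2", "N"), c("AmiB", "CAT"), c("C2", "C")),
    y = list(c("N3", "N"), c("AmiB", "CAT"), c("C1", "C")))
  sw <- detect_domain_swaps(arch)
  expect_equal(nrow(sw), 1)
  expect_setequal(c(sw$protein1, sw$protein2), c("w", "x"))
  expect_equal(sw$swapped_slots, "2")
  expect_equal(sw$swapped_classes, "CAT")
  # identical architectures give no report; <2 shared slots give none
  arch2 <- mk_arch(
    w = list(c("N2", "N"), c("AmiA", "CAT"), c("C2", "C")),
    x = list(c("N2", "N"), c("AmiA", "CAT"), c("C2", "C")))
  expect_equal(nrow(detect_domain_swaps(arch2)), 0)
})

test_that("match profile traces identity along the alignment", {
  s <- scoring_model()
  set.seed(3)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  a <- rand_seq(120, aa20)
  mp <- match_profile(a, a, s, window = 30)
  expect_equal(nrow(mp), 120 - 30 + 1)
  expect_true(all(mp$identity == 100))
  expect_error(match_profile("MKVL", a, s, window = 30), "shorter")
  expect_error(match_profile(a, a, s, window = 3), "window")
  # unrelated sequences: trace stays far below related levels; the
  # global alignment enriches matches above the 5% random baseline
  b <- rand_seq(120, aa20)
  mp2 <- match_profile(a, b, s, window = 30)
  expect_lt(mean(mp2$identity), 35)
  expect_gt(mean(mp2$identity), 0)
})

test_that("match profile dips over a swapped central domain", {
  # two proteins sharing N and C ancestors with unrelated centers
  set.seed(9)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_anc <- rand_seq(100, aa20); c_anc <- rand_seq(100, aa20)
  mid1 <- rand_seq(100, aa20); mid2 <- rand_seq(100, aa20)
  p1 <- paste0(n_anc, mid1, c_anc)
  p2 <- paste0(n_anc, mid2, c_anc)
  mp <- match_profile(p1, p2, scoring_model(), window = 30)
  # flanks near 100%, the central third far lower
  expect_gt(mean(mp$identity[1:50]), 80)
  expect_lt(min(mp$identity[120:180]), 40)
  expect_gt(mean(mp$identity[nrow(mp) - (0:49)]), 80)
})

test_that("internal-start truncation arithmetic is exact", {
  expect_equal(truncation_content(384, 144)$product_length, 241)
  expect_equal(truncation_content(439, 147)$product_length, 293)
  expect_equal(truncation_content(500, 1)$product_length, 500)
  expect_error(truncation_content(384, 400), "out of range")
  arch <- data.frame(family = c("N1", "Ami", "C1"),
                     start = c(5, 150, 350), end = c(120, 320, 430))
  tc <- truncation_content(439, 200, arch)
  expect_equal(tc$lost, "N1")       # ends before the internal start
  expect_equal(tc$truncated, "Ami") # spans it
  expect_equal(tc$retained, "C1")
  tc1 <- truncation_content(439, 1, arch)
  expect_equal(tc1$retained, c("N1", "Ami", "C1"))
})
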