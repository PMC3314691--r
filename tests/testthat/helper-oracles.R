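# Independent reference implementations used as oracles. These are kept
# deliberately separate from the package code paths: plain-R dynamic
# programming for alignment scores, pracma NNLS over an explicit circular
# split design matrix for network weights.

AA4 <- c("A", "C", "D", "E")

rand_seq <- function(n, alphabet = AA4) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Plain-R affine-gap (Gotoh) optimal LOCAL alignment score.
oracle_local_score <- function(a, b, S, go, ge) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e15
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 1:m) for (j in 1:n) {
    h <- max(0, M[i, j], X[i, j], Y[i, j])
    M[i + 1, j + 1] <- h + S[av[i], bv[j]]
    X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Y[i + 1, j] - ge)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# Plain-R affine-gap optimal GLOBAL alignment score.
oracle_global_score <- function(a, b, S, go, ge) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e15
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  M[1, 1] <- 0
  for (i in 1:m) X[i + 1, 1] <- -go - i * ge
  for (j in 1:n) Y[1, j + 1] <- -go - j * ge
  for (i in 1:m) for (j in 1:n) {
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + S[av[i], bv[j]]
    X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Y[i + 1, j] - ge)
  }
  max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
}

# Exhaustive enumeration of all gapped alignments for very short pairs
# (validates the R DP oracle itself on a handful of cases).
oracle_enum_global <- function(a, b, S, go, ge) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, S[av[i], bv[j]] + rec(i + 1, j + 1, 0L))
    if (i <= length(av)) {
      pen <- if (state == 1L) ge else go + ge
      best <- max(best, -pen + rec(i + 1, j, 1L))
    }
    if (j <= length(bv)) {
      pen <- if (state == 2L) ge else go + ge
      best <- max(best, -pen + rec(i, j + 1, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# Random unrooted binary tree with positive branch lengths plus its
# path-length (additive) metric.
random_additive_metric <- function(n) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.2, 2))
  tr <- ape::unroot(tr)
  list(tree = tr, D = stats::cophenetic(tr))
}

# All splits compatible with a circular ordering: contiguous arcs not
# containing the first taxon of the ordering.
circular_splits <- function(ord) {
  n <- length(ord)
  out <- list()
  for (i in 2:n) for (j in i:n) out[[length(out) + 1L]] <- ord[i:j]
  out
}

# Brute-force nonnegative least-squares fit of split weights for a given
# circular ordering; returns weights, the split list and the residual.
nnls_circular_oracle <- function(D, ord) {
  splits <- circular_splits(ord)
  labs <- rownames(D)
  pairs <- utils::combn(labs, 2)
  A <- matrix(0, ncol(pairs), length(splits))
  for (k in seq_along(splits)) {
    inside <- pairs[1, ] %in% splits[[k]]
    inside2 <- pairs[2, ] %in% splits[[k]]
    A[, k] <- as.numeric(xor(inside, inside2))
  }
  d <- apply(pairs, 2, function(p) D[p[1], p[2]])
  fit <- pracma::lsqnonneg(A, d)
  list(splits = splits, weights = fit$x,
       residual = sum((A %*% fit$x - d)^2))
}

# Small planted proteome: single-domain proteins drawn from k ancestor
# families, mutated at the given divergence.
planted_single_domain_proteome <- function(n_fam = 3, per_fam = 3,
                                           len = 120, divergence = 0.2,
                                           seed = 1) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  anc <- replicate(n_fam, paste(sample(aa, len, TRUE), collapse = ""))
  prot <- character(0); fam <- character(0)
  for (f in seq_len(n_fam)) for (r in seq_len(per_fam)) {
    chars <- strsplit(anc[f], "")[[1]]
    hit <- stats::runif(len) < divergence
    chars[hit] <- vapply(chars[hit], function(ch)
      sample(setdiff(aa, ch), 1), "")
    lead <- paste(sample(aa, sample(0:10, 1), TRUE), collapse = "")
    tail <- paste(sample(aa, sample(0:10, 1), TRUE), collapse = "")
    prot <- c(prot, paste0(lead, paste(chars, collapse = ""), tail))
    fam <- c(fam, paste0("fam", f))
  }
  names(prot) <- sprintf("sp%02d", seq_along(prot))
  list(proteins = prot, family = setNames(fam, names(prot)))
}
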