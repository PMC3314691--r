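#' Presence/absence matrix of domain family types
#'
#' Binary proteins x family-types matrix: entry 1 when the family occurs
#' at least once in the protein's architecture (duplications still count
#' once).
#'
#' @param architectures an [build_architectures()] result.
#' @param family_types optional column universe (default: observed
#'   families, sorted).
#' @return integer 0/1 matrix with protein rownames.
#' @export
presence_absence <- function(architectures, family_types = NULL) {
  prots <- attr(architectures, "proteins") %||%
    sort_c(unique(architectures$protein))
  fams <- family_types %||% sort_c(unique(architectures$family))
  M <- matrix(0L, length(prots), length(fams),
              dimnames = list(prots, fams))
  if (nrow(architectures))
    M[cbind(architectures$protein, architectures$family)] <- 1L
  M
}

#' Distances between binary presence/absence rows
#'
#' `hamming`: fraction of mismatching columns. `jaccard`: 1 minus
#' intersection over union of the positive columns (0 when both rows are
#' empty).
#'
#' @param M binary matrix with rownames.
#' @param metric `"hamming"` (default) or `"jaccard"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
binary_distance <- function(M, metric = c("hamming", "jaccard")) {
  metric <- match.arg(metric)
  if (nrow(M) < 2L) stop("need at least two rows")
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- M[i, ] > 0; b <- M[j, ] > 0
      d <- if (metric == "hamming") mean(a != b) else {
        u <- sum(a | b)
        if (u == 0) 0 else 1 - sum(a & b) / u
      }
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix; negative branch
#' length estimates are clamped to zero. For an additive (tree) metric
#' the output realizes the metric exactly.
#'
#' @param D symmetric distance matrix (or `dist`) with labels; at least
#'   3 taxa.
#' @return an `ape` `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Internal bipartitions of an unrooted tree
#'
#' Non-trivial splits (both sides >= 2 tips), canonically keyed by the
#' side not containing the alphabetically smallest tip.
#'
#' @param phy a `phylo` tree.
#' @return named list of character vectors (tip sets); names are the
#'   canonical keys.
#' @export
tree_bipartitions <- function(phy) {
  phy <- ape::unroot(phy)
  labs <- phy$tip.label
  anchor <- sort_c(labs)[1L]
  pp <- ape::prop.part(phy)
  out <- list()
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    if (length(side) < 2L || length(side) > length(labs) - 2L) next
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L) next
    key <- paste(sort_c(side), collapse = ",")
    out[[key]] <- sort_c(side)
  }
  out
}

#' Robinson-Foulds distance
#'
#' Count of internal bipartitions present in exactly one of the two
#' trees; symmetric, 0 for identical topologies, at most `2(n-3)`.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return integer distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  b1 <- names(tree_bipartitions(t1))
  b2 <- names(tree_bipartitions(t2))
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

msa_from_codes <- function(codes, labels) {
  aln <- apply(codes, 1L, decode_aln)
  structure(list(aln = setNames(aln, labels), codes = codes,
                 ncol = ncol(codes)), class = "msa")
}

codes_to_profile <- function(codes) {
  # 22 x L frequency matrix: rows 1..21 residues, 22 gap
  L <- ncol(codes); n <- nrow(codes)
  P <- matrix(0, 22, L)
  for (j in seq_len(L)) {
    cj <- codes[, j]
    tab <- tabulate(ifelse(cj == 0L, 22L, cj), nbins = 22L)
    P[, j] <- tab / n
  }
  P
}

merge_msas <- function(A, B, s) {
  r <- profile_align_cpp(codes_to_profile(A), codes_to_profile(B),
                         s$matrix, s$gap_open, s$gap_extend)
  L <- length(r$pa)
  out <- matrix(0L, nrow(A) + nrow(B), L)
  for (k in seq_len(L)) {
    out[seq_len(nrow(A)), k] <- if (r$pa[k] > 0L) A[, r$pa[k]] else 0L
    out[nrow(A) + seq_len(nrow(B)), k] <-
      if (r$pb[k] > 0L) B[, r$pb[k]] else 0L
  }
  out
}

#' Progressive multiple sequence alignment
#'
#' Minimal ClustalW-style progressive aligner: pairwise global-alignment
#' identities give distances `1 - identity/100`, a neighbor-joining guide
#' tree orders the merges, and profiles are aligned with mean-of-pairs
#' column scores (existing gaps score `-gap_extend` against residues, 0
#' against gaps; new gaps pay the affine penalty). De-gapping any row
#' reproduces the input sequence.
#'
#' @param seqs named character vector (>= 1).
#' @param s a [scoring_model()].
#' @return object of class `msa`: `aln` (named gapped strings), `codes`
#'   (integer matrix, 0 = gap), `ncol`.
#' @export
progressive_msa <- function(seqs, s = scoring_model()) {
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must be uniquely named")
  n <- length(seqs)
  codes1 <- lapply(seq_len(n), function(i) encode_seq(seqs[[i]], ids[i]))
  if (n == 1L)
    return(msa_from_codes(matrix(codes1[[1L]], 1L), ids))
  if (n == 2L) {
    r <- nw_align_cpp(codes1[[1L]], codes1[[2L]], s$matrix,
                      s$gap_open, s$gap_extend)
    codes <- rbind(ifelse(r$pa > 0L, codes1[[1L]][pmax(r$pa, 1L)], 0L),
                   ifelse(r$pb > 0L, codes1[[2L]][pmax(r$pb, 1L)], 0L))
    return(msa_from_codes(codes, ids))
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- 1 - global_identity(seqs[[i]], seqs[[j]], s) / 100
      D[i, j] <- d; D[j, i] <- d
    }
  }
  guide <- nj_tree(D)
  # midpoint rooting keeps tight groups together in the merge order;
  # rooting at an arbitrary leaf would make that leaf align last,
  # against the full (mostly unrelated) profile
  guide <- phangorn::midpoint(guide)
  if (!ape::is.rooted(guide))
    guide <- ape::root(guide, outgroup = ids[1L], resolve.root = TRUE)
  guide <- ape::multi2di(guide)
  # postorder merge of child alignments
  merge_node <- function(node) {
    if (node <= n) {
      i <- match(guide$tip.label[node], ids)
      return(list(codes = matrix(codes1[[i]], 1L),
                  labels = guide$tip.label[node]))
    }
    kids <- guide$edge[guide$edge[, 1L] == node, 2L]
    parts <- lapply(kids, merge_node)
    acc <- parts[[1L]]
    for (k in seq_along(parts)[-1L]) {
      codes <- merge_msas(acc$codes, parts[[k]]$codes, s)
      acc <- list(codes = codes, labels = c(acc$labels,
                                            parts[[k]]$labels))
    }
    acc
  }
  root <- setdiff(guide$edge[, 1L], guide$edge[, 2L])[1L]
  res <- merge_node(root)
  ord <- match(ids, res$labels)
  msa_from_codes(res$codes[ord, , drop = FALSE], ids)
}

default_tree_builder <- function(msa_codes, cols) {
  D <- msa_dist_cpp(msa_codes, cols)
  rownames(D) <- colnames(D) <- rownames(msa_codes)
  nj_tree(D)
}

#' Bootstrap support for the splits of an alignment's tree
#'
#' Builds the reference tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times (one RNG stream,
#' replicate-major order, so results are reproducible given the seed)
#' and reports, for each internal split of the reference tree, the
#' percentage of replicate trees containing it.
#'
#' @param msa an [progressive_msa()] result (or integer code matrix with
#'   rownames).
#' @param tree_builder function(codes, cols) -> `phylo`; default:
#'   neighbor joining on `1 - identity` distances with gaps excluded
#'   pairwise.
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @return list: `tree` (reference `phylo`), `supports` (data.frame
#'   `split`, `support`), `n_reps`.
#' @export
bootstrap_support <- function(msa, tree_builder = default_tree_builder,
                              n_reps = 100L, seed = 1L) {
  codes <- if (inherits(msa, "msa")) {
    m <- msa$codes; rownames(m) <- names(msa$aln); m
  } else msa
  L <- ncol(codes)
  if (L < 2L) stop("alignment must have at least 2 columns")
  ref <- tree_builder(codes, seq_len(L))
  ref_splits <- names(tree_bipartitions(ref))
  hits <- setNames(numeric(length(ref_splits)), ref_splits)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    bt <- tree_builder(codes, cols)
    bs <- names(tree_bipartitions(bt))
    hit <- ref_splits %in% bs
    hits[hit] <- hits[hit] + 1
  }
  supports <- data.frame(split = ref_splits,
                         support = 100 * unname(hits) / n_reps,
                         stringsAsFactors = FALSE)
  list(tree = ref, supports = supports, n_reps = n_reps)
}

split_key_on <- function(side, labs) {
  # canonical key of a split side relative to taxon set labs
  anchor <- sort_c(labs)[1L]
  if (anchor %in% side) side <- setdiff(labs, side)
  if (length(side) < 2L || length(side) > length(labs) - 2L)
    return(NA_character_)
  paste(sort_c(side), collapse = ",")
}

splits_incompatible <- function(s1, s2, labs) {
  a <- s1; b <- s2
  length(intersect(a, b)) > 0 &&
    length(setdiff(a, b)) > 0 &&
    length(setdiff(b, a)) > 0 &&
    length(setdiff(labs, union(a, b))) > 0
}

#' Scan domain classes for phylogenetic incongruence
#'
#' For each pair of domain classes with at least 4 shared proteins,
#' aligns the two classes' domain sequences over the shared proteins,
#' builds neighbor-joining trees with bootstrap supports, and reports
#' the Robinson-Foulds distance plus any pair of incompatible splits
#' both supported at or above `support_min` — the signature of a domain
#' swap between lineages. Candidate recombinants are the proteins whose
#' removal eliminates every supported conflict.
#'
#' @param class_seqs named list: class -> named character vector of that
#'   class's domain sequence per protein.
#' @param s a [scoring_model()].
#' @param n_reps bootstrap replicates (default 100).
#' @param support_min minimum bootstrap support (percent) for a split to
#'   count as a supported conflict (default 70).
#' @param min_split_size minimum number of taxa on the smaller side of a
#'   split for it to enter conflict testing (default 4, reduced
#'   automatically for small taxon sets). Independently mutated domain
#'   instances of one family occasionally share enough coincidental
#'   substitutions to support a 2-3 member clade; such shallow clades
#'   conflict between trees by chance, whereas a genuine domain swap
#'   relocates a protein relative to a whole family.
#' @param max_moved a supported conflict counts as a recombination
#'   signal only if it is explainable by relocating at most this many
#'   proteins (default 2): the smallest cell of the two splits'
#'   incompatibility table is the candidate recombinant set. Conflicts
#'   between arrangements of whole unrelated families (whose
#'   between-family distances are noise, not homology) have only large
#'   cells and are ignored.
#' @param seed RNG seed (one sub-seed per class pair).
#' @return data.frame of class `incongruence_report`: `class1`,
#'   `class2`, `n_shared`, `rf`, `n_conflicts`, `flagged`, `candidates`.
#'   Pairs with fewer than 4 shared proteins are skipped with a message.
#' @export
incongruence_scan <- function(class_seqs, s = scoring_model(),
                              n_reps = 100L, support_min = 70,
                              min_split_size = 4L, max_moved = 2L,
                              seed = 1L) {
  classes <- names(class_seqs)
  rows <- list()
  pair_idx <- 0L
  if (length(classes) >= 2L) {
    for (i in seq_len(length(classes) - 1L)) {
      for (j in (i + 1L):length(classes)) {
        pair_idx <- pair_idx + 1L
        a <- class_seqs[[i]]; b <- class_seqs[[j]]
        shared <- intersect(names(a), names(b))
        if (length(shared) < 4L) {
          message(sprintf("skipping %s vs %s: only %d shared proteins",
                          classes[i], classes[j], length(shared)))
          next
        }
        shared <- sort_c(shared)
        msa1 <- progressive_msa(a[shared], s)
        msa2 <- progressive_msa(b[shared], s)
        bs1 <- bootstrap_support(msa1, n_reps = n_reps,
                                 seed = seed + pair_idx)
        bs2 <- bootstrap_support(msa2, n_reps = n_reps,
                                 seed = seed + pair_idx + 1000L)
        rf <- rf_distance(bs1$tree, bs2$tree)
        msize <- max(2L, min(min_split_size, length(shared) %/% 4L))
        conf <- conflicting_supported_splits(bs1, bs2, shared,
                                             support_min, msize,
                                             max_moved)
        cands <- sort_c(unique(unlist(conf$moved)))
        rows[[length(rows) + 1L]] <- data.frame(
          class1 = classes[i], class2 = classes[j],
          n_shared = length(shared), rf = rf,
          n_conflicts = nrow(conf), flagged = nrow(conf) > 0L,
          candidates = paste(cands, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    class1 = character(0), class2 = character(0), n_shared = integer(0),
    rf = integer(0), n_conflicts = integer(0), flagged = logical(0),
    candidates = character(0), stringsAsFactors = FALSE)
  class(out) <- c("incongruence_report", "data.frame")
  out
}

conflicting_supported_splits <- function(bs1, bs2, labs, support_min,
                                         min_split_size = 2L,
                                         max_moved = 2L) {
  deep <- function(sp) {
    ns <- vapply(strsplit(sp$split, ",", fixed = TRUE), length, 1L)
    sp[pmin(ns, length(labs) - ns) >= min_split_size, , drop = FALSE]
  }
  sp1 <- deep(bs1$supports[bs1$supports$support >= support_min, ,
                           drop = FALSE])
  sp2 <- deep(bs2$supports[bs2$supports$support >= support_min, ,
                           drop = FALSE])
  rows <- list(); moved <- list()
  for (k1 in seq_len(nrow(sp1))) {
    side1 <- strsplit(sp1$split[k1], ",", fixed = TRUE)[[1L]]
    for (k2 in seq_len(nrow(sp2))) {
      side2 <- strsplit(sp2$split[k2], ",", fixed = TRUE)[[1L]]
      if (!splits_incompatible(side1, side2, labs)) next
      cells <- list(intersect(side1, side2), setdiff(side1, side2),
                    setdiff(side2, side1),
                    setdiff(labs, union(side1, side2)))
      sizes <- vapply(cells, length, 1L)
      small <- cells[sizes <= max_moved]
      # a single swap relocates a small set across otherwise-agreeing
      # groups: exactly one small cell (the recombinants). No small cell
      # means a whole-group rearrangement (between-family noise); two
      # small cells mean two independent within-family outliers. With
      # few taxa every cell is small and the distinction is unavailable.
      ok <- if (length(labs) > 8L) length(small) == 1L
            else length(small) >= 1L
      if (!ok) next
      rows[[length(rows) + 1L]] <- data.frame(
        split1 = sp1$split[k1], support1 = sp1$support[k1],
        split2 = sp2$split[k2], support2 = sp2$support[k2],
        stringsAsFactors = FALSE)
      moved[[length(moved) + 1L]] <- unlist(small)
    }
  }
  if (!length(rows))
    return(data.frame(split1 = character(0), support1 = numeric(0),
                      split2 = character(0), support2 = numeric(0),
                      moved = I(list()), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$moved <- moved
  out
}
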