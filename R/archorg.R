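#' Build per-protein domain architectures
#'
#' Orders each protein's classified domain instances by start coordinate
#' (ties broken by end, then family id) into its architecture. Proteins
#' with no instances get an empty architecture and are reported, not
#' dropped.
#'
#' @param instances data.frame `protein`, `family`, `class`, `start`,
#'   `end` (e.g. from [cluster_families()]).
#' @param proteins named character vector of all proteins (so domainless
#'   ones are retained).
#' @param p a [cluster_params()] (used to detect instances that should
#'   have been consolidated).
#' @return data.frame of class `architectures`: `protein`, `slot`,
#'   `family`, `class`, `start`, `end`; zero rows for empty
#'   architectures, but all protein ids are recorded in
#'   `attr(, "proteins")`.
#' @export
build_architectures <- function(instances, proteins,
                                p = cluster_params()) {
  out <- lapply(names(proteins), function(pr) {
    df <- instances[instances$protein == pr, , drop = FALSE]
    if (!nrow(df)) return(NULL)
    df <- df[order(df$start, df$end, df$family), , drop = FALSE]
    if (nrow(df) > 1L) {
      w <- df$end - df$start + 1L
      ov <- df$end[-nrow(df)] - df$start[-1L] + 1L
      shorter <- pmin(w[-nrow(df)], w[-1L])
      if (any(ov >= p$overlap_fraction * shorter))
        stop(sprintf("overlapping instances survived consolidation on %s",
                     pr))
    }
    df$slot <- seq_len(nrow(df))
    df
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(protein = character(0), slot = integer(0),
                      family = character(0), class = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  res <- res[, c("protein", "slot", "family", "class", "start", "end")]
  rownames(res) <- NULL
  attr(res, "proteins") <- names(proteins)
  class(res) <- c("architectures", "data.frame")
  res
}

arch_signature <- function(df) {
  if (!nrow(df)) return("")
  paste(paste0(df$class[order(df$slot)], ":", df$family[order(df$slot)]),
        collapse = "|")
}

org_label <- function(i) {
  if (i <= 26L) return(paste0("Org-", LETTERS[i]))
  paste0("Org-", LETTERS[(i - 27L) %/% 26L + 1L],
         LETTERS[(i - 27L) %% 26L + 1L])
}

#' Group architectures into organizations
#'
#' Proteins sharing an identical ordered (class, family) signature form
#' one organization. Labels are assigned deterministically: `Org-A` to
#' the largest group (ties broken by smallest member protein id), then
#' `Org-B`, ..., continuing `Org-AA`, `Org-AB`, ... beyond 26. Only
#' proteins with at least one domain are grouped.
#'
#' @param architectures an [build_architectures()] result.
#' @return data.frame of class `organizations`: `label`, `signature`,
#'   `size`, `members` (comma-separated protein ids).
#' @export
assign_organizations <- function(architectures) {
  prots <- unique(architectures$protein)
  if (!length(prots))
    return(structure(data.frame(label = character(0),
                                signature = character(0),
                                size = integer(0), members = character(0),
                                stringsAsFactors = FALSE),
                     class = c("organizations", "data.frame")))
  sigs <- vapply(prots, function(pr)
    arch_signature(architectures[architectures$protein == pr, ,
                                 drop = FALSE]), "")
  grp <- split(prots, sigs)
  df <- data.frame(signature = names(grp),
                   size = vapply(grp, length, 1L),
                   minprot = vapply(grp, function(x) min(x), ""),
                   members = vapply(grp, function(x)
                     paste(sort_c(x), collapse = ","), ""),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$size, df$minprot), , drop = FALSE]
  df$label <- vapply(seq_len(nrow(df)), org_label, "")
  rownames(df) <- NULL
  structure(df[, c("label", "signature", "size", "members")],
            class = c("organizations", "data.frame"))
}

#' Class menu and combinatorial space
#'
#' @param n_N,n_CAT,n_C numbers of distinct family types in the
#'   N-terminal, central-catalytic and C-terminal classes.
#' @return object of class `class_menu`.
#' @export
class_menu <- function(n_N, n_CAT, n_C) {
  stopifnot(n_N >= 0, n_CAT >= 0, n_C >= 0,
            n_N == round(n_N), n_CAT == round(n_CAT), n_C == round(n_C))
  structure(list(n_N = as.integer(n_N), n_CAT = as.integer(n_CAT),
                 n_C = as.integer(n_C)), class = "class_menu")
}

#' Number of possible one-of-each domain combinations
#'
#' With `n_N` N-terminal, `n_CAT` central and `n_C` C-terminal family
#' types, assuming one of each, there are `n_N * n_CAT * n_C` possible
#' three-domain organizations (120 for the 6/5/4 menu).
#'
#' @param menu a [class_menu()], or the first of three counts.
#' @param n_CAT,n_C remaining counts when `menu` is a number.
#' @return integer product.
#' @export
enumerate_combinations <- function(menu, n_CAT = NULL, n_C = NULL) {
  if (!inherits(menu, "class_menu")) menu <- class_menu(menu, n_CAT, n_C)
  menu$n_N * menu$n_CAT * menu$n_C
}

#' Organization coverage statistics
#'
#' Summarizes an organization table: how many organizations are observed,
#' how many proteins follow the canonical three-domain pattern (one `N`,
#' one `CAT`, one `C`, in that order), and per-organization counts; when
#' a menu is given, the size of the possible combinatorial space.
#'
#' @param organizations an [assign_organizations()] result.
#' @param menu optional [class_menu()].
#' @param n_total optional total number of proteins for the fractions
#'   (default: sum of organization sizes).
#' @return list: `n_organizations`, `n_proteins`, `canonical_n`,
#'   `canonical_fraction`, `org_counts` (named sizes),
#'   `possible_combinations` (or NA).
#' @export
coverage_stats <- function(organizations, menu = NULL, n_total = NULL) {
  sizes <- setNames(organizations$size, organizations$label)
  n_total <- n_total %||% sum(sizes)
  sigclasses <- lapply(strsplit(organizations$signature, "|", fixed = TRUE),
                       function(x) sub(":.*", "", x))
  canonical <- vapply(sigclasses, function(cl)
    identical(cl, c("N", "CAT", "C")), TRUE)
  canonical_n <- sum(organizations$size[canonical])
  list(n_organizations = nrow(organizations),
       n_proteins = sum(sizes),
       canonical_n = canonical_n,
       canonical_fraction = if (n_total > 0) canonical_n / n_total else NA,
       org_counts = sizes,
       possible_combinations = if (is.null(menu)) NA_integer_
                               else enumerate_combinations(menu))
}

#' Prevalence of the k most common organizations
#'
#' Fraction of all proteins that belong to the `k` largest organizations
#' (e.g. the four most prevalent organizations of a published membership
#' table).
#'
#' @param sizes organization membership counts (or an
#'   [assign_organizations()] result).
#' @param n_total total number of proteins.
#' @param k number of top organizations (default 4).
#' @return fraction in `[0, 1]`.
#' @export
org_prevalence <- function(sizes, n_total, k = 4L) {
  if (inherits(sizes, "organizations")) sizes <- sizes$size
  stopifnot(n_total >= 1, k >= 1)
  sum(sort(sizes, decreasing = TRUE)[seq_len(min(k, length(sizes)))]) /
    n_total
}

#' Detect domain swaps between architecture pairs
#'
#' Reports protein pairs whose architectures have equal slot counts,
#' agree (same family) in at least two slots, and differ in at least one
#' slot where both proteins carry a domain of the same class but a
#' different family — the signature of a domain swap. Symmetric and
#' irreflexive.
#'
#' @param architectures an [build_architectures()] result.
#' @return data.frame: `protein1`, `protein2`, `n_shared`,
#'   `swapped_slots` (comma-separated indices), `swapped_classes`.
#' @export
detect_domain_swaps <- function(architectures) {
  prots <- sort_c(unique(architectures$protein))
  archs <- lapply(prots, function(pr) {
    df <- architectures[architectures$protein == pr, , drop = FALSE]
    df[order(df$slot), , drop = FALSE]
  })
  names(archs) <- prots
  rows <- list()
  if (length(prots) >= 2L) {
    for (i in seq_len(length(prots) - 1L)) {
      for (j in (i + 1L):length(prots)) {
        a <- archs[[i]]; b <- archs[[j]]
        if (!nrow(a) || nrow(a) != nrow(b)) next
        same_fam <- a$family == b$family
        same_cls <- a$class == b$class
        swapped <- !same_fam & same_cls
        if (sum(same_fam) >= 2L && any(swapped)) {
          rows[[length(rows) + 1L]] <- data.frame(
            protein1 = prots[i], protein2 = prots[j],
            n_shared = sum(same_fam),
            swapped_slots = paste(which(swapped), collapse = ","),
            swapped_classes = paste(a$class[swapped], collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(protein1 = character(0), protein2 = character(0),
                      n_shared = integer(0), swapped_slots = character(0),
                      swapped_classes = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Sliding-window identity profile along a global alignment
#'
#' Globally aligns two proteins and reports percent identity in a sliding
#' window along the alignment columns (gap-containing pairs count as
#' non-identical). The high/low/high shape of such a trace between two
#' proteins sharing flanking domains but differing in the central one is
#' the classic partial-match pattern of a domain swap.
#'
#' @param a,b protein sequences.
#' @param s a [scoring_model()].
#' @param window window width in alignment columns (>= 5).
#' @return data.frame `position` (window start column), `identity`.
#' @export
match_profile <- function(a, b, s = scoring_model(), window = 30L) {
  if (window < 5L) stop("window must be >= 5")
  if (nchar(a) < window || nchar(b) < window)
    stop("sequences shorter than the window")
  al <- global_align(a, b, s)
  idc <- as.integer(al$acol == al$bcol & al$acol > 0L)
  n <- length(idc) - window + 1L
  csum <- cumsum(c(0L, idc))
  ident <- (csum[(window + 1L):(length(idc) + 1L)] - csum[1:n]) /
    window * 100
  data.frame(position = seq_len(n), identity = ident)
}

#' Truncation content of an internal translation start
#'
#' A second in-frame initiation codon inside a gene yields a truncated
#' product of `full_length - internal_start_codon + 1` residues (the
#' start codon's residue is included, matching the published 384/144 ->
#' 241 arithmetic). Each domain of the architecture is classified as
#' `lost` (ends before the internal start), `truncated` (spans it) or
#' `retained`.
#'
#' @param full_length full-length product size in residues.
#' @param internal_start_codon 1-based codon of the internal start.
#' @param architecture optional single-protein architecture (data.frame
#'   with `family`, `start`, `end`).
#' @return list: `product_length`, `retained`, `truncated`, `lost`
#'   (character vectors of family ids; empty if no architecture given).
#' @export
truncation_content <- function(full_length, internal_start_codon,
                               architecture = NULL) {
  stopifnot(full_length >= 1)
  if (internal_start_codon < 1 || internal_start_codon > full_length)
    stop("internal start codon out of range")
  res <- list(product_length = full_length - internal_start_codon + 1,
              retained = character(0), truncated = character(0),
              lost = character(0))
  if (!is.null(architecture) && nrow(architecture)) {
    lost <- architecture$end < internal_start_codon
    trunc <- architecture$start < internal_start_codon &
      architecture$end >= internal_start_codon
    res$lost <- architecture$family[lost]
    res$truncated <- architecture$family[trunc]
    res$retained <- architecture$family[!lost & !trunc]
  }
  res
}
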