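#' Parameters for domain-family clustering
#'
#' Dual threshold used to decide whether a pairwise segment match links
#' two regions into the same domain family: E-value strictly below
#' `evalue_max` (default `1e-5`) or percent identity strictly above
#' `identity_min` (default 20). Under the default `OR` rule either
#' criterion suffices — the two criteria describe two independent search
#' methods, a significance-scored local search and an identity-scored
#' global comparison; `AND` requires both.
#'
#' @param evalue_max exclusive E-value ceiling (E equal to it fails).
#' @param identity_min exclusive percent-identity floor (identity equal
#'   to it fails).
#' @param link_rule `"OR"` (default) or `"AND"`.
#' @param overlap_fraction per-protein merge threshold: two intervals on
#'   the same protein are merged when their overlap is at least this
#'   fraction of the shorter one.
#' @param min_seg_len minimum segment length (residues) for an interval
#'   to count as a domain candidate.
#' @param boundary_tol segment endpoints within this many residues are
#'   treated as the same domain boundary when decomposing multi-domain
#'   matches.
#' @param boundary_min_support minimum number of independent segment
#'   endpoints required to accept an internal boundary.
#' @param boundary_min_frac minimum fraction of the local evidence
#'   (endpoints at the boundary plus segments spanning it) that must be
#'   endpoints for the boundary to be accepted; guards against a few
#'   stray alignment ends cutting a well-covered domain.
#' @param identity_evalue_cap an identity-route link must additionally
#'   have an alignment E-value below this lenient cap (default 1):
#'   percent identity alone links diverged homologs whose significance
#'   is marginal, but never regions with no alignment signal at all
#'   (unrelated domain-sized sequences occasionally exceed 20% global
#'   identity by chance).
#' @param identity_min_links identity-route links merge two groups only
#'   when at least this many independent such links connect the same
#'   two E-value-linked groups (default 2). A genuinely diverged family
#'   member aligns above threshold with many family members; a chance
#'   20%-identity pair produces a single link, which under single
#'   linkage would otherwise fuse two whole families.
#' @return object of class `cluster_params`.
#' @export
cluster_params <- function(evalue_max = 1e-5, identity_min = 20,
                           link_rule = c("OR", "AND"),
                           overlap_fraction = 0.5, min_seg_len = 30L,
                           boundary_tol = 10L, boundary_min_support = 2L,
                           boundary_min_frac = 0.25,
                           identity_evalue_cap = 1,
                           identity_min_links = 2L) {
  link_rule <- match.arg(link_rule)
  stopifnot(evalue_max > 0, identity_min >= 0, identity_min < 100,
            overlap_fraction > 0, overlap_fraction <= 1,
            min_seg_len >= 1, boundary_tol >= 0,
            boundary_min_support >= 1,
            boundary_min_frac >= 0, boundary_min_frac <= 1,
            identity_evalue_cap > 0, identity_min_links >= 1)
  structure(list(evalue_max = evalue_max, identity_min = identity_min,
                 link_rule = link_rule,
                 overlap_fraction = overlap_fraction,
                 min_seg_len = as.integer(min_seg_len),
                 boundary_tol = as.integer(boundary_tol),
                 boundary_min_support = as.integer(boundary_min_support),
                 boundary_min_frac = boundary_min_frac,
                 identity_evalue_cap = identity_evalue_cap,
                 identity_min_links = as.integer(identity_min_links)),
            class = "cluster_params")
}

#' Does a segment match link its two regions?
#'
#' Applies the dual threshold of [cluster_params()] to a match: `OR`
#' links when the match passes the E-value criterion or the identity
#' criterion; `AND` requires both. Inequalities are strict.
#'
#' @param match one row of an [all_vs_all()] table (or any list with
#'   `evalue` and `gident`), or vectors via a multi-row data.frame.
#' @param p a [cluster_params()].
#' @return logical.
#' @export
link_predicate <- function(match, p = cluster_params()) {
  pe <- if (!is.null(match$passes_evalue)) match$passes_evalue
        else match$evalue < p$evalue_max
  pi <- if (!is.null(match$passes_identity)) match$passes_identity
        else match$gident > p$identity_min
  if (p$link_rule == "OR") pe | pi else pe & pi
}

#' Merge overlapping intervals on the same protein
#'
#' Two intervals on one protein are merged (to their union) when their
#' overlap is at least `overlap_fraction` of the shorter interval;
#' processing is in fixed (start, end) order and repeated to a fixed
#' point, so the result is independent of input order. Remaining
#' intervals pairwise overlap less than the threshold.
#'
#' @param intervals data.frame with columns `protein`, `start`, `end`.
#' @param p a [cluster_params()].
#' @return consolidated data.frame `protein`, `start`, `end`.
#' @export
consolidate_segments <- function(intervals, p = cluster_params()) {
  if (!nrow(intervals)) return(intervals[, c("protein", "start", "end")])
  out <- lapply(split(intervals, intervals$protein), function(df) {
    iv <- df[order(df$start, df$end), c("start", "end"), drop = FALSE]
    repeat {
      merged <- FALSE
      k <- 1L
      while (k < nrow(iv)) {
        ov <- min(iv$end[k], iv$end[k + 1L]) -
          max(iv$start[k], iv$start[k + 1L]) + 1L
        shorter <- min(iv$end[k] - iv$start[k],
                       iv$end[k + 1L] - iv$start[k + 1L]) + 1L
        if (ov >= p$overlap_fraction * shorter) {
          iv$start[k] <- min(iv$start[k], iv$start[k + 1L])
          iv$end[k] <- max(iv$end[k], iv$end[k + 1L])
          iv <- iv[-(k + 1L), , drop = FALSE]
          merged <- TRUE
        } else k <- k + 1L
      }
      if (!merged) break
      iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    }
    data.frame(protein = df$protein[1L], start = iv$start, end = iv$end,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order_c(res$protein, res$start, res$end), , drop = FALSE]
}

# Cluster segment endpoints on one protein into boundary positions by
# greedy peak extraction: repeatedly take the +-tol window holding the
# most endpoints (ties: leftmost), report its median, remove its points.
# Unlike gap-based 1D clustering this cannot chain two nearby true
# boundaries into one cluster via a few stray points between them.
boundary_positions <- function(points, tol) {
  if (!length(points)) return(data.frame(pos = integer(0),
                                         support = integer(0)))
  pts <- sort(points)
  pos <- integer(0); support <- integer(0)
  while (length(pts)) {
    u <- unique(pts)
    cnt <- vapply(u, function(x) sum(pts >= x - tol & pts <= x + tol), 0L)
    best <- u[which.max(cnt)]
    sel <- pts >= best - tol & pts <= best + tol
    pos <- c(pos, as.integer(round(median(pts[sel]))))
    support <- c(support, sum(sel))
    pts <- pts[!sel]
  }
  ord <- order(pos)
  data.frame(pos = pos[ord], support = support[ord])
}

# Decompose matched segments at well-supported internal boundaries.
# A multi-domain match (e.g. between two proteins sharing their whole
# architecture) spans several domains; partial matches from proteins
# sharing only one domain deposit segment endpoints at the true domain
# edges. Any segment extending across such a supported boundary is cut
# there, so the surviving pieces are single-domain candidates.
split_segments <- function(segs, p, extra_points = NULL) {
  out <- lapply(split(segs, segs$protein), function(df) {
    pts <- c(df$start, df$end + 1L)  # cut positions (interval starts)
    if (!is.null(extra_points))
      pts <- c(pts, extra_points[[df$protein[1L]]])
    bp <- boundary_positions(pts, p$boundary_tol)
    # spanning segments vote against a boundary: a real domain edge is
    # an endpoint for most local alignments touching it
    spanning <- vapply(bp$pos, function(pos)
      sum(df$start + p$boundary_tol < pos &
            df$end + 1L - p$boundary_tol > pos), 0L)
    cuts <- bp$pos[bp$support >= p$boundary_min_support &
                     bp$support >= p$boundary_min_frac *
                       (bp$support + spanning)]
    pieces <- list()
    for (r in seq_len(nrow(df))) {
      s <- df$start[r]; e <- df$end[r]
      inner <- cuts[cuts > s + p$boundary_tol & cuts <= e - p$boundary_tol]
      bounds <- c(s, sort(unique(inner)), e + 1L)
      for (k in seq_len(length(bounds) - 1L)) {
        ps <- bounds[k]; pe <- bounds[k + 1L] - 1L
        if (pe - ps + 1L >= p$min_seg_len)
          pieces[[length(pieces) + 1L]] <- c(ps, pe)
      }
    }
    if (!length(pieces))
      return(data.frame(protein = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE))
    m <- do.call(rbind, pieces)
    data.frame(protein = df$protein[1L], start = m[, 1L], end = m[, 2L],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Map first-pass interval boundaries through every linked alignment onto
# the partner protein. Returns a list: protein -> integer vector of
# projected cut positions.
projected_boundaries <- function(linked, nodes, p) {
  out <- list()
  add <- function(prot, pos) out[[prot]] <<- c(out[[prot]], pos)
  for (r in seq_len(nrow(linked))) {
    mt <- linked[r, ]
    qchars <- strsplit(mt$qaln, "")[[1]]
    schars <- strsplit(mt$saln, "")[[1]]
    qpos <- ifelse(qchars != "-", cumsum(qchars != "-") + mt$qstart - 1L, 0L)
    spos <- ifelse(schars != "-", cumsum(schars != "-") + mt$sstart - 1L, 0L)
    project <- function(cuts_from, from_pos, to_pos, from_lo, from_hi,
                        to_prot) {
      cuts <- cuts_from[cuts_from > from_lo + p$boundary_tol &
                          cuts_from <= from_hi - p$boundary_tol]
      for (x in cuts) {
        k <- which(from_pos >= x & to_pos > 0L)
        if (length(k)) add(to_prot, to_pos[min(k)])
      }
    }
    qn <- nodes[nodes$protein == mt$qid, , drop = FALSE]
    sn <- nodes[nodes$protein == mt$sid, , drop = FALSE]
    if (nrow(qn))
      project(sort(unique(c(qn$start, qn$end + 1L))), qpos, spos,
              mt$qstart, mt$qend, mt$sid)
    if (nrow(sn))
      project(sort(unique(c(sn$start, sn$end + 1L))), spos, qpos,
              mt$sstart, mt$send, mt$qid)
  }
  out
}

# score of an aligned column pair under the model, vectorized
sub_alignment_score <- function(acol, bcol, s) {
  both <- acol > 0L & bcol > 0L
  sc <- sum(s$matrix[cbind(acol[both], bcol[both])])
  sc - (count_gap_opens(acol) + count_gap_opens(bcol)) * s$gap_open -
    (sum(acol == 0L) + sum(bcol == 0L)) * s$gap_extend
}

#' Cluster matched segments into domain families
#'
#' Builds domain families by single-linkage clustering: nodes are
#' consolidated per-protein intervals, edges are pairwise matches mapped
#' onto those intervals, and families are the connected components.
#'
#' Before consolidation, multi-domain matches are decomposed at
#' well-supported boundaries (see `boundary_min_support` in
#' [cluster_params()]): full-length matches between proteins sharing
#' their whole architecture are cut at the domain edges attested by
#' partial matches, which is what makes domain-level resolution possible
#' in a mosaic protein set. Each linked match then contributes edges
#' between the interval pairs its alignment actually connects; an edge is
#' kept when its own sub-alignment passes the dual threshold.
#'
#' @param matches match table from [all_vs_all()].
#' @param proteins named character vector of sequences (for lengths and
#'   class assignment).
#' @param p a [cluster_params()].
#' @param s the [scoring_model()] used for the matches (for sub-alignment
#'   scores).
#' @param annotation optional named character vector mapping family ids
#'   to classes (`N`, `CAT`, `C`), applied after positional assignment.
#' @return list of class `domain_families`: `instances` (data.frame
#'   `protein`, `family`, `class`, `start`, `end`), `families`
#'   (data.frame `family`, `class`, `n_instances`, `representative`), and
#'   `n_nodes`/`n_edges` diagnostics.
#' @export
cluster_families <- function(matches, proteins, p = cluster_params(),
                             s = scoring_model(), annotation = NULL) {
  linked <- matches[link_predicate(matches, p), , drop = FALSE]
  empty <- data.frame(protein = character(0), family = character(0),
                      class = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (!nrow(linked))
    return(structure(list(instances = empty,
                          families = data.frame(family = character(0),
                                                class = character(0),
                                                n_instances = integer(0),
                                                representative = character(0),
                                                stringsAsFactors = FALSE),
                          n_nodes = 0L, n_edges = 0L),
                     class = "domain_families"))
  # Domain extents are delimited by E-value-significant alignments only:
  # identity-only links are real homology signals but their alignment
  # endpoints are too noisy to define boundaries. Proteins whose every
  # match is identity-only still contribute their segments, so they get
  # nodes to attach to.
  seg_side <- function(df) rbind(
    data.frame(protein = df$qid, start = df$qstart, end = df$qend,
               stringsAsFactors = FALSE),
    data.frame(protein = df$sid, start = df$sstart, end = df$send,
               stringsAsFactors = FALSE))
  strong <- linked[linked$evalue < p$evalue_max, , drop = FALSE]
  segs <- seg_side(strong)
  weak <- linked[linked$evalue >= p$evalue_max, , drop = FALSE]
  if (nrow(weak)) {
    wsegs <- seg_side(weak)
    wsegs <- wsegs[!(wsegs$protein %in% segs$protein), , drop = FALSE]
    segs <- rbind(segs, wsegs)
  }
  pieces <- split_segments(segs, p)
  nodes <- consolidate_segments(pieces, p)
  # Second pass: project the first-pass interval boundaries of every
  # match partner through the alignment. A protein whose own matches all
  # span a domain boundary (e.g. because a swap makes its partners share
  # two flanking domains) still inherits the boundary consensus of the
  # rest of the set.
  extra <- projected_boundaries(linked, nodes, p)
  pieces <- split_segments(segs, p, extra_points = extra)
  nodes <- consolidate_segments(pieces, p)
  nodes$node <- paste0(nodes$protein, ":", nodes$start, "-", nodes$end)
  # alignment columns: rebuild position maps from the gapped strings
  edge_rows <- list()
  for (r in seq_len(nrow(linked))) {
    mt <- linked[r, ]
    qchars <- strsplit(mt$qaln, "")[[1]]
    schars <- strsplit(mt$saln, "")[[1]]
    qpos <- ifelse(qchars != "-", cumsum(qchars != "-") + mt$qstart - 1L, 0L)
    spos <- ifelse(schars != "-", cumsum(schars != "-") + mt$sstart - 1L, 0L)
    qn <- nodes[nodes$protein == mt$qid, , drop = FALSE]
    sn <- nodes[nodes$protein == mt$sid, , drop = FALSE]
    if (!nrow(qn) || !nrow(sn)) next
    for (qi in seq_len(nrow(qn))) {
      ovq <- min(qn$end[qi], mt$qend) - max(qn$start[qi], mt$qstart) + 1L
      if (ovq < 0.5 * min(qn$end[qi] - qn$start[qi] + 1L,
                          mt$qend - mt$qstart + 1L)) next
      # columns with a residue pair inside this interval on the q side
      paircols <- which(qpos >= qn$start[qi] & qpos <= qn$end[qi] &
                          qpos > 0L & spos > 0L)
      if (length(paircols) < 0.8 * p$min_seg_len) next
      # target interval = the one capturing most of those aligned pairs
      # (spans would be misled by long gap blocks inside the alignment)
      cnt <- vapply(seq_len(nrow(sn)), function(k)
        sum(spos[paircols] >= sn$start[k] & spos[paircols] <= sn$end[k]),
        0L)
      if (max(cnt) < 0.5 * length(paircols) ||
          max(cnt) < 0.8 * p$min_seg_len) next
      si <- which.max(cnt)
      anchored <- paircols[spos[paircols] >= sn$start[si] &
                             spos[paircols] <= sn$end[si]]
      cols <- seq(min(anchored), max(anchored))
      # sub-alignment statistics over these columns
      qc <- qchars[cols]; sc <- schars[cols]
      acodes <- integer(length(qc))
      acodes[qc != "-"] <- aa_code_map[utf8ToInt(
        paste(qc[qc != "-"], collapse = "")) + 1L]
      bcodes <- integer(length(sc))
      bcodes[sc != "-"] <- aa_code_map[utf8ToInt(
        paste(sc[sc != "-"], collapse = "")) + 1L]
      score <- sub_alignment_score(acodes, bcodes, s)
      ev <- evalue(max(score, 0), nchar(proteins[[mt$qid]]),
                   nchar(proteins[[mt$sid]]), s)
      # identity criterion for the edge: ClustalW-style global identity
      # of the two candidate domain intervals themselves, backed by at
      # least a marginally significant alignment
      gid <- global_identity(
        substr(proteins[[mt$qid]], qn$start[qi], qn$end[qi]),
        substr(proteins[[mt$sid]], sn$start[si], sn$end[si]), s)
      pass_ev <- ev < p$evalue_max
      pass_id <- gid > p$identity_min && ev < p$identity_evalue_cap
      linked_edge <- if (p$link_rule == "OR") pass_ev || pass_id
                     else pass_ev && pass_id
      if (!linked_edge) next
      edge_rows[[length(edge_rows) + 1L]] <-
        data.frame(from = qn$node[qi], to = sn$node[si],
                   by_evalue = pass_ev, stringsAsFactors = FALSE)
    }
  }
  edf <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(from = character(0), to = character(0),
               by_evalue = logical(0), stringsAsFactors = FALSE)
  verts <- data.frame(name = nodes$node, stringsAsFactors = FALSE)
  # identity-only links merge two E-linked groups only when corroborated
  # by identity_min_links independent links between the same groups
  g0 <- igraph::graph_from_data_frame(
    edf[edf$by_evalue, c("from", "to"), drop = FALSE],
    directed = FALSE, vertices = verts)
  comp0 <- igraph::components(g0)$membership
  id_edges <- edf[!edf$by_evalue, , drop = FALSE]
  if (nrow(id_edges)) {
    c1 <- comp0[id_edges$from]; c2 <- comp0[id_edges$to]
    key <- paste(pmin(c1, c2), pmax(c1, c2))
    tally <- table(key)
    keep <- c1 == c2 | tally[key] >= p$identity_min_links
    id_edges <- id_edges[keep, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    rbind(edf[edf$by_evalue, c("from", "to"), drop = FALSE],
          id_edges[, c("from", "to"), drop = FALSE]),
    directed = FALSE, vertices = verts)
  comp <- igraph::components(g)
  nodes$component <- comp$membership[nodes$node]
  # deterministic family ids: size desc, then smallest member protein id,
  # then smallest start
  key <- do.call(rbind, lapply(split(nodes, nodes$component), function(df)
    data.frame(component = df$component[1L],
               size = nrow(df),
               minprot = min(df$protein),
               minstart = min(df$start), stringsAsFactors = FALSE)))
  key <- key[order(-key$size, key$minprot, key$minstart), , drop = FALSE]
  key$family <- sprintf("F%03d", seq_len(nrow(key)))
  nodes$family <- key$family[match(nodes$component, key$component)]
  inst <- nodes[, c("protein", "family", "start", "end")]
  inst <- inst[order_c(inst$protein, inst$start), , drop = FALSE]
  rownames(inst) <- NULL
  # Overlapping or abutting instances of one family are fragments of a
  # single domain and are fused (a residual false-split leaves two
  # same-family pieces side by side). A genuine tandem array of one
  # family is thereby reported as a single instance — its copies cannot
  # be told apart by pairwise homology anyway.
  inst <- do.call(rbind, lapply(split(inst, inst$protein), function(df) {
    df <- df[order(df$start, df$end), , drop = FALSE]
    k <- 1L
    while (k < nrow(df)) {
      nxt <- which(df$family[-seq_len(k)] == df$family[k] &
                     df$start[-seq_len(k)] <= df$end[k] +
                       p$boundary_tol + 1L) + k
      if (length(nxt)) {
        df$end[k] <- max(df$end[c(k, nxt)])
        df <- df[-nxt, , drop = FALSE]
      } else k <- k + 1L
    }
    df
  }))
  inst <- inst[order_c(inst$protein, inst$start), , drop = FALSE]
  rownames(inst) <- NULL
  # Fragment families — rare (<= 3 instances) and short (median width
  # under twice the minimum segment length) — are alignment-edge
  # leftovers straddling linkers, not domains; a real family is either
  # recurrent or domain-sized.
  w <- inst$end - inst$start + 1L
  med_w <- tapply(w, inst$family, median)
  n_inst <- table(inst$family)
  frag <- names(med_w)[med_w < 2 * p$min_seg_len &
                         n_inst[names(med_w)] <= 3L]
  inst <- inst[!(inst$family %in% frag), , drop = FALSE]
  cls <- assign_classes(inst, proteins, annotation)
  inst$class <- cls[inst$family]
  fam <- do.call(rbind, lapply(split(inst, inst$family), function(df) {
    w <- df$end - df$start + 1L
    rep_i <- order(-w, df$protein)[1L]
    data.frame(family = df$family[1L], class = df$class[1L],
               n_instances = nrow(df),
               representative = sprintf("%s:%d-%d", df$protein[rep_i],
                                        df$start[rep_i], df$end[rep_i]),
               stringsAsFactors = FALSE)
  }))
  fam <- fam[order_c(fam$family), , drop = FALSE]
  rownames(fam) <- NULL
  structure(list(instances = inst[, c("protein", "family", "class",
                                      "start", "end")],
                 families = fam, n_nodes = nrow(nodes),
                 n_edges = length(edge_rows)),
            class = "domain_families")
}

#' Positional class of one domain family
#'
#' Majority vote over the family's member instances: a member whose
#' normalized midpoint (interval midpoint / protein length) is below 0.35
#' votes `N`, above 0.65 votes `C`, otherwise `CAT`. An annotation entry
#' for the family overrides the vote; ties vote `UNASSIGNED`, as do
#' families with fewer than 3 members whose votes disagree.
#'
#' @param family_instances data.frame of the family's instances
#'   (`protein`, `start`, `end`).
#' @param proteins named character vector of sequences.
#' @param family family id (used for annotation lookup).
#' @param annotation optional named character vector family -> class.
#' @return one of `"N"`, `"CAT"`, `"C"`, `"UNASSIGNED"`.
#' @export
assign_class <- function(family_instances, proteins, family = NULL,
                         annotation = NULL) {
  if (!is.null(annotation) && !is.null(family) &&
      family %in% names(annotation))
    return(unname(annotation[[family]]))
  lens <- nchar(proteins[family_instances$protein])
  mid <- (family_instances$start + family_instances$end) / 2 / lens
  votes <- ifelse(mid < 0.35, "N", ifelse(mid > 0.65, "C", "CAT"))
  tab <- sort(table(votes), decreasing = TRUE)
  if (length(tab) > 1L && tab[1L] == tab[2L]) return("UNASSIGNED")
  if (length(tab) > 1L && nrow(family_instances) < 3L) return("UNASSIGNED")
  names(tab)[1L]
}

assign_classes <- function(instances, proteins, annotation = NULL) {
  fams <- sort_c(unique(instances$family))
  if (!is.null(annotation)) {
    unknown <- setdiff(names(annotation), fams)
    if (length(unknown))
      warning(sprintf("annotation names unknown families: %s",
                      paste(unknown, collapse = ", ")))
  }
  setNames(vapply(fams, function(f)
    assign_class(instances[instances$family == f, , drop = FALSE],
                 proteins, f, annotation), ""), fams)
}
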