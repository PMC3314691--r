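#' NeighborNet splits network
#'
#' Computes a circular split system from a distance matrix by the
#' NeighborNet agglomeration (via phangorn), with nonnegative
#' least-squares split weights; splits with weight below `drop_tol` are
#' dropped. On an additive (tree) metric the network's splits equal the
#' tree's splits with the tree's branch lengths and the least-squares
#' residual is numerically zero; conflicting signals appear as pairs of
#' incompatible splits with positive weight (drawn as boxes by splits
#' viewers).
#'
#' @param D symmetric distance matrix (or `dist`) with labels.
#' @param drop_tol weights below this are discarded (default 1e-8).
#' @return object of class `splits_network`: `labels` (input order),
#'   `order` (circular taxon ordering), `splits` (list of character
#'   vectors, the side not containing the first taxon of `order`),
#'   `weights`, `residual` (sum of squared distance errors), `n_taxa`.
#' @export
neighbor_net <- function(D, drop_tol = 1e-8) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  labs <- rownames(D)
  if (is.null(labs)) labs <- colnames(D)
  if (is.null(labs)) stop("distance matrix must have labels")
  n <- nrow(D)
  if (n < 2L) stop("need at least two taxa")
  if (n < 4L) {
    sides <- list(); w <- numeric(0)
    if (n == 2L) {
      sides <- list(labs[2L]); w <- D[1L, 2L]
    } else {
      # 3-taxon star: external edge lengths in closed form
      for (i in 1:3) {
        oth <- setdiff(1:3, i)
        wi <- max(0, (D[i, oth[1L]] + D[i, oth[2L]] -
                        D[oth[1L], oth[2L]]) / 2)
        sides[[i]] <- labs[i]; w[i] <- wi
      }
    }
    keep <- w >= drop_tol
    net <- structure(list(labels = labs, order = labs,
                          splits = sides[keep], weights = w[keep],
                          residual = NA_real_, n_taxa = n),
                     class = "splits_network")
    net$residual <- splits_residual(net, D)
    return(net)
  }
  nn <- phangorn::neighborNet(stats::as.dist(D))
  spl <- nn$splits
  if (length(spl)) {
    slabs <- attr(spl, "labels")
    cyc <- attr(spl, "cycle")
    w <- attr(spl, "weights")
    sides <- lapply(unclass(spl), function(ix) sort_c(slabs[ix]))
    ord <- slabs[cyc]
  } else {
    # degenerate metric (e.g. all distances equal): the agglomeration
    # yields no splits; fit weights ourselves over the full circular
    # split set of an arbitrary ordering by active-set NNLS
    ord <- labs
    sides <- list()
    for (i in 2:n) for (j in i:n)
      sides[[length(sides) + 1L]] <- ord[i:j]
    pairs <- utils::combn(labs, 2)
    A <- matrix(0, ncol(pairs), length(sides))
    for (k in seq_along(sides)) {
      A[, k] <- as.numeric(xor(pairs[1, ] %in% sides[[k]],
                               pairs[2, ] %in% sides[[k]]))
    }
    d <- apply(pairs, 2, function(p) D[p[1], p[2]])
    w <- nnls_solve(A, d)
  }
  keep <- which(w >= drop_tol &
                  vapply(sides, length, 1L) >= 1L &
                  vapply(sides, length, 1L) <= n - 1L)
  net <- structure(list(labels = labs, order = ord,
                        splits = sides[keep], weights = unname(w[keep]),
                        residual = NA_real_, n_taxa = n),
                   class = "splits_network")
  net$residual <- splits_residual(net, D)
  net
}

# distance induced by a weighted split system, and its squared error
splits_distance <- function(net) {
  labs <- net$labels
  n <- length(labs)
  Dh <- matrix(0, n, n, dimnames = list(labs, labs))
  for (k in seq_along(net$splits)) {
    inside <- labs %in% net$splits[[k]]
    sep <- outer(inside, inside, FUN = "!=")
    Dh <- Dh + net$weights[k] * sep
  }
  Dh
}

splits_residual <- function(net, D) {
  Dh <- splits_distance(net)
  sum((D[net$labels, net$labels] - Dh)^2) / 2
}

#' @export
print.splits_network <- function(x, ...) {
  cat(sprintf("splits_network: %d taxa, %d splits, residual %.3g\n",
              x$n_taxa, length(x$splits), x$residual))
  invisible(x)
}

#' Write a splits network as a SplitsTree-compatible Nexus file
#'
#' Emits `Taxa` and `Splits` blocks (cycle plus weighted splits, sides
#' given as taxon indices) in the dialect SplitsTree reads.
#'
#' @param net a [neighbor_net()] result.
#' @param path output file.
#' @param comment optional comment line placed after `#NEXUS`.
#' @return invisibly, `path`.
#' @export
write_splits_nexus <- function(net, path, comment = NULL) {
  labs <- net$order
  idx <- setNames(seq_along(labs), labs)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("#NEXUS")
  if (!is.null(comment)) wl("[%s]", comment)
  wl("BEGIN Taxa;")
  wl("DIMENSIONS ntax=%d;", length(labs))
  wl("TAXLABELS")
  for (i in seq_along(labs)) wl("[%d] '%s'", i, labs[i])
  wl(";")
  wl("END; [Taxa]")
  wl("BEGIN Splits;")
  wl("DIMENSIONS ntax=%d nsplits=%d;", length(labs), length(net$splits))
  wl("FORMAT labels=no weights=yes confidences=no intervals=no;")
  wl("PROPERTIES fit=-1.0 cyclic;")
  wl("CYCLE %s;", paste(seq_along(labs), collapse = " "))
  wl("MATRIX")
  for (k in seq_along(net$splits)) {
    side <- sort(unname(idx[net$splits[[k]]]))
    wl("[%d, size=%d] \t%.8f \t %s,", k, length(side), net$weights[k],
       paste(side, collapse = " "))
  }
  wl(";")
  wl("END; [Splits]")
  invisible(path)
}
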