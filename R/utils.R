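# Shared internal helpers: residue coding, deterministic sorting,
# assignment solver, config hashing.

# 20 standard residues + X (unknown, scored 0). Code 22 is reserved for the
# internal mask character used between masking rounds of all_vs_all().
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
MASK_CODE <- 22L

aa_code_map <- local({
  m <- rep(NA_integer_, 127)
  m[utf8ToInt(paste(AA_ALPHABET, collapse = "")) + 1L] <-
    seq_along(AA_ALPHABET)
  m
})

# character string -> integer codes; stops with position of first illegal
# residue (id used in the message when given)
encode_seq <- function(seq, id = NULL) {
  ints <- utf8ToInt(seq)
  bad <- ints > 126L
  codes <- rep(NA_integer_, length(ints))
  codes[!bad] <- aa_code_map[ints[!bad] + 1L]
  if (anyNA(codes)) {
    pos <- which(is.na(codes))[1L]
    stop(sprintf("illegal residue '%s' at position %d%s",
                 substr(seq, pos, pos), pos,
                 if (is.null(id)) "" else sprintf(" in record '%s'", id)),
         call. = FALSE)
  }
  codes
}

decode_aln <- function(codes) {
  # 0 = gap; '#' = mask, never user-visible
  paste(c("-", AA_ALPHABET, "#")[codes + 1L], collapse = "")
}

# locale-independent ordering for reproducible outputs
order_c <- function(...) order(..., method = "radix")
sort_c <- function(x) {
  if (!length(x)) return(character(0))
  sort(x, method = "radix")
}

# Maximum-weight assignment (Hungarian algorithm, shortest-augmenting-path
# form on the equivalent min-cost problem). W is an n x m weight matrix;
# returns an integer vector over rows of W: matched column index, or NA for
# rows matched to padding. O(k^3) with k = max(n, m).
max_weight_assignment <- function(W) {
  if (length(W) == 0L) return(integer(0))
  n0 <- nrow(W); m0 <- ncol(W)
  k <- max(n0, m0)
  top <- max(W)
  C <- matrix(top, k, k)  # padding carries the worst cost
  C[seq_len(n0), seq_len(m0)] <- top - W
  u <- numeric(k)         # row potentials
  v <- numeric(k + 1L)    # column potentials, col 1 is virtual
  p <- integer(k + 1L)    # p[j]: row matched to column j-1 (0 = none)
  way <- integer(k + 1L)
  for (i in seq_len(k)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, k + 1L)
    used <- rep(FALSE, k + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2L:(k + 1L)) {
        if (!used[j]) {
          cur <- C[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(k + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == 1L) break
    }
  }
  res <- rep(NA_integer_, n0)
  for (j in 2L:(k + 1L)) {
    r <- p[j]; cl <- j - 1L
    if (r >= 1L && r <= n0 && cl <= m0) res[r] <- cl
  }
  res
}

# Lawson-Hanson active-set nonnegative least squares: minimize
# ||A x - b|| subject to x >= 0. Used for split-weight estimation when
# the agglomerative solver returns a degenerate (empty) split set.
nnls_solve <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  P <- logical(n)
  w <- as.numeric(crossprod(A, b - A %*% x))
  repeat {
    if (all(P) || max(w[!P]) <= tol) break
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      s[is.na(s)] <- 0
      if (all(s[P] > tol)) { x <- s; break }
      drop_set <- P & s <= tol
      alpha <- min(x[drop_set] / (x[drop_set] - s[drop_set]))
      x <- x + alpha * (s - x)
      P <- P & x > tol
      x[!P] <- 0
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  x
}

# stable 31-bit polynomial rolling hash of a character scalar, for
# config fingerprints in output headers
string_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
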