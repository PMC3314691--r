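#' Scoring model for protein alignments
#'
#' Bundles a substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw Smith-Waterman scores to
#' E-values via \eqn{E = K m n e^{-\lambda S}}. The defaults (BLOSUM62,
#' gap open 11, gap extend 1, \eqn{K = 0.041}, \eqn{\lambda = 0.267}) are
#' the standard gapped parameters for that matrix, so E-values approximate
#' those of a BLASTP search with default settings.
#'
#' The matrix is indexed by the 20 standard residues plus `X`; `X` scores 0
#' against everything (including itself), so unknown residues neither help
#' nor hurt an alignment.
#'
#' @param matrix 20x20 (or 21x21 including `X`) integer substitution
#'   matrix with residue dimnames; default BLOSUM62 from Biostrings.
#' @param gap_open positive gap-opening penalty (a k-long gap costs
#'   `gap_open + k * gap_extend`).
#' @param gap_extend positive per-residue gap-extension penalty.
#' @param K,lambda Karlin-Altschul constants for the E-value formula.
#' @return An object of class `scoring_model`.
#' @export
scoring_model <- function(matrix = NULL, gap_open = 11, gap_extend = 1,
                          K = 0.041, lambda = 0.267) {
  if (is.null(matrix)) {
    b62 <- get_blosum62()
    matrix <- b62
  }
  aa20 <- AA_ALPHABET[1:20]
  if (!all(aa20 %in% rownames(matrix)))
    stop("substitution matrix must cover the 20 standard residues")
  S <- matrix(0L, 22, 22,
              dimnames = list(c(AA_ALPHABET, "#"), c(AA_ALPHABET, "#")))
  S[aa20, aa20] <- as.integer(matrix[aa20, aa20])
  # X scores 0 (already), mask '#' is strongly negative so masked regions
  # cannot be crossed for free in later search rounds
  S["#", ] <- -100L; S[, "#"] <- -100L
  if (!isTRUE(all.equal(S[aa20, aa20], t(S[aa20, aa20]))))
    stop("substitution matrix must be symmetric")
  if (gap_open < 0 || gap_extend <= 0)
    stop("gap penalties must be positive (gap_open may be 0 for linear gaps)")
  if (K <= 0 || lambda <= 0) stop("K and lambda must be positive")
  exp_score <- mean(S[aa20, aa20])
  if (exp_score >= 0)
    warning("expected substitution score under uniform frequencies is >= 0")
  structure(list(matrix = S, gap_open = gap_open, gap_extend = gap_extend,
                 K = K, lambda = lambda),
            class = "scoring_model")
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Simple match/mismatch substitution matrix
#'
#' Convenience constructor for toy scoring schemes used in examples and
#' oracle tests.
#'
#' @param match,mismatch scores for identical / differing residues.
#' @return 21x21 integer matrix over the package alphabet.
#' @export
match_mismatch_matrix <- function(match = 2L, mismatch = -1L) {
  n <- length(AA_ALPHABET)
  M <- matrix(as.integer(mismatch), n, n,
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diag(M) <- as.integer(match)
  M["X", ] <- 0L; M[, "X"] <- 0L
  M
}

check_model <- function(s) {
  if (!inherits(s, "scoring_model")) stop("'s' must be a scoring_model")
  s
}

#' Karlin-Altschul E-value
#'
#' \eqn{E = K m n e^{-\lambda S}}: the expected number of distinct local
#' alignments with score at least `S` between random sequences of lengths
#' `m` and `n`.
#'
#' @param S raw alignment score (>= 0).
#' @param m,n lengths of the two compared sequences.
#' @param s a [scoring_model()].
#' @return E-value (numeric).
#' @export
evalue <- function(S, m, n, s = scoring_model()) {
  check_model(s)
  stopifnot(all(S >= 0), all(m >= 1), all(n >= 1))
  s$K * m * n * exp(-s$lambda * S)
}

#' Bit score of a raw alignment score
#'
#' @inheritParams evalue
#' @return `(lambda * S - ln K) / ln 2`.
#' @export
bitscore <- function(S, s = scoring_model()) {
  check_model(s)
  (s$lambda * S - log(s$K)) / log(2)
}

aln_from_paths <- function(a_codes, b_codes, pa, pb) {
  acol <- ifelse(pa > 0L, a_codes[pmax(pa, 1L)], 0L)
  bcol <- ifelse(pb > 0L, b_codes[pmax(pb, 1L)], 0L)
  ident <- if (length(acol)) {
    both <- acol > 0L & bcol > 0L
    100 * sum(acol == bcol & both) / length(acol)
  } else 0
  list(a_aln = decode_aln(acol), b_aln = decode_aln(bcol),
       length = length(acol), identity = ident,
       acol = acol, bcol = bcol)
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Exact optimal local alignment of two protein sequences under the given
#' scoring model. The traceback is deterministic: the highest-scoring cell
#' with the smallest `(end_a, end_b)` is chosen, and ties among moves
#' prefer the diagonal, then a gap in `b`, then a gap in `a`. If no
#' positive-scoring pair exists, the alignment is empty with score 0.
#'
#' @param a,b protein sequences (single character strings, residues
#'   `ACDEFGHIKLMNPQRSTVWY` plus `X`).
#' @param s a [scoring_model()].
#' @param a_id,b_id identifiers used in the result and in error messages.
#' @return A `local_alignment`: list with `score`, 1-based inclusive
#'   intervals `a_start`/`a_end`/`b_start`/`b_end`, gapped `a_aln`/`b_aln`
#'   strings, column count `length`, percent `identity` (identical pairs /
#'   aligned columns), and `evalue`.
#' @export
local_align <- function(a, b, s = scoring_model(), a_id = "a", b_id = "b") {
  check_model(s)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  ca <- encode_seq(a, a_id); cb <- encode_seq(b, b_id)
  r <- sw_align_cpp(ca, cb, s$matrix, s$gap_open, s$gap_extend)
  al <- aln_from_paths(ca, cb, r$pa, r$pb)
  structure(list(a_id = a_id, b_id = b_id, score = r$score,
                 a_start = r$a_start, a_end = r$a_end,
                 b_start = r$b_start, b_end = r$b_end,
                 a_aln = al$a_aln, b_aln = al$b_aln,
                 length = al$length, identity = al$identity,
                 evalue = evalue(r$score, nchar(a), nchar(b), s),
                 m = nchar(a), n = nchar(b),
                 acol = al$acol, bcol = al$bcol),
            class = "local_alignment")
}

#' Optimal global alignment (Needleman-Wunsch, affine gaps)
#'
#' @inheritParams local_align
#' @return A `global_alignment`: list with `score`, gapped strings,
#'   `length` and percent `identity` (identical pairs / columns with at
#'   least one residue).
#' @export
global_align <- function(a, b, s = scoring_model(), a_id = "a", b_id = "b") {
  check_model(s)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  ca <- encode_seq(a, a_id); cb <- encode_seq(b, b_id)
  r <- nw_align_cpp(ca, cb, s$matrix, s$gap_open, s$gap_extend)
  al <- aln_from_paths(ca, cb, r$pa, r$pb)
  structure(list(a_id = a_id, b_id = b_id, score = r$score,
                 a_aln = al$a_aln, b_aln = al$b_aln,
                 length = al$length, identity = al$identity,
                 acol = al$acol, bcol = al$bcol),
            class = "global_alignment")
}

#' Global percent identity of two sequences
#'
#' Percent identity over a Needleman-Wunsch global alignment: identical
#' aligned pairs divided by columns with at least one residue, times 100.
#' This is the "ClustalW-style" identity used by the dual clustering
#' threshold; symmetric in its arguments and 100 for identical sequences.
#'
#' @inheritParams local_align
#' @return percent identity in `[0, 100]`.
#' @export
global_identity <- function(a, b, s = scoring_model()) {
  global_align(a, b, s)$identity
}

count_gap_opens <- function(col) {
  g <- col == 0L
  sum(g & !c(FALSE, g[-length(g)]))
}

#' All-vs-all homology search
#'
#' Runs exact local alignment on every unordered pair of proteins and
#' reports one segment match per pair per search round. After the best
#' alignment of a pair is found, its intervals are masked in both
#' sequences and the pair is re-searched (`mask_rounds` times, default 1)
#' so that co-linear repeats such as duplicated domains are also reported.
#' Matches shorter than `min_seg_len` columns are dropped.
#'
#' Two significance flags are attached to every match, mirroring the dual
#' criterion used to call shared regions: `passes_evalue` (Karlin-Altschul
#' E-value strictly below `evalue_max`) and `passes_identity` (percent
#' identity strictly above `identity_min`). The identity used for the flag
#' is the ClustalW-style \emph{global} identity of the two full sequences
#' (column `gident`): short spurious local hits routinely exceed 20%
#' column identity, whereas whole-sequence global identity separates
#' related from unrelated pairs. The local column identity is reported as
#' `pident`.
#'
#' @param proteins named character vector of sequences.
#' @param s a [scoring_model()].
#' @param min_seg_len minimum alignment length (columns) to report.
#' @param mask_rounds number of mask-and-research rounds after the best
#'   alignment (0 disables).
#' @param evalue_max,identity_min thresholds for the flags (strict
#'   inequalities; E-value exactly `evalue_max` or identity exactly
#'   `identity_min` fail).
#' @return data.frame of matches (one row per reported segment pair) with
#'   BLAST-tabular style columns `qid, sid, pident, length, mismatch,
#'   gapopen, qstart, qend, sstart, send, evalue, bitscore` plus `score`,
#'   `gident`, `round`, `passes_evalue`, `passes_identity`, and gapped
#'   alignment strings `qaln`, `saln`. The attribute `n_pairs` records the
#'   number of pair evaluations.
#' @export
all_vs_all <- function(proteins, s = scoring_model(), min_seg_len = 30L,
                       mask_rounds = 1L, evalue_max = 1e-5,
                       identity_min = 20) {
  check_model(s)
  if (length(proteins) < 2L) stop("need at least two proteins")
  ids <- names(proteins)
  if (is.null(ids) || anyDuplicated(ids))
    stop("proteins must be uniquely named")
  codes <- lapply(seq_along(proteins),
                  function(i) encode_seq(proteins[[i]], ids[i]))
  names(codes) <- ids
  rows <- list(); n_pairs <- 0L
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      n_pairs <- n_pairs + 1L
      ca <- codes[[i]]; cb <- codes[[j]]
      m <- length(ca); n <- length(cb)
      gid <- global_identity(proteins[[i]], proteins[[j]], s)
      for (round in 0L:mask_rounds) {
        r <- sw_align_cpp(ca, cb, s$matrix, s$gap_open, s$gap_extend)
        if (r$a_end < 0L || length(r$pa) < min_seg_len || r$score <= 0)
          break
        al <- aln_from_paths(codes[[i]], codes[[j]], r$pa, r$pb)
        ev <- evalue(r$score, m, n, s)
        both <- al$acol > 0L & al$bcol > 0L
        rows[[length(rows) + 1L]] <- data.frame(
          qid = ids[i], sid = ids[j],
          pident = al$identity, length = al$length,
          mismatch = sum(both & al$acol != al$bcol),
          gapopen = count_gap_opens(al$acol) + count_gap_opens(al$bcol),
          qstart = r$a_start, qend = r$a_end,
          sstart = r$b_start, send = r$b_end,
          evalue = ev, bitscore = bitscore(r$score, s),
          score = r$score, gident = gid, round = round,
          passes_evalue = ev < evalue_max,
          # the whole-sequence identity criterion backs only the primary
          # alignment; re-search rounds must stand on their own E-value
          passes_identity = round == 0L && gid > identity_min,
          qaln = al$a_aln, saln = al$b_aln,
          stringsAsFactors = FALSE)
        ca[r$a_start:r$a_end] <- MASK_CODE
        cb[r$b_start:r$b_end] <- MASK_CODE
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    qid = character(0), sid = character(0), pident = numeric(0),
    length = integer(0), mismatch = integer(0), gapopen = integer(0),
    qstart = integer(0), qend = integer(0), sstart = integer(0),
    send = integer(0), evalue = numeric(0), bitscore = numeric(0),
    score = numeric(0), gident = numeric(0), round = integer(0),
    passes_evalue = logical(0), passes_identity = logical(0),
    qaln = character(0), saln = character(0), stringsAsFactors = FALSE)
  attr(out, "n_pairs") <- n_pairs
  out
}
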