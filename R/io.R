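#' Read protein sequences from FASTA
#'
#' Strict reader for amino-acid FASTA: identifiers are taken up to the
#' first whitespace and must be unique; sequences are uppercased; a
#' single terminal `*` (stop) is stripped; `;` comment lines are
#' skipped. Residues must be the 20 standard amino acids or `X` —
#' selenocysteine `U`, pyrrolysine `O` and anything else are rejected
#' with the offending line number.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^;", lines)
  lines <- lines[keep]; lineno <- which(keep)
  if (!length(lines) || !any(grepl("^>", lines)))
    stop(sprintf("empty or headerless FASTA: %s", path))
  hdr <- grepl("^>", lines)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate record id '%s' in %s", dup[1L], path))
  grp <- cumsum(hdr)
  seqs <- character(length(ids))
  for (g in seq_along(ids)) {
    body_idx <- which(grp == g & !hdr)
    body <- toupper(gsub("\\s", "", lines[body_idx]))
    seq <- paste(body, collapse = "")
    seq <- sub("\\*$", "", seq)
    bad <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                   seq)
    if (bad > 0) {
      # locate the offending file line
      off <- cumsum(nchar(body))
      row <- which(off >= bad)[1L]
      stop(sprintf(
        "illegal residue '%s' in record '%s' (line %d of %s)",
        substr(seq, bad, bad), ids[g], lineno[body_idx[row]], path))
    }
    if (!nzchar(seq))
      stop(sprintf("record '%s' has an empty sequence", ids[g]))
    seqs[g] <- seq
  }
  setNames(seqs, ids)
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width wrap width (default 60 columns).
#' @param comment optional `;` comment line written first (e.g. the
#'   generator seed).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("; ", comment), con)
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Write a table as TSV with `#` header metadata
#'
#' @param df data.frame.
#' @param path output file.
#' @param meta named vector written as `# key=value` comment lines.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (skipping `#` metadata)
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a family-class annotation table
#'
#' Two- or three-column TSV `family`, `class`, optional `name`
#' (e.g. mapping a recovered family to a published domain name). Classes
#' must be `N`, `CAT` or `C`.
#'
#' @param path TSV file.
#' @return named character vector family -> class, with a `names`
#'   attribute-carrying data.frame in `attr(, "table")`.
#' @export
read_annotation <- function(path) {
  df <- read_tsv(path)
  names(df) <- tolower(names(df))
  if (!all(c("family", "class") %in% names(df)))
    stop("annotation needs 'family' and 'class' columns")
  if (!all(df$class %in% c("N", "CAT", "C")))
    stop("annotation classes must be N, CAT or C")
  out <- setNames(df$class, df$family)
  attr(out, "table") <- df
  out
}

#' Write domain instances as GFF3
#'
#' One `polypeptide_domain` feature per instance (seqid = protein id,
#' 1-based inclusive coordinates, family and class in the attributes).
#'
#' @param instances data.frame `protein`, `family`, `class`, `start`,
#'   `end`.
#' @param path output file.
#' @param meta named vector for `#` header lines.
#' @return invisibly, `path`.
#' @export
write_domains_gff3 <- function(instances, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(meta))
    writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  if (nrow(instances)) {
    lines <- sprintf(
      "%s\tlysmod\tpolypeptide_domain\t%d\t%d\t.\t.\t.\tID=%s_%d_%d;family=%s;class=%s",
      instances$protein, instances$start, instances$end,
      instances$protein, instances$start, instances$end,
      instances$family, instances$class)
    writeLines(lines, con)
  }
  invisible(path)
}
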