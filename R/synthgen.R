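#' Configuration for the synthetic modular-proteome generator
#'
#' The generator emulates a corpus of modular peptidoglycan-hydrolase
#' proteins: each protein is a concatenation of linkers and domains, the
#' domains are drawn from three positional classes (an N-terminal
#' peptidase-like class `N`, a central catalytic class `CAT`, and a
#' C-terminal cell-wall-binding class `C`), about 90% of proteins follow
#' the canonical `N + CAT + C` organization, and domain families are
#' shuffled between lineages at a configurable swap rate, producing the
#' phylogenetic incongruence characteristic of mosaic proteins.
#'
#' Proteins are partitioned into `n_lineages` lineages. Each lineage has a
#' preferred family per slot class; the default preference matrix (6
#' lineages) is constructed so every lineage has, for both its `N` and its
#' `CAT` slot, another lineage sharing exactly that one family — so
#' partial pairwise matches delineate domain boundaries, as they do in
#' real mosaic proteins.
#'
#' @param n_families_per_class named counts of distinct families per class
#'   (default `c(N = 6, CAT = 5, C = 4)`).
#' @param family_length_range inclusive range of ancestor domain lengths
#'   (residues).
#' @param linker_length_range inclusive range of inter-domain linker
#'   lengths (residues).
#' @param divergence per-site substitution probability applied
#'   independently to every domain instance (substitution is to a
#'   uniformly chosen different residue).
#' @param org_distribution named probabilities over organization
#'   templates; template names are `+`-separated class strings such as
#'   `"N+CAT+C"`. Default: 0.90 on `N+CAT+C` and 0.02 each on
#'   `N+C` (missing central domain), `N+CAT+CAT+C`, `N+CAT+C+C`,
#'   `CAT+C`, and `N+CAT`.
#' @param n_proteins number of proteins to generate.
#' @param n_lineages number of lineages (default 6; the designed
#'   preference matrix assumes 6).
#' @param swap_rate per-slot probability that the family is drawn from
#'   another (uniformly chosen) lineage's preference instead of the own
#'   lineage's — a domain swap, recorded in the truth table.
#' @param preference_scheme `"mosaic"` (default): lineages share families
#'   between slots as described above, so domain boundaries are
#'   observable from partial matches; `"disjoint"`: every lineage gets
#'   its own family in every slot (a clean shared history, so domain
#'   trees agree up to within-family noise — the right background for
#'   incongruence tests, where a single engineered swap must stand out).
#' @param background residue frequencies for ancestor and linker sequence
#'   (length 20, default uniform).
#' @param seed integer RNG seed; the generator is fully deterministic
#'   given the config.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_families_per_class = c(N = 6, CAT = 5, C = 4),
                             family_length_range = c(60, 180),
                             linker_length_range = c(0, 20),
                             divergence = 0.2,
                             org_distribution = NULL,
                             n_proteins = 60,
                             n_lineages = 6,
                             swap_rate = 0.05,
                             preference_scheme = c("mosaic", "disjoint"),
                             background = rep(1 / 20, 20),
                             seed = 1L) {
  preference_scheme <- match.arg(preference_scheme)
  if (is.null(org_distribution)) {
    org_distribution <- c("N+CAT+C" = 0.90, "N+C" = 0.02,
                          "N+CAT+CAT+C" = 0.02, "N+CAT+C+C" = 0.02,
                          "CAT+C" = 0.02, "N+CAT" = 0.02)
  }
  stopifnot(all(c("N", "CAT", "C") %in% names(n_families_per_class)),
            all(n_families_per_class >= 1),
            length(family_length_range) == 2,
            family_length_range[1] <= family_length_range[2],
            family_length_range[1] >= 1,
            length(linker_length_range) == 2,
            linker_length_range[1] <= linker_length_range[2],
            linker_length_range[1] >= 0,
            n_proteins >= 1, n_lineages >= 2, swap_rate >= 0,
            swap_rate <= 1, length(background) == 20,
            all(background > 0))
  if (divergence < 0 || divergence > 1)
    stop("divergence must be in [0, 1]")
  if (abs(sum(org_distribution) - 1) > 1e-9)
    stop("org_distribution probabilities must sum to 1")
  cls <- strsplit(names(org_distribution), "+", fixed = TRUE)
  if (!all(unlist(cls) %in% c("N", "CAT", "C")))
    stop("org_distribution templates may only contain N, CAT, C")
  structure(list(n_families_per_class = n_families_per_class,
                 family_length_range = family_length_range,
                 linker_length_range = linker_length_range,
                 divergence = divergence,
                 org_distribution = org_distribution,
                 n_proteins = n_proteins,
                 n_lineages = n_lineages,
                 swap_rate = swap_rate,
                 preference_scheme = preference_scheme,
                 background = background / sum(background),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# deterministic lineage -> preferred family index per class; designed so
# that (for 6 lineages) every lineage shares exactly its N family with one
# other lineage and exactly its CAT family with another
lineage_preferences <- function(config) {
  L <- config$n_lineages
  nf <- config$n_families_per_class
  ell <- seq_len(L)
  if (identical(config$preference_scheme, "disjoint"))
    return(list(N = (ell - 1L) %% nf[["N"]] + 1L,
                CAT = (ell - 1L) %% nf[["CAT"]] + 1L,
                C = (ell - 1L) %% nf[["C"]] + 1L))
  list(N = ((ell - 1) %/% 2) %% nf[["N"]] + 1L,
       CAT = (ell - 1) %% min(3L, nf[["CAT"]]) + 1L,
       C = (ell %/% 2) %% nf[["C"]] + 1L)
}

random_seq <- function(n, background) {
  if (n == 0L) return("")
  paste(sample(AA_ALPHABET[1:20], n, replace = TRUE, prob = background),
        collapse = "")
}

mutate_seq <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < divergence
  if (any(hit)) {
    aa <- AA_ALPHABET[1:20]
    repl <- vapply(chars[hit],
                   function(ch) sample(aa[aa != ch], 1L), "")
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

#' Expected within-family pairwise identity under the substitution model
#'
#' Two instances are independent mutants of the ancestor at per-site rate
#' `d`; a site matches if both are unmutated, or both mutated to the same
#' of the 19 alternatives: \eqn{(1-d)^2 + d^2/19}.
#'
#' @param divergence per-site substitution probability.
#' @return expected fraction of identical sites.
#' @export
expected_family_identity <- function(divergence) {
  (1 - divergence)^2 + divergence^2 / 19
}

#' Generate a synthetic modular proteome with ground truth
#'
#' Builds `n_proteins` proteins as linker-domain-linker concatenations
#' according to [generator_config()], together with a truth table
#' recording every domain instance (family, class, 1-based inclusive
#' coordinates), each protein's lineage and organization template, the
#' per-family ancestor sequences, and all domain-swap events.
#'
#' @param config a [generator_config()].
#' @return list of class `synthetic_proteome` with elements `proteins`
#'   (named character vector), `truth` (list: `instances`, `proteins`
#'   data.frame with lineage/template, `swaps`, `ancestors`, `pieces`),
#'   and `config`.
#' @export
generate_proteome <- function(config) {
  if (!inherits(config, "generator_config"))
    stop("config must be a generator_config")
  set.seed(config$seed)
  nf <- config$n_families_per_class
  fam_ids <- list(N = paste0("N", seq_len(nf[["N"]])),
                  CAT = paste0("CAT", seq_len(nf[["CAT"]])),
                  C = paste0("C", seq_len(nf[["C"]])))
  flr <- config$family_length_range
  ancestors <- list()
  for (cl in c("N", "CAT", "C")) {
    for (f in fam_ids[[cl]]) {
      len <- sample(seq(flr[1], flr[2]), 1L)
      ancestors[[f]] <- random_seq(len, config$background)
    }
  }
  prefs <- lineage_preferences(config)
  templates <- strsplit(names(config$org_distribution), "+", fixed = TRUE)
  names(templates) <- names(config$org_distribution)
  ids <- sprintf("Phage%03d_gp1", seq_len(config$n_proteins))
  lineages <- (seq_len(config$n_proteins) - 1L) %% config$n_lineages + 1L
  tpl_draw <- sample(names(config$org_distribution), config$n_proteins,
                     replace = TRUE, prob = config$org_distribution)
  llr <- config$linker_length_range
  pieces <- list(); inst <- list(); swaps <- list()
  proteins <- character(config$n_proteins)
  for (p in seq_len(config$n_proteins)) {
    tpl <- templates[[tpl_draw[p]]]
    ell <- lineages[p]
    fams <- character(length(tpl))
    seen <- character(0)
    for (k in seq_along(tpl)) {
      cl <- tpl[k]
      fam_idx <- prefs[[cl]][ell]
      fam <- fam_ids[[cl]][fam_idx]
      donor <- NA_integer_
      if (fam %in% seen || runif(1) < config$swap_rate) {
        # duplicated slot class takes another lineage's family; ordinary
        # slots do so with probability swap_rate (a domain swap)
        others <- setdiff(seq_len(config$n_lineages), ell)
        others <- others[vapply(others, function(o)
          fam_ids[[cl]][prefs[[cl]][o]] != fam, TRUE)]
        if (length(others)) {
          donor <- others[sample.int(length(others), 1L)]
          fam <- fam_ids[[cl]][prefs[[cl]][donor]]
          if (!(fam_ids[[cl]][prefs[[cl]][ell]] %in% seen))
            swaps[[length(swaps) + 1L]] <- data.frame(
              protein = ids[p], slot = k, class = cl,
              donor_lineage = donor, family = fam,
              stringsAsFactors = FALSE)
        }
      }
      seen <- c(seen, fam)
      fams[k] <- fam
    }
    # assemble: linker, dom, linker, ..., dom, linker
    segs <- list(); pos <- 0L
    add_piece <- function(type, fam, cl, seq) {
      pieces[[length(pieces) + 1L]] <<- data.frame(
        protein = ids[p], piece = length(segs) + 1L, type = type,
        family = fam, class = cl, seq = seq, stringsAsFactors = FALSE)
      segs[[length(segs) + 1L]] <<- seq
    }
    add_piece("linker", NA, NA,
              random_seq(sample(seq(llr[1], llr[2]), 1L), config$background))
    for (k in seq_along(tpl)) {
      start <- sum(nchar(unlist(segs))) + 1L
      dseq <- mutate_seq(ancestors[[fams[k]]], config$divergence)
      add_piece("domain", fams[k], tpl[k], dseq)
      inst[[length(inst) + 1L]] <- data.frame(
        protein = ids[p], slot = k, family = fams[k], class = tpl[k],
        start = start, end = start + nchar(dseq) - 1L,
        stringsAsFactors = FALSE)
      add_piece("linker", NA, NA,
                random_seq(sample(seq(llr[1], llr[2]), 1L),
                           config$background))
    }
    proteins[p] <- paste(unlist(segs), collapse = "")
  }
  names(proteins) <- ids
  truth <- list(
    instances = do.call(rbind, inst),
    proteins = data.frame(protein = ids, lineage = lineages,
                          template = tpl_draw, stringsAsFactors = FALSE),
    swaps = if (length(swaps)) do.call(rbind, swaps) else data.frame(
      protein = character(0), slot = integer(0), class = character(0),
      donor_lineage = integer(0), family = character(0),
      stringsAsFactors = FALSE),
    ancestors = unlist(ancestors),
    pieces = do.call(rbind, pieces))
  structure(list(proteins = proteins, truth = truth, config = config),
            class = "synthetic_proteome")
}

#' Engineer a single domain swap into a generated proteome
#'
#' Replaces the domain in `slot` of `protein` with a fresh instance of the
#' donor lineage's preferred family for that slot class, rebuilding the
#' protein sequence and updating coordinates and the swap record. Used to
#' plant a known recombinant for incongruence testing.
#'
#' @param proteome a `synthetic_proteome` from [generate_proteome()].
#' @param protein protein id to modify.
#' @param slot 1-based slot index within that protein's architecture.
#' @param donor_lineage lineage whose preferred family replaces the slot.
#' @param seed RNG seed for the fresh instance's substitutions.
#' @return the modified `synthetic_proteome`.
#' @export
apply_domain_swap <- function(proteome, protein, slot, donor_lineage,
                              seed = 1L) {
  stopifnot(inherits(proteome, "synthetic_proteome"))
  config <- proteome$config
  prefs <- lineage_preferences(config)
  pieces <- proteome$truth$pieces
  sel <- pieces$protein == protein & pieces$type == "domain"
  if (sum(sel) < slot) stop("protein has fewer slots than requested")
  row <- which(sel)[slot]
  cl <- pieces$class[row]
  fam <- paste0(cl, prefs[[cl]][donor_lineage])
  if (fam == pieces$family[row])
    stop("donor lineage has the same preferred family for this slot")
  set.seed(seed)
  newseq <- mutate_seq(unname(proteome$truth$ancestors[fam]),
                       config$divergence)
  pieces$seq[row] <- newseq
  pieces$family[row] <- fam
  prows <- which(pieces$protein == protein)
  seqs <- pieces$seq[prows]
  proteome$proteins[[protein]] <- paste(seqs, collapse = "")
  # recompute instance coordinates for this protein
  starts <- cumsum(c(1L, nchar(seqs)))[seq_along(seqs)]
  inst <- proteome$truth$instances
  irows <- which(inst$protein == protein)
  drows <- which(pieces$type[prows] == "domain")
  inst$start[irows] <- starts[drows]
  inst$end[irows] <- starts[drows] + nchar(seqs[drows]) - 1L
  inst$family[irows[slot]] <- fam
  proteome$truth$instances <- inst
  proteome$truth$pieces <- pieces
  proteome$truth$swaps <- rbind(
    proteome$truth$swaps,
    data.frame(protein = protein, slot = slot, class = cl,
               donor_lineage = donor_lineage, family = fam,
               stringsAsFactors = FALSE))
  proteome
}

#' Write a synthetic proteome to FASTA and truth TSVs
#'
#' Writes `proteome.fasta` (60-column wrap, seed recorded in a leading
#' `;` comment line), `truth_instances.tsv` (protein, family, class,
#' start, end) and `truth_meta.tsv` (lineage, template, swap events).
#'
#' @param proteome a `synthetic_proteome`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_proteome <- function(proteome, dir) {
  stopifnot(inherits(proteome, "synthetic_proteome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "proteome.fasta")
  write_fasta(proteome$proteins, fa,
              comment = sprintf("seed=%d", proteome$config$seed))
  ti <- file.path(dir, "truth_instances.tsv")
  write_tsv(proteome$truth$instances[, c("protein", "family", "class",
                                         "start", "end")], ti,
            meta = c(seed = proteome$config$seed))
  meta <- proteome$truth$proteins
  sw <- proteome$truth$swaps
  if (nrow(sw)) {
    agg <- stats::aggregate(slot ~ protein, sw, paste, collapse = ",")
    names(agg) <- c("protein", "swapped_slots")
    meta <- merge(meta, agg, by = "protein", all.x = TRUE)
  } else meta$swapped_slots <- NA_character_
  meta <- meta[order_c(meta$protein), ]
  tm <- file.path(dir, "truth_meta.tsv")
  write_tsv(meta, tm, meta = c(seed = proteome$config$seed))
  invisible(c(fa, ti, tm))
}

#' Extract per-class domain sequences from a proteome's truth table
#'
#' For each positional class, the domain subsequence of every protein
#' carrying exactly one instance of that class — the input for
#' [incongruence_scan()] when working from known coordinates.
#'
#' @param proteome a `synthetic_proteome`.
#' @return named list class -> named character vector.
#' @export
truth_class_sequences <- function(proteome) {
  inst <- proteome$truth$instances
  out <- list()
  for (cl in intersect(c("N", "CAT", "C"), unique(inst$class))) {
    df <- inst[inst$class == cl, , drop = FALSE]
    tab <- table(df$protein)
    df <- df[df$protein %in% names(tab)[tab == 1L], , drop = FALSE]
    out[[cl]] <- setNames(
      substr(proteome$proteins[df$protein], df$start, df$end), df$protein)
  }
  out
}

match_instances <- function(inferred, truth_inst) {
  # for each true instance, the best-overlapping inferred instance
  # (overlap >= 50% of the shorter interval), else NA
  n <- nrow(truth_inst)
  lab <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    ti <- truth_inst[k, ]
    cand <- inferred[inferred$protein == ti$protein, , drop = FALSE]
    if (!nrow(cand)) next
    ov <- pmin(cand$end, ti$end) - pmax(cand$start, ti$start) + 1L
    shorter <- pmin(cand$end - cand$start + 1L, ti$end - ti$start + 1L)
    ok <- ov >= 0.5 * shorter
    if (!any(ok)) next
    best <- which(ok)[which.max(ov[ok])]
    lab[k] <- cand$family[best]
  }
  lab
}

#' Score recovery of planted domain families
#'
#' Compares an inferred set of domain instances (with family labels)
#' against the generator truth. Each true instance is matched to the
#' inferred instance overlapping it by at least 50% of the shorter
#' interval; the adjusted Rand index is computed between the true family
#' labels and the matched inferred labels (unmatched true instances count
#' as singletons), together with per-family precision/recall under the
#' best greedy family mapping.
#'
#' @param inferred data.frame with columns `protein`, `family`, `start`,
#'   `end` (e.g. the `instances` element of [cluster_families()]).
#' @param truth truth list from [generate_proteome()] (or its `instances`
#'   data.frame).
#' @return list of class `recovery_report`: `ari`, `n_true`, `n_matched`,
#'   `n_inferred_unmatched`, and data.frame `per_family`.
#' @export
family_recovery_score <- function(inferred, truth) {
  truth_inst <- if (is.data.frame(truth)) truth else truth$instances
  if (!length(intersect(unique(inferred$protein),
                        unique(truth_inst$protein))))
    stop("inferred and truth share no protein identifiers")
  lab <- match_instances(inferred, truth_inst)
  unmatched <- is.na(lab)
  lab[unmatched] <- paste0("UNMATCHED_", seq_len(sum(unmatched)))
  ari <- mclust::adjustedRandIndex(truth_inst$family, lab)
  tab <- table(truth_inst$family[!unmatched], lab[!unmatched])
  per_family <- do.call(rbind, lapply(rownames(tab), function(f) {
    cnt <- tab[f, , drop = TRUE]
    g <- colnames(tab)[which.max(cnt)]
    tp <- max(cnt)
    data.frame(family = f, mapped_to = g,
               recall = tp / sum(truth_inst$family == f),
               precision = tp / sum(lab == g),
               stringsAsFactors = FALSE)
  }))
  matched_keys <- paste(truth_inst$protein, lab)[!unmatched]
  n_inf_unmatched <- nrow(inferred) - length(unique(matched_keys))
  structure(list(ari = ari, n_true = nrow(truth_inst),
                 n_matched = sum(!unmatched),
                 n_inferred_unmatched = max(0L, n_inf_unmatched),
                 per_family = per_family),
            class = "recovery_report")
}

#' Fraction of proteins with exactly recovered domain architecture
#'
#' Matches inferred to true instances as in [family_recovery_score()],
#' chooses the family-label bijection maximizing total co-assignment
#' weight (Hungarian algorithm on the co-assignment count matrix), and
#' reports the fraction of proteins whose ordered true family string
#' equals the mapped inferred string exactly.
#'
#' @inheritParams family_recovery_score
#' @return fraction in `[0, 1]`.
#' @export
architecture_accuracy <- function(inferred, truth) {
  truth_inst <- if (is.data.frame(truth)) truth else truth$instances
  if (!length(intersect(unique(inferred$protein),
                        unique(truth_inst$protein))))
    stop("inferred and truth share no protein identifiers")
  lab <- match_instances(inferred, truth_inst)
  tf <- sort_c(unique(truth_inst$family))
  gf <- sort_c(unique(inferred$family))
  W <- matrix(0, length(tf), length(gf), dimnames = list(tf, gf))
  ok <- !is.na(lab)
  if (any(ok)) {
    cnt <- table(truth_inst$family[ok], lab[ok])
    W[rownames(cnt), colnames(cnt)] <- cnt
  }
  asn <- max_weight_assignment(W)
  map <- setNames(gf[asn], tf)  # true family -> inferred family (or NA)
  prots <- unique(truth_inst$protein)
  hits <- vapply(prots, function(p) {
    ti <- truth_inst[truth_inst$protein == p, , drop = FALSE]
    ti <- ti[order(ti$start), , drop = FALSE]
    ii <- inferred[inferred$protein == p, , drop = FALSE]
    ii <- ii[order(ii$start), , drop = FALSE]
    want <- unname(map[ti$family])
    if (anyNA(want)) return(FALSE)
    identical(want, ii$family)
  }, TRUE)
  mean(hits)
}
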