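#' Configuration for the end-to-end pipeline
#'
#' Collects every tunable of the pipeline: the scoring model, the
#' clustering thresholds, phylogenetic settings and the seed. All
#' downstream stages are deterministic given this object.
#'
#' @param scoring a [scoring_model()].
#' @param cluster a [cluster_params()].
#' @param mask_rounds mask-and-research rounds in [all_vs_all()].
#' @param n_reps bootstrap replicates for the incongruence scan.
#' @param support_min bootstrap support threshold (percent) for a
#'   conflict to be flagged.
#' @param metric presence/absence distance for the splits network
#'   (`"hamming"` or `"jaccard"`).
#' @param annotation optional named character vector family -> class.
#' @param seed integer seed used for every stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(scoring = scoring_model(),
                            cluster = cluster_params(),
                            mask_rounds = 1L,
                            n_reps = 100L,
                            support_min = 70,
                            metric = c("hamming", "jaccard"),
                            annotation = NULL,
                            seed = 1L) {
  metric <- match.arg(metric)
  structure(list(scoring = scoring, cluster = cluster,
                 mask_rounds = as.integer(mask_rounds),
                 n_reps = as.integer(n_reps), support_min = support_min,
                 metric = metric, annotation = annotation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  string_hash(paste(deparse(config[setdiff(names(config), "scoring")]),
                    collapse = ""))
}

# domain sequences per class: proteins carrying exactly one instance of
# the class contribute the corresponding subsequence
class_sequences <- function(instances, proteins) {
  out <- list()
  for (cl in intersect(c("N", "CAT", "C"), unique(instances$class))) {
    df <- instances[instances$class == cl, , drop = FALSE]
    tab <- table(df$protein)
    keep <- names(tab)[tab == 1L]
    df <- df[df$protein %in% keep, , drop = FALSE]
    out[[cl]] <- setNames(substr(proteins[df$protein], df$start, df$end),
                          df$protein)
  }
  out
}

#' Run the full endolysin-dissection pipeline
#'
#' Orchestrates every stage on a set of protein sequences: all-vs-all
#' homology search, domain-family clustering and class assignment,
#' architecture and organization derivation, combinatorial coverage,
#' domain-swap detection, the presence/absence splits network, and the
#' per-class incongruence scan. When `out_dir` is given, every stage's
#' table is written (TSV/GFF3/Newick/Nexus), each with a header comment
#' carrying the package version, config hash and seed, plus a
#' `summary.json`.
#'
#' @param proteins named character vector of sequences, or a FASTA path.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of class `pipeline_result`: `matches`, `domains`
#'   (the [cluster_families()] object), `architectures`,
#'   `organizations`, `coverage`, `swaps`, `matrix`, `network`,
#'   `class_trees` (bootstrap results per class), `incongruence`,
#'   `summary` (named list).
#' @export
run_pipeline <- function(proteins, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(proteins) && length(proteins) == 1L &&
      is.null(names(proteins)))
    proteins <- read_fasta(proteins)
  if (length(proteins) < 2L) stop("pipeline stage 'input': need >= 2 proteins")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  meta <- c(tool = "lysmod",
            version = as.character(utils::packageVersion("lysmod")),
            config = config_hash(config), seed = config$seed)
  outfile <- function(x) file.path(out_dir, x)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  matches <- stage("scan", all_vs_all(
    proteins, config$scoring, min_seg_len = config$cluster$min_seg_len,
    mask_rounds = config$mask_rounds,
    evalue_max = config$cluster$evalue_max,
    identity_min = config$cluster$identity_min))
  domains <- stage("cluster", cluster_families(
    matches, proteins, config$cluster, config$scoring,
    annotation = config$annotation))
  arch <- stage("architect", build_architectures(
    domains$instances, proteins, config$cluster))
  orgs <- stage("organize", assign_organizations(arch))
  fam_classes <- domains$families$class
  menu <- class_menu(sum(fam_classes == "N"), sum(fam_classes == "CAT"),
                     sum(fam_classes == "C"))
  if (!is.null(config$annotation)) {
    ann <- config$annotation
    menu <- class_menu(sum(ann == "N"), sum(ann == "CAT"),
                       sum(ann == "C"))
  }
  coverage <- stage("coverage", coverage_stats(
    orgs, menu, n_total = length(proteins)))
  swaps <- stage("swaps", detect_domain_swaps(arch))
  M <- stage("matrix", presence_absence(arch))
  network <- NULL
  if (nrow(M) >= 2L && ncol(M) >= 1L) {
    # one network taxon per distinct architecture profile keeps the
    # splits readable (as circling organization groups does in figures)
    D <- stage("network", binary_distance(M, config$metric))
    network <- stage("network", neighbor_net(D))
  }
  cls_seqs <- class_sequences(domains$instances, proteins)
  incong <- stage("incongruence", incongruence_scan(
    cls_seqs, config$scoring, n_reps = config$n_reps,
    support_min = config$support_min, seed = config$seed))
  class_trees <- NULL
  summary <- list(
    n_proteins = length(proteins),
    n_matches = nrow(matches),
    n_pairs = attr(matches, "n_pairs"),
    n_families = nrow(domains$families),
    families_per_class = as.list(table(
      factor(fam_classes, levels = c("N", "CAT", "C", "UNASSIGNED")))),
    domain_menu_total = menu$n_N + menu$n_CAT + menu$n_C,
    possible_combinations = enumerate_combinations(menu),
    n_organizations = coverage$n_organizations,
    canonical_n = coverage$canonical_n,
    canonical_fraction = coverage$canonical_fraction,
    top4_fraction = if (nrow(orgs)) org_prevalence(orgs,
                                                   length(proteins)) else NA,
    n_swap_pairs = nrow(swaps),
    incongruent_pairs = if (nrow(incong))
      sum(incong$flagged) else 0L,
    seed = config$seed)

  if (!is.null(out_dir)) {
    write_tsv(matches[, setdiff(names(matches), c("qaln", "saln"))],
              outfile("matches.tsv"), meta)
    write_tsv(domains$instances, outfile("domains.tsv"), meta)
    write_domains_gff3(domains$instances, outfile("domains.gff3"), meta)
    write_tsv(domains$families, outfile("families.tsv"), meta)
    write_tsv(as.data.frame(arch), outfile("architectures.tsv"), meta)
    write_tsv(as.data.frame(orgs), outfile("organizations.tsv"), meta)
    write_tsv(swaps, outfile("swaps.tsv"), meta)
    write_tsv(data.frame(protein = rownames(M), M, check.names = FALSE),
              outfile("presence_absence.tsv"), meta)
    if (!is.null(network))
      write_splits_nexus(network, outfile("network.nex"),
                         comment = sprintf("lysmod config=%s seed=%d",
                                           config_hash(config),
                                           config$seed))
    write_tsv(as.data.frame(incong), outfile("incongruence.tsv"), meta)
    jsonlite::write_json(summary, outfile("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(matches = matches, domains = domains,
                 architectures = arch, organizations = orgs,
                 coverage = coverage, swaps = swaps, matrix = M,
                 network = network, class_trees = class_trees,
                 incongruence = incong, summary = summary,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "lysmod pipeline: %d proteins, %d domain families, %d organizations\n",
    s$n_proteins, s$n_families, s$n_organizations))
  cat(sprintf("  canonical three-domain fraction: %.3f\n",
              s$canonical_fraction))
  cat(sprintf("  possible combinations: %d; incongruent class pairs: %d\n",
              s$possible_combinations, s$incongruent_pairs))
  invisible(x)
}
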