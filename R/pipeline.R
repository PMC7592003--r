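#' Run the full reference-selection pipeline
#'
#' Orchestrates the complete workflow on a Cq matrix: dispersion screening,
#' the three stability algorithms (geNorm with its V_n recommendation,
#' NormFinder, comparative delta-Cq), the consensus ranking, and — when
#' group labels are available — combination building, combination scoring
#' and cross-normalization of the top candidates. Stages whose
#' preconditions are not met (e.g. NormFinder on a 2-gene panel, V series
#' on fewer than 3 genes) are skipped with a recorded warning instead of
#' aborting the run.
#'
#' The default combination stage pairs the consensus top gene with each of
#' the next `n_combo_partners` genes, scores those pairs as pseudo-genes
#' against the remaining panel, and cross-normalizes the top two genes and
#' their combination against each other.
#'
#' @param cq a Cq matrix, or path to a Cq table ([read_cq_table()]).
#' @param groups optional [sample_groups()] labels or path to a group table.
#' @param panel gene ids to analyze (default: all rows).
#' @param variant comparative delta-Cq variant (see [deltacq_stability()]).
#' @param v_threshold geNorm pairwise-variation cutoff (default 0.15).
#' @param m_threshold geNorm instability flag threshold (default 1.5).
#' @param alpha significance level for cross-normalization verdicts.
#' @param n_combo_partners how many partners to pair with the top gene.
#' @param evaluate_combos run the combination stage (default: whenever
#'   groups are supplied and the panel has >= 4 genes).
#' @param out_dir if non-`NULL`, write `report.json`, `ranking.tsv`,
#'   `dispersion.tsv` and (when computed) `combos.tsv` there.
#' @return object of class `"run_report"`: list with `provenance`,
#'   `dispersion`, `genorm`, `normfinder`, `deltacq`, `consensus`,
#'   `combo_eval`, `crossnorm`, `warnings`.
#' @export
run_pipeline <- function(cq, groups = NULL, panel = NULL,
                         variant = c("sample-mean", "pairwise"),
                         v_threshold = 0.15, m_threshold = 1.5,
                         alpha = 0.05, n_combo_partners = 3L,
                         evaluate_combos = NULL, out_dir = NULL) {
  variant <- match.arg(variant)
  warn_log <- character(0L)
  note <- function(msg) warn_log <<- c(warn_log, msg)
  quietly <- function(expr) withCallingHandlers(expr, warning = function(w) {
    note(conditionMessage(w)); invokeRestart("muffleWarning")
  })
  try_stage <- function(name, expr) {
    tryCatch(quietly(expr), error = function(e) {
      note(sprintf("%s skipped: %s", name, conditionMessage(e)))
      NULL
    })
  }

  provenance <- list(package_version = as.character(utils::packageVersion("refstab")),
                     variant = variant, v_threshold = v_threshold,
                     m_threshold = m_threshold, alpha = alpha)
  if (is.character(cq) && length(cq) == 1L) {
    provenance$cq_path <- cq
    provenance$cq_md5 <- unname(tools::md5sum(cq))
    cq <- read_cq_table(cq)
  }
  mat <- as_cq(cq)
  if (is.character(groups) && length(groups) == 1L) {
    provenance$groups_path <- groups
    provenance$groups_md5 <- unname(tools::md5sum(groups))
    groups <- read_groups(groups)
  }
  if (!is.null(groups)) groups <- align_groups(mat, groups)
  if (is.null(panel)) panel <- rownames(mat)
  mat <- cq_matrix(unclass(mat)[panel, , drop = FALSE],
                   max_cycles = attr(mat, "max_cycles") %||% 45)
  if (is.null(evaluate_combos))
    evaluate_combos <- !is.null(groups) && nrow(mat) >= 4L

  dispersion <- try_stage("dispersion", summarize_dispersion(mat))
  genorm <- try_stage("geNorm",
                      rank_genorm(mat, m_threshold = m_threshold,
                                  v_threshold = v_threshold))
  if (!is.null(genorm) && is.null(genorm$v))
    note("V-stage skipped: fewer than 3 genes, no pairwise variation series")
  normfinder <- try_stage("NormFinder", fit_normfinder(mat, groups))
  deltacq <- try_stage("comparative dCq",
                       deltacq_stability(mat, variant = variant))
  consensus <- if (!is.null(genorm) && !is.null(normfinder) &&
                   !is.null(deltacq))
    try_stage("consensus", overall_ranking(genorm, normfinder, deltacq))
  else {
    note("consensus skipped: not all three methods available")
    NULL
  }

  combo_eval <- NULL
  crossnorm <- NULL
  if (evaluate_combos && !is.null(consensus) && !is.null(groups)) {
    ranked <- consensus$gene
    top <- ranked[1L]
    partners <- ranked[seq(2L, min(1L + n_combo_partners, length(ranked)))]
    combos <- lapply(partners, function(p) combine_refs(mat, c(top, p)))
    if (length(combos) >= 2L)
      combo_eval <- try_stage("combination scoring",
                              evaluate_combinations(mat, combos, groups))
    crossnorm <- try_stage("cross-normalization",
                           cross_normalize(mat, groups,
                                           list(ranked[1L], ranked[2L],
                                                combine_refs(mat, ranked[1:2])),
                                           alpha = alpha,
                                           allow_overlap = TRUE))
  }

  report <- structure(list(provenance = provenance,
                           dispersion = dispersion,
                           genorm = genorm, normfinder = normfinder,
                           deltacq = deltacq, consensus = consensus,
                           combo_eval = combo_eval, crossnorm = crossnorm,
                           warnings = warn_log),
                      class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("refstab pipeline report\n=======================\n")
  if (!is.null(x$consensus)) print(x$consensus)
  if (!is.null(x$genorm) && !is.null(x$genorm$recommended_n))
    cat(sprintf("geNorm recommends %d reference gene(s)%s\n",
                x$genorm$recommended_n,
                if (isTRUE(x$genorm$all_v_above_threshold))
                  " (no V below threshold)" else ""))
  if (!is.null(x$combo_eval)) print(x$combo_eval)
  if (length(x$warnings))
    cat("Warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

# plain-list view of a report, for JSON serialization
report_as_list <- function(x) {
  genorm <- x$genorm
  list(
    provenance = x$provenance,
    dispersion = if (!is.null(x$dispersion)) as.data.frame(x$dispersion),
    genorm = if (!is.null(genorm)) list(
      ranking = genorm$ranking,
      m_value = as.list(genorm$m_value),
      elimination_order = genorm$elimination_order,
      unstable = genorm$unstable,
      v = as.list(genorm$v %||% numeric(0L)),
      recommended_n = genorm$recommended_n),
    normfinder = if (!is.null(x$normfinder)) list(
      mode = x$normfinder$mode,
      stability = as.list(x$normfinder$stability),
      ranking = x$normfinder$ranking),
    deltacq = if (!is.null(x$deltacq)) list(
      variant = x$deltacq$variant,
      stability = as.list(x$deltacq$stability),
      ranking = x$deltacq$ranking),
    consensus = if (!is.null(x$consensus)) as.data.frame(x$consensus),
    combinations = if (!is.null(x$combo_eval)) list(
      table = x$combo_eval$table,
      concordance = x$combo_eval$concordance),
    cross_normalization = if (!is.null(x$crossnorm)) list(
      alpha = x$crossnorm$alpha,
      pairs = x$crossnorm$pairs),
    warnings = x$warnings)
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (full-precision, self-contained) plus flat TSVs of
#' the main tables.
#'
#' @param x a [run_pipeline()] report.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(x, out_dir) {
  stopifnot(inherits(x, "run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, "report.json")
  jsonlite::write_json(report_as_list(x), paths, digits = NA,
                       auto_unbox = TRUE, null = "null")
  if (!is.null(x$dispersion)) {
    p <- file.path(out_dir, "dispersion.tsv")
    write_dispersion(x$dispersion, p); paths <- c(paths, p)
  }
  if (!is.null(x$consensus)) {
    p <- file.path(out_dir, "ranking.tsv")
    write_ranking(x$consensus, p); paths <- c(paths, p)
  }
  if (!is.null(x$combo_eval)) {
    p <- file.path(out_dir, "combos.tsv")
    utils::write.table(x$combo_eval$table, p, sep = "\t", quote = FALSE,
                       row.names = FALSE); paths <- c(paths, p)
  }
  invisible(paths)
}
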