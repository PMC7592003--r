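#' Build a combination reference
#'
#' Merges several reference genes "into a whole": the combined Cq of a
#' sample is the arithmetic mean of the member Cq values, i.e. the geometric
#' mean of the member quantities on the linear scale — the standard
#' multi-gene normalization factor. Samples where any member is undetected
#' are undetected in the combination.
#'
#' @param mat a Cq matrix.
#' @param members gene ids (>= 1, duplicates collapsed).
#' @param label display label; default members joined by `+`.
#' @return object of class `"combination_ref"`: list with `members`, `cq`
#'   (named per-sample combined Cq) and `label`.
#' @export
combine_refs <- function(mat, members, label = NULL) {
  mat <- as_cq(mat)
  members <- unique(as.character(members))
  if (!length(members)) stop("members must be nonempty", call. = FALSE)
  absent <- setdiff(members, rownames(mat))
  if (length(absent))
    stop("member gene(s) not in matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  sub <- unclass(mat)[members, , drop = FALSE]
  cq <- colMeans(sub)                       # NA wherever any member is NA
  structure(list(members = members,
                 cq = cq,
                 label = label %||% paste(members, collapse = "+")),
            class = "combination_ref")
}

#' @export
print.combination_ref <- function(x, ...) {
  cat(sprintf("Combination reference '%s' (%d member(s): %s)\n", x$label,
              length(x$members), paste(x$members, collapse = ", ")))
  invisible(x)
}

# normalize a candidate (gene id or combination_ref) to label/members/cq
candidate_parts <- function(mat, cand) {
  if (inherits(cand, "combination_ref"))
    list(label = cand$label, members = cand$members,
         cq = cand$cq[colnames(mat)])
  else if (is.character(cand) && length(cand) == 1L) {
    if (!cand %in% rownames(mat))
      stop("candidate '", cand, "' not in matrix", call. = FALSE)
    list(label = cand, members = cand, cq = unclass(mat)[cand, ])
  } else stop("candidates must be gene ids or combination_ref objects",
              call. = FALSE)
}

#' Cross-normalization evaluation of candidate references
#'
#' Evaluates candidate references (genes or combinations) by normalizing
#' each candidate to every other and testing the resulting `2^-dCq` relative
#' expression for differences across sample groups. A good reference pair
#' shows no group effect whichever member is treated as the target, so a
#' larger p-value reads as better stability; the verdict is `"stable"` only
#' when both the parametric and the nonparametric p exceed `alpha`.
#'
#' Tests: with two groups, equal-variance Student's t and Mann-Whitney
#' (Wilcoxon rank-sum); with three or more, one-way ANOVA and
#' Kruskal-Wallis. A constant expression vector makes the tests undefined
#' and is reported as `"degenerate"` with a warning rather than a silent
#' p of 1. Pairs sharing a gene (a combination normalized to one of its own
#' members) are skipped by default because they are partially
#' self-normalizing; set `allow_overlap = TRUE` to score them anyway with a
#' `partial_overlap` flag.
#'
#' @param mat a Cq matrix.
#' @param groups [sample_groups()] labels (>= 2 groups).
#' @param candidates list of gene ids and/or [combine_refs()] combinations
#'   (>= 2).
#' @param alpha significance threshold for the verdict (default 0.05).
#' @param allow_overlap score pairs whose target and reference share genes.
#' @return object of class `"crossnorm_report"`: list with `pairs` (one row
#'   per ordered target/reference pair: p-values, verdict, samples used,
#'   flags), `group_stats` (per-pair group mean +/- SD of relative
#'   expression) and `alpha`.
#' @export
cross_normalize <- function(mat, groups, candidates, alpha = 0.05,
                            allow_overlap = FALSE) {
  mat <- as_cq(mat)
  g_all <- align_groups(mat, groups)
  if (nlevels(g_all) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(candidates) < 2L)
    stop("need at least 2 candidates", call. = FALSE)
  parts <- lapply(candidates, candidate_parts, mat = mat)
  labels <- vapply(parts, `[[`, character(1L), "label")
  if (anyDuplicated(labels))
    stop("candidate labels must be unique", call. = FALSE)

  rows <- list()
  group_stats <- list()
  for (i in seq_along(parts)) for (j in seq_along(parts)) {
    if (i == j) next
    tg <- parts[[i]]; rf <- parts[[j]]
    overlap <- intersect(tg$members, rf$members)
    if (length(overlap) && !allow_overlap) {
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg$label, reference = rf$label, n_used = NA_integer_,
        p_parametric = NA_real_, p_nonparametric = NA_real_,
        verdict = "skipped", partial_overlap = TRUE,
        reason = paste("shared gene(s):", paste(overlap, collapse = ", ")),
        stringsAsFactors = FALSE)
      next
    }
    ok <- !is.na(tg$cq) & !is.na(rf$cq)
    expr <- 2^-(tg$cq[ok] - rf$cq[ok])
    gg <- droplevels(g_all[ok])
    usable <- table(gg)
    if (nlevels(gg) < 2L || any(usable < 2L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg$label, reference = rf$label, n_used = sum(ok),
        p_parametric = NA_real_, p_nonparametric = NA_real_,
        verdict = "skipped", partial_overlap = length(overlap) > 0L,
        reason = "a group has fewer than 2 usable samples",
        stringsAsFactors = FALSE)
      next
    }
    key <- paste(tg$label, "vs", rf$label)
    gs <- data.frame(group = levels(gg),
                     n = as.integer(usable),
                     mean = as.numeric(tapply(expr, gg, mean)),
                     sd = as.numeric(tapply(expr, gg, stats::sd)),
                     stringsAsFactors = FALSE)
    group_stats[[key]] <- gs
    if (stats::var(expr) < .Machine$double.eps * max(1, mean(expr))^2) {
      warning("degenerate (constant) expression for ", key,
              "; p undefined", call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg$label, reference = rf$label, n_used = sum(ok),
        p_parametric = NA_real_, p_nonparametric = NA_real_,
        verdict = "degenerate", partial_overlap = length(overlap) > 0L,
        reason = "constant relative expression", stringsAsFactors = FALSE)
      next
    }
    if (nlevels(gg) == 2L) {
      p_par <- stats::t.test(expr ~ gg, var.equal = TRUE)$p.value
      p_np <- suppressWarnings(stats::wilcox.test(expr ~ gg)$p.value)
    } else {
      p_par <- stats::anova(stats::lm(expr ~ gg))[["Pr(>F)"]][1L]
      p_np <- stats::kruskal.test(expr, gg)$p.value
    }
    verdict <- if (p_par > alpha && p_np > alpha) "stable" else "unstable"
    rows[[length(rows) + 1L]] <- data.frame(
      target = tg$label, reference = rf$label, n_used = sum(ok),
      p_parametric = p_par, p_nonparametric = p_np,
      verdict = verdict, partial_overlap = length(overlap) > 0L,
      reason = "", stringsAsFactors = FALSE)
  }
  out <- list(pairs = do.call(rbind, rows), group_stats = group_stats,
              alpha = alpha)
  class(out) <- "crossnorm_report"
  out
}

#' @export
print.crossnorm_report <- function(x, ...) {
  cat(sprintf("Cross-normalization report (alpha = %g)\n", x$alpha))
  y <- x$pairs
  y$p_parametric <- signif(y$p_parametric, 3)
  y$p_nonparametric <- signif(y$p_nonparametric, 3)
  print(y, ...)
  invisible(x)
}

#' Score combination references as pseudo-genes
#'
#' The Cq vectors of all combinations are appended to the candidate matrix
#' as pseudo-genes and their stability is computed with the requested
#' backends (geNorm M, NormFinder stability, comparative delta-Cq). Every
#' gene that is a member of any combination is removed from the comparison
#' panel first — a combination is trivially correlated with its members,
#' which would deflate its pairwise SDs — so all combinations are judged
#' together against the same set of remaining references. Combinations are
#' then ranked per backend and the agreement between backend orderings is
#' summarized by the mean pairwise Spearman correlation.
#'
#' @param mat a Cq matrix whose rows are the candidate reference panel.
#' @param combos list of >= 2 [combine_refs()] combinations (or character
#'   vectors of member ids, combined on the fly).
#' @param groups optional [sample_groups()] labels, used by the NormFinder
#'   backend.
#' @param backends subset of `c("genorm", "normfinder", "deltacq")`.
#' @return object of class `"combo_eval"`: list with `table` (per-combo
#'   values and ranks per backend), `concordance` (mean pairwise Spearman
#'   rho between backend rankings) and `identical_order`.
#' @export
evaluate_combinations <- function(mat, combos, groups = NULL,
                                  backends = c("genorm", "normfinder",
                                               "deltacq")) {
  mat <- as_cq(mat)
  backends <- match.arg(backends, several.ok = TRUE)
  if (length(combos) < 2L)
    stop("need at least 2 combinations to rank", call. = FALSE)
  combos <- lapply(combos, function(cb)
    if (inherits(cb, "combination_ref")) cb else combine_refs(mat, cb))
  labels <- vapply(combos, `[[`, character(1L), "label")
  if (anyDuplicated(labels))
    stop("combination labels must be unique", call. = FALSE)

  members_all <- unique(unlist(lapply(combos, `[[`, "members")))
  rest <- setdiff(rownames(mat), members_all)
  if (!length(rest))
    stop("the combinations use the whole panel; no comparators left",
         call. = FALSE)
  pseudo <- do.call(rbind, lapply(combos, `[[`, "cq"))
  rownames(pseudo) <- labels
  aug <- cq_matrix(rbind(unclass(mat)[rest, , drop = FALSE], pseudo),
                   max_cycles = attr(mat, "max_cycles") %||% 45)
  scores <- matrix(NA_real_, length(combos), length(backends),
                   dimnames = list(labels, backends))
  if ("genorm" %in% backends)
    scores[, "genorm"] <- m_values(aug)[labels]
  if ("normfinder" %in% backends)
    scores[, "normfinder"] <- fit_normfinder(aug, groups)$stability[labels]
  if ("deltacq" %in% backends)
    scores[, "deltacq"] <- deltacq_stability(aug)$stability[labels]
  ranks <- apply(scores, 2L, function(v) order(order(v, seq_along(v))))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = length(combos))
  colnames(ranks) <- paste0(backends, "_rank")
  tab <- data.frame(combination = labels,
                    members = vapply(combos, function(cb)
                      paste(cb$members, collapse = ","), character(1L)),
                    scores, ranks, row.names = NULL, stringsAsFactors = FALSE)
  conc <- NA_real_
  if (length(backends) >= 2L) {
    cors <- utils::combn(seq_along(backends), 2L, function(idx)
      stats::cor(ranks[, idx[1L]], ranks[, idx[2L]], method = "spearman"))
    conc <- mean(cors)
  }
  out <- list(table = tab,
              concordance = conc,
              identical_order = length(backends) < 2L ||
                all(apply(ranks, 1L, function(r) length(unique(r)) == 1L)))
  class(out) <- "combo_eval"
  out
}

#' @export
print.combo_eval <- function(x, ...) {
  cat("Combination stability (lower = more stable)\n")
  y <- x$table
  for (cc in intersect(c("genorm", "normfinder", "deltacq"), names(y)))
    y[[cc]] <- round(y[[cc]], 3)
  print(y, ...)
  if (!is.na(x$concordance))
    cat(sprintf("Backend rank concordance (mean Spearman rho): %.2f%s\n",
                x$concordance,
                if (x$identical_order) " (identical orderings)" else ""))
  invisible(x)
}
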