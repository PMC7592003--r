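#' NormFinder model-based stability estimation
#'
#' Implements the NormFinder analysis-of-variance model on the Cq (log2)
#' scale. Each Cq value is decomposed as gene effect + sample/group effect +
#' gene-by-group interaction + noise; sample effects are removed using the
#' per-sample average across the candidate genes, which is why the model
#' needs at least 3 genes to borrow information from.
#'
#' For each gene i and group g the intragroup variance `sigma2[i,g]` is the
#' two-way residual variance with the small-sample bias correction (the raw
#' residual variance both under-counts the gene's own noise, by a factor
#' (I-2)/I for I genes, and absorbs a share of every other gene's noise
#' through the sample average; the correction inverts that), floored at 0.
#' The intergroup difference `d[i,g]` is the gene-by-group interaction of
#' group-mean Cq (groups weighted equally, not by size). Because the
#' observed interaction partly reflects sampling noise, `d` is shrunk toward
#' 0 by `gamma2 / (gamma2 + sigma2[i,g]/n_g)`, where `gamma2` is the
#' across-genes variance of `d` minus the average sampling variance, floored
#' at 0.
#'
#' The stability value of gene i is the average over groups of
#' `|d_shrunk[i,g]| + sqrt(var(d_shrunk[i,g]))` — a candidate whose
#' expression differs systematically between groups, or is measured noisily,
#' scores high; low values mark good references. Without groups (or with a
#' single group) the stability value reduces to the gene's bias-corrected
#' residual SD.
#'
#' Samples with any undetected gene in the panel are dropped with a warning:
#' the per-sample average across genes, central to the model, is otherwise
#' not comparable between samples.
#'
#' @param mat a Cq matrix (>= 3 genes).
#' @param groups optional [sample_groups()] labels; with >= 2 groups (each
#'   >= 2 complete samples) the grouped estimator is used, otherwise the
#'   pooled one.
#' @param panel gene ids to analyze (default all rows).
#' @return object of class `"normfinder_result"`: list with `stability`
#'   (named, lower = more stable), `ranking`, `sigma2` (gene x group
#'   intragroup variances), `d` and `d_shrunk` (gene x group intergroup
#'   differences, grouped mode only), `gamma2`, `n_per_group`, `mode`.
#' @references Andersen, C.L., Jensen, J.L. and Orntoft, T.F. (2004)
#'   Normalization of real-time quantitative RT-PCR data: a model-based
#'   variance estimation approach. Cancer Research 64, 5245-5250.
#' @export
fit_normfinder <- function(mat, groups = NULL, panel = rownames(mat)) {
  mat <- as_cq(mat)
  panel <- as.character(panel)
  absent <- setdiff(panel, rownames(mat))
  if (length(absent))
    stop("panel gene(s) not in matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  x <- unclass(mat)[panel, , drop = FALSE]
  I <- nrow(x)
  if (I < 3L)
    stop("NormFinder needs at least 3 genes (cross-gene information)",
         call. = FALSE)
  complete <- colSums(is.na(x)) == 0L
  if (!all(complete)) {
    warning(sum(!complete), " sample(s) dropped: undetected value in panel",
            call. = FALSE)
    x <- x[, complete, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("fewer than 2 complete samples", call. = FALSE)

  if (is.null(groups)) {
    g <- factor(rep("all", ncol(x)))
  } else {
    g <- align_groups(mat, groups)[complete]
    g <- droplevels(g)
  }
  grouped <- nlevels(g) >= 2L
  if (grouped) {
    n_g <- table(g)
    if (any(n_g < 2L))
      stop("every group needs >= 2 complete samples; offending: ",
           paste(names(n_g)[n_g < 2L], collapse = ", "), call. = FALSE)
  }

  lv <- levels(g)
  G <- length(lv)
  sigma2 <- matrix(NA_real_, I, G, dimnames = list(panel, lv))
  gg_mean <- matrix(NA_real_, I, G, dimnames = list(panel, lv))
  n_per_group <- stats::setNames(integer(G), lv)
  for (k in seq_len(G)) {
    xg <- x[, g == lv[k], drop = FALSE]
    n <- ncol(xg)
    n_per_group[k] <- n
    gm <- rowMeans(xg)
    sm <- colMeans(xg)
    r <- xg - outer(gm, rep(1, n)) - outer(rep(1, I), sm) + mean(xg)
    s2 <- rowSums(r^2) / (n - 1L)
    # bias correction: invert E[s2_i] = (1-2/I) sigma2_i + mean(sigma2)/I
    sig <- (s2 - sum(s2) / (I * (I - 1L))) * I / (I - 2L)
    sigma2[, k] <- pmax(sig, 0)
    gg_mean[, k] <- gm
  }

  if (!grouped) {
    rho <- sqrt(sigma2[, 1L])
    res <- list(stability = rho,
                ranking = names(sort(rho)),
                sigma2 = sigma2, d = NULL, d_shrunk = NULL, gamma2 = NULL,
                n_per_group = n_per_group, mode = "ungrouped")
    class(res) <- "normfinder_result"
    return(res)
  }

  # gene-by-group interaction of group means, groups weighted equally
  gene_mean <- rowMeans(gg_mean)
  group_mean <- colMeans(gg_mean)
  grand <- mean(gg_mean)
  d <- gg_mean - outer(gene_mean, rep(1, G)) -
    outer(rep(1, I), group_mean) + grand
  samp_var <- sweep(sigma2, 2L, as.numeric(n_per_group), `/`)  # var of d-hat
  gamma2 <- max(0, mean(colSums(d^2) / (I - 1L)) - mean(samp_var))
  shrink <- if (gamma2 > 0) gamma2 / (gamma2 + samp_var) else samp_var * 0
  d_shrunk <- d * shrink
  var_post <- samp_var * shrink                 # = gamma2*sv/(gamma2+sv)
  rho <- rowMeans(abs(d_shrunk) + sqrt(var_post))

  res <- list(stability = rho,
              ranking = names(sort(rho)),
              sigma2 = sigma2, d = d, d_shrunk = d_shrunk, gamma2 = gamma2,
              n_per_group = n_per_group, mode = "grouped")
  class(res) <- "normfinder_result"
  res
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat(sprintf("NormFinder stability (%s mode)\n", x$mode))
  print(data.frame(rank = seq_along(x$ranking), gene = x$ranking,
                   stability = round(x$stability[x$ranking], 3),
                   row.names = NULL))
  invisible(x)
}
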