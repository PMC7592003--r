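#' Comparative delta-Cq stability
#'
#' Two readings of the comparative delta-Cq method are provided:
#'
#' * `"sample-mean"` (default): each sample is centered by its mean Cq over
#'   the panel (`dCq[j,s] = Cq[j,s] - mean_over_genes(Cq[.,s])`) and a
#'   gene's stability is the sample SD across samples of its centered
#'   values. A gene that moves with the panel average has dCq constant and
#'   stability 0.
#' * `"pairwise"`: the classical comparative delta-Cq statistic — the mean,
#'   over all other panel genes k, of the SD across samples of
#'   `Cq[j] - Cq[k]`. This is exactly the mean of [pairwise_variation()]
#'   over partners, so it coincides with the geNorm M of the full panel.
#'
#' With undetected reactions, per-sample means use the genes detected in
#' that sample (counted in `n_incomplete_samples`) and pairwise SDs use
#' pairwise-complete samples.
#'
#' @param mat a Cq matrix.
#' @param variant `"sample-mean"` or `"pairwise"`.
#' @param panel gene ids (default all rows); >= 2 genes (>= 3 for the
#'   pairwise variant) and >= 2 samples.
#' @return object of class `"deltacq_result"`: list with `stability` (named,
#'   cycles; lower = more stable), `ranking`, `variant`, `delta_cq`
#'   (gene x sample matrix of centered values, sample-mean variant only),
#'   `n_incomplete_samples`.
#' @export
deltacq_stability <- function(mat, variant = c("sample-mean", "pairwise"),
                              panel = rownames(mat)) {
  variant <- match.arg(variant)
  mat <- as_cq(mat)
  panel <- as.character(panel)
  absent <- setdiff(panel, rownames(mat))
  if (length(absent))
    stop("panel gene(s) not in matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  x <- unclass(mat)[panel, , drop = FALSE]
  if (ncol(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 genes", call. = FALSE)

  if (variant == "sample-mean") {
    sample_mean <- colMeans(x, na.rm = TRUE)
    dcq <- sweep(x, 2L, sample_mean)
    stab <- apply(dcq, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) return(NA_real_)
      stats::sd(v)
    })
    n_incomplete <- sum(colSums(is.na(x)) > 0L)
    res <- list(stability = stab, variant = variant, delta_cq = dcq,
                n_incomplete_samples = n_incomplete)
  } else {
    if (nrow(x) < 3L)
      stop("pairwise variant needs at least 3 genes", call. = FALSE)
    k <- nrow(x)
    pv <- matrix(0, k, k, dimnames = list(panel, panel))
    for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k)) {
      v <- pairwise_variation(mat, panel[a], panel[b])
      pv[a, b] <- pv[b, a] <- v
    }
    stab <- rowSums(pv) / (k - 1L)
    res <- list(stability = stab, variant = variant, delta_cq = NULL,
                n_incomplete_samples = sum(colSums(is.na(x)) > 0L))
  }
  res$ranking <- names(sort(res$stability, na.last = TRUE))
  class(res) <- "deltacq_result"
  res
}

#' @export
print.deltacq_result <- function(x, ...) {
  cat(sprintf("Comparative dCq stability (%s variant)\n", x$variant))
  print(data.frame(rank = seq_along(x$ranking), gene = x$ranking,
                   mean_sd = round(x$stability[x$ranking], 3),
                   row.names = NULL))
  invisible(x)
}
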