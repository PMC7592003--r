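#' Consensus stability ranking across the three methods
#'
#' Merges a geNorm trace, a NormFinder fit and a comparative delta-Cq result
#' (all over the same gene panel) into one table: per-method stability value
#' and rank, plus a consensus rank defined as the rank of the arithmetic
#' mean of the three per-method ranks. Mean-rank aggregation is used because
#' the three statistics live on different scales; ties in the mean rank are
#' broken by the NormFinder value, then by panel order. Genes whose geNorm
#' M exceeds the trace's threshold are flagged unstable.
#'
#' @param genorm a [rank_genorm()] trace.
#' @param normfinder a [fit_normfinder()] result.
#' @param deltacq a [deltacq_stability()] result.
#' @return a `data.frame` of class `"stability_ranking"` ordered by
#'   consensus rank, with columns `consensus_rank`, `gene`, `genorm_m`,
#'   `genorm_rank`, `normfinder_stability`, `normfinder_rank`,
#'   `deltacq_stability`, `deltacq_rank`, `mean_rank`, `unstable_m`.
#' @export
overall_ranking <- function(genorm, normfinder, deltacq) {
  stopifnot(inherits(genorm, "genorm_trace"),
            inherits(normfinder, "normfinder_result"),
            inherits(deltacq, "deltacq_result"))
  genes <- genorm$rounds[[1L]]$panel          # original panel order
  check <- function(got, method) {
    extra <- setdiff(got, genes); missing <- setdiff(genes, got)
    if (length(extra) || length(missing))
      stop("gene sets differ between geNorm and ", method,
           if (length(missing)) paste0("; missing: ",
                                       paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; extra: ",
                                     paste(extra, collapse = ", ")),
           call. = FALSE)
  }
  check(names(normfinder$stability), "NormFinder")
  check(names(deltacq$stability), "comparative dCq")

  rank_of <- function(ranking) {
    stats::setNames(match(genes, ranking), genes)
  }
  # deterministic per-method ranks: value order with panel order as tie-break
  value_rank <- function(v) {
    v <- v[genes]
    stats::setNames(order(order(v, seq_along(v))), genes)
  }
  g_rank <- rank_of(genorm$ranking)
  n_rank <- value_rank(normfinder$stability)
  d_rank <- value_rank(deltacq$stability)
  mean_rank <- (g_rank + n_rank + d_rank) / 3
  nf_val <- normfinder$stability[genes]
  consensus <- stats::setNames(order(order(mean_rank, nf_val, seq_along(genes))),
                               genes)
  out <- data.frame(consensus_rank = consensus,
                    gene = genes,
                    genorm_m = as.numeric(genorm$m_value[genes]),
                    genorm_rank = g_rank,
                    normfinder_stability = as.numeric(nf_val),
                    normfinder_rank = n_rank,
                    deltacq_stability = as.numeric(deltacq$stability[genes]),
                    deltacq_rank = d_rank,
                    mean_rank = mean_rank,
                    unstable_m = genes %in% genorm$unstable,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$consensus_rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stability_ranking", class(out))
  out
}

#' @export
print.stability_ranking <- function(x, ...) {
  y <- as.data.frame(x)
  for (cc in c("genorm_m", "normfinder_stability", "deltacq_stability",
               "mean_rank"))
    y[[cc]] <- round(y[[cc]], 3)
  cat("Overall stability ranking (lower values = more stable)\n")
  print(y, ...)
  invisible(x)
}

#' Write a stability ranking as TSV
#'
#' @param x result of [overall_ranking()].
#' @param path output path.
#' @export
write_ranking <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
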