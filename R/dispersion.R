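#' Coefficient of variation of Cq values
#'
#' CV on the Cq scale, reported as a percentage of the mean cycle number:
#' `sd / mean * 100`. Used as a first-pass screen for candidate references
#' (a tightly clustered Cq distribution gives a small CV).
#'
#' @param mean mean Cq (cycles), must be positive.
#' @param sd standard deviation of Cq (cycles), non-negative.
#' @return CV in percent.
#' @examples
#' cv(28.34, 1.35)  # 4.76...
#' @export
cv <- function(mean, sd) {
  if (any(!is.finite(mean)) || any(mean <= 0))
    stop("CV undefined for non-positive mean Cq", call. = FALSE)
  if (any(!is.finite(sd)) || any(sd < 0))
    stop("sd must be non-negative", call. = FALSE)
  sd / mean * 100
}

#' Per-gene dispersion screening of raw Cq values
#'
#' Computes, for every gene, the arithmetic mean Cq, sample SD (n-1
#' denominator), interquartile range (type-7 quartiles, the R default), and
#' CV (percent of mean), each over that gene's detected samples. This is the
#' screening stage that precedes the model-based stability algorithms:
#' candidates with small SD/IQR/CV and high abundance (low mean Cq) move
#' forward.
#'
#' @param mat a Cq matrix.
#' @param sort_by_cv if `TRUE`, order rows by ascending CV (genes with
#'   undefined statistics go last).
#' @return a `data.frame` of class `"dispersion_summary"` with columns
#'   `gene`, `n_used`, `mean`, `sd`, `iqr`, `cv`. Genes with fewer than two
#'   detected samples get `NA` statistics and a warning.
#' @export
summarize_dispersion <- function(mat, sort_by_cv = FALSE) {
  mat <- as_cq(mat)
  stats_one <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < 2L)
      return(c(n_used = n, mean = NA_real_, sd = NA_real_,
               iqr = NA_real_, cv = NA_real_))
    m <- mean(v)
    s <- stats::sd(v)
    c(n_used = n, mean = m, sd = s,
      iqr = stats::IQR(v, type = 7),
      cv = cv(m, s))
  }
  res <- t(apply(unclass(mat), 1L, stats_one))
  out <- data.frame(gene = rownames(mat), res, row.names = NULL,
                    stringsAsFactors = FALSE)
  bad <- out$gene[out$n_used < 2L]
  if (length(bad))
    warning("gene(s) with <2 detected samples, statistics undefined: ",
            paste(bad, collapse = ", "), call. = FALSE)
  if (sort_by_cv) out <- out[order(out$cv, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dispersion_summary", class(out))
  out
}

#' @export
print.dispersion_summary <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1L)) & names(y) != "n_used"
  y[num] <- lapply(y[num], round, digits = digits)
  cat("Cq dispersion summary (mean/SD/IQR in cycles, CV in % of mean Cq)\n")
  print(y, ...)
  invisible(x)
}

#' Write a dispersion summary as TSV
#'
#' Full-precision tabular output (`gene`, `mean`, `sd`, `iqr`, `cv`,
#' `n_used`); round for display only.
#'
#' @param x result of [summarize_dispersion()].
#' @param path output path.
#' @export
write_dispersion <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
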