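#' Pairwise variation between two genes
#'
#' The geNorm building block: the sample standard deviation, across samples,
#' of the Cq difference `Cq_j - Cq_k`. Because Cq is minus log2 expression up
#' to an additive constant, this equals the SD of the log2 expression ratio
#' of the two genes. Two genes that covary perfectly (ideal co-regulated
#' references) give 0.
#'
#' @param mat a Cq matrix.
#' @param gene_j,gene_k gene ids.
#' @return SD of the per-sample Cq difference (log2-ratio scale), computed on
#'   samples where both genes are detected.
#' @export
pairwise_variation <- function(mat, gene_j, gene_k) {
  mat <- as_cq(mat)
  for (g in c(gene_j, gene_k))
    if (!g %in% rownames(mat)) stop("gene '", g, "' not in matrix", call. = FALSE)
  d <- mat[gene_j, ] - mat[gene_k, ]
  d <- d[!is.na(d)]
  if (length(d) < 2L)
    stop("fewer than 2 samples where both '", gene_j, "' and '", gene_k,
         "' are detected", call. = FALSE)
  stats::sd(d)
}

#' geNorm M values for a gene panel
#'
#' The expression stability measure M of gene j is the arithmetic mean of
#' its pairwise variations against every other gene in the panel. Lower M
#' means the gene tracks the rest of the panel more tightly, i.e. is a
#' better reference. Each pairwise SD uses pairwise-complete samples.
#'
#' @param mat a Cq matrix.
#' @param panel gene ids to analyze (default: all rows). Must have >= 2.
#' @return named numeric vector of M values (>= 0), one per panel gene.
#' @export
m_values <- function(mat, panel = rownames(mat)) {
  mat <- as_cq(mat)
  panel <- as.character(panel)
  if (length(panel) < 2L) stop("panel needs at least 2 genes", call. = FALSE)
  absent <- setdiff(panel, rownames(mat))
  if (length(absent))
    stop("panel gene(s) not in matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  k <- length(panel)
  pv <- matrix(0, k, k, dimnames = list(panel, panel))
  for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k)) {
    v <- pairwise_variation(mat, panel[a], panel[b])
    pv[a, b] <- pv[b, a] <- v
  }
  rowSums(pv) / (k - 1L)
}

#' geNorm stepwise elimination
#'
#' Runs the full geNorm ranking: M values are computed for the panel, the
#' gene with the highest M is removed, and M is recomputed on the remainder,
#' until only two genes are left. The stability ranking is the reverse of
#' the elimination order; the algorithm cannot order the final two genes, so
#' they are reported as the most stable pair, ordered by their final-round M
#' for presentation. Ties in elimination (equal maximum M) remove the gene
#' appearing later in the panel order, so the trace is deterministic.
#'
#' Each gene is reported with the M value it had in the round it was
#' eliminated (the value usually plotted in geNorm stability charts); a gene
#' whose reported M exceeds `m_threshold` is flagged unstable (1.5 is the
#' conventional ceiling below which a reference is considered acceptable).
#' When the panel has at least 4 genes the pairwise-variation series V_n is
#' also computed via [pairwise_v()].
#'
#' @param mat a Cq matrix.
#' @param panel gene ids (default all rows); >= 2, >= 3 for a nontrivial
#'   trace.
#' @param m_threshold instability flag threshold on M (default 1.5).
#' @param v_threshold threshold passed to [pairwise_v()] (default 0.15).
#' @return object of class `"genorm_trace"`: list with `ranking` (gene ids,
#'   most stable first), `m_value` (reported M per gene, in `ranking`
#'   order), `elimination_order`, `rounds` (per-round panels and M values),
#'   `stable_pair`, `unstable` (flagged genes), and — when computable —
#'   `v` / `recommended_n` from [pairwise_v()].
#' @export
rank_genorm <- function(mat, panel = rownames(mat), m_threshold = 1.5,
                        v_threshold = 0.15) {
  mat <- as_cq(mat)
  panel <- as.character(panel)
  if (length(panel) < 2L) stop("panel needs at least 2 genes", call. = FALSE)
  remaining <- panel
  rounds <- list()
  eliminated <- character(0L)
  reported_m <- stats::setNames(numeric(length(panel)), panel)
  while (length(remaining) >= 2L) {
    m <- m_values(mat, remaining)
    rounds[[length(rounds) + 1L]] <- list(panel = remaining, m = m)
    if (length(remaining) == 2L) {
      reported_m[remaining] <- m
      break
    }
    # ties: drop the gene later in input order (which.max picks the first
    # maximum, so scan from the end)
    worst <- remaining[max(which(m == max(m)))]
    reported_m[worst] <- m[worst]
    eliminated <- c(eliminated, worst)
    remaining <- setdiff(remaining, worst)
  }
  final_m <- rounds[[length(rounds)]]$m
  pair_order <- names(sort(final_m))         # presentation order of the pair
  ranking <- c(pair_order, rev(eliminated))
  out <- list(ranking = ranking,
              m_value = reported_m[ranking],
              elimination_order = eliminated,
              rounds = rounds,
              stable_pair = sort(names(final_m)),
              m_threshold = m_threshold,
              unstable = names(reported_m)[reported_m > m_threshold])
  if (length(panel) >= 3L) {
    v <- pairwise_v(mat, ranking, threshold = v_threshold)
    out$v <- v$v
    out$recommended_n <- v$recommended_n
    out$all_v_above_threshold <- v$none_below_threshold
  }
  class(out) <- "genorm_trace"
  out
}

#' @export
print.genorm_trace <- function(x, ...) {
  cat("geNorm stability trace\n")
  print(data.frame(rank = seq_along(x$ranking), gene = x$ranking,
                   M = round(x$m_value, 3),
                   unstable = x$ranking %in% x$unstable))
  if (!is.null(x$v)) {
    cat("Pairwise variation V_n/V_n+1:",
        paste(sprintf("V%d=%.3f", seq_along(x$v) + 1L, x$v), collapse = ", "),
        "\n")
    cat("Recommended number of references:", x$recommended_n,
        if (isTRUE(x$all_v_above_threshold)) "(no V below threshold)" else "",
        "\n")
  }
  invisible(x)
}

#' geNorm pairwise variation V and optimal reference count
#'
#' For a stability-ordered gene list, the normalization factor NF_n of a
#' sample is the arithmetic mean Cq of the n most stable genes (equivalently
#' the geometric mean of their linear quantities). V_n is the SD across
#' samples of `NF_n - NF_(n+1)`: how much the normalizer changes when the
#' (n+1)-th gene is added. The smallest n (>= 2) with V_n below the
#' threshold is the recommended number of references; if no V qualifies the
#' full panel size is returned with `none_below_threshold = TRUE`.
#'
#' @param mat a Cq matrix.
#' @param ranked_genes gene ids ordered most stable first, length >= 3.
#' @param threshold V cutoff (default 0.15, the conventional value).
#' @return list with `v` (named `V2`, `V3`, ...), `recommended_n`,
#'   `none_below_threshold`, `threshold`, and `n_samples_used` per V.
#' @export
pairwise_v <- function(mat, ranked_genes, threshold = 0.15) {
  mat <- as_cq(mat)
  ranked_genes <- as.character(ranked_genes)
  if (length(ranked_genes) < 3L)
    stop("need at least 3 ranked genes to compute any V", call. = FALSE)
  absent <- setdiff(ranked_genes, rownames(mat))
  if (length(absent))
    stop("gene(s) not in matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  K <- length(ranked_genes)
  ns <- integer(K - 2L)
  v <- stats::setNames(numeric(K - 2L), paste0("V", seq(2L, K - 1L)))
  for (n in seq(2L, K - 1L)) {
    sub <- mat[ranked_genes[seq_len(n + 1L)], , drop = FALSE]
    ok <- colSums(is.na(sub)) == 0L            # complete across the n+1 genes
    if (sum(ok) < 2L)
      stop("fewer than 2 samples complete across the top ", n + 1L, " genes",
           call. = FALSE)
    nf_n <- colMeans(sub[seq_len(n), ok, drop = FALSE])
    nf_n1 <- colMeans(sub[, ok, drop = FALSE])
    v[n - 1L] <- stats::sd(nf_n - nf_n1)
    ns[n - 1L] <- sum(ok)
  }
  below <- which(v < threshold)
  list(v = v,
       recommended_n = if (length(below)) unname(below[1L]) + 1L else K,
       none_below_threshold = !length(below),
       threshold = threshold,
       n_samples_used = ns)
}
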