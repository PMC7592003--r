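#' Configure a synthetic serum-miRNA Cq experiment
#'
#' Describes a simulated RT-qPCR candidate-reference study: patient groups
#' with fixed sizes, gene archetypes (baseline Cq, within-group noise SD,
#' optional per-group shifts modelling disease-dependent expression), an
#' optional sample-level plate/handling effect, an optional exogenous
#' spike-in row, and a missingness (reaction dropout) rate. The generator
#' draws `Cq[g, s] = baseline_g + shift[g, group(s)] + plate_s +
#' Normal(0, sd_g)` — Gaussian noise on the cycle scale, i.e. log-normal
#' expression.
#'
#' @param genes `data.frame` with columns `gene`, `baseline` (cycles) and
#'   `sd` (cycles, >= 0).
#' @param group_sizes named integer vector, group label -> n (each >= 2).
#'   Default mirrors a four-arm liver-disease cohort: HCC 33, CHB 21,
#'   cirrhosis 23, healthy 28.
#' @param shifts optional gene x group matrix of Cq offsets (default all 0);
#'   dimnames must match `genes$gene` and `names(group_sizes)`.
#' @param plate_sd SD of a shared per-sample offset (cycles, default 0).
#' @param missing_rate probability a reaction drops out (default 0).
#' @param spike_in optional `list(id=, baseline=, sd=)` appended as an
#'   exogenous control row (group shifts never apply to it).
#' @param max_cycles passed through to the generated matrix.
#' @return validated object of class `"synthetic_config"`.
#' @seealso [generate_cq()], [default_panel()]
#' @export
synthetic_config <- function(genes,
                             group_sizes = c(HCC = 33, CHB = 21,
                                             cirrhosis = 23, healthy = 28),
                             shifts = NULL, plate_sd = 0, missing_rate = 0,
                             spike_in = NULL, max_cycles = 45) {
  if (!is.data.frame(genes) ||
      !all(c("gene", "baseline", "sd") %in% names(genes)))
    stop("genes must be a data.frame with columns gene, baseline, sd",
         call. = FALSE)
  if (anyDuplicated(genes$gene)) stop("duplicate gene ids", call. = FALSE)
  if (any(!is.finite(genes$baseline)) || any(genes$baseline < 0) ||
      any(genes$baseline > max_cycles))
    stop("baselines must lie in [0, max_cycles]", call. = FALSE)
  if (any(!is.finite(genes$sd)) || any(genes$sd < 0))
    stop("gene SDs must be >= 0", call. = FALSE)
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be named by group label", call. = FALSE)
  if (any(group_sizes < 2L)) stop("each group needs n >= 2", call. = FALSE)
  if (is.null(shifts))
    shifts <- matrix(0, nrow(genes), length(group_sizes),
                     dimnames = list(genes$gene, names(group_sizes)))
  shifts <- as.matrix(shifts)
  if (!identical(rownames(shifts), as.character(genes$gene)) ||
      !identical(colnames(shifts), names(group_sizes)))
    stop("shifts dimnames must match genes$gene x names(group_sizes)",
         call. = FALSE)
  if (length(plate_sd) != 1L || !is.finite(plate_sd) || plate_sd < 0)
    stop("plate_sd must be a single value >= 0", call. = FALSE)
  if (length(missing_rate) != 1L || !is.finite(missing_rate) ||
      missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  if (!is.null(spike_in)) {
    if (!is.list(spike_in) || !all(c("id", "baseline", "sd") %in% names(spike_in)))
      stop("spike_in must be list(id=, baseline=, sd=)", call. = FALSE)
    if (spike_in$id %in% genes$gene)
      stop("spike-in id collides with a gene id", call. = FALSE)
  }
  structure(list(genes = genes, group_sizes = group_sizes, shifts = shifts,
                 plate_sd = plate_sd, missing_rate = missing_rate,
                 spike_in = spike_in, max_cycles = max_cycles),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("Synthetic Cq design: %d gene(s)%s, groups %s\n",
              nrow(x$genes),
              if (is.null(x$spike_in)) "" else " + spike-in",
              paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", ")))
  print(x$genes, ...)
  invisible(x)
}

#' Default six-gene reference panel
#'
#' The fixture used throughout validation: one designed-stable candidate
#' (`miR-S`, within-group SD 0.45 cycles at an abundant baseline of 24.5 —
#' the profile of a good serum miRNA normalizer), four intermediate
#' candidates with SDs 0.9-1.5 at baselines 26.5-33.2 (spanning the Cq
#' range typical of candidate serum miRNAs), and a `U6-like` small RNA with
#' SD 2.0 plus a +1.5-cycle shift in the HCC group, modelling the commonly
#' observed disease-dependent instability of U6 in serum. Group sizes are
#' the default four-arm cohort (33/21/23/28).
#'
#' @return a [synthetic_config()].
#' @export
default_panel <- function() {
  genes <- data.frame(
    gene = c("miR-S", "miR-I1", "miR-I2", "miR-I3", "miR-I4", "U6-like"),
    baseline = c(24.5, 26.5, 28.3, 30.9, 33.2, 29.0),
    sd = c(0.45, 0.9, 1.1, 1.3, 1.5, 2.0),
    stringsAsFactors = FALSE)
  cfg <- synthetic_config(genes)
  cfg$shifts["U6-like", "HCC"] <- 1.5
  cfg
}

#' Generate a synthetic Cq matrix with known ground truth
#'
#' Draws one experiment from a [synthetic_config()]. The seed fully
#' determines the output, so the same call is bit-identical across runs; the
#' returned truth table records each gene's designed baseline, SD and group
#' shifts for recovery checks. Values are truncated to `[0, max_cycles]`
#' (a detected reaction cannot report a cycle beyond the protocol).
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list of class `"synthetic_cq"`: `cq` ([cq_matrix()]), `groups`
#'   ([sample_groups()] factor), `truth` (`data.frame` of design values,
#'   with shift columns `shift.<group>`), `config`, `seed`.
#' @examples
#' sim <- generate_cq(default_panel(), seed = 1)
#' dim(sim$cq)   # 6 x 105
#' @export
generate_cq <- function(config, seed = NULL) {
  if (!inherits(config, "synthetic_config"))
    stop("config must be a synthetic_config", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  gs <- config$group_sizes
  group <- factor(rep(names(gs), times = gs), levels = names(gs))
  sample_ids <- paste0(rep(names(gs), times = gs), "_",
                       unlist(lapply(gs, seq_len)))
  n <- length(sample_ids)
  gene_ids <- as.character(config$genes$gene)
  plate <- if (config$plate_sd > 0) stats::rnorm(n, 0, config$plate_sd)
           else numeric(n)
  m <- matrix(NA_real_, length(gene_ids), n,
              dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(gene_ids)) {
    shift <- config$shifts[i, as.integer(group)]
    m[i, ] <- config$genes$baseline[i] + shift + plate +
      stats::rnorm(n, 0, config$genes$sd[i])
  }
  if (!is.null(config$spike_in)) {
    sp <- config$spike_in
    m <- rbind(m, matrix(sp$baseline + stats::rnorm(n, 0, sp$sd), 1L,
                         dimnames = list(sp$id, NULL)))
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(m)) < config$missing_rate, nrow(m))
    m[drop] <- NA_real_
  }
  m <- pmin(pmax(m, 0), config$max_cycles)
  truth <- cbind(config$genes,
                 stats::setNames(as.data.frame(config$shifts),
                                 paste0("shift.", colnames(config$shifts))))
  rownames(truth) <- NULL
  structure(list(cq = cq_matrix(m, max_cycles = config$max_cycles),
                 groups = sample_groups(stats::setNames(as.character(group),
                                                        sample_ids)),
                 truth = truth, config = config, seed = seed),
            class = "synthetic_cq")
}

#' @export
print.synthetic_cq <- function(x, ...) {
  cat(sprintf("Synthetic Cq experiment (seed %s)\n",
              if (is.null(x$seed)) "unset" else x$seed))
  print(x$cq, ...)
  invisible(x)
}

#' Write a synthetic experiment to disk
#'
#' Emits the standard file trio: Cq TSV (`<prefix>_cq.tsv`), group TSV
#' (`<prefix>_groups.tsv`) and design-truth JSON (`<prefix>_truth.json`).
#'
#' @param x a [generate_cq()] result.
#' @param prefix path prefix for the three files.
#' @return invisibly, the three paths.
#' @export
write_synthetic <- function(x, prefix) {
  stopifnot(inherits(x, "synthetic_cq"))
  paths <- paste0(prefix, c("_cq.tsv", "_groups.tsv", "_truth.json"))
  write_cq_table(x$cq, paths[1L])
  utils::write.table(data.frame(sample = names(x$groups),
                                group = as.character(x$groups)),
                     paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x$truth, paths[3L], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
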