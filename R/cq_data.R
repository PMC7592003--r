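#' Construct and validate a Cq matrix
#'
#' A Cq matrix is the universal input of the package: a numeric matrix of
#' quantification-cycle values with genes (miRNAs) in rows and samples in
#' columns. Undetected reactions are represented as `NA` and are never
#' imputed; every downstream statistic works on pairwise-complete samples
#' and reports how many samples it used.
#'
#' @param x numeric matrix with unique, non-empty rownames (gene ids) and
#'   colnames (sample ids). `NA` marks an undetected reaction.
#' @param max_cycles maximum admissible Cq. The default of 45 corresponds to
#'   a standard 45-cycle qPCR protocol; a detected reaction cannot have a Cq
#'   beyond the number of cycles run.
#' @return the validated matrix with class `"cq_matrix"` prepended.
#' @examples
#' m <- cq_matrix(matrix(c(24, 25, 30, 31), 2, 2,
#'                dimnames = list(c("miR-a", "miR-b"), c("s1", "s2"))))
#' @export
cq_matrix <- function(x, max_cycles = 45) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("Cq data must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("Cq matrix needs rownames (gene ids) and colnames (sample ids)",
         call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  v <- x[!is.na(x)]
  if (any(!is.finite(v)))
    stop("non-finite Cq values present (use NA for undetected reactions)",
         call. = FALSE)
  if (length(v) && (min(v) < 0 || max(v) > max_cycles))
    stop("Cq values outside [0, ", max_cycles, "]", call. = FALSE)
  attr(x, "max_cycles") <- max_cycles
  class(x) <- c("cq_matrix", class(unclass(x)))
  x
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("Cq matrix: %d genes x %d samples, %d undetected cell(s)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  print(utils::head(unclass(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

# Accept either a cq_matrix or a plain labelled numeric matrix at any
# user-facing entry point.
as_cq <- function(x) {
  if (inherits(x, "cq_matrix")) return(x)
  cq_matrix(as.matrix(x))
}

guess_sep <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a Cq matrix from delimited text
#'
#' Reads a TSV or CSV table with a header row of ids and one id column.
#' Cells equal to the sentinel token (or empty) are flagged as undetected
#' (`NA`); anything else must parse as a number. Ragged rows and duplicate
#' ids are rejected rather than repaired.
#'
#' @param path file path; delimiter auto-detected from the extension
#'   (`.csv` gives comma, anything else tab) unless `sep` is given.
#' @param orientation `"genes"` (default) if genes are in rows,
#'   `"samples"` if the table is transposed.
#' @param sep field delimiter override.
#' @param na_token sentinel marking an undetected reaction (default `"NA"`);
#'   empty cells are always treated as undetected.
#' @param max_cycles passed to [cq_matrix()].
#' @return a [cq_matrix()].
#' @seealso [write_cq_table()] for the inverse operation.
#' @export
read_cq_table <- function(path, orientation = c("genes", "samples"),
                          sep = NULL, na_token = "NA", max_cycles = 45) {
  orientation <- match.arg(orientation)
  sep <- guess_sep(path, sep)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("Cq table needs a header row and at least one data row: ", path,
         call. = FALSE)
  # sentinel keeps trailing empty (undetected) cells that strsplit drops
  cells <- lapply(strsplit(paste0(lines, sep, "\x01"), sep, fixed = TRUE),
                  function(r) r[-length(r)])
  header <- trimws(cells[[1L]])
  # tolerate an unnamed corner cell either present or absent
  ncol_expect <- length(header)
  body <- cells[-1L]
  widths <- lengths(body)
  corner <- header[1L] == "" || tolower(header[1L]) %in% c("gene", "id", "sample")
  ids_expected <- if (corner) ncol_expect else ncol_expect + 1L
  bad <- which(widths != ids_expected)
  if (length(bad))
    stop(sprintf("ragged table: row %d has %d fields, expected %d",
                 bad[1L] + 1L, widths[bad[1L]], ids_expected), call. = FALSE)
  col_ids <- if (corner) header[-1L] else header
  row_ids <- trimws(vapply(body, `[`, character(1L), 1L))
  raw <- lapply(body, function(r) trimws(r[-1L]))
  vals <- matrix(NA_real_, nrow = length(row_ids), ncol = length(col_ids),
                 dimnames = list(row_ids, col_ids))
  for (i in seq_along(raw)) {
    tok <- raw[[i]]
    missing <- tok == na_token | tok == ""
    num <- suppressWarnings(as.numeric(tok))
    bad_cell <- which(!missing & is.na(num))
    if (length(bad_cell))
      stop(sprintf("non-numeric Cq token '%s' at row '%s', column '%s'",
                   tok[bad_cell[1L]], row_ids[i], col_ids[bad_cell[1L]]),
           call. = FALSE)
    num[missing] <- NA_real_
    vals[i, ] <- num
  }
  if (orientation == "samples") vals <- t(vals)
  cq_matrix(vals, max_cycles = max_cycles)
}

#' Write a Cq matrix to delimited text
#'
#' Values are written at full precision (17 significant digits) so that a
#' write/read round trip is bit-identical.
#'
#' @param x a Cq matrix.
#' @param path output path; delimiter auto-detected from the extension
#'   unless `sep` is given.
#' @param sep field delimiter override.
#' @param na_token token written for undetected reactions.
#' @export
write_cq_table <- function(x, path, sep = NULL, na_token = "NA") {
  x <- as_cq(x)
  sep <- guess_sep(path, sep)
  fmt <- function(v) ifelse(is.na(v), na_token, sprintf("%.17g", v))
  header <- paste(c("gene", colnames(x)), collapse = sep)
  rows <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], fmt(x[i, ])), collapse = sep), character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Construct sample-group labels
#'
#' @param x named character vector or factor mapping sample id to group
#'   label, or a two-column data.frame (sample, group). Group order is the
#'   order of first appearance.
#' @return a named factor with one level per group.
#' @export
sample_groups <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("need two columns: sample id, group", call. = FALSE)
    g <- as.character(x[[2L]]); names(g) <- as.character(x[[1L]]); x <- g
  }
  if (is.factor(x)) x <- stats::setNames(as.character(x), names(x))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("sample ids (names) required for every group label", call. = FALSE)
  dup <- duplicated(names(x))
  if (any(dup)) {
    for (id in unique(names(x)[dup])) {
      if (length(unique(x[names(x) == id])) > 1L)
        stop("sample '", id, "' carries conflicting group labels", call. = FALSE)
    }
    x <- x[!dup]
  }
  if (!length(x)) stop("empty group mapping", call. = FALSE)
  stats::setNames(factor(x, levels = unique(x)), names(x))
}

#' Read sample-group metadata
#'
#' Expects two-column delimited text (sample id, group label), with or
#' without a header line. Labels are kept verbatim; group order is order of
#' first appearance. A sample listed twice with conflicting labels is an
#' error.
#'
#' @param path file path (TSV by default, CSV by extension).
#' @param sep field delimiter override.
#' @return a named factor as from [sample_groups()].
#' @export
read_groups <- function(path, sep = NULL) {
  sep <- guess_sep(path, sep)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty group file: ", path, call. = FALSE)
  cells <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(cells) < 2L)
  if (length(bad))
    stop(sprintf("group file row %d does not have two fields", bad[1L]),
         call. = FALSE)
  first <- tolower(trimws(cells[[1L]][1:2]))
  if (first[1L] %in% c("sample", "sample_id", "id") || first[2L] %in% c("group", "label"))
    cells <- cells[-1L]
  if (!length(cells)) stop("group file has a header but no data: ", path, call. = FALSE)
  ids <- trimws(vapply(cells, `[`, character(1L), 1L))
  lab <- trimws(vapply(cells, `[`, character(1L), 2L))
  sample_groups(stats::setNames(lab, ids))
}

# Align a groups factor to the samples of a Cq matrix; every sample must be
# labelled exactly once.
align_groups <- function(mat, groups) {
  groups <- sample_groups(groups)
  missing <- setdiff(colnames(mat), names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  stats::setNames(factor(as.character(groups[colnames(mat)]),
                         levels = levels(groups)), colnames(mat))
}

# Resolve a reference specification (gene id, combination_ref, or named Cq
# vector) to a per-sample Cq vector aligned with `mat`, plus a label.
resolve_reference <- function(mat, reference) {
  if (inherits(reference, "combination_ref")) {
    cq <- reference$cq[colnames(mat)]
    return(list(cq = stats::setNames(as.numeric(cq), colnames(mat)),
                label = reference$label, members = reference$members))
  }
  if (is.character(reference) && length(reference) == 1L) {
    if (!reference %in% rownames(mat))
      stop("reference gene '", reference, "' not in matrix", call. = FALSE)
    return(list(cq = mat[reference, ], label = reference, members = reference))
  }
  if (is.numeric(reference)) {
    if (is.null(names(reference)))
      stop("a numeric reference Cq vector must be named by sample id",
           call. = FALSE)
    cq <- reference[colnames(mat)]
    return(list(cq = stats::setNames(as.numeric(cq), colnames(mat)),
                label = "custom reference", members = character(0L)))
  }
  stop("reference must be a gene id, a combination_ref, or a named Cq vector",
       call. = FALSE)
}

#' Relative expression by the 2^-dCq transform
#'
#' Computes per-sample relative expression of a target against a reference:
#' `2^-(Cq_target - Cq_reference)`, the standard delta-Cq quantification with
#' amplification efficiency assumed to be 2 (one doubling per cycle).
#' Samples where either value is undetected are dropped and counted.
#'
#' @param mat a Cq matrix.
#' @param target gene id (row of `mat`).
#' @param reference gene id, a [combine_refs()] combination, or a named
#'   per-sample Cq vector.
#' @return object of class `"relative_expression"`: list with `values`
#'   (named positive numeric), `target`, `reference`, `n_used`,
#'   `dropped_samples` and a `degenerate` flag (`TRUE` when target and
#'   reference coincide, making every value exactly 1).
#' @examples
#' m <- cq_matrix(matrix(c(25, 22, 26, 22), 2, 2,
#'                dimnames = list(c("t", "r"), c("s1", "s2"))))
#' relative_expression(m, "t", "r")$values  # 2^-3, 2^-4
#' @export
relative_expression <- function(mat, target, reference) {
  mat <- as_cq(mat)
  if (!target %in% rownames(mat))
    stop("target gene '", target, "' not in matrix", call. = FALSE)
  ref <- resolve_reference(mat, reference)
  tv <- mat[target, ]
  ok <- !is.na(tv) & !is.na(ref$cq)
  if (!any(ok))
    stop("no samples where both target and reference are detected",
         call. = FALSE)
  degenerate <- identical(target, ref$label) ||
    (length(ref$members) == 1L && identical(target, ref$members))
  vals <- 2^-(tv[ok] - ref$cq[ok])
  if (degenerate) vals[] <- 1
  structure(list(values = vals, target = target, reference = ref$label,
                 n_used = sum(ok), dropped_samples = colnames(mat)[!ok],
                 degenerate = degenerate),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("2^-dCq expression of %s vs %s (%d sample(s)%s)\n",
              x$target, x$reference, x$n_used,
              if (x$degenerate) ", degenerate self-normalization" else ""))
  print(round(x$values, 4), ...)
  invisible(x)
}

#' Normalize every gene to a spike-in control
#'
#' Computes [relative_expression()] of each gene against an exogenous
#' spike-in row (e.g. cel-miR-67 added at fixed amount before extraction).
#' The spike row itself is excluded from the output.
#'
#' @param mat a Cq matrix containing the spike row.
#' @param spike_id row id of the spike-in.
#' @return named list of `relative_expression` objects, one per other gene.
#' @export
spike_normalize <- function(mat, spike_id) {
  mat <- as_cq(mat)
  if (!spike_id %in% rownames(mat))
    stop("spike-in '", spike_id, "' not in matrix", call. = FALSE)
  targets <- setdiff(rownames(mat), spike_id)
  stats::setNames(
    lapply(targets, function(g) relative_expression(mat, g, spike_id)),
    targets)
}

#' Average technical replicates into one Cq per sample
#'
#' Optional utility for data delivered with technical replicates still
#' separate: columns mapping to the same sample id are collapsed by the
#' arithmetic mean of their detected Cq values (all-undetected stays `NA`).
#'
#' @param mat a Cq matrix whose columns are replicate wells.
#' @param sample_of vector (same length as `ncol(mat)`) giving the biological
#'   sample id of each column.
#' @return a Cq matrix with one column per sample, in order of first
#'   appearance.
#' @export
collapse_replicates <- function(mat, sample_of) {
  mat <- as_cq(mat)
  sample_of <- as.character(sample_of)
  if (length(sample_of) != ncol(mat))
    stop("sample_of must label every column", call. = FALSE)
  ids <- unique(sample_of)
  out <- vapply(ids, function(s)
    rowMeans(mat[, sample_of == s, drop = FALSE], na.rm = TRUE),
    numeric(nrow(mat)))
  out[is.nan(out)] <- NA_real_
  cq_matrix(matrix(out, nrow = nrow(mat),
                   dimnames = list(rownames(mat), ids)),
            max_cycles = attr(mat, "max_cycles") %||% 45)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
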