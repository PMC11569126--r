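#' Construct an omics expression matrix with an explicit missingness mask
#'
#' The container used throughout the package: a genes x samples numeric
#' matrix plus a logical mask marking missing cells, and a flag recording
#' whether values are linear intensities or log2 intensities. Missingness is
#' carried by the mask, never by sentinel numbers, so an observed zero (a
#' real single-cell count of 0) and a missing proteomics intensity (NA)
#' remain distinct states.
#'
#' Values stored at masked positions carry no information: every operation
#' in the package indexes through the mask, so a masked cell may hold NA or
#' any leftover number without affecting results.
#'
#' @param values numeric matrix, rows = genes, columns = samples; rownames
#'   and colnames are required and must be unique.
#' @param mask logical matrix of the same shape, `TRUE` = missing. Defaults
#'   to `is.na(values)`.
#' @param space `"linear"` or `"log2"`. Observed linear values must be >= 0.
#' @return An object of class `omics_matrix` (list with `values`, `mask`,
#'   `space`).
#' @export
omics_matrix <- function(values, mask = is.na(values),
                         space = c("linear", "log2")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (gene ids) and colnames (sample ids)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    stop("`mask` must be a logical matrix with the same dimensions")
  mask[is.na(mask)] <- TRUE
  if (any(is.na(values) & !mask))
    stop("NA values present at unmasked positions")
  if (space == "linear" && any(values[!mask] < 0, na.rm = TRUE))
    stop("linear-space observed values must be >= 0")
  dimnames(mask) <- dimnames(values)
  structure(list(values = values, mask = mask, space = space),
            class = "omics_matrix")
}

#' @method print omics_matrix
#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d genes x %d samples (%s space), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$space,
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an omics_matrix
#' @param m an `omics_matrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Observed values with NA at masked cells
#'
#' Canonical numeric view of an `omics_matrix`: the stored values with every
#' masked cell replaced by NA. Use this, not `m$values`, whenever masked
#' entries must not leak into a computation.
#' @param m an `omics_matrix`.
#' @return Numeric matrix with NA exactly at masked positions.
#' @export
observed_values <- function(m) {
  v <- m$values
  v[m$mask] <- NA_real_
  v
}

#' Group labels for the samples of an expression matrix
#'
#' @param assignment named character vector mapping sample id -> group id,
#'   or a two-column data.frame (sample_id, group_id).
#' @return An object of class `group_labels` with fields `assignment` (named
#'   character vector) and `groups` (group ids ordered by first appearance).
#' @export
group_labels <- function(assignment) {
  if (is.data.frame(assignment)) {
    if (ncol(assignment) < 2)
      stop("label table needs two columns: sample_id, group_id")
    a <- as.character(assignment[[2]])
    names(a) <- as.character(assignment[[1]])
    assignment <- a
  }
  if (is.null(names(assignment)) || anyDuplicated(names(assignment)))
    stop("sample ids must be present and unique in the label assignment")
  groups <- unique(unname(assignment))   # order of first appearance
  if (length(groups) < 2)
    stop("at least two groups are required (K >= 2)")
  structure(list(assignment = assignment, groups = groups),
            class = "group_labels")
}

#' @method print group_labels
#' @export
print.group_labels <- function(x, ...) {
  cat(sprintf("group_labels: %d samples in %d groups (%s)\n",
              length(x$assignment), length(x$groups),
              paste(x$groups, collapse = ", ")))
  invisible(x)
}

# group membership check: labels must cover all samples of m
match_labels <- function(m, g) {
  miss <- setdiff(sample_ids(m), names(g$assignment))
  if (length(miss))
    stop("samples without a group label: ", paste(miss, collapse = ", "))
  g$assignment[sample_ids(m)]
}

#' Ground-truth record of masked entries
#'
#' Holds the index set of masked cells together with their true values and
#' the mechanism (LLOD censoring or MAR) that removed them, for evaluating
#' imputation accuracy.
#'
#' @param gene_id,sample_id character vectors of positions.
#' @param true_value numeric vector of the values that were masked.
#' @param mechanism character vector, each `"LLOD"` or `"MAR"`.
#' @return A data.frame of class `missingness_truth` with columns
#'   gene_id, sample_id, true_value, mechanism.
#' @export
missingness_truth <- function(gene_id, sample_id, true_value, mechanism) {
  stopifnot(length(gene_id) == length(sample_id),
            length(gene_id) == length(true_value),
            length(gene_id) == length(mechanism))
  if (!all(mechanism %in% c("LLOD", "MAR")))
    stop("mechanism must be 'LLOD' or 'MAR'")
  key <- paste(gene_id, sample_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene, sample) positions in missingness truth")
  out <- data.frame(gene_id = as.character(gene_id),
                    sample_id = as.character(sample_id),
                    true_value = as.numeric(true_value),
                    mechanism = as.character(mechanism),
                    stringsAsFactors = FALSE)
  class(out) <- c("missingness_truth", "data.frame")
  out
}

#' Read an expression matrix from TSV/CSV or MatrixMarket triplet files
#'
#' TSV/CSV layout: first column gene ids, header row sample ids, cells
#' numeric; `NA` or empty cells mark missing values. MatrixMarket (`mtx`)
#' input is the single-cell convention: entries absent from the sparse file
#' are observed zeros, not missing, and gene/sample ids come from two
#' side-car text files (one id per line).
#'
#' @param path file path of the matrix.
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @param space `"linear"` or `"log2"`.
#' @param genes_path,samples_path id files, required for `format = "mtx"`.
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path, format = c("tsv", "csv", "mtx"),
                              space = c("linear", "log2"),
                              genes_path = NULL, samples_path = NULL) {
  format <- match.arg(format)
  space <- match.arg(space)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    if (is.null(genes_path) || is.null(samples_path))
      stop("mtx input requires `genes_path` and `samples_path`")
    sm <- Matrix::readMM(path)
    vals <- as.matrix(sm)
    rn <- readLines(genes_path)
    cn <- readLines(samples_path)
    if (length(rn) != nrow(vals) || length(cn) != ncol(vals))
      stop("id file lengths do not match matrix dimensions")
    dimnames(vals) <- list(rn, cn)
    # sparse zeros are observed zeros: mask all-false
    return(omics_matrix(vals, mask = matrix(FALSE, nrow(vals), ncol(vals),
                                            dimnames = dimnames(vals)),
                        space = space))
  }
  sep <- if (format == "tsv") "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character",
                           na.strings = c("NA", ""), quote = "\"",
                           comment.char = "")
  gid <- tab[[1]]
  if (anyDuplicated(gid))
    stop("duplicate gene ids in ", path)
  cells <- as.matrix(tab[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(!is.na(cells) & is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    stop(sprintf("non-numeric cell '%s' at gene '%s', sample '%s'",
                 cells[b[1], b[2]], gid[b[1]], colnames(cells)[b[2]]))
  }
  dimnames(vals) <- list(gid, colnames(cells))
  omics_matrix(vals, space = space)
}

#' Read a two-column sample/group label table
#'
#' @param path TSV with columns sample_id, group_id; a header line is
#'   detected and skipped if its first field is `sample_id`.
#' @return A [group_labels()] object; group order is order of first
#'   appearance in the file.
#' @export
read_group_labels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (nrow(tab) && identical(tab[1, 1], "sample_id"))
    tab <- tab[-1, , drop = FALSE]
  group_labels(tab[, 1:2])
}

#' Convert a linear-space matrix to log2
#'
#' Observed entries become `log2(value + pseudo)`; the mask and ids are
#' unchanged. Values at masked cells are set to NA.
#' @param m an `omics_matrix` in linear space.
#' @param pseudo nonnegative pseudo-count added before the log.
#' @return An `omics_matrix` in log2 space.
#' @export
to_log2 <- function(m, pseudo = 0) {
  stopifnot(inherits(m, "omics_matrix"), pseudo >= 0)
  if (m$space != "linear") stop("matrix is already in log2 space")
  v <- observed_values(m)
  if (any(v < 0, na.rm = TRUE)) stop("negative observed value in linear matrix")
  out <- log2(v + pseudo)
  omics_matrix(out, mask = m$mask, space = "log2")
}

#' Convert a log2-space matrix back to linear
#'
#' Observed entries become `2^value - pseudo`; inverse of [to_log2()] for
#' the same `pseudo`.
#' @param m an `omics_matrix` in log2 space.
#' @param pseudo nonnegative pseudo-count subtracted after exponentiation.
#' @return An `omics_matrix` in linear space.
#' @export
to_linear <- function(m, pseudo = 0) {
  stopifnot(inherits(m, "omics_matrix"), pseudo >= 0)
  if (m$space != "log2") stop("matrix is already in linear space")
  v <- 2^observed_values(m) - pseudo
  v[!is.na(v) & v < 0 & v > -1e-12] <- 0   # clamp float dust at zero
  omics_matrix(v, mask = m$mask, space = "linear")
}

# internal: matrix in the requested space, converting if needed
ensure_space <- function(m, space, pseudo = 0) {
  if (m$space == space) return(m)
  if (space == "linear") to_linear(m, pseudo) else to_log2(m, pseudo)
}

#' Write package tables or matrices to TSV
#'
#' Deterministic, lossless TSV writers for the package's tabular types.
#' `write_suite_table()` dispatches on class: signature score tables keep
#' the column order gene_id, direction, assigned_group, score, p_value
#' (plus q_value/rank when present); missingness-truth tables keep
#' gene_id, sample_id, true_value, mechanism. An empty table writes a
#' header-only file.
#'
#' @param obj a `signature_scores`, `missingness_truth` or plain data.frame.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_suite_table <- function(obj, path) {
  if (inherits(obj, "signature_scores")) {
    lead <- intersect(c("gene_id", "direction", "assigned_group", "score",
                        "p_value", "q_value", "rank"), names(obj))
    obj <- obj[, c(lead, setdiff(names(obj), lead)), drop = FALSE]
  } else if (inherits(obj, "missingness_truth")) {
    obj <- obj[, c("gene_id", "sample_id", "true_value", "mechanism"),
               drop = FALSE]
  } else if (!is.data.frame(obj)) {
    stop("unsupported table type: ", paste(class(obj), collapse = "/"))
  }
  utils::write.table(obj, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_suite_table
#' @param m an `omics_matrix`; masked cells are written as `NA`.
#' @export
write_omics_matrix <- function(m, path) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- observed_values(m)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_suite_table
#' @param g a `group_labels` object.
#' @export
write_group_labels <- function(g, path) {
  stopifnot(inherits(g, "group_labels"))
  utils::write.table(data.frame(sample_id = names(g$assignment),
                                group_id = unname(g$assignment)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read back a signature score table written by [write_suite_table()]
#' @param path TSV path.
#' @return A `signature_scores` data.frame.
#' @export
read_score_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = NA, stringsAsFactors = FALSE)
  class(tab) <- c("signature_scores", "data.frame")
  tab
}

#' Read back a missingness truth table written by [write_suite_table()]
#' @param path TSV path.
#' @return A `missingness_truth` data.frame.
#' @export
read_missingness_truth <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  missingness_truth(tab$gene_id, tab$sample_id, tab$true_value, tab$mechanism)
}
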