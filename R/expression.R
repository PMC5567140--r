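#' Expression matrix with a two-group design
#'
#' Container for a log2 (or raw-intensity) expression matrix together with
#' the control/treated assignment of its sample columns. This is the unit
#' of data every downstream stage (normalization, differential expression)
#' consumes.
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#'   Row and column names are required and must be unique.
#' @param group Factor or character vector, one entry per sample column,
#'   with exactly the levels \code{control} and \code{treated} (both must
#'   be present). May be named by sample id; if so the names must match
#'   the column names of \code{values}.
#' @param log2_scale Logical flag recording whether \code{values} are
#'   already on the log2 scale.
#'
#' @return An object of class \code{expr_matrix}: a list with elements
#'   \code{values}, \code{group} (named factor) and \code{log2_scale}.
#' @export
expr_matrix <- function(values, group, log2_scale = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature (row) and sample (column) names",
         call. = FALSE)
  dup_f <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_f))
    stop("duplicate feature ids: ", paste(unique(dup_f), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids", call. = FALSE)
  if (anyNA(values))
    stop("missing values are not permitted in an expression matrix",
         call. = FALSE)
  if (length(group) != ncol(values))
    stop("'group' must have one entry per sample column", call. = FALSE)
  if (!is.null(names(group))) {
    if (!setequal(names(group), colnames(values)))
      stop("names of 'group' do not match sample ids", call. = FALSE)
    group <- group[colnames(values)]
  }
  group <- factor(as.character(group), levels = c("control", "treated"))
  if (anyNA(group))
    stop("group labels must be 'control' or 'treated'", call. = FALSE)
  if (nlevels(droplevels(group)) < 2L)
    stop("both 'control' and 'treated' groups must be present",
         call. = FALSE)
  names(group) <- colnames(values)
  structure(list(values = values, group = group,
                 log2_scale = isTRUE(log2_scale)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%s vs %s), %s scale\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "control"), sum(x$group == "treated"),
              if (x$log2_scale) "log2" else "linear"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its design file
#'
#' The matrix file is TSV with a header row: first column feature id,
#' remaining columns one per sample. The design file is a two-column TSV
#' (header \code{sample_id}, \code{group}) mapping every sample column to
#' \code{control} or \code{treated}.
#'
#' @param path Path to the expression TSV.
#' @param design_path Path to the design TSV.
#' @param log2_scale Whether the stored values are log2 (default TRUE).
#' @return An [expr_matrix].
#' @export
read_expr_matrix <- function(path, design_path, log2_scale = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    stop("matrix file must have a feature-id column and >=1 sample column",
         call. = FALSE)
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1L]
    rows <- which(ids == d)
    stop(sprintf("duplicate feature id '%s' at data rows %s", d,
                 paste(rows, collapse = ", ")), call. = FALSE)
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num) && !anyNA(vals)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at row %d (feature '%s'), column '%s'",
                 bad[1L], ids[bad[1L]], colnames(vals)[bad[2L]]),
         call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(vals))
  design <- utils::read.delim(design_path, header = TRUE, sep = "\t",
                              colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(design)))
    stop("design file must have columns 'sample_id' and 'group'",
         call. = FALSE)
  missing <- setdiff(colnames(num), design$sample_id)
  if (length(missing))
    stop("samples absent from design file: ",
         paste(missing, collapse = ", "), call. = FALSE)
  grp <- stats::setNames(design$group, design$sample_id)[colnames(num)]
  expr_matrix(num, grp, log2_scale = log2_scale)
}

#' Write an expression matrix and its design file as TSV
#'
#' @param m An [expr_matrix].
#' @param path Output path for the matrix TSV.
#' @param design_path Output path for the two-column design TSV.
#' @return Invisibly, \code{path}.
#' @export
write_expr_matrix <- function(m, path, design_path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(feature_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  des <- data.frame(sample_id = names(m$group),
                    group = as.character(m$group))
  utils::write.table(des, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Quantile-normalize the sample columns of an expression matrix
#'
#' After normalization every sample column holds the same multiset of
#' values: the cross-sample means of the order statistics. Tied values
#' within a column receive the mean of the reference values at the ranks
#' they jointly occupy, so the map is well defined and idempotent.
#'
#' @param m An [expr_matrix] with at least two samples.
#' @return A quantile-normalized [expr_matrix] with unchanged ids.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  x <- m$values
  if (ncol(x) < 2L) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(m)
  }
  ref <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(col) {
    r <- rank(col, ties.method = "min")
    runs <- rank(col, ties.method = "max")
    # mean of reference values over the rank interval each (tied) value spans
    cs <- c(0, cumsum(ref))
    (cs[runs + 1L] - cs[r]) / (runs - r + 1L)
  })
  dimnames(out) <- dimnames(x)
  expr_matrix(out, m$group, log2_scale = m$log2_scale)
}

#' Log2-transform an expression matrix exactly once
#'
#' @param m An [expr_matrix].
#' @param already_log If TRUE the matrix is assumed log2 already and
#'   returned unchanged (with the scale flag set).
#' @return An [expr_matrix] on the log2 scale.
#' @export
log2_transform <- function(m, already_log = m$log2_scale) {
  stopifnot(inherits(m, "expr_matrix"))
  if (isTRUE(already_log)) {
    m$log2_scale <- TRUE
    return(m)
  }
  bad <- which(m$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "non-positive value on linear scale at feature '%s', sample '%s'",
      rownames(m$values)[bad[1L, 1L]], colnames(m$values)[bad[1L, 2L]]),
      call. = FALSE)
  expr_matrix(log2(m$values), m$group, log2_scale = TRUE)
}
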