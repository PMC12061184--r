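# File formats: expression matrices and label tables (CSV/TSV) and the
# JSON model archive. The archive round-trips at full double precision so
# reloaded models predict identically.

.sep_from_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix
#'
#' Expects a delimited text file (comma for `.csv`, tab otherwise) with a
#' header row of gene ids and a first column of sample ids; orientation is
#' samples x genes. Use `transpose = TRUE` for genes x samples exports.
#'
#' @param path file path.
#' @param transpose is the file stored genes x samples?
#' @return numeric matrix with sample ids as row names and gene ids as
#'   column names.
#' @export
read_expression <- function(path, transpose = FALSE) {
  sep <- .sep_from_path(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   colClasses = "character", quote = "\"")
  ids <- df[[1]]
  M <- matrix(NA_real_, nrow(df), ncol(df) - 1,
              dimnames = list(ids, colnames(df)[-1]))
  for (j in seq_len(ncol(M))) {
    col <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad) > 0)
      stop("non-numeric or missing value at row '", ids[bad[1]],
           "', column '", colnames(M)[j], "'", call. = FALSE)
    M[, j] <- num
  }
  if (transpose) M <- t(M)
  if (anyDuplicated(colnames(M)))
    stop("duplicate gene ids: ",
         paste(unique(colnames(M)[duplicated(colnames(M))]), collapse = ", "),
         call. = FALSE)
  M
}

#' Read class labels
#'
#' Two-column delimited file: sample id, class label. The labels are
#' reordered to match `sample_ids` when given; samples without a label are
#' an error.
#'
#' @param path file path.
#' @param sample_ids optional character vector fixing the sample order
#'   (typically `rownames()` of the expression matrix).
#' @return named factor of class labels.
#' @export
read_labels <- function(path, sample_ids = NULL) {
  sep <- .sep_from_path(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("label file needs two columns", call. = FALSE)
  lab <- df[[2]]
  names(lab) <- df[[1]]
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, names(lab))
    if (length(missing) > 0)
      stop("no label for samples: ", paste(missing, collapse = ", "),
           call. = FALSE)
    lab <- lab[sample_ids]
  }
  factor(lab, levels = sort(unique(lab)))
}

#' Save a fitted model as a JSON archive
#'
#' Serialises coefficients, penalties, standardization parameters and fit
#' metadata with full double precision, so [read_gnmc()] reproduces
#' predictions exactly.
#'
#' @param object a fitted `gnmc` object.
#' @param path output file path.
#' @export
write_gnmc <- function(object, path) {
  if (is.null(object$regulator_ids))
    object$regulator_ids <- paste0("R", seq_len(nrow(object$B)))
  if (is.null(object$target_ids))
    object$target_ids <- paste0("T", seq_len(ncol(object$B)))
  if (is.null(object$class_names))
    object$class_names <- paste0("class", seq_len(nrow(object$Theta)))
  arc <- list(
    package = "gnmc", format = 1L,
    B = unname(object$B), Theta = unname(object$Theta),
    theta0 = unname(object$theta0), lambda = object$lambda,
    class_names = object$class_names,
    regulator_ids = object$regulator_ids, target_ids = object$target_ids,
    x_center = unname(object$x_center), x_scale = unname(object$x_scale),
    y_center = unname(object$y_center), y_scale = unname(object$y_scale),
    square = object$square, n = object$n,
    converged = object$converged, status = object$status,
    n_cycles = object$n_cycles, objective = object$objective,
    objective_trace = object$objective_trace,
    control = unclass(object$control))
  jsonlite::write_json(arc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a fitted model from a JSON archive
#'
#' @param path path written by [write_gnmc()].
#' @return object of class `gnmc` (prediction methods work; the training
#'   data itself is not stored in the archive).
#' @export
read_gnmc <- function(path) {
  arc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(arc$package, "gnmc")) stop("not a gnmc model archive")
  B <- matrix(unlist(arc$B), nrow = length(arc$regulator_ids),
              dimnames = list(arc$regulator_ids, arc$target_ids))
  Theta <- matrix(unlist(arc$Theta), nrow = length(arc$class_names),
                  dimnames = list(arc$class_names, arc$target_ids))
  theta0 <- as.numeric(arc$theta0)
  names(theta0) <- arc$class_names
  structure(list(
    call = quote(read_gnmc()), B = B, Theta = Theta, theta0 = theta0,
    lambda = as.list(arc$lambda),
    objective_trace = as.numeric(arc$objective_trace),
    objective = arc$objective, converged = arc$converged,
    status = arc$status, n_cycles = arc$n_cycles, square = arc$square,
    class_names = arc$class_names, regulator_ids = arc$regulator_ids,
    target_ids = arc$target_ids, n = arc$n,
    x_center = as.numeric(arc$x_center), x_scale = as.numeric(arc$x_scale),
    y_center = as.numeric(arc$y_center), y_scale = as.numeric(arc$y_scale),
    Xs = NULL, Ys = NULL, Z = NULL,
    control = do.call(gnmc_control, as.list(arc$control))),
    class = "gnmc")
}

#' Write an edge list as TSV
#'
#' @param edges data frame with columns `regulator`, `target` and
#'   optionally `weight` (as produced by [class_networks()]).
#' @param path output file path.
#' @export
write_edges <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
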