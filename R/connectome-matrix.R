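#' @keywords internal
ms_weightings <- c("binary", "FA", "FN", "FL")

#' Construct and validate a connectome adjacency matrix
#'
#' A `connectome_matrix` is one subject's symmetric non-negative adjacency
#' over the retained nodes of an atlas, in one of four weightings:
#' `binary` (edge presence, values in \{0, 1\}), `FA` (mean fractional
#' anisotropy along the tract, dimensionless in \[0, 1\]), `FN` (streamline
#' count, >= 0) or `FL` (mean tract length in mm, >= 0).
#'
#' @param values Square numeric matrix with dimnames equal to the retained
#'   atlas node ids (atlas order). Small asymmetries (relative magnitude
#'   <= `tol`) are symmetrised as `(M + t(M))/2`; larger asymmetry is an
#'   error, since tractography-derived matrices are symmetric by
#'   construction and gross asymmetry signals file corruption. The diagonal
#'   is forced to zero.
#' @param weighting One of `"binary"`, `"FA"`, `"FN"`, `"FL"`.
#' @param atlas The `ms_atlas` the matrix is defined over.
#' @param subject_id Subject identifier string.
#' @param tol Relative symmetry tolerance (default `1e-6`).
#' @return A `connectome_matrix`: the validated numeric matrix with
#'   attributes `subject_id`, `weighting` and `atlas_name`.
#' @export
connectome_matrix <- function(values, weighting, atlas, subject_id = "subject",
                              tol = 1e-6) {
  weighting <- match.arg(weighting, ms_weightings)
  stopifnot(inherits(atlas, "ms_atlas"))
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("adjacency matrix must be square, got ", nrow(values), "x", ncol(values),
         call. = FALSE)
  }
  ids <- retained_nodes(atlas)
  if (nrow(values) != length(ids)) {
    stop("matrix dimension ", nrow(values), " does not match the ",
         length(ids), " retained atlas nodes", call. = FALSE)
  }
  if (!is.null(rownames(values))) {
    if (!setequal(rownames(values), ids)) {
      stop("matrix node ids do not match retained atlas nodes", call. = FALSE)
    }
    if (!identical(colnames(values), rownames(values))) {
      stop("matrix row and column ids differ", call. = FALSE)
    }
    values <- values[ids, ids, drop = FALSE]  # reorder to atlas order
  } else {
    dimnames(values) <- list(ids, ids)
  }
  if (anyNA(values)) stop("matrix contains missing values", call. = FALSE)
  mx <- max(abs(values))
  asym <- max(abs(values - t(values)))
  if (asym > tol * max(mx, 1e-300)) {
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance (%.3g relative)",
                 asym, tol), call. = FALSE)
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (any(values < 0)) stop("negative entries are not allowed", call. = FALSE)
  if (weighting == "FA" && any(values > 1 + 1e-9)) {
    stop("FA entries must lie in [0, 1]", call. = FALSE)
  }
  if (weighting == "binary" && !all(values %in% c(0, 1))) {
    stop("binary entries must be 0 or 1", call. = FALSE)
  }
  structure(values,
            subject_id = subject_id,
            weighting = weighting,
            atlas_name = attr(atlas, "name"),
            class = c("connectome_matrix", "matrix", "array"))
}

#' @export
print.connectome_matrix <- function(x, ...) {
  cat(sprintf("<connectome_matrix> subject '%s', weighting %s, %d nodes, %d edges\n",
              attr(x, "subject_id"), attr(x, "weighting"), nrow(x),
              sum(x[upper.tri(x)] > 0)))
  invisible(x)
}

#' Read an adjacency matrix from CSV/TSV
#'
#' Expects a square numeric table whose first column and header row hold the
#' node ids of the retained atlas nodes (in any order); the matrix is
#' reordered to atlas order, symmetrised within tolerance and
#' diagonal-zeroed via [connectome_matrix()]. The delimiter is sniffed:
#' a tab character in the header line selects TSV, otherwise CSV.
#'
#' @inheritParams connectome_matrix
#' @param path File path.
#' @return A `connectome_matrix`.
#' @export
read_connectome <- function(path, atlas, weighting, subject_id = NULL,
                            tol = 1e-6) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  if (nrow(m) != ncol(m)) {
    stop("matrix table is not square: ", nrow(m), " rows x ", ncol(m),
         " value columns", call. = FALSE)
  }
  dimnames(m) <- list(ids, colnames(tab)[-1])
  if (is.null(subject_id)) {
    subject_id <- sub("\\.(csv|tsv)$", "", basename(path))
  }
  connectome_matrix(m, weighting = weighting, atlas = atlas,
                    subject_id = subject_id, tol = tol)
}

#' Write an adjacency matrix to CSV
#'
#' Writes a square table with a `node_id` first column and node-id header.
#' Values are written with enough precision (15 significant digits) that
#' [read_connectome()] round-trips within `1e-9`.
#'
#' @param m A `connectome_matrix`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(m, path) {
  stopifnot(inherits(m, "connectome_matrix"))
  df <- as.data.frame(unclass(m))
  df <- cbind(node_id = rownames(m), df)
  readr::write_csv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}
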