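#' Group-consistency backbone mask
#'
#' Retains an edge iff the fraction of subjects in which it is present
#' (streamline count FN > 0) is *strictly above* the threshold. Consistency
#' thresholding suppresses spurious connections caused by normalisation
#' error or partial-volume effects; the default keeps edges reconstructed in
#' more than 75% of subjects. One backbone is computed for the whole study
#' and applied to all four weightings of every subject.
#'
#' @param cohort An `ms_cohort` (>= 2 subjects).
#' @param threshold Presence-fraction threshold in (0, 1); default 0.75.
#' @param scope `"pooled"` (default) computes presence over all subjects;
#'   `"per-group"` requires the fraction to exceed the threshold within
#'   every group.
#' @param strict Use strict inequality (default `TRUE`, reading "above
#'   75%" literally); `FALSE` uses `>=`.
#' @param weighting Weighting used to judge presence (default `"FN"`).
#' @return A `backbone_mask`: symmetric logical matrix with `FALSE`
#'   diagonal and attributes `threshold` and `n_subjects_used`.
#' @export
consistency_mask <- function(cohort, threshold = 0.75, scope = c("pooled", "per-group"),
                             strict = TRUE, weighting = "FN") {
  stopifnot(inherits(cohort, "ms_cohort"))
  scope <- match.arg(scope)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  sub <- cohort[cohort$weighting == weighting, ]
  if (nrow(sub) < 2L) {
    stop("need >= 2 subjects with weighting '", weighting, "'", call. = FALSE)
  }
  cmp <- if (strict) `>` else `>=`
  pres_frac <- function(mats) {
    Reduce(`+`, lapply(mats, function(m) unclass(m) > 0)) / length(mats)
  }
  if (scope == "pooled") {
    keep <- cmp(pres_frac(sub$matrix), threshold)
  } else {
    keep <- Reduce(`&`, lapply(split(sub$matrix, sub$group),
                               function(mats) cmp(pres_frac(mats), threshold)))
  }
  diag(keep) <- FALSE
  structure(keep,
            threshold = threshold,
            n_subjects_used = nrow(sub),
            scope = scope,
            class = c("backbone_mask", "matrix", "array"))
}

#' @export
print.backbone_mask <- function(x, ...) {
  cat(sprintf("<backbone_mask> %d nodes, %d edges retained (threshold %s, %s, n=%d)\n",
              nrow(x), sum(x[upper.tri(x)]), format(attr(x, "threshold")),
              attr(x, "scope"), attr(x, "n_subjects_used")))
  invisible(x)
}

#' Apply a backbone mask to a matrix
#'
#' Entries outside the mask are set to zero; entries inside are unchanged.
#' Idempotent.
#'
#' @param m A `connectome_matrix`.
#' @param mask A `backbone_mask` of matching dimension.
#' @return A `connectome_matrix` in the same weighting.
#' @export
apply_mask <- function(m, mask) {
  stopifnot(inherits(m, "connectome_matrix"), inherits(mask, "backbone_mask"))
  if (!all(dim(m) == dim(mask))) {
    stop("mask dimension ", nrow(mask), " does not match matrix dimension ",
         nrow(m), call. = FALSE)
  }
  out <- unclass(m)
  out[!unclass(mask)] <- 0
  attributes(out) <- attributes(m)
  out
}

#' Binarize a weighted matrix
#'
#' Positive entries become 1, zeros stay 0. Idempotent.
#'
#' @param m A `connectome_matrix`.
#' @return A `connectome_matrix` with `weighting = "binary"`.
#' @export
binarize <- function(m) {
  stopifnot(inherits(m, "connectome_matrix"))
  out <- unclass(m)
  out[] <- as.numeric(out > 0)
  attributes(out) <- attributes(m)
  attr(out, "weighting") <- "binary"
  out
}
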