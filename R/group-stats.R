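#' z-transform a vector of per-subject values
#'
#' Centers and scales to pooled mean 0 and sample SD 1 across all subjects
#' (per property, per weighting). Topological properties live on
#' incommensurate scales across weightings; z-scoring puts them on a common
#' scale before the parametric comparisons. A zero-variance input yields
#' all zeros with attribute `zero_variance = TRUE`.
#'
#' @param values Numeric vector (>= 2 values).
#' @return z-scores with mean 0, SD 1 (or flagged zeros).
#' @export
z_transform <- function(values) {
  if (length(values) < 2) stop("need >= 2 values", call. = FALSE)
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    out <- rep(0, length(values))
    attr(out, "zero_variance") <- TRUE
    return(out)
  }
  (values - mean(values)) / s
}

#' One-way ANOVA
#'
#' Classical between/within mean-square F with df `(k-1, sum(n)-k)` and its
#' upper-tail p from the F distribution. Degenerate within-group variance
#' with real between-group separation yields the sentinel F = 1e12 with
#' p ~ 0 (flagged).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length (>= 2 groups of >= 2 values).
#' @return Tibble: `F_stat`, `p`, `df1`, `df2`, `degenerate`.
#' @export
oneway_anova <- function(values, groups) {
  fs <- f_stats_columns(matrix(values, ncol = 1), groups)
  p <- pf(fs$f, fs$df1, fs$df2, lower.tail = FALSE)
  tibble(F_stat = fs$f, p = p, df1 = fs$df1, df2 = fs$df2,
         degenerate = fs$degenerate)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, monotone non-decreasing in p.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Post-hoc pairwise Welch t-tests
#'
#' Two-sided Welch t per group pair, uncorrected (table-style raw pairwise
#' p-values). Welch is robust to the unequal variances typical of small
#' patient groups; `method = "tukey"` gives Tukey HSD adjusted p-values
#' from a pooled-variance fit instead.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (each group >= 2 values).
#' @return Tibble: `pair` (e.g. `"Ep-con"`), `estimate` (mean difference
#'   first minus second), `p`.
#' @param method `"welch"` (default) or `"tukey"`.
#' @export
posthoc_pairwise <- function(values, groups, method = c("welch", "tukey")) {
  method <- match.arg(method)
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) stop("every group needs >= 2 values", call. = FALSE)
  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  if (method == "tukey") {
    tk <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
    return(tibble(pair = sub("(.*)-(.*)", "\\2-\\1", rownames(tk)),
                  estimate = -tk[, "diff"], p = tk[, "p adj"]))
  }
  purrr::map_dfr(pairs, function(pr) {
    x <- values[groups == pr[1]]
    y <- values[groups == pr[2]]
    if (sd(x) == 0 && sd(y) == 0) {
      p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      return(tibble(pair = paste(pr, collapse = "-"),
                    estimate = mean(x) - mean(y), p = p))
    }
    tt <- t.test(x, y)
    tibble(pair = paste(pr, collapse = "-"),
           estimate = unname(diff(rev(tt$estimate))), p = tt$p.value)
  })
}

#' Group comparison of topological properties
#'
#' For every (scope, metric, node, weighting) cell of a [compute_metrics()]
#' table: z-transforms the per-subject values (pooled across groups), runs
#' a one-way ANOVA on the z-scores, adjusts p-values by Benjamini-Hochberg
#' within FDR families (nodal properties: across nodes within one metric
#' and weighting; global properties: across metrics within one weighting),
#' and attaches uncorrected pairwise post-hoc p-values where the cell
#' passes `q < posthoc_alpha`.
#'
#' @param metrics Tibble from [compute_metrics()].
#' @param z_scores Run the ANOVA on z-scores (default `TRUE`); `FALSE`
#'   analyses raw values.
#' @param posthoc_alpha FDR level gating the post-hoc tests (default 0.05);
#'   `NULL` computes post-hoc for every cell.
#' @param posthoc_method `"welch"` or `"tukey"`.
#' @return A `group_stats` tibble: `scope`, `metric`, `node`, `weighting`,
#'   `F_stat`, `p`, `q_fdr`, and one `posthoc_<pair>` column per group pair
#'   (NA where gated off).
#' @export
compare_groups <- function(metrics, z_scores = TRUE, posthoc_alpha = 0.05,
                           posthoc_method = "welch") {
  stopifnot(all(c("subject_id", "group", "weighting", "scope", "node",
                  "metric", "value") %in% names(metrics)))
  cells <- metrics %>%
    group_by(scope, metric, node, weighting) %>%
    summarise(
      res = list({
        v <- if (z_scores) as.numeric(z_transform(value)) else value
        oneway_anova(v, group)
      }),
      vals = list(if (z_scores) as.numeric(z_transform(value)) else value),
      grps = list(group),
      .groups = "drop"
    ) %>%
    tidyr::unnest(res)
  cells <- cells %>%
    mutate(.family = ifelse(scope == "nodal",
                            paste(scope, metric, weighting, sep = "|"),
                            paste(scope, weighting, sep = "|"))) %>%
    group_by(.family) %>%
    mutate(q_fdr = bh_fdr(p)) %>%
    ungroup()
  do_post <- if (is.null(posthoc_alpha)) {
    rep(TRUE, nrow(cells))
  } else {
    cells$q_fdr < posthoc_alpha
  }
  post <- purrr::map2(seq_len(nrow(cells)), do_post, function(i, go) {
    if (!go) return(NULL)
    posthoc_pairwise(cells$vals[[i]], cells$grps[[i]], posthoc_method)
  })
  pairs <- unique(unlist(lapply(post, function(p) if (!is.null(p)) p$pair)))
  out <- cells %>% select(scope, metric, node, weighting, F_stat, p, q_fdr,
                          degenerate)
  for (pr in pairs) {
    col <- paste0("posthoc_", gsub("-", "_", pr))
    out[[col]] <- vapply(post, function(tb) {
      if (is.null(tb)) NA_real_ else tb$p[tb$pair == pr]
    }, numeric(1))
  }
  class(out) <- c("group_stats", class(out))
  out
}

#' Unpaired t-test from printed summary statistics
#'
#' Reconstructs a two-sided unpaired t-test from group means and standard
#' errors as printed in demographics tables:
#' `t = (m_a - m_b) / sqrt(se_a^2 + se_b^2)`, df = `n_a + n_b - 2`.
#'
#' @param mean_a,se_a,n_a First group mean, standard error (> 0), size.
#' @param mean_b,se_b,n_b Second group.
#' @return Tibble: `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(mean_a, se_a, n_a, mean_b, se_b, n_b) {
  if (se_a <= 0 || se_b <= 0) stop("standard errors must be > 0", call. = FALSE)
  if (n_a < 2 || n_b < 2) stop("group sizes must be >= 2", call. = FALSE)
  t <- (mean_a - mean_b) / sqrt(se_a^2 + se_b^2)
  df <- n_a + n_b - 2
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Fisher's exact test on a 2x2 or 2x3 contingency table
#'
#' Exact conditional p-value with fixed margins (sum of point probabilities
#' not exceeding the observed table's), as used for categorical
#' demographics comparisons.
#'
#' @param counts Matrix of non-negative integer counts (2 rows, 2-3 cols).
#' @return The exact p-value.
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  fisher.test(counts)$p.value
}
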