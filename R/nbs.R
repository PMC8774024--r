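#' NBS configuration
#'
#' @param n_perm Number of label permutations (default 5000).
#' @param primary_alpha Primary component-forming threshold, expressed as an
#'   upper-tail probability of the F(k-1, n-k) reference distribution
#'   (default 0.01); edges with F above the corresponding quantile enter
#'   components.
#' @param component_stat `"intensity"` (default; sum of F minus threshold
#'   over a component's edges) or `"extent"` (edge count). Intensity retains
#'   power for strong effects confined to one or two edges; extent favours
#'   broad weak effects.
#' @param seed Integer seed for the permutation stream.
#' @return An `nbs_config` list.
#' @export
nbs_config <- function(n_perm = 5000, primary_alpha = 0.01,
                       component_stat = c("intensity", "extent"), seed = 1) {
  stopifnot(n_perm >= 1, primary_alpha > 0, primary_alpha < 1)
  structure(list(n_perm = as.integer(n_perm), primary_alpha = primary_alpha,
                 component_stat = match.arg(component_stat),
                 seed = as.integer(seed)),
            class = "nbs_config")
}

#' Edge-wise one-way F statistics
#'
#' Classical one-way ANOVA F computed per retained edge on that edge's
#' weights across subjects. Edges with zero total variance get F = 0; edges
#' with perfect group separation (zero within-group variance, positive
#' between-group variance) are capped at the sentinel `1e12` and flagged.
#'
#' @param cohort An `ms_cohort` with >= 2 groups of >= 2 subjects.
#' @param weighting Weighting to analyse.
#' @param mask Optional `backbone_mask`; the edge universe is the mask's
#'   upper triangle (all node pairs when `NULL`).
#' @return Tibble with columns `node_a`, `node_b`, `F_stat`, `degenerate`.
#' @export
edgewise_f <- function(cohort, weighting, mask = NULL) {
  ev <- cohort_edge_values(cohort, weighting, mask)
  fs <- f_stats_columns(ev$values, ev$groups)
  mutate(ev$edges[, c("node_a", "node_b")],
         F_stat = fs$f, degenerate = fs$degenerate)
}

#' Connected components of suprathreshold edges
#'
#' Edges whose F exceeds the threshold form a graph; its connected
#' components are the candidate networks scored by the permutation test.
#'
#' @param f_stats Tibble from [edgewise_f()] (columns `node_a`, `node_b`,
#'   `F_stat`).
#' @param threshold Primary F threshold (> 0).
#' @return Tibble with one row per component: `component`, `n_edges`,
#'   `stat_extent`, `stat_intensity`, and `edges` (list-column of edge
#'   tibbles). Empty (zero-row) when no edge is suprathreshold.
#' @export
suprathreshold_components <- function(f_stats, threshold) {
  stopifnot(threshold > 0)
  keep <- which(f_stats$F_stat > threshold)
  empty <- tibble(component = integer(0), n_edges = integer(0),
                  stat_extent = numeric(0), stat_intensity = numeric(0),
                  edges = list())
  if (!length(keep)) return(empty)
  sub <- f_stats[keep, ]
  nodes <- sort(unique(c(sub$node_a, sub$node_b)))
  comp <- edge_components(match(sub$node_a, nodes), match(sub$node_b, nodes))
  purrr::map_dfr(sort(unique(comp)), function(ci) {
    ed <- sub[comp == ci, c("node_a", "node_b", "F_stat")]
    tibble(component = ci, n_edges = nrow(ed),
           stat_extent = as.numeric(nrow(ed)),
           stat_intensity = sum(ed$F_stat - threshold),
           edges = list(ed))
  })
}

#' Network-based statistic permutation test
#'
#' Edge-wise one-way ANOVA with family-wise error control over connected
#' components: the observed suprathreshold components are scored, group
#' labels are permuted `n_perm` times (full relabelling preserving group
#' sizes), the null distribution is the maximum component statistic per
#' permutation, and each observed component gets
#' `p_fwe = (1 + #\{null >= observed\}) / (n_perm + 1)` (add-one estimator,
#' so p >= 1/(n_perm+1)). The primary threshold is the
#' `1 - primary_alpha` quantile of F(k-1, n-k).
#'
#' Post-hoc two-sided Welch t-tests between each pair of groups are
#' attached per suprathreshold edge for reporting.
#'
#' @param cohort An `ms_cohort`.
#' @param weighting Weighting to analyse.
#' @param mask A `backbone_mask` (or `NULL` for all node pairs).
#' @param config An [nbs_config()].
#' @return An `nbs_result` with elements `components` (tibble incl.
#'   `p_fwe`), `edge_stats`, `posthoc`, `threshold`, `null_max`, `config`,
#'   `weighting`. Methods: [tidy.nbs_result()], [glance.nbs_result()],
#'   [autoplot.nbs_result()].
#' @export
nbs_test <- function(cohort, weighting, mask = NULL, config = nbs_config()) {
  stopifnot(inherits(config, "nbs_config"))
  ev <- cohort_edge_values(cohort, weighting, mask)
  if (ncol(ev$values) == 0L) stop("edge universe is empty", call. = FALSE)
  X <- ev$values
  g <- as.factor(ev$groups)
  k <- nlevels(g)
  n <- nrow(X)
  fs <- f_stats_columns(X, g)
  threshold <- qf(1 - config$primary_alpha, fs$df1, fs$df2)
  f_tbl <- mutate(ev$edges[, c("node_a", "node_b")],
                  F_stat = fs$f, degenerate = fs$degenerate)
  comps <- suprathreshold_components(f_tbl, threshold)

  nodes <- retained_nodes_of_edges(ev$edges)
  ea_all <- match(ev$edges$node_a, nodes)
  eb_all <- match(ev$edges$node_b, nodes)

  set.seed(config$seed)
  null_max <- numeric(config$n_perm)
  for (b in seq_len(config$n_perm)) {
    gp <- g[sample.int(n)]
    fp <- f_stats_columns(X, gp)$f
    keep <- which(fp > threshold)
    null_max[b] <- if (length(keep)) {
      max_component_stat(ea_all[keep], eb_all[keep], fp[keep] - threshold,
                         config$component_stat)
    } else 0
  }
  if (nrow(comps)) {
    obs <- if (config$component_stat == "extent") comps$stat_extent else comps$stat_intensity
    comps$stat <- obs
    comps$p_fwe <- vapply(obs, function(s) {
      (1 + sum(null_max >= s)) / (config$n_perm + 1)
    }, numeric(1))
  } else {
    comps$stat <- numeric(0)
    comps$p_fwe <- numeric(0)
  }

  posthoc <- edge_posthoc(X, g, ev$edges, which(fs$f > threshold))

  structure(list(components = comps, edge_stats = f_tbl, posthoc = posthoc,
                 threshold = threshold, null_max = null_max,
                 config = config, weighting = weighting,
                 df1 = fs$df1, df2 = fs$df2),
            class = "nbs_result")
}

retained_nodes_of_edges <- function(edges) {
  sort(unique(c(edges$node_a, edges$node_b)))
}

# Welch pairwise t per selected edge (uncorrected, for table-style reporting)
edge_posthoc <- function(X, g, edges, sel) {
  if (!length(sel)) {
    return(tibble(node_a = character(0), node_b = character(0),
                  pair = character(0), p = numeric(0)))
  }
  lv <- levels(g)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  purrr::map_dfr(sel, function(e) {
    purrr::map_dfr(pairs, function(pr) {
      x <- X[g == pr[1], e]; y <- X[g == pr[2], e]
      p <- tryCatch(t.test(x, y)$p.value, error = function(err) NA_real_)
      tibble(node_a = edges$node_a[e], node_b = edges$node_b[e],
             pair = paste(pr, collapse = "-"), p = p)
    })
  })
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> weighting %s, %d permutations, F threshold %.3f (%s statistic)\n",
              x$weighting, x$config$n_perm, x$threshold,
              x$config$component_stat))
  if (nrow(x$components)) {
    print(x$components[, c("component", "n_edges", "stat", "p_fwe")])
  } else {
    cat("no suprathreshold components\n")
  }
  invisible(x)
}

#' Tidy an NBS result into an edge-level table
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return Tibble with one row per suprathreshold edge: `component`,
#'   `node_a`, `node_b`, `F_stat`, component `stat` and `p_fwe`.
#' @export
tidy.nbs_result <- function(x, ...) {
  if (!nrow(x$components)) {
    return(tibble(component = integer(0), node_a = character(0),
                  node_b = character(0), F_stat = numeric(0),
                  stat = numeric(0), p_fwe = numeric(0)))
  }
  purrr::map_dfr(seq_len(nrow(x$components)), function(i) {
    mutate(x$components$edges[[i]],
           component = x$components$component[i],
           stat = x$components$stat[i],
           p_fwe = x$components$p_fwe[i])
  }) %>% select(component, node_a, node_b, F_stat, stat, p_fwe)
}

#' One-row summary of an NBS result
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return One-row tibble: `weighting`, `n_perm`, `threshold`,
#'   `n_components`, `n_significant` (p_fwe < 0.05), `min_p_fwe`.
#' @export
glance.nbs_result <- function(x, ...) {
  tibble(weighting = x$weighting, n_perm = x$config$n_perm,
         threshold = x$threshold, n_components = nrow(x$components),
         n_significant = sum(x$components$p_fwe < 0.05),
         min_p_fwe = if (nrow(x$components)) min(x$components$p_fwe) else NA_real_)
}

#' Turn a result object into a tidy tibble
#' @param x A result object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model/result summary
#' @param x A result object.
#' @param ... Passed to methods.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")
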