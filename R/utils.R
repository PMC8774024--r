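# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# connected-component label per edge, via union-find on the edge endpoints;
# ea/eb are integer node indices. Result is independent of edge order
# (labels are renumbered by smallest member node).
edge_components <- function(ea, eb) {
  if (!length(ea)) return(integer(0))
  nmax <- max(ea, eb)
  parent <- seq_len(nmax)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(ea)) {
    ra <- find(ea[k]); rb <- find(eb[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(ea, find, integer(1))
  match(roots, sort(unique(roots)))
}

# largest component statistic among suprathreshold edges (permutation step)
max_component_stat <- function(ea, eb, excess, stat = c("intensity", "extent")) {
  stat <- match.arg(stat)
  if (!length(ea)) return(0)
  comp <- edge_components(ea, eb)
  if (stat == "extent") {
    max(tabulate(comp))
  } else {
    max(rowsum(excess, comp))
  }
}

# vectorized one-way F over the columns of X (subjects x variables);
# g is the group vector. Degenerate columns (within-group variance ~ 0 but
# between-group variance > 0) are capped at the sentinel 1e12.
f_stat_sentinel <- 1e12

f_stats_columns <- function(X, g) {
  g <- as.factor(g)
  ni <- as.vector(table(g))
  if (any(ni < 2)) stop("every group needs >= 2 subjects", call. = FALSE)
  k <- length(ni)
  n <- nrow(X)
  # centered sums of squares: avoids the catastrophic cancellation of the
  # raw-sums formula, where a constant nonzero column leaves pure rounding
  # noise in SStot and can masquerade as perfect group separation
  Xc <- X - rep(colMeans(X), each = n)
  SStot <- colSums(Xc^2)
  S <- rowsum(Xc, g)
  SSb <- pmin(pmax(colSums(S^2 / ni), 0), SStot)
  SSw <- SStot - SSb
  # a column whose total variation is rounding noise relative to its
  # magnitude has no variance at all
  zero_tot <- SStot <= 1e-10 * pmax(colSums(X^2), .Machine$double.xmin)
  tol <- 1e-9 * pmax(SStot, .Machine$double.xmin)
  f <- (SSb / (k - 1)) / (SSw / (n - k))
  degenerate <- !zero_tot & SSw <= tol & SSb > tol  # perfect separation
  f[degenerate] <- f_stat_sentinel
  f[zero_tot | (SSb <= tol)] <- 0
  list(f = f, df1 = k - 1, df2 = n - k, degenerate = degenerate)
}
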