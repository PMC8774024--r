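# Independent oracles, deliberately written with different algorithms than
# the package (dense Floyd-Warshall vs Dijkstra; exhaustive simple-path
# enumeration vs igraph betweenness; hand step-up vs p.adjust; ...).

# all-pairs shortest paths by Floyd-Warshall on a length matrix
floyd_warshall <- function(lengths) {
  d <- as.matrix(lengths)
  n <- nrow(d)
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# betweenness by exhaustive enumeration of simple paths (N <= 8)
betweenness_oracle <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  counts <- numeric(n)
  all_paths <- function(cur, target, visited, dist) {
    last <- cur[length(cur)]
    if (last == target) return(list(list(path = cur, dist = dist)))
    out <- list()
    for (nxt in which(is.finite(len[last, ]))) {
      if (!visited[nxt]) {
        v2 <- visited; v2[nxt] <- TRUE
        out <- c(out, all_paths(c(cur, nxt), target, v2, dist + len[last, nxt]))
      }
    }
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      visited <- rep(FALSE, n); visited[s] <- TRUE
      paths <- all_paths(s, t, visited, 0)
      if (!length(paths)) next
      dists <- vapply(paths, `[[`, numeric(1), "dist")
      dmin <- min(dists)
      shortest <- paths[dists <= dmin * (1 + 1e-12) + 1e-12]
      for (p in shortest) {
        interior <- setdiff(p$path, c(s, t))
        counts[interior] <- counts[interior] + 1 / length(shortest)
      }
    }
  }
  counts / ((n - 1) * (n - 2) / 2)
}

# one-way ANOVA F from a fitted linear model (textbook route)
anova_oracle <- function(values, groups) {
  fit <- stats::anova(stats::lm(values ~ factor(groups)))
  list(f = fit$`F value`[1], p = fit$`Pr(>F)`[1])
}

# one-way ANOVA F recomputed from group summary statistics only
anova_from_summaries <- function(values, groups) {
  groups <- factor(groups)
  ni <- tapply(values, groups, length)
  mi <- tapply(values, groups, mean)
  vi <- tapply(values, groups, var)
  n <- sum(ni); k <- length(ni)
  grand <- sum(ni * mi) / n
  msb <- sum(ni * (mi - grand)^2) / (k - 1)
  msw <- sum((ni - 1) * vi) / (n - k)
  msb / msw
}

# Benjamini-Hochberg step-up by hand
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Fisher exact p on a 2xC table by full enumeration of fixed-margin tables
fisher_oracle <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  log_prob <- function(t2) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(t2) + 1) -
      sum(lgamma(t2 + 1))
  }
  p_obs <- log_prob(tab)
  enumerate <- function(fixed_top, col) {
    if (col == ncol(tab)) {
      rem <- rs[1] - sum(fixed_top)
      if (rem < 0 || rem > cs[col]) return(numeric(0))
      t2 <- rbind(c(fixed_top, rem), cs - c(fixed_top, rem))
      if (any(t2 < 0)) return(numeric(0))
      return(log_prob(t2))
    }
    unlist(lapply(0:min(cs[col], rs[1] - sum(fixed_top)), function(x) {
      enumerate(c(fixed_top, x), col + 1)
    }))
  }
  lp <- enumerate(numeric(0), 1)
  sum(exp(lp[lp <= p_obs + 1e-9]))
}
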