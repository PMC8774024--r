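#' Null-model configuration for small-world indices
#'
#' @param n_null Number of degree-preserving random networks (default 100).
#' @param swaps_per_edge Attempted double-edge swaps per edge (default 10).
#' @param seed Integer seed.
#' @return A `null_model_config` list.
#' @export
null_model_config <- function(n_null = 100, swaps_per_edge = 10, seed = 1) {
  stopifnot(n_null >= 1, swaps_per_edge >= 1)
  structure(list(n_null = as.integer(n_null),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 seed = as.integer(seed)),
            class = "null_model_config")
}

#' Degree-preserving rewiring (Maslov-Sneppen double-edge swaps)
#'
#' Randomises a network while exactly preserving its binary degree
#' sequence: repeatedly picks two edges (a,b), (c,d) and rewires them to
#' (a,d), (c,b), rejecting swaps that would create self-loops or duplicate
#' edges. Weights travel with their rewired edges, so the weight multiset
#' is preserved too. `swaps_per_edge * E` swaps are attempted.
#'
#' @param m A `connectome_matrix` (or non-negative symmetric matrix).
#' @param config A [null_model_config()]; its `seed` makes the rewiring
#'   deterministic.
#' @return A matrix of the same class/attributes. When the graph has fewer
#'   than 2 edges a copy is returned with attribute `rewire_warning = TRUE`.
#' @export
rewire_preserving_degree <- function(m, config = null_model_config()) {
  w <- unclass(m)
  n <- nrow(w)
  idx <- which(upper.tri(w) & w > 0)
  ne <- length(idx)
  if (ne < 2) {
    out <- m
    attr(out, "rewire_warning") <- TRUE
    return(out)
  }
  set.seed(config$seed)
  ea <- ((idx - 1L) %% n) + 1L
  eb <- ((idx - 1L) %/% n) + 1L
  wts <- w[idx]
  adj <- w > 0
  n_attempts <- config$swaps_per_edge * ne
  pick1 <- sample.int(ne, n_attempts, replace = TRUE)
  pick2 <- sample.int(ne, n_attempts, replace = TRUE)
  orient <- runif(n_attempts) < 0.5
  for (t in seq_len(n_attempts)) {
    e1 <- pick1[t]; e2 <- pick2[t]
    if (e1 == e2) next
    a <- ea[e1]; b <- eb[e1]; c <- ea[e2]; d <- eb[e2]
    # two possible re-pairings; pick one at random for detailed balance
    if (orient[t]) { tmp <- c; c <- d; d <- tmp }
    # propose (a,d) and (c,b)
    if (a == d || c == b) next
    if (adj[a, d] || adj[c, b]) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c, d] <- adj[d, c] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    adj[c, b] <- adj[b, c] <- TRUE
    ea[e1] <- min(a, d); eb[e1] <- max(a, d)
    ea[e2] <- min(c, b); eb[e2] <- max(c, b)
  }
  out <- matrix(0, n, n, dimnames = dimnames(w))
  out[cbind(ea, eb)] <- wts
  out <- out + t(out)
  attr(out, "subject_id") <- attr(m, "subject_id")
  attr(out, "weighting") <- attr(m, "weighting")
  attr(out, "atlas_name") <- attr(m, "atlas_name")
  class(out) <- class(m)
  out
}

#' Small-world indices gamma, lambda, sigma
#'
#' Compares the network's mean clustering coefficient `C_p` and
#' characteristic path length `L_p` with their means over `n_null`
#' degree-preserving random networks: `gamma = C_p / <C_p^rand>`,
#' `lambda = L_p / <L_p^rand>`, `sigma = gamma / lambda`. `sigma > 1`
#' (high clustering at near-random path length) indicates small-world
#' organisation. A null that comes out disconnected contributes its
#' reachable-pair mean path length and is counted in
#' `n_disconnected_nulls`.
#'
#' @param m A `connectome_matrix` (ideally connected, post-backbone).
#' @param config A [null_model_config()]; null `k` is rewired with seed
#'   `config$seed + k` for reproducibility.
#' @param convention Length convention for weighted distances.
#' @return List with `gamma`, `lambda`, `sigma`, `c_p`, `l_p`,
#'   `c_p_rand`, `l_p_rand`, `n_disconnected_nulls`.
#' @export
small_world_indices <- function(m, config = null_model_config(),
                                convention = "reciprocal") {
  cp <- mean(clustering_coefficient(m))
  d <- distance_matrix(m, convention)
  lp <- characteristic_path_length(d)
  cps <- numeric(config$n_null)
  lps <- numeric(config$n_null)
  disc <- 0L
  for (k in seq_len(config$n_null)) {
    cfg_k <- config
    cfg_k$seed <- config$seed + k
    r <- rewire_preserving_degree(m, cfg_k)
    cps[k] <- mean(clustering_coefficient(r))
    dr <- distance_matrix(r, convention)
    if (unreachable_fraction(dr) > 0) disc <- disc + 1L
    lps[k] <- characteristic_path_length(dr)
  }
  gamma <- cp / mean(cps)
  lambda <- lp / mean(lps)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       c_p = cp, l_p = lp, c_p_rand = mean(cps), l_p_rand = mean(lps),
       n_disconnected_nulls = disc)
}
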