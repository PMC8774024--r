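# Test fixtures are built in code: small atlases, hand graphs, and cohorts
# with fully controlled edge values.

# write an n_pairs-pair bilateral atlas JSON and load it
make_test_atlas <- function(n_pairs = 3, exclude = character(0)) {
  ids <- as.vector(rbind(paste0("N", seq_len(n_pairs), "_L"),
                         paste0("N", seq_len(n_pairs), "_R")))
  nodes <- lapply(ids, function(id) {
    list(id = id, hemisphere = substr(id, nchar(id), nchar(id)),
         gyrus = "test", excluded = FALSE)
  })
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(name = "test_atlas", nodes = nodes),
                       path, auto_unbox = TRUE)
  atl <- load_atlas(path)
  if (length(exclude)) atl <- exclude_nodes(atl, exclude)
  atl
}

# connectome matrix from an edge list (1-based node indices) on a test atlas
cm_from_edges <- function(edges, n_nodes, weights = 1, weighting = "binary",
                          atlas = NULL, subject_id = "s") {
  if (is.null(atlas)) atlas <- make_test_atlas(ceiling(n_nodes / 2))
  ids <- retained_nodes(atlas)[seq_len(n_nodes)]
  if (length(ids) < n_nodes) stop("atlas too small")
  m <- matrix(0, n_nodes, n_nodes, dimnames = list(ids, ids))
  weights <- rep_len(weights, nrow(edges))
  for (k in seq_len(nrow(edges))) {
    m[edges[k, 1], edges[k, 2]] <- weights[k]
    m[edges[k, 2], edges[k, 1]] <- weights[k]
  }
  atl <- if (n_nodes == length(retained_nodes(atlas))) atlas else {
    exclude_nodes(atlas, setdiff(retained_nodes(atlas), ids))
  }
  connectome_matrix(m, weighting, atl, subject_id)
}

# classic named graphs as plain binary matrices (no atlas machinery)
path3 <- function() {
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 1; m[2, 3] <- m[3, 2] <- 1
  dimnames(m) <- list(paste0("n", 1:3), paste0("n", 1:3))
  m
}
complete_graph <- function(n) {
  m <- matrix(1, n, n); diag(m) <- 0
  dimnames(m) <- list(paste0("n", 1:n), paste0("n", 1:n))
  m
}
star_graph <- function(n) {
  m <- matrix(0, n, n); m[1, 2:n] <- 1; m[2:n, 1] <- 1
  dimnames(m) <- list(paste0("n", 1:n), paste0("n", 1:n))
  m
}
ring_lattice <- function(n = 20, k = 4) {
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (s in seq_len(k / 2)) {
      j <- ((i - 1 + s) %% n) + 1
      m[i, j] <- m[j, i] <- 1
    }
  }
  dimnames(m) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  m
}
er_graph <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  m[ut] <- as.numeric(runif(sum(ut)) < p)
  m <- m + t(m)
  dimnames(m) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  m
}

# cohort in which every subject shares a base matrix (a ring, so connected)
# except that one edge (between nodes 1 and 2) takes the per-subject values
# given in `edge_values`; groups has one label per subject.
cohort_with_edge_values <- function(edge_values, groups, n_nodes = 6,
                                    weighting = "FA", base_weight = 0.5) {
  atlas <- make_test_atlas(n_nodes / 2)
  ids <- retained_nodes(atlas)
  base <- matrix(0, n_nodes, n_nodes, dimnames = list(ids, ids))
  for (i in seq_len(n_nodes)) {
    j <- (i %% n_nodes) + 1
    base[i, j] <- base[j, i] <- base_weight
  }
  rows <- purrr::map_dfr(seq_along(edge_values), function(s) {
    m <- base
    m[1, 2] <- m[2, 1] <- edge_values[s]
    tibble::tibble(
      subject_id = sprintf("s%02d", s), group = groups[s],
      weighting = weighting,
      matrix = list(connectome_matrix(m, weighting, atlas,
                                      sprintf("s%02d", s)))
    )
  })
  ms_cohort(rows, atlas)
}

# cohort of identical subjects (one matrix replicated), 3 groups
identical_cohort <- function(n_per_group = 3, n_nodes = 6) {
  atlas <- make_test_atlas(n_nodes / 2)
  ids <- retained_nodes(atlas)
  m <- matrix(0, n_nodes, n_nodes, dimnames = list(ids, ids))
  for (i in seq_len(n_nodes)) {
    j <- (i %% n_nodes) + 1
    m[i, j] <- m[j, i] <- 0.5
  }
  m[1, 3] <- m[3, 1] <- 0.4
  groups <- rep(c("Ep", "nEp", "con"), each = n_per_group)
  rows <- purrr::map_dfr(seq_along(groups), function(s) {
    sid <- sprintf("s%02d", s)
    purrr::map_dfr(c("binary", "FA"), function(w) {
      v <- if (w == "binary") (m > 0) * 1 else m
      tibble::tibble(subject_id = sid, group = groups[s], weighting = w,
                     matrix = list(connectome_matrix(v, w, atlas, sid)))
    })
  })
  ms_cohort(rows, atlas)
}
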