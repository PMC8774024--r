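ms_global_metrics <- c("global_efficiency", "shortest_path_length",
                       "unreachable_fraction", "local_efficiency",
                       "clustering_coefficient")
ms_nodal_metrics <- c("nodal_efficiency", "degree_centrality",
                      "betweenness_centrality", "clustering_coefficient",
                      "nodal_shortest_path_length", "local_efficiency")

#' Compute topological properties of a cohort
#'
#' Applies the backbone mask (when given) to every matrix and returns one
#' tidy table of global and nodal properties per subject and weighting.
#'
#' Global metrics: `global_efficiency`, `shortest_path_length` (reachable
#' -pair mean), `unreachable_fraction`, `local_efficiency` (network mean),
#' `clustering_coefficient` (network mean `C_p`), and - when
#' `small_world = TRUE` - `gamma`, `lambda`, `sigma` against
#' degree-preserving nulls. Nodal metrics: `nodal_efficiency`,
#' `degree_centrality`, `betweenness_centrality`, `clustering_coefficient`,
#' `nodal_shortest_path_length`, `local_efficiency`.
#'
#' @param cohort An `ms_cohort`.
#' @param mask Optional `backbone_mask` from [consistency_mask()].
#' @param weightings Weightings to process (default: all present).
#' @param metrics Which metrics to compute (default: all of the above);
#'   subsetting skips the costlier computations.
#' @param small_world Compute gamma/lambda/sigma (default `FALSE`; the null
#'   ensemble dominates run time).
#' @param null_config [null_model_config()] for the small-world nulls; each
#'   subject-weighting pair gets a distinct derived seed.
#' @param convention Length convention for weighted distances
#'   (see [edge_lengths()]).
#' @param lp_method Path-length averaging (see
#'   [characteristic_path_length()]).
#' @return Tibble with columns `subject_id`, `group`, `weighting`, `scope`
#'   (`"global"`/`"nodal"`), `node` (`NA` for global rows), `metric`,
#'   `value`.
#' @export
compute_metrics <- function(cohort, mask = NULL,
                            weightings = NULL,
                            metrics = NULL,
                            small_world = FALSE,
                            null_config = null_model_config(),
                            convention = "reciprocal",
                            lp_method = "reachable-mean") {
  stopifnot(inherits(cohort, "ms_cohort"))
  if (is.null(weightings)) weightings <- sort(unique(cohort$weighting))
  want_g <- if (is.null(metrics)) ms_global_metrics else intersect(metrics, ms_global_metrics)
  want_n <- if (is.null(metrics)) ms_nodal_metrics else intersect(metrics, ms_nodal_metrics)
  if (!is.null(metrics)) {
    unknown <- setdiff(metrics, unique(c(ms_global_metrics, ms_nodal_metrics)))
    if (length(unknown)) {
      stop("unknown metric(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  sub <- cohort[cohort$weighting %in% weightings, ]
  out <- vector("list", nrow(sub))
  for (k in seq_len(nrow(sub))) {
    m <- sub$matrix[[k]]
    if (!is.null(mask)) m <- apply_mask(m, mask)
    d <- distance_matrix(m, convention)
    cc <- if (any(c(want_g, want_n) == "clustering_coefficient") || small_world) {
      clustering_coefficient(m)
    }
    le <- if (any(c(want_g, want_n) == "local_efficiency")) {
      local_efficiency(m, convention)
    }
    glob <- c(
      global_efficiency = if ("global_efficiency" %in% want_g) global_efficiency(d),
      shortest_path_length = if ("shortest_path_length" %in% want_g) {
        characteristic_path_length(d, lp_method)
      },
      unreachable_fraction = if ("unreachable_fraction" %in% want_g) {
        unreachable_fraction(d)
      },
      local_efficiency = if ("local_efficiency" %in% want_g) mean(le),
      clustering_coefficient = if ("clustering_coefficient" %in% want_g) mean(cc)
    )
    if (small_world) {
      cfg <- null_config
      cfg$seed <- null_config$seed + 1000L * (k - 1L)
      sw <- small_world_indices(m, cfg, convention)
      glob <- c(glob, gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
    }
    ids <- rownames(d)
    nodal <- list(
      nodal_efficiency = if ("nodal_efficiency" %in% want_n) nodal_efficiency(d),
      degree_centrality = if ("degree_centrality" %in% want_n) degree_centrality(m),
      betweenness_centrality = if ("betweenness_centrality" %in% want_n) {
        betweenness_centrality(m, convention)
      },
      clustering_coefficient = if ("clustering_coefficient" %in% want_n) cc,
      nodal_shortest_path_length = if ("nodal_shortest_path_length" %in% want_n) {
        nodal_path_length(d)
      },
      local_efficiency = if ("local_efficiency" %in% want_n) le
    )
    nodal <- nodal[!vapply(nodal, is.null, logical(1))]
    out[[k]] <- bind_rows(
      tibble(subject_id = sub$subject_id[k], group = sub$group[k],
             weighting = sub$weighting[k], scope = "global",
             node = NA_character_, metric = names(glob),
             value = unname(glob)),
      purrr::map_dfr(names(nodal), function(nm) {
        tibble(subject_id = sub$subject_id[k], group = sub$group[k],
               weighting = sub$weighting[k], scope = "nodal",
               node = ids, metric = nm, value = unname(nodal[[nm]]))
      })
    )
  }
  bind_rows(out)
}
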