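#' Planted group effect on one edge
#'
#' Effects are multiplicative reductions (multiplier in (0, 1]) applied to
#' one edge in one weighting for the affected groups, matching the
#' directionality of the study findings (patient groups show *lower* FA/FN
#' on disrupted connections) without committing to units the literature does
#' not give.
#'
#' @param node_a,node_b Edge endpoints (retained node ids).
#' @param weighting One of `"FA"`, `"FN"`, `"FL"`.
#' @param groups Character vector of affected group labels (subset of the
#'   patient groups, e.g. `c("Ep")` or `c("Ep", "nEp")`).
#' @param multiplier Real in (0, 1].
#' @return One-row tibble usable in `sim_config(effects = ...)`.
#' @export
planted_effect <- function(node_a, node_b, weighting, groups, multiplier) {
  stopifnot(is.numeric(multiplier), multiplier > 0, multiplier <= 1)
  weighting <- match.arg(weighting, c("FA", "FN", "FL"))
  tibble(node_a = node_a, node_b = node_b, weighting = weighting,
         groups = list(as.character(groups)), multiplier = multiplier)
}

#' Default planted effects
#'
#' Encodes the qualitative finding pattern the generator emulates: an
#' Ep-specific FA reduction on the interhemispheric supplementary-motor-area
#' connection (A6m_L--A6m_R) and FN reductions in both patient groups on the
#' two trunk/limb sensorimotor connections. The multiplier 0.6 gives
#' detection power >= 0.8 at n = 10 per group under the default noise level.
#'
#' @return Tibble of planted effects.
#' @export
default_planted_effects <- function() {
  bind_rows(
    planted_effect("A6m_L", "A6m_R", "FA", "Ep", 0.6),
    planted_effect("A123tru_L", "A4ul_L", "FN", c("Ep", "nEp"), 0.6),
    planted_effect("A123tru_R", "A4t_R", "FN", c("Ep", "nEp"), 0.6)
  )
}

#' Simulation configuration for synthetic cohorts
#'
#' Defines the population template (one shared binary support with FN/FA/FL
#' weights), subject-level variability, and the planted group effects. The
#' defaults emulate the study conditions: three groups of 10 subjects over
#' the 22 retained nodes of the packaged 28-subregion motor-sensory atlas,
#' hub structure at the bilateral medial area 6 (A6m_L/A6m_R), and
#' reductions at the three reported edges.
#'
#' @param n_per_group Subjects per group (default 10).
#' @param seed Integer seed; the template uses `seed`, subject-level draws
#'   use `seed + 1`.
#' @param groups Group labels (default `Ep`, `nEp`, `con`).
#' @param hub_nodes Hub node ids (default bilateral medial area 6).
#' @param edge_density Connection probability between non-hub node pairs.
#' @param hub_density Connection probability between a hub and any other
#'   node; redrawn until every hub reaches >= 80% of the other nodes.
#' @param fn_log_mean,fn_log_sd Lognormal parameters of template streamline
#'   counts (FN).
#' @param hub_fn_boost,hub_fl_boost Multipliers on hub-incident FN / FL,
#'   giving the hubs the highest strength as observed for the
#'   supplementary motor area.
#' @param fa_mean,fa_sd,fa_range Truncated-normal parameters for template FA;
#'   the (0.2, 0.8) range reflects the tracking FA floor of 0.2.
#' @param fl_mean,fl_sd,fl_range Truncated-normal parameters for template
#'   mean tract length (mm).
#' @param subject_noise_sd Multiplicative lognormal jitter per subject, edge
#'   and weighting (sdlog scale).
#' @param edge_drop Named per-group probabilities that a subject loses a
#'   non-hub, non-homotopic template edge entirely (zero in all weightings).
#'   Higher dropout in the patient groups produces the global binary/FL
#'   efficiency deficits the multiplicative effects alone cannot.
#' @param hub_attenuation Named per-group multiplier in (0, 1] applied to
#'   every hub-incident edge in the weighted layers (FA, FN, FL). The
#'   default 0.9 for the Ep group encodes the reported hub degradation at
#'   the bilateral medial area 6 - a marked drop of A6m degree centrality
#'   and nodal efficiency in the stimulation-epilepsy group - which a
#'   single-edge effect diluted over ~21 hub connections cannot produce.
#'   A 10% strength shift against a per-edge noise SD of 5% (so a hub
#'   strength SD near 5%/sqrt(21)) is decisive at n = 10 per group.
#'   Groups not named keep their hub edges untouched.
#' @param effects Tibble of [planted_effect()] rows.
#' @param atlas Atlas (default: packaged atlas with default exclusions,
#'   22 retained nodes).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_per_group = 10,
                       seed = 1,
                       groups = c("Ep", "nEp", "con"),
                       hub_nodes = c("A6m_L", "A6m_R"),
                       edge_density = 0.35,
                       hub_density = 0.9,
                       fn_log_mean = 4,
                       fn_log_sd = 0.8,
                       hub_fn_boost = 3,
                       hub_fl_boost = 1.6,
                       fa_mean = 0.5,
                       fa_sd = 0.1,
                       fa_range = c(0.2, 0.8),
                       fl_mean = 60,
                       fl_sd = 15,
                       fl_range = c(10, 150),
                       subject_noise_sd = 0.05,
                       edge_drop = c(Ep = 0.15, nEp = 0.08, con = 0.02),
                       hub_attenuation = c(Ep = 0.9),
                       effects = default_planted_effects(),
                       atlas = NULL) {
  if (is.null(atlas)) {
    atlas <- load_atlas()
    atlas <- exclude_nodes(atlas, default_excluded_nodes(atlas))
  }
  cfg <- list(
    n_per_group = n_per_group, seed = as.integer(seed), groups = groups,
    hub_nodes = hub_nodes, edge_density = edge_density,
    hub_density = hub_density, fn_log_mean = fn_log_mean,
    fn_log_sd = fn_log_sd, hub_fn_boost = hub_fn_boost,
    hub_fl_boost = hub_fl_boost, fa_mean = fa_mean, fa_sd = fa_sd,
    fa_range = fa_range, fl_mean = fl_mean, fl_sd = fl_sd,
    fl_range = fl_range, subject_noise_sd = subject_noise_sd,
    edge_drop = edge_drop, hub_attenuation = hub_attenuation,
    effects = effects, atlas = atlas
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.numeric(cfg$n_per_group) || cfg$n_per_group < 1) {
    stop("n_per_group must be >= 1", call. = FALSE)
  }
  if (length(cfg$groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (cfg$edge_density <= 0 || cfg$edge_density > 1) {
    stop("edge_density must lie in (0, 1]", call. = FALSE)
  }
  pos <- c("fn_log_sd", "fa_sd", "fl_sd", "fa_mean", "fl_mean",
           "hub_fn_boost", "hub_fl_boost")
  for (p in pos) {
    if (cfg[[p]] <= 0) stop(p, " must be > 0", call. = FALSE)
  }
  if (cfg$subject_noise_sd < 0) stop("subject_noise_sd must be >= 0", call. = FALSE)
  if (any(cfg$edge_drop < 0) || any(cfg$edge_drop >= 1)) {
    stop("edge_drop rates must lie in [0, 1)", call. = FALSE)
  }
  missing_drop <- setdiff(cfg$groups, names(cfg$edge_drop))
  if (length(missing_drop)) {
    stop("edge_drop lacks rates for group(s): ",
         paste(missing_drop, collapse = ", "), call. = FALSE)
  }
  if (length(cfg$hub_attenuation)) {
    if (any(cfg$hub_attenuation <= 0) || any(cfg$hub_attenuation > 1)) {
      stop("hub_attenuation multipliers must lie in (0, 1]", call. = FALSE)
    }
    bad_att <- setdiff(names(cfg$hub_attenuation), cfg$groups)
    if (length(bad_att)) {
      stop("hub_attenuation names unknown group(s): ",
           paste(bad_att, collapse = ", "), call. = FALSE)
    }
  }
  ids <- retained_nodes(cfg$atlas)
  unknown_hub <- setdiff(cfg$hub_nodes, ids)
  if (length(unknown_hub)) {
    stop("hub node(s) not retained in atlas: ",
         paste(unknown_hub, collapse = ", "), call. = FALSE)
  }
  if (nrow(cfg$effects)) {
    eff_nodes <- unique(c(cfg$effects$node_a, cfg$effects$node_b))
    unknown <- setdiff(eff_nodes, ids)
    if (length(unknown)) {
      stop("planted-effect endpoint(s) not retained in atlas: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    bad_grp <- setdiff(unique(unlist(cfg$effects$groups)), cfg$groups)
    if (length(bad_grp)) {
      stop("planted-effect group(s) unknown: ", paste(bad_grp, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(cfg)
}

# serializable echo of a config (drops the atlas tibble, keeps its name)
sim_config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$atlas <- attr(cfg$atlas, "name")
  if (nrow(cfg$effects)) {
    out$effects <- purrr::pmap(cfg$effects,
      function(node_a, node_b, weighting, groups, multiplier) {
        list(node_a = node_a, node_b = node_b, weighting = weighting,
             groups = as.list(groups), multiplier = multiplier)
      })
  } else {
    out$effects <- list()
  }
  out$edge_drop <- as.list(cfg$edge_drop)
  out$hub_attenuation <- as.list(cfg$hub_attenuation)
  out
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# homotopic (left/right counterpart) logical matrix over retained ids
homotopic_pairs <- function(ids) {
  base <- sub("_[LR]$", "", ids)
  hemi <- sub("^.*_", "", ids)
  outer(seq_along(ids), seq_along(ids), function(i, j) {
    base[i] == base[j] & hemi[i] != hemi[j]
  })
}

#' Generate the population template networks
#'
#' Draws one binary support shared by all weightings (deterministic
#' tractography yields a single streamline set from which every weight
#' derives) and population-level FN/FA/FL weights on it. Hubs connect to at
#' least 80% of the other nodes, homotopic left/right pairs are always
#' connected, planted-effect edges are always present, and the support is
#' redrawn (up to 1000 times) until connected.
#'
#' @param config A [sim_config()].
#' @return Named list of `connectome_matrix` objects
#'   (`binary`, `FA`, `FN`, `FL`) for a pseudo-subject `"template"`.
#' @export
generate_template <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  atlas <- config$atlas
  ids <- retained_nodes(atlas)
  n <- length(ids)
  is_hub <- ids %in% config$hub_nodes
  homo <- homotopic_pairs(ids)
  prob <- matrix(config$edge_density, n, n)
  prob[is_hub, ] <- config$hub_density
  prob[, is_hub] <- config$hub_density
  prob[homo] <- 1
  if (nrow(config$effects)) {
    ai <- match(config$effects$node_a, ids)
    bi <- match(config$effects$node_b, ids)
    prob[cbind(ai, bi)] <- 1
    prob[cbind(bi, ai)] <- 1
  }
  ut <- upper.tri(prob)
  support <- NULL
  for (try in seq_len(1000L)) {
    s <- matrix(0, n, n)
    s[ut] <- as.numeric(runif(sum(ut)) < prob[ut])
    s <- s + t(s)
    deg_to_hub_ok <- all(rowSums(s)[is_hub] >= 0.8 * (n - 1))
    g <- igraph::graph_from_adjacency_matrix(s, mode = "undirected")
    if (deg_to_hub_ok && igraph::is_connected(g)) {
      support <- s
      break
    }
  }
  if (is.null(support)) {
    stop("could not draw a connected template in 1000 attempts; ",
         "raise edge_density", call. = FALSE)
  }
  e_idx <- which(upper.tri(support) & support > 0)
  ne <- length(e_idx)
  hub_inc <- (matrix(is_hub, n, n) | matrix(is_hub, n, n, byrow = TRUE))[e_idx]

  fn <- rlnorm(ne, config$fn_log_mean, config$fn_log_sd)
  fn[hub_inc] <- fn[hub_inc] * config$hub_fn_boost
  fa <- rtruncnorm(ne, config$fa_mean, config$fa_sd,
                   config$fa_range[1], config$fa_range[2])
  fl <- rtruncnorm(ne, config$fl_mean, config$fl_sd,
                   config$fl_range[1], config$fl_range[2])
  fl[hub_inc] <- pmin(fl[hub_inc] * config$hub_fl_boost, config$fl_range[2])

  fill <- function(vals) {
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[e_idx] <- vals
    m + t(m)
  }
  list(
    binary = connectome_matrix(fill(rep(1, ne)), "binary", atlas, "template"),
    FA = connectome_matrix(fill(fa), "FA", atlas, "template"),
    FN = connectome_matrix(fill(fn), "FN", atlas, "template"),
    FL = connectome_matrix(fill(fl), "FL", atlas, "template")
  )
}

#' Generate a synthetic three-group cohort
#'
#' Each subject is the template under i.i.d. multiplicative lognormal edge
#' noise, minus a per-group random subset of droppable edges (dropout zeroes
#' the edge in all four weightings, so the subject's weightings share one
#' binary support), with the group's hub attenuation applied to hub-incident
#' weighted edges and planted multipliers then applied to the affected
#' edges/weightings; the binary matrix is derived as FN > 0.
#'
#' @param config A [sim_config()].
#' @return An `ms_cohort` with `3 * n_per_group` subjects (groups x n).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  template <- generate_template(config)
  atlas <- config$atlas
  ids <- retained_nodes(atlas)
  n <- length(ids)
  support <- unclass(template$binary) > 0
  ut <- upper.tri(support)
  e_idx <- which(ut & support)
  is_hub <- ids %in% config$hub_nodes
  homo <- homotopic_pairs(ids)
  hub_or_homo_free_hub <- (matrix(is_hub, n, n) | matrix(is_hub, n, n, byrow = TRUE))
  hub_or_homo <- hub_or_homo_free_hub | homo
  droppable <- e_idx[!hub_or_homo[e_idx]]

  eff <- config$effects
  if (nrow(eff)) {
    ai <- match(eff$node_a, ids); bi <- match(eff$node_b, ids)
    lo <- pmin(ai, bi); hi <- pmax(ai, bi)
    eff_idx <- (hi - 1L) * n + lo  # linear index in the upper triangle
    if (!all(support[eff_idx])) {
      stop("planted-effect edge absent from template support", call. = FALSE)
    }
  }

  set.seed(config$seed + 1L)
  sdlog <- config$subject_noise_sd
  tvals <- lapply(template[c("FA", "FN", "FL")], function(m) unclass(m)[e_idx])

  rows <- vector("list", 0L)
  for (g in config$groups) {
    for (s in seq_len(config$n_per_group)) {
      sid <- sprintf("%s_%02d", g, s)
      vals <- lapply(tvals, function(v) {
        v * rlnorm(length(v), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      })
      vals$FA <- pmin(pmax(vals$FA, config$fa_range[1] + 1e-9),
                      config$fa_range[2] - 1e-9)
      drop <- droppable[runif(length(droppable)) < config$edge_drop[[g]]]
      if (length(drop)) {
        at <- match(drop, e_idx)
        for (w in names(vals)) vals[[w]][at] <- 0
      }
      if (g %in% names(config$hub_attenuation)) {
        att <- config$hub_attenuation[[g]]
        hub_e <- hub_or_homo_free_hub[e_idx]
        for (w in names(vals)) vals[[w]][hub_e] <- vals[[w]][hub_e] * att
      }
      if (nrow(eff)) {
        for (k in seq_len(nrow(eff))) {
          if (g %in% eff$groups[[k]]) {
            at <- match(eff_idx[k], e_idx)
            vals[[eff$weighting[k]]][at] <- vals[[eff$weighting[k]]][at] *
              eff$multiplier[k]
          }
        }
      }
      fill <- function(v) {
        m <- matrix(0, n, n, dimnames = list(ids, ids))
        m[e_idx] <- v
        m + t(m)
      }
      mats <- list(
        binary = connectome_matrix(fill(as.numeric(vals$FN > 0)), "binary",
                                   atlas, sid),
        FA = connectome_matrix(fill(vals$FA), "FA", atlas, sid),
        FN = connectome_matrix(fill(vals$FN), "FN", atlas, sid),
        FL = connectome_matrix(fill(vals$FL), "FL", atlas, sid)
      )
      rows[[length(rows) + 1L]] <- tibble(
        subject_id = sid, group = g, weighting = names(mats), matrix = mats
      )
    }
  }
  ms_cohort(bind_rows(rows), atlas, sim_config = config)
}

# strip planted effects, equalize dropout and drop the hub attenuation so
# groups differ only by label
null_config <- function(config) {
  validate_sim_config(config)
  config$effects <- config$effects[0, ]
  config$edge_drop[] <- mean(config$edge_drop)
  config$hub_attenuation <- numeric(0)
  config
}

#' Generate a null cohort (no group differences)
#'
#' [generate_cohort()] with every planted effect stripped and the edge
#' dropout rate equalised across groups: the three groups differ only by
#' label. Used as the type-I-error harness for the permutation and FDR
#' machinery.
#'
#' @param config A [sim_config()].
#' @return An `ms_cohort`.
#' @export
null_cohort <- function(config) {
  generate_cohort(null_config(config))
}
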