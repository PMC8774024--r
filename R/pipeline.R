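pipeline_defaults <- function() {
  list(
    cohort_dir = NULL,          # manifest dir; NULL -> simulate
    output_dir = "msconn_out",
    n_per_group = 10,
    planted_effects = TRUE,     # FALSE -> null cohort (simulation only)
    backbone_threshold = 0.75,
    backbone_scope = "pooled",
    weightings = c("binary", "FA", "FN", "FL"),
    small_world = TRUE,
    n_null = 100,
    swaps_per_edge = 10,
    n_perm = 5000,
    primary_alpha = 0.01,
    component_stat = "intensity",
    fdr_alpha = 0.05,
    posthoc_method = "welch",
    seed = 1
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a named list; unknown keys are an
#' error (listing them), missing keys are filled with the documented
#' defaults (backbone threshold 0.75, 5000 permutations, 100 null
#' networks, FDR level 0.05, ...).
#'
#' @param config Path to a YAML or JSON file, a named list, or `NULL` for
#'   all defaults.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  config <- config %||% list()
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, config)
  if (cfg$backbone_threshold <= 0 || cfg$backbone_threshold >= 1) {
    stop("backbone_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$primary_alpha <= 0 || cfg$primary_alpha >= 1) {
    stop("primary_alpha must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1) {
    stop("fdr_alpha must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$n_perm < 1 || cfg$n_null < 0) {
    stop("n_perm must be >= 1 and n_null >= 0", call. = FALSE)
  }
  bad_w <- setdiff(cfg$weightings, c("binary", "FA", "FN", "FL"))
  if (length(bad_w)) {
    stop("unknown weighting(s): ", paste(bad_w, collapse = ", "), call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

# master seed -> per-stage seeds via a fixed counter scheme, so stages are
# independently reproducible: simulate = +1000, metrics nulls = +2000,
# NBS on weighting j = +3000 + j
stage_seed <- function(master, stage, offset = 0L) {
  master + 1000L * stage + as.integer(offset)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> backbone -> metrics -> group statistics -> NBS ->
#' report. Fully deterministic under the master seed: every stage derives
#' its own seed from it. Outputs written to `config$output_dir`:
#' `metrics.csv`, `group_stats.csv`, `nbs_<weighting>.json`, `report.md`
#' and `config_resolved.json`.
#'
#' @param config A `pipeline_config` from [validate_config()] (or anything
#'   that function accepts).
#' @return Invisibly, a list with `cohort`, `mask`, `metrics`, `stats`,
#'   `nbs` (one result per weighting) and `output_dir`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_stage <- function(stage, msg) {
    message(sprintf("[msconn %6.1fs] %-10s %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    stage, msg))
  }

  if (is.null(cfg$cohort_dir)) {
    sim <- sim_config(n_per_group = cfg$n_per_group,
                      seed = stage_seed(cfg$seed, 1L))
    cohort <- if (cfg$planted_effects) generate_cohort(sim) else null_cohort(sim)
    log_stage("simulate", sprintf("%d subjects", length(unique(cohort$subject_id))))
  } else {
    cohort <- read_cohort(file.path(cfg$cohort_dir, "manifest.json"))
    log_stage("load", sprintf("%d subjects from %s",
                              length(unique(cohort$subject_id)), cfg$cohort_dir))
  }

  mask <- consistency_mask(cohort, threshold = cfg$backbone_threshold,
                           scope = cfg$backbone_scope)
  log_stage("backbone", sprintf("%d edges retained", sum(mask[upper.tri(mask)])))

  metrics <- compute_metrics(
    cohort, mask, weightings = cfg$weightings,
    small_world = cfg$small_world && cfg$n_null > 0,
    null_config = null_model_config(max(cfg$n_null, 1), cfg$swaps_per_edge,
                                    seed = stage_seed(cfg$seed, 2L))
  )
  readr::write_csv(metrics, file.path(cfg$output_dir, "metrics.csv"),
                   progress = FALSE)
  log_stage("metrics", sprintf("%d rows", nrow(metrics)))

  stats <- compare_groups(metrics, posthoc_alpha = cfg$fdr_alpha,
                          posthoc_method = cfg$posthoc_method)
  readr::write_csv(stats, file.path(cfg$output_dir, "group_stats.csv"),
                   progress = FALSE)
  log_stage("group-stats", sprintf("%d cells", nrow(stats)))

  nbs <- list()
  for (j in seq_along(cfg$weightings)) {
    w <- cfg$weightings[j]
    res <- nbs_test(cohort, w, mask,
                    nbs_config(cfg$n_perm, cfg$primary_alpha,
                               cfg$component_stat,
                               seed = stage_seed(cfg$seed, 3L, j)))
    nbs[[w]] <- res
    jsonlite::write_json(
      list(weighting = w, threshold = res$threshold,
           components = tidy(res), posthoc = res$posthoc,
           summary = glance(res)),
      file.path(cfg$output_dir, paste0("nbs_", w, ".json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    log_stage("nbs", sprintf("%s: %d component(s)", w, nrow(res$components)))
  }

  echo <- unclass(cfg)
  jsonlite::write_json(echo, file.path(cfg$output_dir, "config_resolved.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  write_report(cfg, cohort, stats, nbs,
               file.path(cfg$output_dir, "report.md"))
  log_stage("report", "written")

  invisible(list(cohort = cohort, mask = mask, metrics = metrics,
                 stats = stats, nbs = nbs, output_dir = cfg$output_dir))
}

format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

write_report <- function(cfg, cohort, stats, nbs, path) {
  lines <- c(
    "# Motor-sensory connectome group analysis",
    "",
    sprintf("- subjects: %d (%s)", length(unique(cohort$subject_id)),
            paste(capture_group_sizes(cohort), collapse = ", ")),
    sprintf("- backbone threshold: %s (%s)", cfg$backbone_threshold,
            cfg$backbone_scope),
    sprintf("- NBS: %d permutations, primary alpha %s, %s statistic",
            cfg$n_perm, cfg$primary_alpha, cfg$component_stat),
    "",
    "## Significant connections (NBS, p_fwe < 0.05)",
    ""
  )
  any_conn <- FALSE
  for (w in names(nbs)) {
    td <- tidy(nbs[[w]])
    td <- td[td$p_fwe < 0.05, ]
    if (nrow(td)) {
      any_conn <- TRUE
      lines <- c(lines, sprintf("| %s and %s | %s | F=%.2f | p_fwe=%s |",
                                td$node_a, td$node_b, w, td$F_stat,
                                format_p(td$p_fwe)))
    }
  }
  if (!any_conn) lines <- c(lines, "none")
  glob <- stats[stats$scope == "global" & stats$q_fdr < cfg$fdr_alpha, ]
  lines <- c(lines, "", "## Global properties with significant group differences", "")
  if (nrow(glob)) {
    lines <- c(lines, "| property | weighting | F | p | q |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %.2f | %s | %s |", glob$metric,
                       glob$weighting, glob$F_stat, format_p(glob$p),
                       format_p(glob$q_fdr)))
  } else {
    lines <- c(lines, "none")
  }
  nod <- stats[stats$scope == "nodal" & stats$q_fdr < cfg$fdr_alpha, ]
  lines <- c(lines, "", "## Nodal properties with significant group differences", "")
  if (nrow(nod)) {
    lines <- c(lines, "| node | property | weighting | F | p | q |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %.2f | %s | %s |", nod$node,
                       nod$metric, nod$weighting, nod$F_stat, format_p(nod$p),
                       format_p(nod$q_fdr)))
  } else {
    lines <- c(lines, "none")
  }
  writeLines(lines, path)
  invisible(path)
}

capture_group_sizes <- function(cohort) {
  gr <- table(cohort_subjects(cohort)$group)
  paste0(names(gr), "=", as.integer(gr))
}
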