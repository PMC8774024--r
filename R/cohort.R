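#' Assemble a study cohort
#'
#' A cohort is the unit every analysis stage consumes: one row per subject
#' and weighting, with the adjacency matrix in a list-column, plus the shared
#' atlas as an attribute. Group labels are usually the three study groups
#' (`Ep` = patients with intraoperative stimulation-related epilepsy,
#' `nEp` = patients without, `con` = healthy controls) but any >= 2 labels
#' are accepted.
#'
#' @param subjects Tibble/data frame with columns `subject_id`, `group`,
#'   `weighting`, `matrix` (list of `connectome_matrix`).
#' @param atlas The shared `ms_atlas`.
#' @param sim_config Optional simulation configuration recorded for
#'   provenance (set by [generate_cohort()]).
#' @return An `ms_cohort` tibble.
#' @export
ms_cohort <- function(subjects, atlas, sim_config = NULL) {
  stopifnot(inherits(atlas, "ms_atlas"))
  subjects <- as_tibble(subjects)
  needed <- c("subject_id", "group", "weighting", "matrix")
  if (!all(needed %in% names(subjects))) {
    stop("cohort table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(subjects) == 0L) stop("cohort is empty", call. = FALSE)
  # every subject must carry the same weightings
  wt_by_subj <- split(subjects$weighting, subjects$subject_id)
  ref <- sort(wt_by_subj[[1]])
  same <- vapply(wt_by_subj, function(w) identical(sort(w), ref), logical(1))
  if (!all(same)) {
    stop("subjects carry differing weighting sets", call. = FALSE)
  }
  n_ret <- length(retained_nodes(atlas))
  ok_dim <- vapply(subjects$matrix, function(m) nrow(m) == n_ret, logical(1))
  if (!all(ok_dim)) {
    stop("matrix dimensions do not all match the retained atlas nodes",
         call. = FALSE)
  }
  structure(subjects,
            atlas = atlas,
            sim_config = sim_config,
            class = c("ms_cohort", class(subjects)))
}

#' @export
print.ms_cohort <- function(x, ...) {
  gr <- table(x$group[!duplicated(x$subject_id)])
  cat(sprintf("<ms_cohort> %d subjects (%s), weightings: %s, %d retained nodes\n",
              length(unique(x$subject_id)),
              paste(names(gr), gr, sep = "=", collapse = ", "),
              paste(sort(unique(x$weighting)), collapse = "/"),
              length(retained_nodes(cohort_atlas(x)))))
  invisible(x)
}

#' Atlas of a cohort
#' @param cohort An `ms_cohort`.
#' @return The `ms_atlas` the cohort is defined over.
#' @export
cohort_atlas <- function(cohort) {
  stopifnot(inherits(cohort, "ms_cohort"))
  attr(cohort, "atlas")
}

#' Subject/group assignment table of a cohort
#' @param cohort An `ms_cohort`.
#' @return Tibble with one row per subject: `subject_id`, `group`.
#' @export
cohort_subjects <- function(cohort) {
  distinct(as_tibble(cohort)[, c("subject_id", "group")])
}

#' Extract one subject's matrix in one weighting
#' @param cohort An `ms_cohort`.
#' @param subject_id,weighting Selectors.
#' @return A `connectome_matrix`.
#' @export
cohort_matrix <- function(cohort, subject_id, weighting) {
  i <- which(cohort$subject_id == subject_id & cohort$weighting == weighting)
  if (length(i) != 1L) {
    stop("no unique matrix for subject '", subject_id, "', weighting '",
         weighting, "'", call. = FALSE)
  }
  cohort$matrix[[i]]
}

# Subjects-by-edges value matrix for one weighting; edge universe = upper
# triangle of `mask` (all off-diagonal pairs when mask is NULL). Used by the
# backbone, NBS and metric stages.
cohort_edge_values <- function(cohort, weighting, mask = NULL) {
  sub <- cohort[cohort$weighting == weighting, ]
  if (nrow(sub) == 0L) {
    stop("cohort has no matrices in weighting '", weighting, "'", call. = FALSE)
  }
  ids <- retained_nodes(cohort_atlas(cohort))
  n <- length(ids)
  if (is.null(mask)) {
    keep <- upper.tri(matrix(TRUE, n, n))
  } else {
    keep <- unclass(mask) & upper.tri(matrix(TRUE, n, n))
  }
  idx <- which(keep)
  rows <- ((idx - 1L) %% n) + 1L
  cols <- ((idx - 1L) %/% n) + 1L
  X <- t(vapply(sub$matrix, function(m) unclass(m)[idx], numeric(length(idx))))
  rownames(X) <- sub$subject_id
  list(
    values = X,
    edges = tibble(node_a = ids[rows], node_b = ids[cols], i = rows, j = cols),
    groups = sub$group
  )
}

#' Read a cohort from a manifest
#'
#' The manifest is JSON:
#' `{"atlas": path, "exclude": [node ids], "subjects":
#'   [{"id": ..., "group": ..., "matrices": {"FA": path, ...}}, ...]}`.
#' Relative paths are resolved against the manifest's directory. Matrices
#' must cover the retained nodes after applying the manifest's exclusion
#' list (or the atlas default when the key is absent).
#'
#' @param path Manifest JSON path.
#' @return An `ms_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  atlas <- load_atlas(if (is.null(man$atlas)) NULL else resolve(man$atlas))
  exclude <- if (!is.null(man$exclude)) {
    unlist(man$exclude)
  } else {
    default_excluded_nodes(atlas)
  }
  if (length(exclude)) atlas <- exclude_nodes(atlas, exclude)
  rows <- purrr::map_dfr(man$subjects, function(s) {
    purrr::map_dfr(names(s$matrices), function(w) {
      tibble(
        subject_id = s$id, group = s$group, weighting = w,
        matrix = list(read_connectome(resolve(s$matrices[[w]]), atlas,
                                      weighting = w, subject_id = s$id))
      )
    })
  })
  ms_cohort(rows, atlas)
}

#' Write a cohort directory (matrices plus manifest)
#'
#' @param cohort An `ms_cohort`.
#' @param dir Output directory (created if missing). One CSV per
#'   subject-weighting pair plus `manifest.json`; the simulation
#'   configuration, when present, is echoed to `sim_config.json`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ms_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- cohort_atlas(cohort)
  files <- character(nrow(cohort))
  for (k in seq_len(nrow(cohort))) {
    f <- sprintf("%s_%s.csv", cohort$subject_id[k], cohort$weighting[k])
    write_connectome(cohort$matrix[[k]], file.path(dir, f))
    files[k] <- f
  }
  subj <- cohort_subjects(cohort)
  manifest <- list(
    atlas = NULL,  # packaged default
    exclude = as.list(atlas$id[atlas$excluded]),
    subjects = purrr::pmap(subj, function(subject_id, group) {
      rows <- which(cohort$subject_id == subject_id)
      list(id = subject_id, group = group,
           matrices = as.list(setNames(files[rows], cohort$weighting[rows])))
    })
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  cfg <- attr(cohort, "sim_config")
  if (!is.null(cfg)) {
    jsonlite::write_json(sim_config_as_list(cfg),
                         file.path(dir, "sim_config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(mpath)
}
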