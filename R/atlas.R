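#' Load a node atlas
#'
#' An atlas names the network nodes (cortical subregions) in a fixed order
#' shared by every adjacency matrix of a cohort. Each node carries a
#' hemisphere, an anatomical parent gyrus, and an `excluded` flag marking
#' tumour-invaded subregions that are dropped from all analyses.
#'
#' The packaged default is a 28-subregion bilateral parcellation of the
#' motor-sensory network (precentral gyrus, paracentral lobule, postcentral
#' gyrus, superior frontal gyrus) with Brainnetome-style labels such as
#' `"A6m_L"` (left medial area 6, the supplementary motor area) or
#' `"A123tru_R"` (right trunk subregion of areas 1/2/3). It is a documented
#' synthetic stand-in: the exact subregion membership of the study it
#' emulates is not public.
#'
#' @param path Path to an atlas JSON file
#'   (`{"name": ..., "nodes": [{"id","hemisphere","gyrus","excluded"}, ...]}`).
#'   When `NULL` (default) the packaged motor-sensory atlas is loaded.
#' @return An object of class `ms_atlas`: a tibble with columns `id`,
#'   `hemisphere`, `gyrus`, `excluded`, plus attributes `name` and (if the
#'   file provides one) `default_exclusion`.
#' @examples
#' atl <- load_atlas()
#' nrow(atl)                       # 28
#' sum(!atl$excluded)              # 28 before exclusion
#' atl22 <- exclude_nodes(atl, default_excluded_nodes(atl))
#' sum(!atl22$excluded)            # 22
#' @export
load_atlas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motor_sensory_atlas.json", package = "msconn")
  }
  if (!file.exists(path)) {
    stop("atlas file not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(raw$nodes) || NROW(raw$nodes) == 0L) {
    stop("atlas has an empty node list", call. = FALSE)
  }
  nodes <- as_tibble(raw$nodes)
  required <- c("id", "hemisphere")
  missing <- setdiff(required, names(nodes))
  if (length(missing)) {
    stop("atlas nodes lack required field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(nodes$gyrus)) nodes$gyrus <- NA_character_
  if (is.null(nodes$excluded)) nodes$excluded <- FALSE
  nodes <- nodes[, c("id", "hemisphere", "gyrus", "excluded")]
  new_atlas(nodes,
            name = raw$name %||% "atlas",
            default_exclusion = raw$default_exclusion)
}

new_atlas <- function(nodes, name, default_exclusion = NULL) {
  validate_atlas_nodes(nodes)
  structure(
    as_tibble(nodes),
    name = name,
    default_exclusion = default_exclusion,
    class = c("ms_atlas", class(as_tibble(nodes)))
  )
}

validate_atlas_nodes <- function(nodes) {
  if (NROW(nodes) == 0L) stop("atlas has an empty node list", call. = FALSE)
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup)) {
    stop("duplicate node_id in atlas: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (!all(nodes$hemisphere %in% c("L", "R"))) {
    stop("hemisphere must be 'L' or 'R'", call. = FALSE)
  }
  suffix <- ifelse(endsWith(nodes$id, "_L"), "L",
                   ifelse(endsWith(nodes$id, "_R"), "R", NA_character_))
  bad <- is.na(suffix) | suffix != nodes$hemisphere
  if (any(bad)) {
    stop("node_id suffix inconsistent with hemisphere: ",
         paste(nodes$id[bad], collapse = ", "), call. = FALSE)
  }
  invisible(nodes)
}

#' Default tumour-exclusion list of the packaged atlas
#'
#' @param atlas An `ms_atlas`, typically `load_atlas()`.
#' @return Character vector of node ids flagged for exclusion by the atlas
#'   file (six left-hemisphere subregions for the packaged fixture).
#' @export
default_excluded_nodes <- function(atlas = load_atlas()) {
  ex <- attr(atlas, "default_exclusion")
  if (is.null(ex)) character(0) else as.character(ex)
}

#' Flag tumour-invaded nodes as excluded
#'
#' Subregions invaded by a tumour are unreliable after spatial normalisation
#' and atlas-based tracking, so they are removed from the analysis: an
#' excluded node never appears in any matrix, metric or statistic.
#'
#' @param atlas An `ms_atlas`.
#' @param exclude Character vector of node ids to flag. Every id must exist
#'   in the atlas. Idempotent: already-excluded ids may be repeated.
#' @return The atlas with the union of previous and new exclusions flagged;
#'   node order unchanged.
#' @export
exclude_nodes <- function(atlas, exclude) {
  stopifnot(inherits(atlas, "ms_atlas"))
  exclude <- as.character(exclude)
  unknown <- setdiff(exclude, atlas$id)
  if (length(unknown)) {
    stop("unknown node_id in exclusion list: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  atlas$excluded <- atlas$excluded | atlas$id %in% exclude
  atlas
}

#' Retained (non-excluded) node ids of an atlas, in atlas order
#' @param atlas An `ms_atlas`.
#' @return Character vector.
#' @export
retained_nodes <- function(atlas) {
  stopifnot(inherits(atlas, "ms_atlas"))
  atlas$id[!atlas$excluded]
}

#' @export
print.ms_atlas <- function(x, ...) {
  cat(sprintf("<ms_atlas '%s'> %d nodes (%d retained)\n",
              attr(x, "name"), nrow(x), sum(!x$excluded)))
  NextMethod()
}
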