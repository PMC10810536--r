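# Node metadata: parcel names, resting-state-network labels, coordinates.

#' Canonical resting-state network labels
#'
#' The eight-network partition used throughout: seven cortical resting-state
#' networks plus a subcortical/cerebellar group.
#' @export
RSN_LABELS <- c("CON", "DMN", "DAN", "LIM", "VAN", "SMN", "VIS", "SUB")

#' Default network sizes (74-node parcellation)
#'
#' Cortical cluster counts per network (62 in total) plus 12 subcortical and
#' cerebellar regions.
#' @export
DEFAULT_RSN_SIZES <- c(CON = 10, DMN = 16, DAN = 9, LIM = 5,
                       VAN = 11, SMN = 6, VIS = 5, SUB = 12)

#' Construct a node metadata table
#'
#' @param node_id integer vector, 0-based, unique and contiguous from 0 (the
#'   on-disk identity; R-level functions index nodes by position `1..n`).
#' @param name character region names.
#' @param rsn character, each an element of [RSN_LABELS].
#' @param hemisphere character, one of `"L"`, `"R"`, `"M"`.
#' @param x,y,z numeric coordinates in mm.
#' @return A `data.frame` of class `tc_nodes`.
#' @export
node_table <- function(node_id, name, rsn, hemisphere, x, y, z) {
  n <- length(node_id)
  if (!identical(as.integer(sort(node_id)), 0:(n - 1L)))
    stop_tc("node_id must be unique and contiguous from 0", class = "tc_param_error")
  if (!all(rsn %in% RSN_LABELS))
    stop_tc("unknown rsn label(s): %s",
            paste(setdiff(rsn, RSN_LABELS), collapse = ", "),
            class = "tc_param_error")
  if (!all(hemisphere %in% c("L", "R", "M")))
    stop_tc("hemisphere must be L, R or M", class = "tc_param_error")
  df <- data.frame(node_id = as.integer(node_id), name = as.character(name),
                   rsn = as.character(rsn), hemisphere = as.character(hemisphere),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  df <- df[order(df$node_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("tc_nodes", "data.frame")
  df
}

#' Synthetic node table with pseudo-anatomical coordinates
#'
#' Builds a node table for a synthetic parcellation: nodes are grouped into
#' the eight canonical networks, split between hemispheres, and given
#' deterministic pseudo-anatomical coordinates (Gaussian blobs around a fixed
#' per-network centre, mirrored across the midline) so that spatial-gradient
#' analyses are executable. Coordinates carry no anatomical meaning.
#'
#' @param rsn_sizes named integer vector of nodes per network; names must be
#'   a subset of [RSN_LABELS]. Defaults to [DEFAULT_RSN_SIZES] (74 nodes).
#' @param seed integer seed for the coordinate jitter (fixed default so the
#'   table is reproducible independently of the cohort seed).
#' @return A `tc_nodes` table.
#' @export
synthetic_nodes <- function(rsn_sizes = DEFAULT_RSN_SIZES, seed = 20240112L) {
  if (is.null(names(rsn_sizes)) || !all(names(rsn_sizes) %in% RSN_LABELS))
    stop_tc("rsn_sizes must be named with canonical RSN labels", class = "tc_param_error")
  if (any(rsn_sizes < 1))
    stop_tc("all rsn_sizes must be >= 1", class = "tc_param_error")
  # fixed per-network blob centres (|x|, y, z) in mm, loosely anterior/posterior
  centres <- list(
    CON = c(40, 20, 35), DMN = c(15, -10, 40), DAN = c(30, -45, 50),
    LIM = c(25, 5, -15), VAN = c(45, 10, 10), SMN = c(35, -20, 55),
    VIS = c(15, -85, 5), SUB = c(15, -15, 0))
  rsn <- rep(names(rsn_sizes), rsn_sizes)
  n <- length(rsn)
  hemi <- unlist(lapply(rsn_sizes, function(k) {
    h <- rep(c("L", "R"), length.out = k)
    h
  }), use.names = FALSE)
  idx_in_rsn <- unlist(lapply(rsn_sizes, seq_len), use.names = FALSE)
  name <- sprintf("%s_%s_%02d", rsn, hemi, idx_in_rsn)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  jit <- matrix(stats::rnorm(3 * n, sd = 8), ncol = 3)
  cen <- t(vapply(rsn, function(r) centres[[r]], numeric(3)))
  xyz <- cen + jit
  xyz[, 1] <- abs(xyz[, 1]) * ifelse(hemi == "L", -1, 1)
  node_table(node_id = 0:(n - 1L), name = name, rsn = rsn, hemisphere = hemi,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}
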