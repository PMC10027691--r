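#' Build a region-of-interest registry
#'
#' Loads the packaged ROI table for one of the two analysis families:
#' `"connectivity-16"` — the 8 bilateral cortical areas (STC, MFG, IFG, PreC,
#' SMG, AG, SPL, plus occipital cortex as a control) whose subROI-to-subROI
#' correlation matrices form the connectivity feature space; or
#' `"activation-86"` — the 43-label-per-hemisphere surface parcellation
#' (Desikan base with a 9-way superior-temporal split and ventral/dorsal
#' precentral/postcentral splits) used for activation-pattern decoding.
#'
#' SubROI counts follow the published parcellation where stated; rows where the
#' count is a package default (the precentral areas, and most activation-ROI
#' unit counts) carry `inferred = TRUE`.
#'
#' @param mode `"connectivity-16"` or `"activation-86"`.
#' @return A tibble with columns `roi`, `area`/`label`, `hemisphere`,
#'   `n_subrois` (or `n_units`), `inferred`.
#' @examples
#' build_registry("connectivity-16")
#' @export
build_registry <- function(mode = c("connectivity-16", "activation-86")) {
  mode <- match.arg(mode)
  file <- switch(mode,
    "connectivity-16" = "rois_connectivity16.tsv",
    "activation-86"   = "rois_activation86.tsv"
  )
  path <- system.file("extdata", file, package = "wmconn", mustWork = TRUE)
  reg <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  if (mode == "activation-86") names(reg)[names(reg) == "n_units"] <- "n_subrois"
  stopifnot(
    all(reg$n_subrois >= 1L),
    !anyDuplicated(reg$roi),
    nrow(reg) == if (mode == "connectivity-16") 16L else 86L
  )
  attr(reg, "mode") <- mode
  reg
}

#' Enumerate all candidate ROI networks
#'
#' Produces every unordered subset of the registry's ROIs with the requested
#' sizes, in lexicographic canonical order of the sorted member names. Over
#' the 16-ROI connectivity registry with sizes 2-4 this is the full
#' C(16,2) + C(16,3) + C(16,4) = 2500-network search space.
#'
#' @param registry Registry tibble from [build_registry()].
#' @param sizes Integer vector, subset of 2:4.
#' @return A tibble with columns `network` (canonical id, members joined by
#'   `+`), `size`, `members` (list of character vectors), `n_features`
#'   (feature-vector length, see [pattern_feature_count()]).
#' @examples
#' nets <- enumerate_networks(build_registry("connectivity-16"))
#' nrow(nets)  # 2500
#' @export
enumerate_networks <- function(registry, sizes = 2:4) {
  sizes <- sort(unique(as.integer(sizes)))
  if (length(sizes) == 0L || !all(sizes %in% 2:4)) {
    abort("`sizes` must be a non-empty subset of {2, 3, 4}")
  }
  rois <- sort(registry$roi)
  counts <- stats::setNames(registry$n_subrois, registry$roi)
  member_sets <- purrr::list_flatten(purrr::map(sizes, function(k) {
    if (length(rois) < k) return(list())
    utils::combn(rois, k, simplify = FALSE)
  }))
  out <- tibble::tibble(
    network = vapply(member_sets, paste, "", collapse = "+"),
    size = vapply(member_sets, length, 1L),
    members = member_sets,
    n_features = vapply(member_sets, function(m) {
      pattern_feature_count(counts[m])
    }, 1)
  )
  out[order(out$network), , drop = FALSE]
}

#' Filter networks by required and excluded members
#'
#' Keeps networks that contain at least one ROI from `include` (if given) and
#' none from `exclude`, preserving order. With the default empty sets the
#' input is returned unchanged. Over the full 2500-network space,
#' `include = c("LOC", "ROC")` keeps the 1044 occipital-containing networks
#' and adding `exclude = c("LSTC", "RSTC")` keeps the 675 control networks
#' with occipital but no superior-temporal members.
#'
#' @param networks Tibble from [enumerate_networks()].
#' @param include Character vector of ROI names; empty means no constraint.
#' @param exclude Character vector of ROI names to forbid.
#' @param registry Optional registry for name validation.
#' @return Filtered tibble.
#' @export
filter_networks <- function(networks, include = character(), exclude = character(),
                            registry = NULL) {
  if (!is.null(registry)) {
    bad <- setdiff(c(include, exclude), registry$roi)
    if (length(bad)) abort(paste0("unknown ROI name(s): ", paste(bad, collapse = ", ")))
  }
  keep <- vapply(networks$members, function(m) {
    (length(include) == 0L || any(include %in% m)) && !any(exclude %in% m)
  }, TRUE)
  networks[keep, , drop = FALSE]
}

#' Feature-vector length of a connectivity pattern
#'
#' A network of ROIs A, B, C ... yields one correlation matrix per unordered
#' ROI pair with N_A x N_B entries; the concatenated feature vector therefore
#' has length T = sum over pairs of N_A * N_B. For the worked left-STC /
#' left-SMG / right-STC example this is 34*29 + 34*34 + 29*34 = 3128.
#'
#' @param n_subrois Named or unnamed numeric vector of subROI counts, one per
#'   member ROI (length 2-4).
#' @return Integer feature count.
#' @examples
#' pattern_feature_count(c(LSTC = 34, LSMG = 34, RSTC = 29))  # 3128
#' @export
pattern_feature_count <- function(n_subrois) {
  n <- as.numeric(n_subrois)
  if (length(n) < 2L) abort("a network needs at least 2 member ROIs")
  if (any(!is.finite(n) | n < 1)) abort("subROI counts must be positive")
  tot <- (sum(n)^2 - sum(n^2)) / 2
  as.integer(round(tot))
}

#' Vertex count of a subdivided icosahedral mesh
#'
#' Recursive edge-midpoint subdivision of the icosahedron gives the standard
#' cortical-surface source spaces; order `k` has `10 * 4^k + 2` vertices
#' (12, 42, 162, 642, ...). Order 3 matches the fsaverage3 hemisphere mesh
#' on which the subROI patches are defined.
#'
#' @param order Non-negative integer subdivision order (vectorized).
#' @return Integer vertex counts.
#' @examples
#' ico_vertex_count(0:3)  # 12 42 162 642
#' @export
ico_vertex_count <- function(order) {
  order <- as.numeric(order)
  if (any(!is.finite(order) | order < 0 | order != round(order))) {
    abort("`order` must be a non-negative integer")
  }
  as.integer(10 * 4^order + 2)
}
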