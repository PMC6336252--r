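#' Build a genetic map
#'
#' Constructs a marker map of equally spaced loci on a set of linkage
#' groups. The default emulates a diploid genome of 10 linkage groups,
#' each carrying 101 markers at 1 cM spacing (1,010 markers, 1,000 cM).
#'
#' @param group_count Number of linkage groups.
#' @param markers_per_group Number of markers per linkage group.
#' @param spacing Map distance in centimorgans between adjacent markers.
#'
#' @return An object of class `genetic_map`: a list with elements
#'   `group_count`, `markers_per_group`, `spacing`, `n_markers`,
#'   `marker_ids`, `group` (linkage group of each marker) and `pos_cM`
#'   (position of each marker within its group, starting at 0).
#' @examples
#' map <- build_map()
#' map$n_markers            # 1010
#' map_length_cM(map)       # 1000
#' @export
build_map <- function(group_count = 10, markers_per_group = 101, spacing = 1) {
  if (length(group_count) != 1L || group_count < 1 || group_count != round(group_count))
    stop("invalid configuration: 'group_count' must be a positive integer")
  if (length(markers_per_group) != 1L || markers_per_group < 1 ||
      markers_per_group != round(markers_per_group))
    stop("invalid configuration: 'markers_per_group' must be a positive integer")
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("invalid configuration: 'spacing' must be a positive map distance")
  group_count <- as.integer(group_count)
  markers_per_group <- as.integer(markers_per_group)
  n <- group_count * markers_per_group
  group <- rep(seq_len(group_count), each = markers_per_group)
  pos <- rep(seq(0, by = spacing, length.out = markers_per_group), group_count)
  ids <- sprintf("LG%02d_M%03d", group, rep(seq_len(markers_per_group), group_count))
  structure(
    list(group_count = group_count,
         markers_per_group = markers_per_group,
         spacing = spacing,
         n_markers = n,
         marker_ids = ids,
         group = group,
         pos_cM = pos),
    class = "genetic_map")
}

#' Total map length
#'
#' @param map A `genetic_map`.
#' @return Total map length in cM, summed over linkage groups.
#' @export
map_length_cM <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  map$group_count * (map$markers_per_group - 1) * map$spacing
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map: %d linkage groups x %d markers (%g cM spacing), %d markers, %g cM total\n",
              x$group_count, x$markers_per_group, x$spacing,
              x$n_markers, map_length_cM(x)))
  invisible(x)
}

#' Haldane recombination fraction
#'
#' Maps a distance in centimorgans to a recombination fraction under the
#' Haldane mapping function (independent crossovers, no interference):
#' `c = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param distance_cM Map distance in cM (non-negative, vectorized).
#' @return Recombination fraction in `[0, 0.5)`.
#' @examples
#' recombination_fraction(1)    # ~0.009901
#' @export
recombination_fraction <- function(distance_cM) {
  if (any(!is.finite(distance_cM)) || any(distance_cM < 0))
    stop("invalid argument: 'distance_cM' must be non-negative")
  (1 - exp(-2 * distance_cM / 100)) / 2
}
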