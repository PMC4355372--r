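#' Classify scan objects as single cells, clusters, or ignored
#'
#' Size-threshold classification of fluorescent nuclei objects. An object is
#' a single cell when both linear extents lie in \[5, 50) um; a cluster when
#' the smaller extent is at least 5 um and the larger extent lies in
#' \[50, 250\] um; anything else (debris below 5 um, artifacts above 250 um)
#' is ignored. The 50 um boundary is assigned to the cluster class: enlarged
#' (polyploid) nuclei cross it from below and are deliberately treated as
#' clusters, which is the documented source of a bounded overcount at high
#' radiation dose.
#'
#' Intensity is not used for classification; it is carried through for
#' diagnostics of the polyploid subpopulation.
#'
#' @param width,depth numeric vectors of object extents in micrometres (> 0).
#' @param single_range,cluster_range numeric length-2 size windows in um;
#'   defaults 5-50 and 50-250.
#' @return character vector with values "single", "cluster" or "ignored".
#' @examples
#' classify_objects(c(10, 60, 3), c(10, 70, 3))
#' @export
classify_objects <- function(width, depth,
                             single_range = c(5, 50),
                             cluster_range = c(50, 250)) {
  if (length(width) != length(depth)) stop("width and depth lengths differ")
  if (any(width <= 0) || any(depth <= 0)) {
    stop("object dimensions must be > 0")
  }
  lo <- pmin(width, depth)
  hi <- pmax(width, depth)
  out <- rep("ignored", length(width))
  out[lo >= single_range[1] & hi < single_range[2]] <- "single"
  out[lo >= single_range[1] & hi >= cluster_range[1] & hi <= cluster_range[2]] <- "cluster"
  out
}

#' Cell count of one well from its object list
#'
#' The cell number is the number of single-cell objects plus a fixed weight
#' (default 3, the average number of nuclei observed in merged objects)
#' times the number of cluster objects. Ignored objects do not contribute.
#'
#' @param objects data.frame with columns well, width_um, depth_um
#'   (intensity optional); all rows must come from a single well.
#' @param cluster_weight nuclei attributed to each cluster object.
#' @return one-row data.frame: well, n_single, n_cluster, n_ignored, count.
#' @examples
#' obj <- data.frame(well = "A1", width_um = c(10, 12, 60), depth_um = c(9, 11, 80),
#'                   intensity = 1)
#' count_well(obj)  # 2 singles + 1 cluster -> count 5
#' @export
count_well <- function(objects, cluster_weight = 3) {
  if (nrow(objects) == 0L) {
    return(data.frame(well = NA_character_, n_single = 0L, n_cluster = 0L,
                      n_ignored = 0L, count = 0, stringsAsFactors = FALSE))
  }
  wells <- unique(canonical_well(objects$well))
  if (length(wells) > 1L) {
    stop("count_well expects objects from a single well, got: ",
         paste(wells, collapse = ", "))
  }
  cls <- classify_objects(objects$width_um, objects$depth_um)
  n_single <- sum(cls == "single")
  n_cluster <- sum(cls == "cluster")
  n_ignored <- sum(cls == "ignored")
  data.frame(well = wells, n_single = n_single, n_cluster = n_cluster,
             n_ignored = n_ignored,
             count = n_single + cluster_weight * n_cluster,
             stringsAsFactors = FALSE)
}

#' Per-well cell counts for a mapped plate
#'
#' Joins a scan-object table with a plate map: every mapped well gets a
#' count (0 when it holds no objects). Objects in unmapped wells trigger a
#' warning and are recorded in the `n_unmapped` attribute of the result.
#'
#' @param objects object table (see [read_object_table()]).
#' @param map plate map rows covering the same plate.
#' @param cluster_weight passed to [count_well()].
#' @return the map with columns n_single, n_cluster, n_ignored, count added.
#' @export
count_plate <- function(objects, map, cluster_weight = 3) {
  map <- validate_plate_map(map)
  if (anyDuplicated(map$well)) {
    stop("count_plate expects the map of a single physical plate ",
         "(duplicate wells found)")
  }
  if (nrow(objects)) objects$well <- canonical_well(objects$well)
  grouped <- group_objects(objects, wells = map$well)
  counted <- do.call(rbind, lapply(names(grouped), function(w) {
    cw <- count_well(grouped[[w]], cluster_weight = cluster_weight)
    cw$well <- w
    cw
  }))
  out <- merge(map, counted, by = "well", sort = FALSE)
  out <- out[order(match(out$well, map$well)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- nrow(objects) - sum(out$n_single + out$n_cluster + out$n_ignored)
  out
}
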