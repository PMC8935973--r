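#' Great-circle (geodesic) distance between points
#'
#' Straight-line foraging distances are measured on the WGS84 sphere
#' (mean radius 6,371,008.8 m) with the haversine formula; an ellipsoidal
#' alternative is available, which differs by under 0.3\% at city scale.
#'
#' @param p1,p2 Two-column matrices or length-2 vectors of `c(lon, lat)` in
#'   decimal degrees. Recycled against each other row-wise.
#' @param method `"haversine"` (default, spherical) or `"ellipsoid"`
#'   (Karney-style geodesic via \pkg{geosphere}).
#' @return Distance(s) in meters.
#' @examples
#' geodesic_distance(c(0, 0), c(1, 0))  # one degree of equator, ~111195 m
#' @export
geodesic_distance <- function(p1, p2, method = c("haversine", "ellipsoid")) {
  method <- match.arg(method)
  if (method == "haversine")
    geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M)
  else
    geosphere::distGeo(p1, p2)
}

#' Mean center of capture coordinates (triangulated colony location)
#'
#' Points are projected onto a local tangent plane centered on their
#' centroid (equirectangular scaling, exact to well under a metre over the
#' <= 50 km extents this is meant for), averaged in meters, and unprojected
#' back to WGS84. The mean center minimizes the sum of squared planar
#' distances to the points.
#'
#' @param points Matrix or data frame with two columns, lon and lat
#'   (decimal degrees).
#' @return Numeric `c(lon, lat)`.
#' @export
colony_center <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) == 0L) stop("colony_center() needs at least one point")
  storage.mode(pts) <- "double"
  lon0 <- mean(pts[, 1]); lat0 <- mean(pts[, 2])
  k <- pi / 180 * EARTH_RADIUS_M
  x <- (pts[, 1] - lon0) * k * cos(lat0 * pi / 180)
  y <- (pts[, 2] - lat0) * k
  c(lon = lon0 + mean(x) / (k * cos(lat0 * pi / 180)),
    lat = lat0 + mean(y) / k)
}

#' Effective number of colonies from a sampled colony count
#'
#' For social haplodiploids the number of colonies detected in an area is a
#' minimum; the effective number corrects it for the mating system:
#' \deqn{colNe = \frac{4.5\,N\,m\,n}{1 + 2m}}
#' with `N` detected colonies, mating frequency `m` and `n` queens per
#' colony. Under monogyny and monoandry (`m = n = 1`) this is `1.5 * N`.
#'
#' @param N Integer vector of detected colony counts (>= 0).
#' @param m Mating frequency (>= 1).
#' @param n Queens per colony (>= 1).
#' @return Numeric colNe values.
#' @examples
#' effective_colonies(2)        # 3
#' effective_colonies(3, m = 2) # 5.4
#' @export
effective_colonies <- function(N, m = 1, n = 1) {
  if (any(N < 0)) stop("N must be >= 0")
  if (m < 1) stop("mating frequency m must be >= 1")
  if (n < 1) stop("queen number n must be >= 1")
  (4.5 * N * m * n) / (1 + 2 * m)
}

#' Drop clusters that cannot be triangulated
#'
#' A colony location can only be triangulated from sisters netted at two or
#' more distinct spots. This removes size-1 clusters and clusters whose
#' member capture coordinates are pairwise within `coord_tol_m` of one
#' another (repeat GPS records of a single netting spot).
#'
#' @param partition A [sibship_partition] (or plain list of character vectors
#'   of worker ids).
#' @param captures Data frame with columns `worker_id`, `lon`, `lat`.
#' @param coord_tol_m Distance below which two capture points count as "the
#'   same coordinates" (meters; default 0.5). Use `0` for exact equality.
#' @return The partition restricted to triangulable clusters (support values
#'   carried along when present).
#' @export
triangulable_clusters <- function(partition, captures, coord_tol_m = 0.5) {
  clusters <- if (inherits(partition, "sibship_partition"))
    partition$clusters else partition
  support <- if (inherits(partition, "sibship_partition"))
    partition$support else rep(NA_real_, length(clusters))
  missing_ids <- setdiff(unlist(clusters), captures$worker_id)
  if (length(missing_ids))
    stop("no capture record for worker(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  keep <- vapply(clusters, function(ws) {
    if (length(ws) < 2L) return(FALSE)
    i <- match(ws, captures$worker_id)
    pts <- cbind(captures$lon[i], captures$lat[i])
    if (coord_tol_m <= 0) {
      nrow(unique(pts)) >= 2L
    } else {
      d <- geodesic_distance(pts[rep(seq_len(nrow(pts)), each = nrow(pts)), ],
                             pts[rep(seq_len(nrow(pts)), times = nrow(pts)), ])
      any(d > coord_tol_m)
    }
  }, logical(1))
  out <- list(clusters = clusters[keep], support = support[keep],
              total_loglik = NA_real_)
  class(out) <- "sibship_partition"
  out
}

#' Colony records from triangulable clusters and captures
#'
#' For each cluster: the colony center (mean center of member captures), the
#' geodesic distance from each member's capture point back to that center,
#' and their arithmetic mean (the colony's mean foraging distance). Sisters
#' captured in different grid cells still contribute to their own colony's
#' distances.
#'
#' @inheritParams triangulable_clusters
#' @param grid Optional [make_grid()] grid; if given, each colony is
#'   assigned the cell containing its center (half-open bounds).
#' @return Data frame with one row per colony: `colony_id`, `lon`, `lat`,
#'   `cell_id`, `n_members`, `mean_fd_m`, plus a `member_distances`
#'   list-column of per-worker distances (meters).
#' @export
colony_records <- function(partition, captures, grid = NULL) {
  clusters <- if (inherits(partition, "sibship_partition"))
    partition$clusters else partition
  rows <- lapply(seq_along(clusters), function(j) {
    ws <- clusters[[j]]
    i <- match(ws, captures$worker_id)
    if (anyNA(i)) stop("no capture record for worker(s): ",
                       paste(ws[is.na(i)], collapse = ", "))
    pts <- cbind(captures$lon[i], captures$lat[i])
    ctr <- colony_center(pts)
    d <- geodesic_distance(pts, rbind(ctr)[rep(1, nrow(pts)), , drop = FALSE])
    list(colony_id = j, lon = unname(ctr[1]), lat = unname(ctr[2]),
         n_members = length(ws), mean_fd_m = mean(d), dists = d,
         workers = ws)
  })
  out <- data.frame(
    colony_id = vapply(rows, `[[`, 0, "colony_id"),
    lon = vapply(rows, `[[`, 0, "lon"),
    lat = vapply(rows, `[[`, 0, "lat"),
    n_members = vapply(rows, `[[`, 0, "n_members"),
    mean_fd_m = vapply(rows, `[[`, 0, "mean_fd_m")
  )
  out$member_distances <- lapply(rows, `[[`, "dists")
  out$members <- lapply(rows, `[[`, "workers")
  out$cell_id <- if (!is.null(grid)) cell_of(grid, out$lon, out$lat)
  else NA_integer_
  out
}

#' Per-cell colony summaries: N, colNe and aveMeanFD
#'
#' Counts colony centers per grid cell, converts the count to an effective
#' colony number via [effective_colonies()], and averages the member
#' colonies' mean foraging distances (aveMeanFD, with its natural log for
#' downstream normal-theory modelling). Cells without colonies are omitted.
#' Colonies whose center falls outside the grid are excluded with a warning.
#'
#' @param colonies Data frame from [colony_records()] (needs `lon`, `lat`,
#'   `mean_fd_m`).
#' @param grid A [make_grid()] grid.
#' @param m,n Mating frequency and queen number for [effective_colonies()].
#' @return Data frame with `cell_id`, `N`, `colNe`, `aveMeanFD_m`,
#'   `ln_aveMeanFD`, ordered by `cell_id`.
#' @export
summarize_cells <- function(colonies, grid, m = 1, n = 1) {
  cid <- cell_of(grid, colonies$lon, colonies$lat)
  if (anyNA(cid)) {
    warning(sum(is.na(cid)), " colony center(s) outside the grid; excluded")
    colonies <- colonies[!is.na(cid), , drop = FALSE]
    cid <- cid[!is.na(cid)]
  }
  if (!nrow(colonies))
    return(data.frame(cell_id = integer(), N = integer(), colNe = numeric(),
                      aveMeanFD_m = numeric(), ln_aveMeanFD = numeric()))
  agg <- aggregate(colonies$mean_fd_m, by = list(cell_id = cid),
                   FUN = mean)
  cnt <- as.data.frame(table(cell_id = cid), stringsAsFactors = FALSE)
  out <- data.frame(
    cell_id = as.integer(cnt$cell_id),
    N = as.integer(cnt$Freq)
  )
  out$colNe <- effective_colonies(out$N, m = m, n = n)
  out$aveMeanFD_m <- agg$x[match(out$cell_id, agg$cell_id)]
  out$ln_aveMeanFD <- log(out$aveMeanFD_m)
  out[order(out$cell_id), , drop = FALSE]
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper over [stats::shapiro.test()] used to decide whether a
#' variable (typically aveMeanFD) needs a log transform before linear
#' modelling.
#'
#' @param values Numeric vector (3 to 5000 non-missing, non-constant values).
#' @return List with `statistic` (W) and `p.value`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2L)
    stop("normality check undefined for a constant vector")
  ht <- stats::shapiro.test(values)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}
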