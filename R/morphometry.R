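#' Palatal plane from landmarks
#'
#' The slicing reference plane passes through the ANS-PNS line (anterior and
#' posterior nasal spine) and a lateral reference landmark; the normal is
#' oriented superiorly. Airway cross sections are taken parallel to this
#' plane.
#'
#' @param lms a [landmarks] object containing `ANS`, `PNS` and at least one
#'   further (lateral) reference point.
#' @param lateral name of the lateral reference landmark; default: the
#'   first landmark that is neither ANS nor PNS.
#' @return list with `origin` (ANS) and unit `normal`.
#' @export
palatal_plane <- function(lms, lateral = NULL) {
  ans <- landmark_point(lms, "ANS")
  pns <- landmark_point(lms, "PNS")
  if (is.null(lateral)) {
    others <- setdiff(lms$name, c("ANS", "PNS"))
    if (!length(others)) stop("palatal plane needs a lateral reference landmark")
    lateral <- others[1]
  }
  lat <- landmark_point(lms, lateral)
  n <- pracma_cross(pns - ans, lat - ans)
  len <- sqrt(sum(n^2))
  if (len < 1e-9 * max(1, sqrt(sum((pns - ans)^2)))) {
    stop("degenerate palatal-plane landmarks (collinear)")
  }
  n <- n / len
  if (n[3] < 0) n <- -n # superior orientation
  list(origin = ans, normal = n)
}

plane_axes <- function(normal) {
  # in-plane projections of the patient axes: Lat along +x, AP along +y
  proj <- function(a) {
    v <- a - sum(a * normal) * normal
    l <- sqrt(sum(v^2))
    if (l < 1e-12) stop("plane normal parallel to a patient axis; AP/Lat undefined")
    v / l
  }
  list(lat = proj(c(1, 0, 0)), ap = proj(c(0, 1, 0)))
}

# Intersect a surface with the plane offset at `station` along the normal;
# returns a list of closed 3D loops (k x 3 matrices).
plane_section_loops <- function(surface, origin, normal, station) {
  v <- surface$vertices
  f <- surface$faces
  s <- as.numeric(v %*% normal - sum(origin * normal) - station)
  s[s == 0] <- 1e-12 # nudge exact hits off the plane for robust crossing tests
  side <- s > 0
  cross_tri <- side[f[, 1]] + side[f[, 2]] + side[f[, 3]]
  cand <- which(cross_tri == 1L | cross_tri == 2L)
  if (!length(cand)) return(list())
  segs_a <- segs_b <- matrix(0, length(cand), 3)
  keys_a <- keys_b <- character(length(cand))
  edge_point <- function(i, j) {
    t <- s[i] / (s[i] - s[j])
    v[i, ] + t * (v[j, ] - v[i, ])
  }
  edge_key <- function(i, j) paste(min(i, j), max(i, j), sep = "-")
  for (kk in seq_along(cand)) {
    tri <- f[cand[kk], ]
    pos <- tri[side[tri]]
    neg <- tri[!side[tri]]
    if (length(pos) == 1L) {
      a <- pos; b1 <- neg[1]; b2 <- neg[2]
    } else {
      a <- neg; b1 <- pos[1]; b2 <- pos[2]
    }
    segs_a[kk, ] <- edge_point(a, b1)
    segs_b[kk, ] <- edge_point(a, b2)
    keys_a[kk] <- edge_key(a, b1)
    keys_b[kk] <- edge_key(a, b2)
  }
  # chain segments: crossing edges are shared by exactly two crossing
  # triangles on a watertight surface, so edge keys define the adjacency
  loops <- list()
  used <- rep(FALSE, length(cand))
  seg_of_key <- split(rep(seq_along(cand), 2), c(keys_a, keys_b))
  for (start in seq_along(cand)) {
    if (used[start]) next
    loop_pts <- list(segs_a[start, ])
    used[start] <- TRUE
    cur_seg <- start
    cur_key <- keys_b[start]
    loop_pts[[2]] <- segs_b[start, ]
    repeat {
      nxt <- setdiff(seg_of_key[[cur_key]], cur_seg)
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      nxt <- nxt[1]
      used[nxt] <- TRUE
      if (keys_a[nxt] == cur_key) {
        loop_pts[[length(loop_pts) + 1]] <- segs_b[nxt, ]
        cur_key <- keys_b[nxt]
      } else {
        loop_pts[[length(loop_pts) + 1]] <- segs_a[nxt, ]
        cur_key <- keys_a[nxt]
      }
      cur_seg <- nxt
    }
    pts <- do.call(rbind, loop_pts)
    # drop the duplicated closing point
    if (nrow(pts) > 1 && sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 1e-9) {
      pts <- pts[-nrow(pts), , drop = FALSE]
    }
    if (nrow(pts) >= 3) loops[[length(loops) + 1]] <- pts
  }
  loops
}

#' Metrics of one cross-section polygon
#'
#' Area by the shoelace formula in the section plane; AP and Lat diameters
#' as the polygon's extents along the in-plane projections of the anterior
#' (+y) and lateral (+x) patient axes. Outputs follow the clinical
#' convention: cm and cm^2.
#'
#' @param polygon k x 3 matrix of ordered polygon vertices (mm), or k x 2
#'   in-plane coordinates when `normal` is the +z axis.
#' @param normal unit normal of the section plane.
#' @return list with `A_cm2`, `AP_cm`, `Lat_cm`.
#' @export
section_metrics <- function(polygon, normal = c(0, 0, 1)) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) == 2) polygon <- cbind(polygon, 0)
  if (nrow(polygon) < 3) stop("degenerate polygon (fewer than 3 vertices)")
  ax <- plane_axes(normal)
  # orthonormal in-plane basis for the shoelace area
  e1 <- ax$lat
  e2 <- pracma_cross(normal, e1)
  p <- sweep(polygon, 2, polygon[1, ])
  x <- as.numeric(p %*% e1)
  y <- as.numeric(p %*% e2)
  j <- c(2:length(x), 1)
  area_mm2 <- abs(sum(x * y[j] - x[j] * y)) / 2
  ap_mm <- diff(range(polygon %*% ax$ap))
  lat_mm <- diff(range(polygon %*% ax$lat))
  if (area_mm2 <= 0) stop("degenerate polygon (zero area)")
  list(A_cm2 = area_mm2 / 100, AP_cm = ap_mm / 10, Lat_cm = lat_mm / 10)
}

#' Slice an airway surface into equidistant cross sections
#'
#' Intersects a watertight airway surface with planes parallel to the
#' palatal plane at fixed spacing (1 mm clinically), chains the intersection
#' segments into closed polygons, keeps the largest-area polygon per station
#' (the main air channel; discarded side components are counted), and
#' computes area and AP/Lat diameters.
#'
#' @param surface a watertight [tri_surface] of the airway lumen.
#' @param plane list with `origin` and `normal`, e.g. from
#'   [palatal_plane()].
#' @param spacing station spacing in mm.
#' @return An object of class `airway_profile`: data.frame `sections`
#'   (station, area_cm2, ap_cm, lat_cm, region), the section polygons, and
#'   the plane.
#' @export
slice_airway <- function(surface, plane, spacing = 1) {
  stopifnot(inherits(surface, "tri_surface"), spacing > 0)
  if (!is_watertight(surface)) {
    stop("airway surface must be watertight for cross-section morphometry")
  }
  s <- as.numeric(surface$vertices %*% plane$normal -
                    sum(plane$origin * plane$normal))
  # stations snap to multiples of the spacing so profiles of different
  # surfaces (pre / post / simulated) share a common grid
  lo <- ceiling((min(s) + spacing / 2) / spacing)
  hi <- floor((max(s) - spacing / 2) / spacing)
  if (hi < lo) stop("surface thinner than one station spacing")
  stations <- seq(lo, hi) * spacing
  rows <- list()
  polys <- list()
  n_discarded <- 0L
  for (st in stations) {
    loops <- plane_section_loops(surface, plane$origin, plane$normal, st)
    if (!length(loops)) {
      warning(sprintf("empty airway section at station %.2f mm (gap)", st))
      next
    }
    mets <- lapply(loops, section_metrics, normal = plane$normal)
    areas <- vapply(mets, `[[`, numeric(1), "A_cm2")
    k <- which.max(areas)
    n_discarded <- n_discarded + length(loops) - 1L
    rows[[length(rows) + 1]] <- data.frame(
      station = st, area_cm2 = mets[[k]]$A_cm2, ap_cm = mets[[k]]$AP_cm,
      lat_cm = mets[[k]]$Lat_cm, region = "other",
      stringsAsFactors = FALSE)
    polys[[length(polys) + 1]] <- loops[[k]]
  }
  if (!length(rows)) stop("no non-empty airway cross sections found")
  structure(list(sections = do.call(rbind, rows), polygons = polys,
                 plane = plane, spacing = spacing,
                 n_discarded_components = n_discarded),
            class = "airway_profile")
}

#' @export
print.airway_profile <- function(x, ...) {
  cat(sprintf(
    "airway_profile: %d sections at %.1f mm spacing, stations [%.1f, %.1f] mm\n",
    nrow(x$sections), x$spacing, min(x$sections$station),
    max(x$sections$station)))
  for (r in unique(x$sections$region)) {
    idx <- x$sections$region == r
    cat(sprintf("  %s: %d sections, min area %.2f cm^2\n", r, sum(idx),
                min(x$sections$area_cm2[idx])))
  }
  invisible(x)
}

#' Tag velo- and laryngopharyngeal regions of a profile
#'
#' Stations between the palatal plane and the soft-palate tip are tagged
#' VPX (velopharynx); between the soft-palate tip and the epiglottis tip,
#' oropharynx ("other"); below the epiglottis tip, LPX (laryngopharynx).
#' Explicit station bounds override the landmark-derived ones.
#'
#' @param profile an `airway_profile`.
#' @param lms [landmarks] with `soft_palate_tip` and `epiglottis_tip`
#'   (ignored when both bounds are given explicitly).
#' @param vpx_bounds,lpx_bounds optional numeric length-2 station intervals
#'   (mm along the palatal-plane normal, typically negative below the
#'   plane).
#' @return the profile with the `region` column filled in.
#' @export
partition_regions <- function(profile, lms = NULL, vpx_bounds = NULL,
                              lpx_bounds = NULL) {
  stopifnot(inherits(profile, "airway_profile"))
  st <- profile$sections$station
  station_of <- function(p) {
    sum((p - profile$plane$origin) * profile$plane$normal)
  }
  if (is.null(vpx_bounds) || is.null(lpx_bounds)) {
    if (is.null(lms)) {
      stop("need landmarks or explicit station bounds for region partition")
    }
    sp <- station_of(landmark_point(lms, "soft_palate_tip"))
    eg <- station_of(landmark_point(lms, "epiglottis_tip"))
    if (is.null(vpx_bounds)) vpx_bounds <- c(sp, 0)
    if (is.null(lpx_bounds)) lpx_bounds <- c(min(st) - profile$spacing, eg)
  }
  if (vpx_bounds[1] > vpx_bounds[2] || lpx_bounds[1] > lpx_bounds[2]) {
    stop("region bounds must be increasing station intervals")
  }
  region <- rep("other", length(st))
  region[st >= vpx_bounds[1] & st <= vpx_bounds[2]] <- "VPX"
  region[st >= lpx_bounds[1] & st <= lpx_bounds[2]] <- "LPX"
  if (!any(region == "LPX")) {
    warning("LPX region is empty under the given bounds")
  }
  profile$sections$region <- region
  profile
}

#' Narrowest cross section of a region
#'
#' @param profile an `airway_profile` with regions tagged.
#' @param region region tag ("VPX", "LPX" or "other").
#' @return one-row data.frame (station, area_cm2, ap_cm, lat_cm, region);
#'   area ties resolve to the inferior-most station.
#' @export
narrowest_section <- function(profile, region = "VPX") {
  sec <- profile$sections[profile$sections$region == region, , drop = FALSE]
  if (!nrow(sec)) stop("empty region: ", region)
  k <- which(sec$area_cm2 == min(sec$area_cm2))
  k <- k[which.min(sec$station[k])] # inferior-most on ties
  sec[k, , drop = FALSE]
}

#' Write an airway profile as CSV
#'
#' @param profile an `airway_profile`.
#' @param path output CSV path.
#' @export
write_airway_profile <- function(profile, path) {
  write.csv(profile$sections, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
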