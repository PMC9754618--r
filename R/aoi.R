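#' @title Basic-feature (AOI) coverage and revisit metrics
#' @description Basic features are expert-defined polygonal areas of interest
#'   on the reference images; one physical feature keeps one identity across
#'   all perspectives it is visible from. Metrics per participant and
#'   sculpture: number of distinct features fixated, percentage of fixations
#'   on features, and revisits per minute. A revisit is a re-entry into a
#'   feature after at least one fixation outside it following a prior visit;
#'   continuous dwelling inside a feature is not a revisit.
#' @name aoi_metrics
NULL

# signed twice-area of triangle (a,b,c); sign gives orientation
cross2 <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

on_segment <- function(px, py, ax, ay, bx, by, eps = 1e-9) {
  if (abs(cross2(ax, ay, bx, by, px, py)) > eps *
      max(1, abs(bx - ax), abs(by - ay))) return(FALSE)
  px >= min(ax, bx) - eps && px <= max(ax, bx) + eps &&
    py >= min(ay, by) - eps && py <= max(ay, by) + eps
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' A point exactly on a polygon edge or vertex counts as inside; interior
#' membership follows the even-odd (ray-casting) rule, so the test is valid
#' for any simple polygon, convex or not.
#'
#' @param px,py point coordinates, px.
#' @param vertices n x 2 matrix of polygon vertices (closing edge implicit).
#' @return logical scalar.
#' @export
point_in_polygon <- function(px, py, vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  j <- c(n, seq_len(n - 1))
  # boundary first: inclusive by convention
  for (k in seq_len(n)) {
    if (on_segment(px, py, v[j[k], 1], v[j[k], 2], v[k, 1], v[k, 2]))
      return(TRUE)
  }
  inside <- FALSE
  for (k in seq_len(n)) {
    x1 <- v[j[k], 1]; y1 <- v[j[k], 2]
    x2 <- v[k, 1]; y2 <- v[k, 2]
    if ((y1 > py) != (y2 > py)) {
      xcross <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xcross) inside <- !inside
    }
  }
  inside
}

#' Polygon area (shoelace formula)
#'
#' @param vertices n x 2 matrix of polygon vertices.
#' @return area, px^2 (non-negative).
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# proper/improper intersection test between segments (a,b) and (c,d)
segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy, eps = 1e-12) {
  d1 <- cross2(cx, cy, dx, dy, ax, ay)
  d2 <- cross2(cx, cy, dx, dy, bx, by)
  d3 <- cross2(ax, ay, bx, by, cx, cy)
  d4 <- cross2(ax, ay, bx, by, dx, dy)
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) return(TRUE)
  # collinear touching / overlap
  (abs(d1) <= eps && on_segment(ax, ay, cx, cy, dx, dy)) ||
    (abs(d2) <= eps && on_segment(bx, by, cx, cy, dx, dy)) ||
    (abs(d3) <= eps && on_segment(cx, cy, ax, ay, bx, by)) ||
    (abs(d4) <= eps && on_segment(dx, dy, ax, ay, bx, by))
}

# TRUE iff the closed polygon has no self-intersection between non-adjacent
# edges (shared endpoints of adjacent edges are allowed)
polygon_is_simple <- function(vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  if (n < 3) return(FALSE)
  a <- seq_len(n)
  b <- c(2:n, 1)
  for (i in seq_len(n - 1)) {
    for (k in seq.int(i + 1, n)) {
      # skip adjacent edges (share a vertex), incl. the wrap-around pair
      if (k == i + 1 || (i == 1 && k == n)) next
      if (segments_intersect(v[a[i], 1], v[a[i], 2], v[b[i], 1], v[b[i], 2],
                             v[a[k], 1], v[a[k], 2], v[b[k], 1], v[b[k], 2]))
        return(FALSE)
    }
  }
  TRUE
}

#' Map each fixation of a scanpath to its basic feature
#'
#' For each fixation, finds the feature whose polygon on that fixation's
#' reference image contains the position (boundary inclusive). Overlapping
#' polygons are resolved to the smallest area, then lexicographically by
#' `feature_id`. Fixations on a reference image without polygons, or outside
#' every polygon, map to `NA`.
#'
#' @param sp a `scanpath`.
#' @param aois an `aoi_set` for the scanpath's sculpture.
#' @return character vector of `feature_id` or `NA`, in fixation order
#'   (the AOI hit sequence).
#' @export
hit_test <- function(sp, aois) {
  stopifnot(inherits(sp, "scanpath"), inherits(aois, "aoi_set"))
  if (!identical(sp$sculpture_id, aois$sculpture_id)) {
    stop_validation("scanpath is on '%s' but AOI set is for '%s'",
                    sp$sculpture_id, aois$sculpture_id)
  }
  reg_img <- vapply(aois$regions, `[[`, integer(1), "ref_image")
  areas <- vapply(aois$regions, function(r) polygon_area(r$vertices), numeric(1))
  fids <- vapply(aois$regions, `[[`, character(1), "feature_id")
  fix <- sp$fixations
  vapply(seq_len(nrow(fix)), function(i) {
    cand <- which(reg_img == fix$ref_image[i])
    hit <- cand[vapply(cand, function(k)
      point_in_polygon(fix$x[i], fix$y[i], aois$regions[[k]]$vertices),
      logical(1))]
    if (length(hit) == 0) return(NA_character_)
    hit <- hit[order(areas[hit], fids[hit])]
    fids[hit[1]]
  }, character(1))
}

#' Number of distinct basic features fixated
#'
#' Feature identity is shared across reference images: the same feature hit
#' from two perspectives counts once.
#'
#' @param hits AOI hit sequence from [hit_test()].
#' @return integer count.
#' @export
n_features_fixated <- function(hits) {
  length(unique(hits[!is.na(hits)]))
}

#' Percentage of fixations on basic features
#'
#' @param hits AOI hit sequence from [hit_test()]; must be non-empty.
#' @return percentage in 0..100; `NA` with a warning for an empty sequence.
#' @export
pct_on_features <- function(hits) {
  if (length(hits) == 0) {
    warning("empty hit sequence: percentage undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * sum(!is.na(hits)) / length(hits)
}

#' Count revisits in an AOI hit sequence
#'
#' Per feature, a revisit is counted when the gaze re-enters the feature
#' after at least one fixation outside it (any fixation not hitting that
#' feature, including fixations inside another feature) following a prior
#' visit. Consecutive fixations inside the same feature are a single visit.
#' Counts are summed over features.
#'
#' @param hits AOI hit sequence from [hit_test()].
#' @return integer total revisit count.
#' @export
#' @examples
#' count_revisits(c("A", NA, "A"))       # 1
#' count_revisits(c("A", "A", "A"))      # 0
#' count_revisits(c("A", "B", "A", "B")) # 2
count_revisits <- function(hits) {
  feats <- unique(hits[!is.na(hits)])
  total <- 0L
  for (f in feats) {
    # state machine: "out" (never/currently outside after a visit) vs "in"
    state <- "unvisited"
    for (h in hits) {
      inside <- !is.na(h) && h == f
      if (inside) {
        if (state == "left") total <- total + 1L
        state <- "in"
      } else if (state == "in") {
        state <- "left"
      }
    }
  }
  total
}

#' Revisits per minute
#'
#' @param hits AOI hit sequence from [hit_test()].
#' @param inspection_time_ms inspection time, ms, > 0.
#' @return revisits per minute of inspection time.
#' @export
revisits_per_minute <- function(hits, inspection_time_ms) {
  stopifnot(inspection_time_ms > 0)
  count_revisits(hits) / (inspection_time_ms / 60000)
}

#' Per-participant AOI metrics
#'
#' @param ft a `fixation_table`.
#' @param aoi_sets named list of `aoi_set` objects, one per sculpture in `ft`
#'   (names = sculpture ids).
#' @param inspection `"span"` or `"sum"`, see [inspection_time()].
#' @return data frame, one row per (participant, sculpture):
#'   `n_features_fixated`, `pct_on_features`, `n_revisits`,
#'   `revisits_per_min`, `inspection_time_ms`.
#' @export
aoi_metrics <- function(ft, aoi_sets, inspection = c("span", "sum")) {
  inspection <- match.arg(inspection)
  sps <- scanpaths(ft)
  rows <- lapply(sps, function(sp) {
    aois <- aoi_sets[[sp$sculpture_id]]
    if (is.null(aois)) {
      stop_validation("no AOI set supplied for sculpture '%s'", sp$sculpture_id)
    }
    hits <- hit_test(sp, aois)
    it <- inspection_time(sp, inspection)
    data.frame(participant_id = sp$participant_id,
               sculpture_id = sp$sculpture_id,
               n_features_fixated = n_features_fixated(hits),
               pct_on_features = pct_on_features(hits),
               n_revisits = count_revisits(hits),
               revisits_per_min = revisits_per_minute(hits, it),
               inspection_time_ms = it,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
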