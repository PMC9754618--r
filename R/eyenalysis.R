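#' @title Double-mapping scanpath distance in (x, y, scaled duration)
#' @description The similarity of two participants' scanpaths is measured by
#'   double mapping: each fixation of one scanpath is mapped to its nearest
#'   fixation of the other (and vice versa), nearest in 3-D Euclidean distance
#'   over x (px), y (px) and the fixation duration rescaled to px. The summed
#'   mapped distances are normalised by the larger of the two fixation counts.
#'   Because fixations on a free-standing sculpture are mapped onto eight
#'   reference images (45 degree steps), the distance is computed per
#'   reference image and averaged, yielding one distance per participant pair
#'   per sculpture. The duration axis is scaled so that the longest fixation
#'   on a sculpture spans the sculpture's pixel height; this conversion factor
#'   is in px per ms.
#' @name eyenalysis
NULL

#' Euclidean distance between two points
#'
#' @param p,q numeric vectors of equal length (here: `c(x, y, z)` with z the
#'   scaled duration).
#' @return distance, px.
#' @export
#' @examples
#' point_distance(c(0, 0, 0), c(3, 4, 0)) # 5
point_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  sqrt(sum((p - q)^2))
}

#' Double-mapping distance between two point sets
#'
#' For each point of `S` the nearest point of `T` is found, and vice versa;
#' the two sums of nearest-neighbour distances are added and divided by
#' `max(|S|, |T|)`, so both scanpaths contribute all their fixations
#' regardless of unequal lengths. Nearest-neighbour search is exact (full
#' enumeration); ties go to the lower index, which cannot change the value.
#'
#' @param S,T numeric matrices (rows = points, columns = dimensions), both
#'   non-empty, same number of columns.
#' @return distance, px.
#' @export
#' @examples
#' double_map_distance(matrix(c(0, 0, 0), 1), matrix(c(3, 4, 0), 1)) # 10
double_map_distance <- function(S, T) {
  S <- as.matrix(S); T <- as.matrix(T)
  if (nrow(S) == 0 || nrow(T) == 0) {
    stop_validation("double_map_distance requires non-empty point sets")
  }
  stopifnot(ncol(S) == ncol(T))
  # per-dimension difference matrices: exact for coincident points (no
  # cancellation), so d(S, S) is exactly zero
  d2 <- 0
  for (k in seq_len(ncol(S))) {
    d2 <- d2 + outer(S[, k], T[, k], "-")^2
  }
  D <- sqrt(d2)
  (sum(apply(D, 1, min)) + sum(apply(D, 2, min))) / max(nrow(S), nrow(T))
}

#' Duration-to-pixel conversion factor for a sculpture
#'
#' Scales fixation duration (ms) onto a third spatial axis (px) such that the
#' longest fixation observed on the sculpture spans the sculpture's pixel
#' height: `value = height_px / max(duration_ms)`. The factor is computed
#' cohort-wide per sculpture; a configured override (e.g. a published value)
#' can be supplied instead.
#'
#' @param ft a `fixation_table` (all participants).
#' @param sculpture_id sculpture to compute the factor for.
#' @param height_px sculpture silhouette height on the reference images, px.
#'   Required unless `value` is given.
#' @param value optional configured factor in px/ms; bypasses computation.
#' @return object of class `conversion_factor`: list with `sculpture_id`,
#'   `value` (px/ms) and `source` (`"computed"` or `"configured"`).
#' @export
conversion_factor <- function(ft, sculpture_id, height_px = NULL, value = NULL) {
  if (!is.null(value)) {
    stopifnot(is.numeric(value), value > 0)
    out <- list(sculpture_id = sculpture_id, value = value,
                source = "configured")
  } else {
    stopifnot(inherits(ft, "fixation_table"), is.numeric(height_px),
              height_px > 0)
    durs <- ft$duration_ms[ft$sculpture_id == sculpture_id]
    if (length(durs) == 0) {
      stop_validation("no fixations for sculpture '%s'", sculpture_id)
    }
    out <- list(sculpture_id = sculpture_id, value = height_px / max(durs),
                source = "computed")
  }
  class(out) <- "conversion_factor"
  out
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat(sprintf("<conversion_factor> %s: %.4g px/ms (%s)\n",
              x$sculpture_id, x$value, x$source))
  invisible(x)
}

# fixations -> list of (x, y, duration * factor) matrices keyed by ref_image
scanpath_points <- function(sp, factor_value) {
  fix <- sp$fixations
  split_idx <- split(seq_len(nrow(fix)), fix$ref_image)
  lapply(split_idx, function(i)
    cbind(x = fix$x[i], y = fix$y[i], z = fix$duration_ms[i] * factor_value))
}

#' Scanpath distance between two participants on one sculpture
#'
#' Fixations are converted to 3-D points (z = duration x conversion factor)
#' and partitioned by reference image; the double-mapping distance is
#' computed on each reference image where *both* scanpaths have at least one
#' fixation, and the per-image distances are averaged. Reference images
#' covered by only one participant are skipped (their count is recorded in
#' attribute `"n_images_skipped"`); if no image is shared the distance is
#' undefined (`NA` with a warning).
#'
#' @param A,B `scanpath` objects on the same sculpture.
#' @param factor a `conversion_factor` for that sculpture (or a bare numeric
#'   px/ms value).
#' @return mean per-image distance, px, with attributes `"n_images_used"` and
#'   `"n_images_skipped"`; `NA` if no reference image is shared.
#' @export
scanpath_distance <- function(A, B, factor) {
  stopifnot(inherits(A, "scanpath"), inherits(B, "scanpath"))
  if (!identical(A$sculpture_id, B$sculpture_id)) {
    stop_validation("scanpaths are on different sculptures ('%s' vs '%s')",
                    A$sculpture_id, B$sculpture_id)
  }
  fv <- if (inherits(factor, "conversion_factor")) factor$value else
    as.numeric(factor)
  stopifnot(is.numeric(fv), fv > 0)
  pa <- scanpath_points(A, fv)
  pb <- scanpath_points(B, fv)
  shared <- intersect(names(pa), names(pb))
  n_skipped <- length(union(names(pa), names(pb))) - length(shared)
  if (length(shared) == 0) {
    warning(sprintf("no shared reference image between %s and %s; distance undefined",
                    A$participant_id, B$participant_id), call. = FALSE)
    d <- NA_real_
  } else {
    d <- mean(vapply(shared, function(img)
      double_map_distance(pa[[img]], pb[[img]]), numeric(1)))
  }
  attr(d, "n_images_used") <- length(shared)
  attr(d, "n_images_skipped") <- n_skipped
  d
}

#' Pairwise distance matrix for one sculpture
#'
#' Computes [scanpath_distance()] between every pair of participants on one
#' sculpture and labels each cell with the pair's expertise divergence.
#'
#' @param ft a `fixation_table`.
#' @param profiles output of [expertise_profiles()] covering all participants
#'   in `ft`.
#' @param sculpture_id sculpture to analyse.
#' @param factor a `conversion_factor` (or numeric px/ms) for the sculpture.
#' @return object of class `distance_matrix`: list with `sculpture_id`,
#'   `participants` (character, row/column order), `distances` (symmetric
#'   numeric matrix, zero diagonal, `NA` for undefined pairs), `divergence`
#'   (integer matrix, `NA` diagonal), `n_missing` (undefined off-diagonal
#'   pairs) and `n_images_skipped` (total skipped reference images).
#' @export
pairwise_distances <- function(ft, profiles, sculpture_id, factor) {
  stopifnot(inherits(ft, "fixation_table"))
  sub <- ft[ft$sculpture_id == sculpture_id, ]
  if (nrow(sub) == 0) stop_validation("no fixations for sculpture '%s'",
                                      sculpture_id)
  class(sub) <- class(ft)
  sps <- scanpaths(sub)
  ids <- sort(vapply(sps, `[[`, "", "participant_id"))
  sps <- sps[match(paste(ids, sculpture_id, sep = "|"), names(sps))]
  n <- length(ids)
  if (n < 2) stop_validation("need >= 2 participants, got %d", n)
  codes <- profiles$code[match(ids, profiles$participant_id)]
  if (anyNA(codes)) {
    stop_validation("missing expertise profile for participant(s): %s",
                    paste(ids[is.na(codes)], collapse = ", "))
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  skipped <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d <- scanpath_distance(sps[[i]], sps[[j]], factor)
      skipped <- skipped + attr(d, "n_images_skipped")
      D[i, j] <- D[j, i] <- as.numeric(d)
    }
  }
  div <- abs(outer(codes, codes, "-"))
  diag(div) <- NA_integer_
  dimnames(div) <- dimnames(D)
  out <- list(sculpture_id = sculpture_id, participants = ids, distances = D,
              divergence = div,
              n_missing = sum(is.na(D[upper.tri(D)])),
              n_images_skipped = skipped)
  class(out) <- "distance_matrix"
  out
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> sculpture %s: %d participants, %d pair(s) undefined\n",
              x$sculpture_id, length(x$participants), x$n_missing))
  invisible(x)
}

#' Summarise pairwise distances by expertise divergence
#'
#' Pools the off-diagonal cells of a distance matrix by divergence group
#' (self-comparisons, the zero diagonal, are excluded) and reports mean,
#' sample SD and pair count per group. Groups with one pair get SD 0 and a
#' degenerate flag; empty groups are omitted with a warning; undefined
#' (`NA`) pairs are dropped from their group's count.
#'
#' @param dm a `distance_matrix`.
#' @return data frame: `divergence`, `n`, `mean`, `sd`, `degenerate`.
#' @export
divergence_summary <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"))
  ut <- upper.tri(dm$distances)
  d <- dm$distances[ut]
  g <- dm$divergence[ut]
  keep <- !is.na(d)
  d <- d[keep]; g <- g[keep]
  rows <- list()
  for (dev in sort(unique(dm$divergence[ut]))) {
    vals <- d[g == dev]
    if (length(vals) == 0) {
      warning(sprintf("divergence group %d has no defined pairs; omitted", dev),
              call. = FALSE)
      next
    }
    rows[[as.character(dev)]] <- data.frame(
      divergence = dev, n = length(vals), mean = mean(vals),
      sd = if (length(vals) > 1) stats::sd(vals) else 0,
      degenerate = length(vals) == 1)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean distance per pair of expertise levels
#'
#' The level-pair cell means behind the divergence summary: mean and sample
#' SD of the pairwise distances within each unordered pair of expertise
#' levels (within-level cells included).
#'
#' @param dm a `distance_matrix`.
#' @param profiles output of [expertise_profiles()] covering the matrix's
#'   participants.
#' @return data frame: `level_a`, `level_b` (a <= b in expertise order),
#'   `divergence`, `n`, `mean`, `sd`.
#' @export
level_pair_means <- function(dm, profiles) {
  stopifnot(inherits(dm, "distance_matrix"))
  codes <- profiles$code[match(dm$participants, profiles$participant_id)]
  if (anyNA(codes)) stop_validation("missing expertise profile for matrix participants")
  ut <- which(upper.tri(dm$distances), arr.ind = TRUE)
  ca <- pmin(codes[ut[, 1]], codes[ut[, 2]])
  cb <- pmax(codes[ut[, 1]], codes[ut[, 2]])
  d <- dm$distances[upper.tri(dm$distances)]
  keep <- !is.na(d)
  key <- paste(ca, cb)[keep]
  d <- d[keep]
  rows <- lapply(sort(unique(key)), function(k) {
    vals <- d[key == k]
    cc <- as.integer(strsplit(k, " ")[[1]])
    data.frame(level_a = EXPERTISE_LEVELS[cc[1] + 1],
               level_b = EXPERTISE_LEVELS[cc[2] + 1],
               divergence = cc[2] - cc[1], n = length(vals),
               mean = mean(vals),
               sd = if (length(vals) > 1) stats::sd(vals) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool level-pair cell means into divergence means
#'
#' Aggregation identity linking the level-by-level distance tables to the
#' divergence summary: the pooled mean at divergence d is the pair-count
#' weighted mean of the level-pair cell means with that divergence.
#'
#' @param cells data frame with columns `level_a`, `level_b` (values in
#'   [EXPERTISE_LEVELS]), `mean` (cell mean distance) and `n` (number of
#'   pairs in the cell).
#' @return data frame: `divergence`, `n`, `mean`.
#' @export
#' @examples
#' cells <- data.frame(level_a = "layperson", level_b = EXPERTISE_LEVELS,
#'                     mean = c(1372, 8479, 9434, 7660), n = c(10, 25, 25, 25))
#' pool_divergence_means(cells)
pool_divergence_means <- function(cells) {
  stopifnot(all(c("level_a", "level_b", "mean", "n") %in% names(cells)))
  dv <- abs(expertise_code(cells$level_a) - expertise_code(cells$level_b))
  rows <- lapply(sort(unique(dv)), function(d) {
    sel <- dv == d
    data.frame(divergence = d, n = sum(cells$n[sel]),
               mean = stats::weighted.mean(cells$mean[sel], cells$n[sel]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
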