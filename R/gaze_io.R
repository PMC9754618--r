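#' @title Fixation tables, scanpaths, and AOI sets: reading, writing, validation
#' @description Boundary layer of the package. All invariants of the data model
#'   (positive durations, reference-image index in 1..8, monotone onsets,
#'   consecutive ordinals, simple polygons) are enforced here, so downstream
#'   analysis code can assume clean inputs.
#' @name gaze_io
NULL

FIXATION_COLUMNS <- c("participant_id", "sculpture_id", "ref_image",
                      "x", "y", "onset_ms", "duration_ms")

#' Construct a validated fixation table
#'
#' Validates a data frame of fixations (one row per fixation) against the data
#' model and returns it with class `fixation_table`. Rows are grouped by
#' (participant, sculpture) and ordered by ordinal; if no `ordinal` column is
#' present, ordinals are derived from row order within each group.
#'
#' @param df data frame with columns `participant_id`, `sculpture_id`,
#'   `ref_image` (integer 1..8), `x`, `y` (px), `onset_ms` (>= 0),
#'   `duration_ms` (> 0) and optionally `ordinal`.
#' @return a `fixation_table` (a data frame) with a derived `ordinal` column,
#'   ordered by participant, sculpture, ordinal.
#' @export
as_fixation_table <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(FIXATION_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop_validation("fixation table is missing column(s): %s",
                    paste(missing, collapse = ", "))
  }
  for (col in c("ref_image", "x", "y", "onset_ms", "duration_ms")) {
    df[[col]] <- as.numeric(df[[col]])
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0) {
      stop_validation("row %d: column '%s' is not a finite number", bad[1], col)
    }
  }
  bad <- which(df$duration_ms <= 0)
  if (length(bad) > 0) {
    stop_validation("row %d: duration_ms must be > 0 (got %g)",
                    bad[1], df$duration_ms[bad[1]])
  }
  bad <- which(df$onset_ms < 0)
  if (length(bad) > 0) {
    stop_validation("row %d: onset_ms must be >= 0 (got %g)",
                    bad[1], df$onset_ms[bad[1]])
  }
  bad <- which(df$ref_image < 1 | df$ref_image > 8 |
                 df$ref_image != round(df$ref_image))
  if (length(bad) > 0) {
    stop_validation("row %d: ref_image must be an integer in 1..8 (got %g)",
                    bad[1], df$ref_image[bad[1]])
  }
  df$ref_image <- as.integer(df$ref_image)
  df$participant_id <- as.character(df$participant_id)
  df$sculpture_id <- as.character(df$sculpture_id)

  df$.row <- seq_len(nrow(df))
  key <- interaction(df$participant_id, df$sculpture_id, drop = TRUE)
  if (!"ordinal" %in% names(df)) {
    df$ordinal <- stats::ave(df$.row, key, FUN = function(r) rank(r))
  }
  df$ordinal <- as.integer(df$ordinal)

  for (grp in split(df, key)) {
    grp <- grp[order(grp$ordinal), ]
    if (!identical(grp$ordinal, seq_len(nrow(grp)))) {
      stop_validation(
        "participant '%s' on sculpture '%s': ordinals must be consecutive 1..n",
        grp$participant_id[1], grp$sculpture_id[1])
    }
    if (is.unsorted(grp$onset_ms)) {
      i <- which(diff(grp$onset_ms) < 0)[1]
      stop_validation(
        "row %d: onset_ms decreases within participant '%s' on sculpture '%s'",
        grp$.row[i + 1], grp$participant_id[1], grp$sculpture_id[1])
    }
  }
  df <- df[order(df$participant_id, df$sculpture_id, df$ordinal), ]
  df$.row <- NULL
  rownames(df) <- NULL
  class(df) <- c("fixation_table", "data.frame")
  df
}

#' Read a delimited fixation table
#'
#' @param path file path of a delimited text file with a header row.
#' @param delim field delimiter (default `","`; use `"\t"` for TSV).
#' @param col_map optional named character vector mapping the standard column
#'   names (names) to the column names used in the file (values), e.g.
#'   `c(onset_ms = "start")`.
#' @return a [`as_fixation_table()`]-validated `fixation_table`.
#' @export
read_fixation_table <- function(path, delim = ",", col_map = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(df)) {
        stop_validation("fixation table is missing column(s): %s (mapped to %s)",
                        src, std)
      }
      names(df)[names(df) == src] <- std
    }
  }
  as_fixation_table(df)
}

#' Write a fixation table
#'
#' Inverse of [read_fixation_table()]: `read(write(x))` reproduces `x`
#' field for field.
#'
#' @param ft a `fixation_table`.
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_fixation_table <- function(ft, path, delim = ",") {
  utils::write.table(as.data.frame(ft), path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Split a fixation table into scanpaths
#'
#' A scanpath is the ordered fixation sequence of one participant on one
#' sculpture, with its inspection time (end of last fixation minus onset of
#' the first).
#'
#' @param ft a `fixation_table`.
#' @return a `scanpath_set`: a list of `scanpath` objects, named
#'   `"<participant>|<sculpture>"`.
#' @export
scanpaths <- function(ft) {
  stopifnot(inherits(ft, "fixation_table"))
  key <- interaction(ft$participant_id, ft$sculpture_id, drop = TRUE)
  out <- lapply(split(as.data.frame(ft), key), function(grp) {
    grp <- grp[order(grp$ordinal), ]
    rownames(grp) <- NULL
    sp <- list(participant_id = grp$participant_id[1],
               sculpture_id = grp$sculpture_id[1],
               fixations = grp,
               inspection_time = inspection_span(grp))
    class(sp) <- "scanpath"
    sp
  })
  names(out) <- vapply(out, function(sp)
    paste(sp$participant_id, sp$sculpture_id, sep = "|"), character(1))
  out <- out[order(names(out))]
  class(out) <- "scanpath_set"
  out
}

inspection_span <- function(fix) {
  if (nrow(fix) == 0) return(0)
  max(fix$onset_ms + fix$duration_ms) - min(fix$onset_ms)
}

#' Inspection time of a scanpath
#'
#' @param sp a `scanpath`.
#' @param method `"span"` (default): end of last fixation minus onset of the
#'   first; `"sum"`: total fixated time (sum of durations), offered as an
#'   alternative reading of "inspection time".
#' @return time in ms.
#' @export
inspection_time <- function(sp, method = c("span", "sum")) {
  method <- match.arg(method)
  if (method == "span") inspection_span(sp$fixations)
  else sum(sp$fixations$duration_ms)
}

#' @export
print.scanpath <- function(x, ...) {
  cat(sprintf("<scanpath> participant %s on %s: %d fixations over %.0f ms\n",
              x$participant_id, x$sculpture_id, nrow(x$fixations),
              x$inspection_time))
  invisible(x)
}

#' @export
print.scanpath_set <- function(x, ...) {
  cat(sprintf("<scanpath_set> %d scanpaths (%d participants, %d sculptures)\n",
              length(x),
              length(unique(vapply(x, `[[`, "", "participant_id"))),
              length(unique(vapply(x, `[[`, "", "sculpture_id")))))
  invisible(x)
}

# ---- AOI sets ---------------------------------------------------------------

#' Construct a validated AOI (basic-feature) set
#'
#' Basic features are expert-defined areas of interest on a sculpture. One
#' physical feature keeps one `feature_id` across all reference images it is
#' visible on.
#'
#' @param sculpture_id sculpture the features belong to.
#' @param regions list of regions, each a list with `feature_id` (character),
#'   `ref_image` (integer 1..8), and `vertices` (n x 2 matrix or list of
#'   `[x, y]` pairs, n >= 3, simple polygon, px).
#' @return an `aoi_set`.
#' @export
aoi_set <- function(sculpture_id, regions) {
  regions <- lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    v <- r$vertices
    if (is.list(v)) v <- do.call(rbind, lapply(v, as.numeric))
    v <- as.matrix(v)
    if (nrow(v) < 3) {
      stop_validation("region %d ('%s'): polygon needs >= 3 vertices, got %d",
                      i, r$feature_id %||% "?", nrow(v))
    }
    if (!all(is.finite(v))) {
      stop_validation("region %d ('%s'): non-finite vertex coordinate",
                      i, r$feature_id %||% "?")
    }
    if (!polygon_is_simple(v)) {
      stop_validation("region %d ('%s'): polygon is self-intersecting",
                      i, r$feature_id %||% "?")
    }
    ri <- as.numeric(r$ref_image)
    if (length(ri) != 1 || ri < 1 || ri > 8 || ri != round(ri)) {
      stop_validation("region %d ('%s'): ref_image must be an integer in 1..8",
                      i, r$feature_id %||% "?")
    }
    list(feature_id = as.character(r$feature_id), ref_image = as.integer(ri),
         vertices = unname(v))
  })
  out <- list(sculpture_id = as.character(sculpture_id), regions = regions)
  class(out) <- "aoi_set"
  out
}

#' Read an AOI set from YAML or JSON
#'
#' Expected structure:
#' `{sculpture_id, regions: [{feature_id, ref_image, vertices: [[x,y],...]}]}`.
#' Format is chosen by file extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path file path.
#' @return an `aoi_set`.
#' @export
read_aoi_set <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    stop_validation("unsupported AOI file extension '%s' (use yaml or json)", ext))
  aoi_set(raw$sculpture_id, raw$regions)
}

#' Write an AOI set to YAML or JSON
#'
#' @param aois an `aoi_set`.
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_aoi_set <- function(aois, path) {
  stopifnot(inherits(aois, "aoi_set"))
  payload <- list(
    sculpture_id = aois$sculpture_id,
    regions = lapply(aois$regions, function(r) {
      list(feature_id = r$feature_id, ref_image = r$ref_image,
           vertices = lapply(seq_len(nrow(r$vertices)),
                             function(i) as.numeric(r$vertices[i, ])))
    }))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(payload, path),
    json = jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA),
    stop_validation("unsupported AOI file extension '%s' (use yaml or json)", ext))
  invisible(path)
}

#' @export
print.aoi_set <- function(x, ...) {
  feats <- unique(vapply(x$regions, `[[`, "", "feature_id"))
  cat(sprintf("<aoi_set> sculpture %s: %d regions, %d distinct features\n",
              x$sculpture_id, length(x$regions), length(feats)))
  invisible(x)
}

#' Read participant metadata
#'
#' @param path CSV with columns `participant_id` and `years_experience`.
#' @param delim field delimiter.
#' @return data frame with those two columns.
#' @export
read_participant_metadata <- function(path, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE)
  for (col in c("participant_id", "years_experience")) {
    if (!col %in% names(df)) {
      stop_validation("participant metadata is missing column(s): %s", col)
    }
  }
  df$participant_id <- as.character(df$participant_id)
  df$years_experience <- as.numeric(df$years_experience)
  if (any(!is.finite(df$years_experience) | df$years_experience < 0)) {
    stop_validation("years_experience must be finite and >= 0")
  }
  df[, c("participant_id", "years_experience")]
}

#' Write a summary table with fixed decimal formatting
#'
#' Writes a delimited file with deterministic column order and fixed decimal
#' formatting per column: ratios and rates to 2 decimals, distances to
#' integers, ties rounded half-up (see [round_half_up()]).
#'
#' @param rows data frame to write; columns are written in their current order.
#' @param path output path.
#' @param digits named integer vector: decimal places for the named numeric
#'   columns; numeric columns not named are written unformatted.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(rows, path, digits = NULL, delim = ",") {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (col in names(digits)) {
    if (col %in% names(out)) {
      out[[col]] <- format_fixed(as.numeric(out[[col]]), digits[[col]])
    }
  }
  utils::write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
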