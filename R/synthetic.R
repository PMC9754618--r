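#' @title Synthetic fixation-cohort generator
#' @description Generates fixation tables, participant metadata and AOI sets
#'   with the statistical structure the analysis assumes: four expertise
#'   groups of five participants viewing two sculptures from eight
#'   perspectives, a two-state (global/local) Markov mode sequence with
#'   configurable persistence, right-skewed lognormal fixation durations per
#'   mode, configurable attraction towards basic features with revisit bias,
#'   and group-specific gaze centers that control between-group scanpath
#'   separation. Every quantity the analysis estimates has a closed-form
#'   expectation under this generator ([expected_metrics()]), enabling
#'   parameter-recovery validation.
#' @name synthetic_gaze
NULL

#' Group-level generator parameters
#'
#' @param p_local stationary probability that a fixation is in local mode.
#' @param dur_global,dur_local lognormal duration parameters per mode:
#'   `c(median, sigma)` with median in ms and sigma the log-scale SD.
#' @param switch_persistence probability of staying in the current mode at
#'   each step; otherwise the mode is redrawn as Bernoulli(`p_local`), so the
#'   stationary local share stays `p_local` at any persistence.
#' @param aoi_attraction probability a fixation is aimed inside a basic
#'   feature (uniform over the feature's polygon).
#' @param n_fix mean number of fixations per sculpture (Poisson).
#' @param revisit_bias when aiming at a feature, probability of returning to
#'   an already-visited feature rather than drawing one uniformly.
#' @param spatial_jitter_px SD (px) of the Gaussian scatter of non-AOI
#'   fixations around the group gaze center.
#' @param center_offset_px `c(dx, dy)` offset (px) of the group's gaze center
#'   from the image center; level-dependent offsets separate the groups'
#'   scanpaths.
#' @return list of validated group parameters.
#' @export
group_params <- function(p_local = 0.32,
                         dur_global = c(median = 110, sigma = 0.3),
                         dur_local = c(median = 350, sigma = 0.3),
                         switch_persistence = 0.75,
                         aoi_attraction = 0.08,
                         n_fix = 300,
                         revisit_bias = 0.3,
                         spatial_jitter_px = 120,
                         center_offset_px = c(0, 0)) {
  for (p in c(p_local = p_local, switch_persistence = switch_persistence,
              aoi_attraction = aoi_attraction, revisit_bias = revisit_bias)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop_validation("generator probabilities must lie in [0, 1]")
    }
  }
  if (any(c(dur_global, dur_local, n_fix, spatial_jitter_px) <= 0)) {
    stop_validation("duration parameters, n_fix and jitter must be > 0")
  }
  list(p_local = p_local, dur_global = unname(dur_global),
       dur_local = unname(dur_local),
       switch_persistence = switch_persistence,
       aoi_attraction = aoi_attraction, n_fix = n_fix,
       revisit_bias = revisit_bias, spatial_jitter_px = spatial_jitter_px,
       center_offset_px = unname(center_offset_px))
}

#' Cohort configuration for the synthetic generator
#'
#' Defaults emulate the study design the analysis targets: four expertise
#' groups of five participants, two sculptures ("moses", small and abstract;
#' "daphne", tall and detailed) photographed from eight perspectives at 45
#' degree steps onto 800 x 1200 px reference images. Group gaze centers are
#' offset by 50 px in x and 30 px in y per expertise level, so scanpath
#' separation grows with expertise divergence.
#'
#' @param groups named list (names in [EXPERTISE_LEVELS]) of lists with
#'   `n_participants` and `params` ([group_params()]).
#' @param sculptures named list per sculpture: `height_px` (silhouette height
#'   on the reference image), `image_size` `c(width, height)` px,
#'   `n_features` (basic features in the default rectangular layout).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param gap_ms inter-fixation gap (saccade allowance), ms.
#' @param n_ref_images number of reference images per sculpture.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(groups = NULL,
                          sculptures = list(
                            moses = list(height_px = 900,
                                         image_size = c(800, 1200),
                                         n_features = 12),
                            daphne = list(height_px = 1100,
                                          image_size = c(800, 1200),
                                          n_features = 20)),
                          seed = 1L, gap_ms = 30, n_ref_images = 8) {
  if (is.null(groups)) {
    groups <- lapply(seq_along(EXPERTISE_LEVELS), function(i) {
      list(n_participants = 5,
           params = group_params(center_offset_px = c(50, 30) * (i - 1)))
    })
    names(groups) <- EXPERTISE_LEVELS
  }
  stopifnot(all(names(groups) %in% EXPERTISE_LEVELS),
            length(sculptures) >= 1, is.numeric(seed))
  for (g in groups) {
    stopifnot(is.numeric(g$n_participants), g$n_participants >= 1)
  }
  out <- list(groups = groups, sculptures = sculptures,
              seed = as.integer(seed), gap_ms = gap_ms,
              n_ref_images = as.integer(n_ref_images))
  class(out) <- "cohort_config"
  out
}

# years-of-experience bands per level used when sampling metadata
LEVEL_YEAR_BANDS <- list(layperson = c(0, 0), novice = c(0.5, 4.5),
                         semi_expert = c(5, 10), expert = c(11, 30))

#' Default rectangular basic-feature layout
#'
#' Axis-aligned rectangles arranged in a grid over the image (two columns up
#' to 8 features, four beyond), with
#' a small deterministic horizontal shift per reference image emulating the
#' perspective change. Every feature appears on every reference image under
#' one identity.
#'
#' @param sculpture_id sculpture id.
#' @param image_size `c(width, height)` px.
#' @param n_features number of features.
#' @param n_ref_images number of reference images.
#' @return an `aoi_set`.
#' @export
default_aoi_layout <- function(sculpture_id, image_size = c(800, 1200),
                               n_features = 12, n_ref_images = 8) {
  cols <- if (n_features <= 8) 2 else 4
  rows_n <- ceiling(n_features / cols)
  mx <- 80; my <- 100  # margins; right margin also absorbs per-image shift
  w <- min(65, floor((image_size[1] - 2 * mx) / cols) - 10)
  h <- min(65, floor((image_size[2] - 2 * my) / rows_n) - 10)
  gx <- if (cols > 1) (image_size[1] - 2 * mx - cols * w) / (cols - 1) else 0
  gy <- if (rows_n > 1) (image_size[2] - 2 * my - rows_n * h) / (rows_n - 1) else 0
  regions <- list()
  for (img in seq_len(n_ref_images)) {
    shift <- (img - 1) * 8
    for (f in seq_len(n_features)) {
      col <- (f - 1) %% cols
      row <- (f - 1) %/% cols
      x0 <- mx + col * (w + gx) + shift
      y0 <- my + row * (h + gy)
      regions[[length(regions) + 1]] <- list(
        feature_id = sprintf("feature_%02d", f),
        ref_image = img,
        vertices = rbind(c(x0, y0), c(x0 + w, y0),
                         c(x0 + w, y0 + h), c(x0, y0 + h)))
    }
  }
  aoi_set(sculpture_id, regions)
}

rlnorm_med <- function(n, median, sigma) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sigma)
}

#' Generate a synthetic cohort
#'
#' Deterministic given the configuration (including its seed). Each
#' (participant, sculpture) stream draws its fixation count from
#' Poisson(`n_fix`) (minimum 2), a mode sequence from the persistence chain,
#' durations from the mode's lognormal, a reference image uniformly over
#' 1..`n_ref_images` per fixation, and positions either inside an attracting
#' feature or scattered around the group gaze center; onsets accumulate
#' duration plus the inter-fixation gap. Each participant/sculpture stream
#' uses its own counter-derived substream of the seed, so adding participants
#' does not reshuffle existing ones.
#'
#' @param config a [cohort_config()].
#' @return list with `fixations` (a `fixation_table`), `meta` (participant
#'   metadata data frame), `aois` (named list of `aoi_set`), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  aois <- lapply(names(config$sculptures), function(sid) {
    s <- config$sculptures[[sid]]
    default_aoi_layout(sid, s$image_size, s$n_features, config$n_ref_images)
  })
  names(aois) <- names(config$sculptures)

  # participant metadata: one substream per participant
  meta <- list(); counter <- 0L
  for (lev in names(config$groups)) {
    g <- config$groups[[lev]]
    band <- LEVEL_YEAR_BANDS[[lev]]
    for (i in seq_len(g$n_participants)) {
      counter <- counter + 1L
      set.seed((config$seed + 104729L * counter) %% 2147483647L)
      yrs <- if (band[1] == band[2]) band[1] else
        stats::runif(1, band[1], band[2])
      meta[[counter]] <- data.frame(
        participant_id = sprintf("%s_%02d", substr(lev, 1, 3), i),
        years_experience = round(yrs, 2), level = lev,
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)

  fix <- list(); counter <- 1000L
  for (lev in names(config$groups)) {
    g <- config$groups[[lev]]
    for (i in seq_len(g$n_participants)) {
      pid <- sprintf("%s_%02d", substr(lev, 1, 3), i)
      for (sid in names(config$sculptures)) {
        counter <- counter + 1L
        set.seed((config$seed + 104729L * counter) %% 2147483647L)
        fix[[length(fix) + 1]] <-
          simulate_scanpath(pid, sid, g$params, config$sculptures[[sid]],
                            aois[[sid]], config$gap_ms, config$n_ref_images)
      }
    }
  }
  ft <- as_fixation_table(do.call(rbind, fix))
  list(fixations = ft, meta = meta[, c("participant_id", "years_experience")],
       aois = aois, config = config)
}

simulate_scanpath <- function(pid, sid, pars, sculpture, aois, gap_ms,
                              n_ref_images) {
  n <- max(2L, stats::rpois(1, pars$n_fix))
  # two-state mode chain: stay w.p. persistence, else redraw Bernoulli(p_local)
  modes <- logical(n)
  modes[1] <- stats::runif(1) < pars$p_local
  if (n > 1) {
    for (k in 2:n) {
      modes[k] <- if (stats::runif(1) < pars$switch_persistence) modes[k - 1]
        else stats::runif(1) < pars$p_local
    }
  }
  durations <- numeric(n)
  durations[modes] <- rlnorm_med(sum(modes), pars$dur_local[1],
                                 pars$dur_local[2])
  durations[!modes] <- rlnorm_med(sum(!modes), pars$dur_global[1],
                                  pars$dur_global[2])
  ref_image <- sample.int(n_ref_images, n, replace = TRUE)

  feats <- unique(vapply(aois$regions, `[[`, character(1), "feature_id"))
  reg_key <- paste(vapply(aois$regions, `[[`, character(1), "feature_id"),
                   vapply(aois$regions, `[[`, integer(1), "ref_image"))
  center <- c(sculpture$image_size[1] / 2, sculpture$image_size[2] / 2) +
    pars$center_offset_px
  x <- numeric(n); y <- numeric(n)
  visited <- character(0)
  for (k in seq_len(n)) {
    if (stats::runif(1) < pars$aoi_attraction) {
      f <- if (length(visited) > 0 && stats::runif(1) < pars$revisit_bias)
        sample(visited, 1) else sample(feats, 1)
      reg <- aois$regions[[match(paste(f, ref_image[k]), reg_key)]]
      v <- reg$vertices
      # rejection-sample a uniform point in the polygon from its bbox
      repeat {
        px <- stats::runif(1, min(v[, 1]), max(v[, 1]))
        py <- stats::runif(1, min(v[, 2]), max(v[, 2]))
        if (point_in_polygon(px, py, v)) break
      }
      x[k] <- px; y[k] <- py
      visited <- union(visited, f)
    } else {
      x[k] <- min(max(stats::rnorm(1, center[1], pars$spatial_jitter_px), 0),
                  sculpture$image_size[1])
      y[k] <- min(max(stats::rnorm(1, center[2], pars$spatial_jitter_px), 0),
                  sculpture$image_size[2])
    }
  }
  onset <- cumsum(c(0, durations[-n] + gap_ms))
  data.frame(participant_id = pid, sculpture_id = sid, ref_image = ref_image,
             x = x, y = y, onset_ms = onset, duration_ms = durations,
             stringsAsFactors = FALSE)
}

#' Closed-form expected metrics under the generator
#'
#' Analytic expectations of the global/local metrics implied by a group's
#' generator parameters at a given classification threshold, accounting for
#' threshold leakage of the lognormal duration mixtures (global-mode
#' fixations exceeding the threshold and local-mode fixations below it):
#' \itemize{
#'   \item `p_label_local`: stationary probability a fixation is *labelled*
#'     local: `p_local * P(dur_local > t) + (1 - p_local) * P(dur_global > t)`.
#'   \item `gl_ratio`: `(1 - p_label_local) / p_label_local`.
#'   \item `switch_rate_hz`: exact label-transition probability under the
#'     mode chain (summing over mode transitions and per-mode leakage),
#'     divided by the mean per-fixation pitch (mean duration + gap) in s.
#' }
#'
#' @param config a [cohort_config()].
#' @param threshold_ms classification threshold, ms (default 187).
#' @return data frame, one row per group: `level`, `p_label_local`,
#'   `gl_ratio`, `switch_rate_hz`.
#' @export
expected_metrics <- function(config, threshold_ms = 187) {
  stopifnot(inherits(config, "cohort_config"))
  rows <- lapply(names(config$groups), function(lev) {
    p <- config$groups[[lev]]$params
    qg <- 1 - stats::plnorm(threshold_ms, log(p$dur_global[1]), p$dur_global[2])
    ql <- 1 - stats::plnorm(threshold_ms, log(p$dur_local[1]), p$dur_local[2])
    pl <- p$p_local
    p_label <- pl * ql + (1 - pl) * qg
    # mode transition matrix: stay w.p. s else redraw Bernoulli(p_local)
    s <- p$switch_persistence
    trans <- matrix(c(s + (1 - s) * (1 - pl), (1 - s) * pl,
                      (1 - s) * (1 - pl), s + (1 - s) * pl),
                    2, 2, byrow = TRUE)  # rows/cols: global, local
    pi_ <- c(1 - pl, pl)
    q <- c(qg, ql)  # P(label local | mode)
    p_switch <- 0
    for (a in 1:2) for (b in 1:2) {
      p_switch <- p_switch + pi_[a] * trans[a, b] *
        (q[a] * (1 - q[b]) + (1 - q[a]) * q[b])
    }
    mean_dur <- pl * p$dur_local[1] * exp(p$dur_local[2]^2 / 2) +
      (1 - pl) * p$dur_global[1] * exp(p$dur_global[2]^2 / 2)
    nbar <- p$n_fix
    # expected switches over expected inspection time (span convention)
    hz <- (nbar - 1) * p_switch /
      ((nbar * mean_dur + (nbar - 1) * config$gap_ms) / 1000)
    data.frame(level = lev, p_label_local = p_label,
               gl_ratio = (1 - p_label) / p_label,
               switch_rate_hz = hz, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
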