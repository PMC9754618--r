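#' @title Expertise classification and divergence grouping
#' @description Participants are assigned one of four expertise levels from
#'   their years of experience in sculpting, and every unordered pair of
#'   participants is assigned a divergence group: the absolute difference of
#'   the two levels (0..3). Pairwise scanpath distances are later summarised
#'   by these divergence groups.
#' @name expertise
NULL

#' Expertise level labels, in increasing order (codes 0..3)
#' @export
EXPERTISE_LEVELS <- c("layperson", "novice", "semi_expert", "expert")

#' Classify years of experience into an expertise level
#'
#' Thresholds: 0 years = layperson; more than 0 but fewer than `novice_max`
#' years = novice; from `novice_max` up to and including `semi_expert_max`
#' years = semi-expert; more than `semi_expert_max` years = expert. The
#' defaults (5 and 10 years) follow the convention that professional experts
#' have more than 10 years of practice. The boundary values 5 and 10 are
#' assigned to semi-expert; both cut points are configurable.
#'
#' @param years_experience numeric vector, >= 0.
#' @param novice_max upper bound (exclusive) for novices, years.
#' @param semi_expert_max upper bound (inclusive) for semi-experts, years.
#' @return ordered factor with levels [EXPERTISE_LEVELS].
#' @export
#' @examples
#' classify_expertise(c(0, 2, 7, 14))
classify_expertise <- function(years_experience, novice_max = 5,
                               semi_expert_max = 10) {
  y <- as.numeric(years_experience)
  if (any(!is.finite(y) | y < 0)) {
    stop_validation("years_experience must be finite and >= 0")
  }
  code <- ifelse(y == 0, 0L,
          ifelse(y < novice_max, 1L,
          ifelse(y <= semi_expert_max, 2L, 3L)))
  factor(EXPERTISE_LEVELS[code + 1L], levels = EXPERTISE_LEVELS, ordered = TRUE)
}

#' Numeric code (0..3) of an expertise level
#' @param level factor or character of levels in [EXPERTISE_LEVELS].
#' @return integer vector 0..3.
#' @export
expertise_code <- function(level) {
  match(as.character(level), EXPERTISE_LEVELS) - 1L
}

#' Build expertise profiles from participant metadata
#'
#' @param meta data frame with `participant_id` and `years_experience`.
#' @inheritParams classify_expertise
#' @return data frame with `participant_id`, `years_experience`, `level`
#'   (ordered factor) and `code` (0..3).
#' @export
expertise_profiles <- function(meta, novice_max = 5, semi_expert_max = 10) {
  stopifnot(all(c("participant_id", "years_experience") %in% names(meta)))
  level <- classify_expertise(meta$years_experience, novice_max, semi_expert_max)
  data.frame(participant_id = as.character(meta$participant_id),
             years_experience = as.numeric(meta$years_experience),
             level = level, code = expertise_code(level),
             stringsAsFactors = FALSE)
}

#' Mean years of experience per expertise level
#'
#' Metadata summary reported alongside the classification.
#'
#' @param profiles output of [expertise_profiles()].
#' @return data frame with `level`, `n`, `mean_years`.
#' @export
experience_summary <- function(profiles) {
  agg <- stats::aggregate(years_experience ~ level, data = profiles,
                          FUN = mean, drop = FALSE)
  n <- as.integer(table(profiles$level))
  data.frame(level = factor(EXPERTISE_LEVELS, levels = EXPERTISE_LEVELS,
                            ordered = TRUE),
             n = n, mean_years = agg$years_experience[match(EXPERTISE_LEVELS,
                                                            as.character(agg$level))])
}

#' Partition participant pairs by expertise divergence
#'
#' Every unordered pair of distinct participants is assigned to exactly one
#' divergence group, `|code_i - code_j|` in 0..3. With four groups of g
#' participants each this yields 4*g*(g-1)/2 pairs at divergence 0 and
#' (4-d)*g^2 pairs at divergence d in 1..3 (e.g. 40/75/50/25 for g = 5).
#'
#' @param profiles output of [expertise_profiles()]; >= 2 rows.
#' @return object of class `divergence_groups`: list with `pairs` (data frame
#'   `id_a`, `id_b`, `level_a`, `level_b`, `divergence`) and `counts`
#'   (data frame `divergence`, `n_pairs`).
#' @export
divergence_groups <- function(profiles) {
  if (nrow(profiles) < 2) {
    stop_validation("need >= 2 participant profiles to form pairs")
  }
  idx <- utils::combn(nrow(profiles), 2)
  pairs <- data.frame(
    id_a = profiles$participant_id[idx[1, ]],
    id_b = profiles$participant_id[idx[2, ]],
    level_a = as.character(profiles$level[idx[1, ]]),
    level_b = as.character(profiles$level[idx[2, ]]),
    divergence = abs(profiles$code[idx[1, ]] - profiles$code[idx[2, ]]),
    stringsAsFactors = FALSE)
  counts <- data.frame(divergence = 0:3,
                       n_pairs = vapply(0:3, function(d)
                         sum(pairs$divergence == d), integer(1)))
  out <- list(pairs = pairs, counts = counts)
  class(out) <- "divergence_groups"
  out
}

#' @export
print.divergence_groups <- function(x, ...) {
  cat(sprintf("<divergence_groups> %d pairs\n", nrow(x$pairs)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
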