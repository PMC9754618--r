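# Shared fixture builders. All fixtures are constructed in code; independent
# oracles used across the suite live here too, written deliberately as
# different algorithms from the package implementations they check.

fixation_df <- function(participant = "p1", sculpture = "moses",
                        ref_image = 1, x = 0, y = 0, duration = 200,
                        gap = 30) {
  n <- max(length(ref_image), length(x), length(y), length(duration))
  ref_image <- rep_len(ref_image, n)
  x <- rep_len(x, n); y <- rep_len(y, n)
  duration <- rep_len(duration, n)
  onset <- cumsum(c(0, duration[-n] + gap))
  data.frame(participant_id = participant, sculpture_id = sculpture,
             ref_image = ref_image, x = x, y = y, onset_ms = onset,
             duration_ms = duration, stringsAsFactors = FALSE)
}

make_scanpath <- function(...) {
  scanpaths(as_fixation_table(fixation_df(...)))[[1]]
}

square_aoi <- function(feature_id, ref_image, x0, y0, side = 10) {
  list(feature_id = feature_id, ref_image = ref_image,
       vertices = rbind(c(x0, y0), c(x0 + side, y0),
                        c(x0 + side, y0 + side), c(x0, y0 + side)))
}

# four levels x g participants with deterministic years inside each band
make_profiles <- function(g = 5) {
  years <- c(rep(0, g), seq(1, 4, length.out = g), seq(5, 10, length.out = g),
             seq(11, 29, length.out = g))
  expertise_profiles(data.frame(
    participant_id = sprintf("p%02d", seq_len(4 * g)),
    years_experience = years))
}

# O(n*m) double-loop nearest-neighbour oracle for the double-mapping distance
brute_double_map <- function(S, T) {
  nn <- function(A, B) {
    s <- 0
    for (i in seq_len(nrow(A))) {
      best <- Inf
      for (j in seq_len(nrow(B))) {
        d <- sqrt(sum((A[i, ] - B[j, ])^2))
        if (d < best) best <- d
      }
      s <- s + best
    }
    s
  }
  (nn(S, T) + nn(T, S)) / max(nrow(S), nrow(T))
}

# independent even-odd ray-casting oracle (horizontal ray to +Inf), with the
# same boundary-inclusive convention as the implementation contract
oracle_point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  nxt <- c(2:n, 1)
  for (k in seq_len(n)) {  # boundary check via distance to segment
    a <- v[k, ]; b <- v[nxt[k], ]
    ab <- b - a
    t <- if (sum(ab^2) == 0) 0 else
      max(0, min(1, sum((c(px, py) - a) * ab) / sum(ab^2)))
    if (sqrt(sum((a + t * ab - c(px, py))^2)) < 1e-9) return(TRUE)
  }
  crossings <- 0
  for (k in seq_len(n)) {
    a <- v[k, ]; b <- v[nxt[k], ]
    if ((a[2] <= py && b[2] > py) || (b[2] <= py && a[2] > py)) {
      xint <- a[1] + (py - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
      if (xint > px) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# run-length oracle for revisits: per feature, number of maximal runs - 1
oracle_revisits <- function(hits) {
  feats <- unique(hits[!is.na(hits)])
  total <- 0L
  for (f in feats) {
    r <- rle(!is.na(hits) & hits == f)
    total <- total + max(0L, sum(r$values) - 1L)
  }
  total
}
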