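rand_points <- function(n, zscale = 100) {
  cbind(runif(n, 0, 800), runif(n, 0, 1200), runif(n, 0, zscale))
}

test_that("point distance is plain 3-D Euclidean distance", {
  expect_equal(point_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(point_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(point_distance(c(1, 2, 2), c(0, 0, 0)), 3)
})

test_that("double mapping matches hand-computed cases", {
  expect_equal(double_map_distance(matrix(c(0, 0, 0), 1),
                                   matrix(c(3, 4, 0), 1)), 10)
  S <- rand_points(7)
  expect_equal(double_map_distance(S, S), 0)
  expect_error(double_map_distance(S[0, ], S), "non-empty")
})

test_that("double mapping agrees with the brute-force oracle", {
  set.seed(5)
  for (rep in 1:10) {
    S <- rand_points(sample(1:50, 1))
    T <- rand_points(sample(1:50, 1))
    expect_equal(double_map_distance(S, T), brute_double_map(S, T),
                 tolerance = 1e-9)
    expect_equal(double_map_distance(S, T), double_map_distance(T, S))
  }
})

test_that("small rigid translations shift the distance by exactly 2*delta", {
  set.seed(8)
  # well-separated points: spacing >> delta so neighbours stay index-matched
  S <- cbind(seq(0, 900, by = 100), seq(0, 1800, by = 200), 0)
  delta <- 3
  T <- S; T[, 1] <- T[, 1] + delta
  expect_equal(double_map_distance(S, T), 2 * delta)
})

test_that("conversion factor scales the longest fixation to the height", {
  ft <- as_fixation_table(fixation_df(duration = c(100, 500, 250)))
  cf <- conversion_factor(ft, "moses", height_px = 1000)
  expect_equal(cf$value, 2)
  expect_equal(cf$source, "computed")
  cf1 <- conversion_factor(ft, "moses", height_px = 500)
  expect_equal(cf1$value, 1)
  # doubling all durations halves the factor: scaled z of the longest
  # fixation is unchanged
  ft2 <- as_fixation_table(within(fixation_df(duration = c(200, 1000, 500)),
                                  onset_ms <- onset_ms * 2))
  cf2 <- conversion_factor(ft2, "moses", height_px = 1000)
  expect_equal(cf2$value, cf$value / 2)
  expect_equal(max(ft2$duration_ms) * cf2$value, max(ft$duration_ms) * cf$value)
  # configured override
  cfg <- conversion_factor(ft, "moses", value = 1.097)
  expect_equal(cfg$source, "configured")
  expect_error(conversion_factor(ft, "nope", height_px = 10), "no fixations")
})

test_that("scanpath distance averages per-image distances and skips unshared images", {
  # identical single fixations on images 1-2; A alone on image 3
  A <- make_scanpath("a", ref_image = c(1, 2, 3), x = c(10, 20, 30),
                     y = 5, duration = 100)
  B <- make_scanpath("b", ref_image = c(1, 2), x = c(10, 20), y = 5,
                     duration = 100)
  d <- scanpath_distance(A, B, 1)
  expect_equal(as.numeric(d), 0)
  expect_equal(attr(d, "n_images_used"), 2)
  expect_equal(attr(d, "n_images_skipped"), 1)

  # two single-fixation scanpaths separated by (3, 4, 0) on one image
  A <- make_scanpath("a", ref_image = 1, x = 0, y = 0, duration = 100)
  B <- make_scanpath("b", ref_image = 1, x = 3, y = 4, duration = 100)
  expect_equal(as.numeric(scanpath_distance(A, B, 1)), 10)

  # no shared image: undefined with warning
  C <- make_scanpath("c", ref_image = 5, x = 0, y = 0, duration = 100)
  expect_warning(d <- scanpath_distance(A, C, 1), "no shared reference image")
  expect_true(is.na(d))

  # self-distance is zero on every image
  sp <- make_scanpath("a", ref_image = c(1, 1, 4, 7), x = rnorm(4, 100),
                      y = rnorm(4, 100), duration = c(100, 300, 80, 200))
  expect_equal(as.numeric(scanpath_distance(sp, sp, 0.5)), 0)

  expect_error(scanpath_distance(A, make_scanpath("d", sculpture = "daphne"), 1),
               "different sculptures")
})

test_that("durations and conversion factor trade off exactly", {
  set.seed(13)
  mk <- function(scale) {
    df <- rbind(fixation_df("a", ref_image = sample(1:4, 20, TRUE),
                            x = runif(20, 0, 800), y = runif(20, 0, 1200),
                            duration = runif(20, 50, 400) * scale),
                fixation_df("b", ref_image = sample(1:4, 25, TRUE),
                            x = runif(25, 0, 800), y = runif(25, 0, 1200),
                            duration = runif(25, 50, 400) * scale))
    as_fixation_table(df)
  }
  set.seed(13); ft1 <- mk(1)
  set.seed(13); ft3 <- mk(3)
  f1 <- conversion_factor(ft1, "moses", height_px = 900)
  f3 <- conversion_factor(ft3, "moses", height_px = 900)
  sp1 <- scanpaths(ft1); sp3 <- scanpaths(ft3)
  expect_equal(as.numeric(scanpath_distance(sp1[[1]], sp1[[2]], f1)),
               as.numeric(scanpath_distance(sp3[[1]], sp3[[2]], f3)))
})

test_that("pairwise matrices are symmetric, zero-diagonal and match direct calls", {
  set.seed(17)
  n <- 4
  dfs <- lapply(1:n, function(i)
    fixation_df(sprintf("p%02d", i), ref_image = sample(1:8, 30, TRUE),
                x = runif(30, 0, 800), y = runif(30, 0, 1200),
                duration = runif(30, 50, 500)))
  ft <- as_fixation_table(do.call(rbind, dfs))
  prof <- expertise_profiles(data.frame(
    participant_id = sprintf("p%02d", 1:n),
    years_experience = c(0, 0, 7, 20)))
  fac <- conversion_factor(ft, "moses", height_px = 900)
  dm <- pairwise_distances(ft, prof, "moses", fac)
  expect_equal(dm$distances, t(dm$distances))
  expect_equal(diag(dm$distances), setNames(rep(0, n), dm$participants))
  expect_true(all(dm$distances >= 0))
  sps <- scanpaths(ft)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    expect_equal(dm$distances[i, j],
                 as.numeric(scanpath_distance(sps[[i]], sps[[j]], fac)))
  }
  expect_equal(dm$divergence["p01", "p02"], 0L)
  expect_equal(dm$divergence["p01", "p04"], 3L)
  # identical participants give a zero cell
  ft2 <- as_fixation_table(do.call(rbind, c(dfs[1],
    list(within(dfs[[1]], participant_id <- "p99")))))
  prof2 <- expertise_profiles(data.frame(participant_id = c("p01", "p99"),
                                         years_experience = 0))
  dm2 <- pairwise_distances(ft2, prof2, "moses", 1)
  expect_equal(dm2$distances["p01", "p99"], 0)
})

test_that("divergence summary pools off-diagonal cells by divergence", {
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  # codes 0,0,1,3 -> divergences: ab=0 ac=1 ad=3 bc=1 bd=3 cd=2
  vals <- c(ab = 10, ac = 20, ad = 30, bc = 40, bd = 50, cd = 60)
  D["a", "b"] <- D["b", "a"] <- vals["ab"]
  D["a", "c"] <- D["c", "a"] <- vals["ac"]
  D["a", "d"] <- D["d", "a"] <- vals["ad"]
  D["b", "c"] <- D["c", "b"] <- vals["bc"]
  D["b", "d"] <- D["d", "b"] <- vals["bd"]
  D["c", "d"] <- D["d", "c"] <- vals["cd"]
  codes <- c(0, 0, 1, 3)
  div <- abs(outer(codes, codes, "-")); diag(div) <- NA
  dimnames(div) <- dimnames(D)
  dm <- structure(list(sculpture_id = "m", participants = letters[1:4],
                       distances = D, divergence = div, n_missing = 0L,
                       n_images_skipped = 0L), class = "distance_matrix")
  s <- divergence_summary(dm)
  expect_equal(s$divergence, c(0, 1, 2, 3))
  expect_equal(s$n, c(1L, 2L, 1L, 2L))
  expect_equal(s$mean, c(10, 30, 60, 40))
  expect_true(all(s$degenerate == (s$n == 1)))
  expect_equal(s$sd[s$divergence == 3], sd(c(30, 50)))
})

test_that("pooled divergence means equal pair-count weighted cell means", {
  cells <- data.frame(
    level_a = c("layperson", "novice", "semi_expert", "expert",
                "layperson", "novice", "semi_expert",
                "layperson", "novice", "layperson"),
    level_b = c("layperson", "novice", "semi_expert", "expert",
                "novice", "semi_expert", "expert",
                "semi_expert", "expert", "expert"),
    mean = c(1372, 6410, 8483, 4961, 8479, 6632, 6365, 9434, 5246, 7660),
    n = c(10, 10, 10, 10, 25, 25, 25, 25, 25, 25))
  pooled <- pool_divergence_means(cells)
  expect_equal(pooled$n, c(40, 75, 50, 25))
  expect_equal(pooled$mean[pooled$divergence == 0],
               mean(c(1372, 6410, 8483, 4961)))
  expect_equal(pooled$mean[pooled$divergence == 2], mean(c(9434, 5246)))
  # unequal weights: weighted, not plain, mean
  cells2 <- data.frame(level_a = c("layperson", "novice"),
                       level_b = c("novice", "semi_expert"),
                       mean = c(100, 200), n = c(10, 30))
  expect_equal(pool_divergence_means(cells2)$mean, 175)
})

test_that("level pair means recover the per-cell structure of the matrix", {
  set.seed(23)
  prof <- make_profiles(2)
  dfs <- lapply(prof$participant_id, function(p)
    fixation_df(p, ref_image = sample(1:8, 20, TRUE), x = runif(20, 0, 800),
                y = runif(20, 0, 1200), duration = runif(20, 50, 400)))
  ft <- as_fixation_table(do.call(rbind, dfs))
  dm <- pairwise_distances(ft, prof, "moses",
                           conversion_factor(ft, "moses", height_px = 900))
  cells <- level_pair_means(dm, prof)
  expect_equal(sum(cells$n), choose(8, 2))
  # pooling the cells reproduces divergence_summary means
  pooled <- pool_divergence_means(cells)
  ds <- divergence_summary(dm)
  expect_equal(pooled$mean, ds$mean)
  expect_equal(pooled$n, ds$n)
})
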