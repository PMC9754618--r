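concave_poly <- rbind(c(0, 0), c(10, 0), c(10, 10), c(5, 4), c(0, 10))
star_poly <- local({
  th <- seq(0, 2 * pi, length.out = 11)[-11]
  r <- rep(c(10, 4), 5)
  cbind(50 + r * cos(th), 50 + r * sin(th))
})

test_that("point-in-polygon is boundary inclusive and handles concavity", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_true(point_in_polygon(5, 5, sq))
  expect_true(point_in_polygon(0, 0, sq))    # vertex
  expect_true(point_in_polygon(5, 0, sq))    # edge
  expect_false(point_in_polygon(10.01, 5, sq))
  expect_true(point_in_polygon(5, 1, concave_poly))
  expect_false(point_in_polygon(5, 6, concave_poly))  # inside the notch
})

test_that("point-in-polygon agrees with the even-odd oracle on random points", {
  set.seed(31)
  polys <- list(rbind(c(2, 3), c(60, 8), c(80, 70), c(30, 90)),
                concave_poly * 8, star_poly)
  for (v in polys) {
    px <- runif(1000, min(v[, 1]) - 5, max(v[, 1]) + 5)
    py <- runif(1000, min(v[, 2]) - 5, max(v[, 2]) + 5)
    got <- mapply(point_in_polygon, px, py, MoreArgs = list(vertices = v))
    want <- mapply(oracle_point_in_polygon, px, py, MoreArgs = list(v = v))
    expect_equal(got, want)
  }
})

test_that("point-in-polygon agrees with mgcv::in.out on interior points", {
  skip_if_not_installed("mgcv")
  set.seed(37)
  v <- concave_poly * 10
  bnd <- rbind(v, v[1, ])
  px <- runif(400, -10, 110); py <- runif(400, -10, 110)
  got <- mapply(point_in_polygon, px, py, MoreArgs = list(vertices = v))
  want <- as.logical(mgcv::in.out(bnd, cbind(px, py)))
  # boundary convention may differ; random points are almost surely interior
  expect_equal(got, want)
})

test_that("hit testing maps fixations to features with tie-breaking", {
  regions <- list(square_aoi("head", 1, 0, 0, side = 10),
                  square_aoi("alpha", 1, 2, 2, side = 4),   # nested, smaller
                  square_aoi("beta", 1, 2, 2, side = 4),    # identical twin
                  square_aoi("head", 2, 50, 50, side = 10))
  aois <- aoi_set("moses", regions)
  sp <- make_scanpath(ref_image = c(1, 1, 1, 2, 2),
                      x = c(5, 3, 30, 55, 3), y = c(9, 3, 30, 55, 3),
                      duration = 100)
  hits <- hit_test(sp, aois)
  expect_equal(hits[1], "head")        # only the big square contains (5,9)
  expect_equal(hits[2], "alpha")       # smallest area, then lexicographic
  expect_true(is.na(hits[3]))          # outside everything
  expect_equal(hits[4], "head")        # same feature on another image
  expect_true(is.na(hits[5]))          # (3,3) has no polygon on image 2
  # vertex hit is inclusive
  sp_v <- make_scanpath(ref_image = 1, x = 0, y = 0, duration = 100)
  expect_equal(hit_test(sp_v, aois), "head")
  # fixations on an image with no polygons at all
  sp_8 <- make_scanpath(ref_image = 8, x = 5, y = 5, duration = 100)
  expect_true(is.na(hit_test(sp_8, aois)))
})

test_that("feature counts and percentages follow the hit sequence", {
  expect_equal(n_features_fixated(c("head", NA, "head")), 1)
  expect_equal(n_features_fixated(c("head", "hands", "head")), 2)
  expect_equal(n_features_fixated(rep(NA_character_, 4)), 0)
  expect_equal(pct_on_features(c("a", NA, NA, "b", NA, NA, NA, NA, NA, "a")), 30)
  expect_equal(pct_on_features(c("a", "b")), 100)
  expect_equal(pct_on_features(rep(NA_character_, 5)), 0)
  expect_warning(p <- pct_on_features(character(0)), "empty")
  expect_true(is.na(p))
})

test_that("revisits follow the leave-and-return definition", {
  expect_equal(count_revisits(c("A", NA, "A")), 1)
  expect_equal(count_revisits(c("A", "A", "A")), 0)     # dwelling, no revisit
  expect_equal(count_revisits(c("A", "B", "A", "B")), 2)  # B counts as leaving A
  expect_equal(count_revisits(character(0)), 0)
  expect_equal(count_revisits(rep(NA_character_, 3)), 0)
  expect_equal(revisits_per_minute(c("A", NA, "A"), 30000), 2)
})

test_that("revisit counts match the run-length oracle on all short sequences", {
  alphabet <- c("A", "B", NA)
  for (len in 1:6) {
    grids <- do.call(expand.grid, c(rep(list(alphabet), len),
                                    stringsAsFactors = FALSE))
    for (r in seq_len(nrow(grids))) {
      hits <- as.character(unlist(grids[r, ]))
      expect_equal(count_revisits(hits), oracle_revisits(hits))
    }
  }
})

test_that("revisits are order-sensitive and bounded by visits minus one", {
  set.seed(41)
  for (rep in 1:20) {
    hits <- sample(c("A", "B", "C", NA), 30, replace = TRUE)
    rv <- count_revisits(hits)
    # bound: per feature, revisits <= visits - 1
    bound <- sum(vapply(unique(na.omit(hits)), function(f) {
      runs <- rle(!is.na(hits) & hits == f)
      max(0L, sum(runs$values) - 1L)
    }, integer(1)))
    expect_lte(rv, bound)
    # sorting by feature removes all re-entries
    expect_equal(count_revisits(sort(hits, na.last = TRUE)), 0)
    # percentage is order-invariant
    expect_equal(pct_on_features(sample(hits)), pct_on_features(hits))
  }
})

test_that("per-participant AOI metrics combine hits and inspection time", {
  aois <- aoi_set("moses", list(square_aoi("head", 1, 0, 0, side = 10)))
  df <- fixation_df("a", ref_image = 1, x = c(5, 50, 5, 50), y = 5,
                    duration = 100, gap = 0)  # inspection 400 ms
  m <- aoi_metrics(as_fixation_table(df), list(moses = aois))
  expect_equal(m$n_features_fixated, 1)
  expect_equal(m$pct_on_features, 50)
  expect_equal(m$n_revisits, 1)
  expect_equal(m$revisits_per_min, 1 / (400 / 60000))
  expect_error(aoi_metrics(as_fixation_table(df), list(daphne = aois)),
               "no AOI set")
})
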