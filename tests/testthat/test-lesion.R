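# standard fixture: a few well-separated lesions of one kind
fixture_lesions <- function(kind, n = 3) {
  data.frame(row = c(30, 70, 100, 45, 90)[seq_len(n)],
             col = c(40, 90, 30, 100, 60)[seq_len(n)],
             radius = c(6, 5, 7, 4, 5)[seq_len(n)],
             kind = kind, contrast = 0.3)
}

test_that("synthetic fundus rasters honor layout, determinism and truth masks", {
  bg <- synth_fundus(NULL, seed = 1)
  expect_identical(dim(bg$image), c(128L, 128L))
  expect_true(all(bg$image >= 0 & bg$image <= 1))
  expect_false(any(bg$masks$red) || any(bg$masks$bright))

  one <- synth_fundus(data.frame(row = 60, col = 60, radius = 10,
                                 kind = "red", contrast = 0.3), seed = 2)
  expect_lt(abs(sum(one$masks$red) - pi * 100) / (pi * 100), 0.05)

  a <- synth_fundus(fixture_lesions("red"), seed = 3)
  b <- synth_fundus(fixture_lesions("red"), seed = 3)
  expect_identical(a$image, b$image)

  overlap <- data.frame(row = c(60, 62), col = c(60, 62), radius = c(8, 8),
                        kind = c("red", "bright"), contrast = 0.3)
  expect_error(synth_fundus(overlap, seed = 4), class = "kcbgwo_input_error")

  outside <- data.frame(row = 2, col = 2, radius = 10, kind = "red",
                        contrast = 0.3)
  expect_error(synth_fundus(outside, seed = 5), class = "kcbgwo_input_error")
})

test_that("binarization separates a bimodal image exactly and flips with polarity", {
  img <- matrix(0.2, 40, 40)
  blob <- make_disc_mask(40, 40, 20, 20, 8)
  img[blob] <- 0.8
  expect_identical(binarize_image(img, "bright"), blob)
  expect_identical(binarize_image(img, "dark"), !blob)
  expect_error(binarize_image(matrix(0.5, 10, 10), "dark"),
               class = "kcbgwo_input_error")
})

test_that("quantile binarization recovers a 5% dark-lesion area within 20%", {
  f <- synth_fundus(data.frame(row = 64, col = 64, radius = 21, kind = "red",
                               contrast = 0.3),
                    width = 90, height = 90, seed = 6)
  truth_area <- sum(f$masks$red)  # ~5.4% of 8100 pixels
  mask <- binarize_image(f$image, "dark", "quantile",
                         q = truth_area / length(f$image))
  expect_lt(abs(sum(mask) - truth_area) / truth_area, 0.2)
})

test_that("refinement fills holes, removes specks, and is idempotent on fixtures", {
  disc <- make_disc_mask(40, 40, 20, 20, 9)
  holed <- disc; holed[20, 20] <- FALSE
  ref <- refine_mask(holed, closing_radius = 2, opening_radius = 0,
                     min_size = 1)
  expect_true(ref[20, 20])

  specks <- matrix(FALSE, 30, 30)
  specks[cbind(c(3, 10, 25), c(4, 20, 7))] <- TRUE
  expect_false(any(refine_mask(specks, 0, 0, min_size = 5)))

  for (s in 1:3) {
    f <- synth_fundus(fixture_lesions("red"), seed = s)
    m <- binarize_image(f$image, "dark")
    once <- refine_mask(m)
    twice <- refine_mask(once)
    expect_identical(once, twice)
  }
})

test_that("region features: disc complexity near 1, ellipse elongation near its axis ratio", {
  disc <- make_disc_mask(41, 41, 21, 21, 10)
  f <- region_features(disc)
  expect_identical(nrow(f), 1L)
  expect_identical(f$area, 317L)
  expect_gt(f$complexity, 0.95)
  expect_lt(f$complexity, 1.3)

  rr <- matrix(1:61, 61, 61)
  cc <- matrix(1:61, 61, 61, byrow = TRUE)
  ell <- ((rr - 31) / 24)^2 + ((cc - 31) / 8)^2 <= 1
  fe <- region_features(ell)
  expect_lt(abs(fe$elongation - 3) / 3, 0.1)
  expect_gte(fe$elongation, 1)

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  fs <- region_features(single)
  expect_identical(fs$area, 1L)
  expect_identical(fs$elongation, 1)

  expect_identical(nrow(region_features(matrix(FALSE, 5, 5))), 0L)
})

test_that("components are 8-connected and mean intensity reflects the image", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal touch: one component
  m[5, 6] <- TRUE                    # far away: second component
  f <- region_features(m)
  expect_identical(nrow(f), 2L)
  expect_identical(sort(f$area), c(1L, 2L))

  img <- matrix(0.1, 6, 6); img[m] <- 0.9
  f2 <- region_features(m, img)
  expect_equal(f2$mean_intensity, c(0.9, 0.9), tolerance = 1e-12)
})

test_that("screening accepts planted lesions and reports reasons for rejects", {
  f <- synth_fundus(fixture_lesions("red", 3), seed = 11)
  sc <- screen_lesions(f$image, "red")
  expect_identical(sum(sc$calls$accepted), 3L)
  expect_true(all(sc$calls$reason[sc$calls$accepted] == "none"))

  # with opening disabled, small specks reach the size filter and are
  # emitted as rejected calls (opening with any disc >= 3x3 would silently
  # delete them instead)
  specky <- f$image
  for (p in list(c(20, 110), c(110, 115))) {
    d <- make_disc_mask(128, 128, p[1], p[2], 1)
    specky[d] <- specky[d] - 0.3
  }
  sc2 <- screen_lesions(specky, "red", opening_radius = 0)
  small <- sc2$calls[sc2$calls$area < 8, ]
  expect_gte(nrow(small), 2)
  expect_true(all(small$reason == "too-small"))
  expect_true(all(!small$accepted))

  # constant blank image: nothing below the quantile threshold, no calls
  sc3 <- screen_lesions(matrix(0.5, 64, 64), "red",
                        method = "quantile", q = 0.05)
  expect_identical(nrow(sc3$calls), 0L)
  expect_false(any(sc3$accepted_mask))
})

test_that("bright screening mirrors red screening on bright fixtures", {
  f <- synth_fundus(fixture_lesions("bright", 3), seed = 13)
  sc <- screen_lesions(f$image, "bright")
  expect_identical(sum(sc$calls$accepted), 3L)
  expect_gte(jaccard_index(sc$accepted_mask, f$masks$bright), 0.6)
})

test_that("red and bright screening never cross-fire on disjoint planted sets", {
  mixed <- rbind(fixture_lesions("red", 2),
                 data.frame(row = c(100, 45), col = c(30, 100),
                            radius = c(7, 4), kind = "bright",
                            contrast = 0.3))
  f <- synth_fundus(mixed, seed = 14)
  sc_b <- screen_lesions(f$image, "bright")
  # no accepted bright call touches a planted dark lesion
  expect_identical(sum(sc_b$accepted_mask & f$masks$red), 0L)
  # and no accepted bright centroid falls in a red lesion
  acc_b <- sc_b$calls[sc_b$calls$accepted, ]
  for (i in seq_len(nrow(acc_b)))
    expect_false(f$masks$red[round(acc_b$centroid_row[i]),
                             round(acc_b$centroid_col[i])])
  sc_r <- screen_lesions(f$image, "red", method = "quantile", q = 0.02)
  expect_identical(sum(sc_r$accepted_mask & f$masks$bright), 0L)
})

test_that("screening call tables serialize to CSV", {
  f <- synth_fundus(fixture_lesions("red", 2), seed = 15)
  sc <- screen_lesions(f$image, "red")
  path <- withr::local_tempfile(fileext = ".csv")
  calls_to_csv(sc, path)
  back <- read.csv(path)
  expect_identical(nrow(back), nrow(sc$calls))
  expect_true(all(c("kind", "area", "accepted", "reason") %in% names(back)))
})

test_that("RGB conversion takes the green channel by default", {
  arr <- array(0, c(4, 4, 3))
  arr[, , 1] <- 0.9; arr[, , 2] <- 0.4; arr[, , 3] <- 0.1
  expect_true(all(rgb_to_intensity(arr) == 0.4))
  lum <- rgb_to_intensity(arr, "luminance")
  expect_equal(lum[1, 1], 0.299 * 0.9 + 0.587 * 0.4 + 0.114 * 0.1,
               tolerance = 1e-12)
})
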