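fake_estimate <- function(hbt, fs = 1) {
  structure(list(hbo = hbt / 2, hbr = hbt / 2, hbt = hbt, fs = fs,
                 n_vertices = nrow(hbt), n_samples = ncol(hbt)),
            class = "source_estimate")
}

test_that("scout averaging is the grand mean over vertices and samples", {
  X <- matrix(7, 50, 10)
  est <- fake_estimate(X)
  sc <- nirs_scout("A", 3:12)
  expect_equal(unname(scout_average(est, sc)["hbt"]), 7)
  ## 2 vertices x 2 samples {1,2,3,4} -> 2.5
  X2 <- matrix(0, 5, 2); X2[2, ] <- c(1, 3); X2[4, ] <- c(2, 4)
  est2 <- fake_estimate(X2)
  expect_equal(unname(scout_average(est2, nirs_scout("B", c(2, 4)))["hbt"]),
               2.5)
  ## scout of all vertices equals the global mean
  set.seed(10)
  X3 <- matrix(rnorm(200), 20, 10)
  est3 <- fake_estimate(X3)
  expect_equal(unname(scout_average(est3, nirs_scout("C", 1:20))["hbt"]),
               mean(X3))
  ## invariance to vertex ordering
  perm <- sample(10)
  expect_equal(scout_average(est3, nirs_scout("D", (1:10)[perm])),
               scout_average(est3, nirs_scout("D", 1:10)))
  expect_error(scout_average(est3, nirs_scout("E", 1:3), window = c(0, 99)),
               "window")
})

test_that("the t-interval rule reproduces hand-computed values", {
  ci <- ci_eq1(c(1, 2, 3))
  expect_equal(ci$mean, 2)
  expect_equal(ci$sem, 1 / sqrt(3), tolerance = 1e-9)
  expect_equal(ci$sem, 0.57735, tolerance = 1e-4)
  expect_equal(ci$t, 4.30265, tolerance = 1e-5)
  expect_equal(ci$ci_high, 2 + 4.30265 * 0.57735, tolerance = 1e-4)
  expect_equal(ci$ci_high, 4.4844, tolerance = 1e-3)
  ## constant sample: degenerate interval at the mean
  c2 <- ci_eq1(rep(5, 10))
  expect_equal(c2$sem, 0)
  expect_equal(c2$ci_low, 5); expect_equal(c2$ci_high, 5)
  expect_error(ci_eq1(3), "n >= 2")
  ## literal one-sided form: upper bound only
  c3 <- ci_eq1(c(1, 2, 3), two_sided = FALSE)
  expect_true(is.na(c3$ci_low))
  expect_equal(c3$ci_high, ci$ci_high)
})

test_that("interval width shrinks as 1/sqrt(n)", {
  set.seed(11)
  width <- function(n) {
    mean(replicate(300, { ci <- ci_eq1(rnorm(n)); ci$ci_high - ci$ci_low }))
  }
  w <- vapply(c(10, 40, 160), width, 0)
  expect_equal(w[1] / w[2], 2, tolerance = 0.15)
  expect_equal(w[2] / w[3], 2, tolerance = 0.15)
})

test_that("per-concert ROI statistics keep the interval ordering", {
  set.seed(12)
  pv <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("hbo", "hbr", "hbt")))
  st <- roi_stats(pv, "PRG", 3, performer = "first")
  expect_equal(nrow(st), 3)
  expect_true(all(st$ci_low <= st$mean & st$mean <= st$ci_high))
  expect_true(all(st$sem >= 0))
  expect_equal(unique(st$n), 5)
})

test_that("trend tables mark lost concerts as explicit gaps, never values", {
  set.seed(13)
  stats <- do.call(rbind, lapply(c(1, 2, 3, 5, 7), function(ci)
    roi_stats(matrix(rnorm(15), 5, 3,
                     dimnames = list(NULL, c("hbo", "hbr", "hbt"))),
              "rIFG", ci, performer = "second")))
  tt <- trend_table(stats, concerts = 1:7)
  hbt <- tt[tt$chromophore == "HbT", ]
  expect_equal(nrow(hbt), 7)
  expect_equal(hbt$concert_index, 1:7)       # strictly increasing
  expect_equal(sum(hbt$gap), 2)
  expect_equal(hbt$concert_index[hbt$gap], c(4, 6))
  expect_true(all(is.na(hbt$mean[hbt$gap])))   # no interpolation
  expect_true(all(!is.na(hbt$mean[!hbt$gap])))
  ## single concert: single-row table per chromophore
  t1 <- trend_table(stats[stats$concert_index == 1, ], concerts = 1)
  expect_equal(nrow(t1[t1$chromophore == "HbT", ]), 1)
})

test_that("a linearly decreasing series yields a negative fitted slope", {
  stats <- do.call(rbind, lapply(1:7, function(ci)
    roi_stats(cbind(hbo = rnorm(5, 0), hbr = rnorm(5, 0),
                    hbt = rnorm(5, 1 - 0.12 * ci, 0.01)),
              "rIFG", ci)))
  tt <- trend_table(stats)
  expect_lt(trend_slope(tt, "rIFG", "HbT")$slope, 0)
})

test_that("trend tables export to TSV and JSON", {
  stats <- roi_stats(matrix(1:6, 2, 3,
                            dimnames = list(NULL, c("hbo", "hbr", "hbt"))),
                     "STG", 1)
  tt <- trend_table(stats, concerts = 1:2)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_trend_table(tt, tsv); write_trend_table(tt, js)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(tt))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(nrow(parsed), nrow(tt))
  unlink(c(tsv, js))
})
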