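## Construct a piece_channel_means object directly.
pcm <- function(values, ssc, pieces = paste0("p", seq_len(nrow(values)))) {
  rownames(values) <- pieces
  structure(values, ssc = ssc, chromophore = "hbt", units = "Molar mm",
            class = c("piece_channel_means", "matrix"))
}

test_that("SSC subtraction removes the pooled short-channel mean and clamps", {
  v <- matrix(c(5.0, 2.0, 3.0, 2.0, 4.0), 1,
              dimnames = list(NULL, c("L1", "L2", "L3", "S1", "S2")))
  rep_ <- ssc_subtract(pcm(v, c("S1", "S2")))
  expect_equal(rep_$ssc_mean, rep(3.0, 3))
  expect_equal(rep_$corrected[rep_$pair == "L1"], 2.0)       # 5 - 3
  expect_equal(rep_$corrected[rep_$pair == "L2"], 0.0)       # clamped
  expect_identical(rep_$corrected[rep_$pair == "L2"], 0.0)   # exactly zero
  expect_true(rep_$zeroed[rep_$pair == "L2"])
  expect_equal(rep_$corrected[rep_$pair == "L3"], 0.0)       # 3 - 3
  expect_false(rep_$zeroed[rep_$pair == "L3"])               # not negative
  ## short pairs excluded from output
  expect_false(any(rep_$pair %in% c("S1", "S2")))
})

test_that("long channels equal to the SSC mean correct to all zeros", {
  v <- matrix(c(3, 3, 3, 2, 4), 1,
              dimnames = list(NULL, c("L1", "L2", "L3", "S1", "S2")))
  rep_ <- ssc_subtract(pcm(v, c("S1", "S2")))
  expect_equal(rep_$corrected, rep(0, 3))
})

test_that("subtraction is invariant to adding a constant to every channel", {
  set.seed(5)
  v <- matrix(runif(10, 1, 2), 2, 5,
              dimnames = list(NULL, c("L1", "L2", "L3", "S1", "S2")))
  r1 <- ssc_subtract(pcm(v, c("S1", "S2")))
  r2 <- ssc_subtract(pcm(v + 7, c("S1", "S2")))
  expect_equal(r2$corrected, r1$corrected, tolerance = 1e-12)
})

test_that("corrected output is nonnegative and bounded by the input", {
  set.seed(6)
  v <- matrix(rnorm(40), 4, 10,
              dimnames = list(NULL, c(paste0("L", 1:8), "S1", "S2")))
  v[, c("S1", "S2")] <- abs(v[, c("S1", "S2")])   # nonnegative SSC mean
  rep_ <- ssc_subtract(pcm(v, c("S1", "S2")))
  expect_true(all(rep_$corrected >= 0))
  expect_true(all(rep_$corrected <= pmax(rep_$raw_mean, 0) + 1e-12))
})

test_that("dominance ratio and zeroed fraction match arithmetic", {
  ## long channels exactly twice the SSC level
  v <- matrix(c(2, 2, 2, 1, 1), 1,
              dimnames = list(NULL, c("L1", "L2", "L3", "S1", "S2")))
  d <- ssc_dominance(pcm(v, c("S1", "S2")))
  expect_equal(d$ratio[d$piece == "overall"], 0.5)
  expect_equal(d$zeroed_fraction[d$piece == "overall"], 0)
  ## SSC >= all long channels: everything zeroed
  v2 <- matrix(c(1, 2, 3, 5, 5), 1,
               dimnames = list(NULL, c("L1", "L2", "L3", "S1", "S2")))
  d2 <- ssc_dominance(pcm(v2, c("S1", "S2")))
  expect_equal(d2$zeroed_fraction[d2$piece == "overall"], 1.0)
  ## zero SSC: correction is the identity, ratio 0
  v3 <- matrix(c(1, 2, 3, 0, 0), 1,
               dimnames = list(NULL, c("L1", "L2", "L3", "S1", "S2")))
  r3 <- ssc_subtract(pcm(v3, c("S1", "S2")))
  expect_equal(r3$corrected, c(1, 2, 3))
  d3 <- ssc_dominance(pcm(v3, c("S1", "S2")))
  expect_equal(d3$ratio[d3$piece == "overall"], 0)
})

test_that("a montage without short channels cannot be SSC-corrected", {
  v <- matrix(1:3, 1, dimnames = list(NULL, c("L1", "L2", "L3")))
  expect_error(ssc_subtract(pcm(v, character(0))), "short")
})

test_that("shared superficial signal at unit coupling is removed from piece means", {
  ## long = cortical + 1.0 x superficial, SSC = superficial: compare the
  ## corrected means against a superficial-free run of the same seed
  gt_sup <- quiet_truth(superficial_amp = c(mayer = 5e-7, resp = 3e-7,
                                            cardiac = 2e-7))
  gt_ref <- quiet_truth()
  sess_sup <- short_session(seed = 21, truth = gt_sup, tag = "sup")
  sess_ref <- short_session(seed = 21, truth = gt_ref, tag = "nosup")
  get_means <- function(sess) {
    od <- bandpass(intensity_to_od(sess$recordings$second))
    conc <- od_to_conc(od, mbll_params(test_montage()))
    piece_channel_means(conc, pieces_from_events(
      sess$recordings$second$events))
  }
  m_sup <- get_means(sess_sup); m_ref <- get_means(sess_ref)
  sup_contrib <- m_sup - m_ref             # superficial part of each mean
  corr <- ssc_subtract(m_sup)
  ## pre-clamp residual superficial contamination
  resid <- (corr$raw_mean - corr$ssc_mean) -
    m_ref[cbind(corr$piece, corr$pair)]
  long <- setdiff(colnames(m_sup), attr(m_sup, "ssc"))
  removed <- 1 - sum(abs(resid)) / sum(abs(sup_contrib[, long]))
  expect_gte(removed, 0.9)
})
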