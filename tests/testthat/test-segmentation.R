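test_that("time-to-cell conversion follows the floor rule at 75 Hz", {
  expect_equal(time_to_index(0, 75), 0L)
  expect_equal(time_to_index(20, 75), 1500L)
  expect_equal(time_to_index(12.5, 75), 937L)
  expect_error(time_to_index(-1, 75), "negative")
  ## a 20 s window at 75 Hz holds exactly 1500 samples
  expect_length(sample_window(0, 20, 75), 1500)
})

test_that("window length equals floor(b fs) - floor(a fs) for random windows", {
  set.seed(8)
  for (i in 1:50) {
    a <- runif(1, 0, 100); b <- a + runif(1, 0, 50); fs <- sample(c(10, 75), 1)
    expect_length(sample_window(a, b, fs),
                  floor(b * fs) - floor(a * fs))
  }
})

test_that("pieces are extracted from start/end label pairs", {
  ev <- data.frame(label = c("p1/start", "p1/end", "p2/start", "p2/end"),
                   onset = c(10, 190, 200, 260), duration = 0)
  p <- pieces_from_events(ev)
  expect_equal(p$id, c("p1", "p2"))
  expect_equal(p$duration, c(180, 60))
  ## shuffled event order gives the same table
  p2 <- pieces_from_events(ev[c(3, 1, 4, 2), ])
  expect_equal(as.data.frame(p2), as.data.frame(p))
  ## unmatched start is excluded with a warning and reported
  ev3 <- rbind(ev, data.frame(label = "p3/start", onset = 270, duration = 0))
  expect_warning(p3 <- pieces_from_events(ev3), "unmatched")
  expect_equal(nrow(p3), 2)
  expect_equal(attr(p3, "unmatched"), "p3")
  ## end before start is a labeling error naming the piece
  ev4 <- data.frame(label = c("x/start", "x/end"), onset = c(50, 10),
                    duration = 0)
  expect_error(pieces_from_events(ev4), "'x'")
})

test_that("whole-piece protocol uses the full piece and no baseline", {
  w <- windows_whole_piece(list(id = "p", start = 10, end = 190))
  expect_null(w$baseline)
  expect_equal(w$analysis, c(10, 190))
  expect_error(windows_whole_piece(list(id = "p", start = 10, end = 10)),
               "length")
})

test_that("onset protocol takes 5 s baseline and the first 20 s", {
  w <- windows_initial(list(id = "p", start = 100, end = 400))
  expect_equal(w$baseline, c(95, 100))
  expect_equal(w$analysis, c(100, 120))
  expect_true(is_skipped(windows_initial(list(id = "p", start = 3,
                                              end = 400))))
  expect_true(is_skipped(windows_initial(list(id = "p", start = 100,
                                              end = 115))))
})

test_that("mid protocol models 3 min and extracts 60-120 s", {
  w <- windows_mid(list(id = "p", start = 50, end = 500))
  expect_equal(w$baseline, c(30, 50))
  expect_equal(w$model_span, c(50, 230))
  expect_equal(w$analysis, c(110, 170))
  ## strict three-minute threshold: exactly 180 s is excluded
  expect_true(is_skipped(windows_mid(list(id = "p", start = 50, end = 230))))
  expect_false(is_skipped(windows_mid(list(id = "p", start = 50,
                                           end = 230.1))))
})

test_that("mid-protocol filter keeps exactly the pieces longer than 3 min", {
  durs <- c(90, 120, 150, 170, 200, 240, 300, 360, 420)
  starts <- 30 + cumsum(c(0, durs[-length(durs)] + 10))
  pieces <- data.frame(id = paste0("p", seq_along(durs)),
                       start = starts, end = starts + durs)
  wins <- protocol_windows_for(pieces, "mid")
  expect_length(wins, 5)
  expect_setequal(names(wins), pieces$id[durs > 180])
})

test_that("lengthening a piece never removes it from the mid selection", {
  set.seed(9)
  for (i in 1:20) {
    start <- runif(1, 25, 100); dur <- runif(1, 100, 400)
    before <- !is_skipped(windows_mid(list(id = "p", start = start,
                                           end = start + dur)))
    after <- !is_skipped(windows_mid(list(id = "p", start = start,
                                          end = start + dur + 50)))
    expect_true(!before || after)
  }
})

test_that("windows beyond the recording bound are skipped with a reason", {
  pieces <- data.frame(id = "p", start = 30, end = 250)
  wins <- protocol_windows_for(pieces, "mid", recording_duration_s = 200)
  expect_length(wins, 0)
  expect_match(attr(wins, "skipped")[["p"]], "beyond")
})

test_that("adjacent pieces produce non-overlapping whole-piece windows", {
  ev <- data.frame(label = c("a/start", "a/end", "b/start", "b/end"),
                   onset = c(10, 100, 100, 200), duration = 0)
  p <- pieces_from_events(ev)
  wa <- windows_whole_piece(p[1, ]); wb <- windows_whole_piece(p[2, ])
  ia <- sample_window(wa$analysis[1], wa$analysis[2], 75)
  ib <- sample_window(wb$analysis[1], wb$analysis[2], 75)
  expect_length(intersect(ia, ib), 0)
})
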