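panel_from <- function(m) {
  structure(m, start_date = as.Date("2018-01-01"),
            dimnames = list(NULL, c("Mon", "Tue", "Wed", "Thu", "Fri",
                                    "Sat", "Sun")),
            class = c("weekday_panel", class(m)))
}

test_that("detector flags exactly the cells beyond 2 weekday SDs", {
  # constant panel: zero SD, nothing exceeds, empty result
  const <- panel_from(matrix(100, nrow = 5, ncol = 7))
  expect_equal(nrow(detect_singularities(const)), 0L)

  # arithmetic oracle: nine 100s and one 300 in the Monday column
  # mean 120, sample SD sqrt(36000/9) = 63.246, threshold 126.49
  m <- matrix(100, nrow = 10, ncol = 7)
  m[4, 1] <- 300
  hits <- detect_singularities(panel_from(m))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$week, 4L)
  expect_equal(hits$day, 1L)
  expect_equal(hits$value, 300)

  expect_error(detect_singularities(panel_from(matrix(1, 2, 7))),
               "at least 3 weeks")
})

test_that("detector recovers injected outliers exactly on a noiseless base", {
  s <- simulate_counts(noiseless_config(12, base_level = 1000,
                                        profile = c(1.3, 1.2, 1.1, 1.0,
                                                    0.9, 0.6, 0.2)),
                       seed = 1)
  inj <- inject_singularities(s, k = 5, magnitude = 3, seed = 9)
  hits <- detect_singularities(to_panel(inj$series))
  expect_equal(hits[c("week", "day")], inj$positions[c("week", "day")],
               ignore_attr = TRUE)
})

test_that("replacement averages same-weekday neighbours, handling borders", {
  m <- matrix(100, nrow = 8, ncol = 7)
  m[5, 1] <- 400
  flagged <- data.frame(week = 5L, day = 1L)
  out <- replace_singularities(panel_from(m), flagged)
  expect_equal(unname(out[5, 1]), 100)            # equal neighbours
  expect_equal(dim(out), dim(m))
  expect_equal(out[-5, ], m[-5, ], ignore_attr = TRUE)

  m2 <- matrix(100, nrow = 8, ncol = 7)
  m2[4, 2] <- 90; m2[6, 2] <- 110; m2[5, 2] <- 500
  out2 <- replace_singularities(panel_from(m2), data.frame(week = 5L,
                                                           day = 2L))
  expect_equal(unname(out2[5, 2]), 100)           # mean of 90 and 110

  # flagged first week: two nearest later non-flagged values
  m3 <- matrix(rep(c(10, 20, 30, 40), each = 7), nrow = 4, ncol = 7,
               byrow = TRUE)
  out3 <- replace_singularities(panel_from(m3), data.frame(week = 1L,
                                                           day = 3L))
  expect_equal(unname(out3[1, 3]), 25)            # mean of weeks 2 and 3

  # adjacent flagged weeks are skipped when hunting neighbours
  m4 <- matrix(100, nrow = 8, ncol = 7)
  m4[3, 1] <- 900; m4[4, 1] <- 900
  f4 <- data.frame(week = c(3L, 4L), day = c(1L, 1L))
  out4 <- replace_singularities(panel_from(m4), f4)
  expect_equal(unname(out4[3, 1]), 100)
  expect_equal(unname(out4[4, 1]), 100)

  # "preceding" mode averages the two prior non-flagged weeks
  m5 <- matrix(rep(c(10, 20, 30, 40, 50), each = 7), nrow = 5, ncol = 7,
               byrow = TRUE)
  out5 <- replace_singularities(panel_from(m5), data.frame(week = 4L,
                                                           day = 1L),
                                neighbours = "preceding")
  expect_equal(unname(out5[4, 1]), 25)            # mean of weeks 2 and 3
})

test_that("clean panels pass through detect-replace untouched", {
  # evenly spaced columns: max deviation 4.5 < 2 * sd (6.06), so no flags
  m <- panel_from(outer(1:10, 1:7, function(w, tau) 100 + 3 * tau + w))
  hits <- detect_singularities(m)
  expect_equal(nrow(hits), 0L)
  out <- replace_singularities(m, hits)
  expect_equal(out, m)
})

test_that("replacement never recreates a flag under the original thresholds", {
  s <- simulate_counts(noiseless_config(12, base_level = 1000,
                                        profile = c(1.3, 1.2, 1.1, 1.0,
                                                    0.9, 0.6, 0.2)),
                       seed = 2)
  inj <- inject_singularities(s, k = 5, magnitude = 3, seed = 5)
  panel <- to_panel(inj$series)
  hits <- detect_singularities(panel)
  cleaned <- replace_singularities(panel, hits)
  m0 <- colMeans(panel)
  s0 <- apply(panel, 2, sd)
  for (i in seq_len(nrow(hits))) {
    w <- hits$week[i]; tau <- hits$day[i]
    expect_lte(abs(cleaned[w, tau] - m0[tau]), 2 * s0[tau])
  }
})

test_that("preprocess_series trims, replaces and logs in one pass", {
  s <- simulate_counts(noiseless_config(10), seed = 1)
  inj <- inject_singularities(s, k = 3, magnitude = 3, seed = 7)
  pre <- preprocess_series(inj$series)
  expect_s3_class(pre$series, "daily_counts")
  expect_equal(nrow(pre$replacements), 3L)
  expect_setequal(pre$replacements$week, inj$positions$week)
  # replaced values equal the noiseless base again
  expect_equal(pre$series$count, s$count)
})
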