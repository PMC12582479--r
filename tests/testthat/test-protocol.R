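test_that("default protocol encodes the session structure", {
  p <- default_protocol()
  expect_s3_class(p, "protocol_spec")
  expect_equal(p$n_b_visits, 4L)
  expect_equal(p$condition_temperatures[["T_21-36"]], c(21, 36))
  expect_equal(p$condition_temperatures[["T_26-26"]], c(26, 26))
  mid <- p$sections$label %in% c("A", "B")
  expect_equal(sum(p$sections$duration[mid]), 147)
  expect_equal(p$sections$label[1], "prep")
  expect_equal(p$sections$label[nrow(p$sections)], "A_post")
})

test_that("protocol validation rejects malformed section sequences", {
  sec <- data.frame(label = c("A_pre", "B", "A_post"),
                    duration = c(14, 21, 14), room = c("A", "B", "A"))
  expect_error(protocol_spec(sec, list(), 0:2, 0:2), "prep")
  sec2 <- data.frame(label = c("prep", "A_pre", "A", "B", "A_post"),
                     duration = rep(10, 5), room = c("A", "A", "A", "B", "A"))
  ct <- list("T_26-26" = c(26, 26), "T_26-31" = c(26, 31),
             "T_26-36" = c(26, 36), "T_21-36" = c(21, 36))
  expect_error(protocol_spec(sec2, ct, rep(1, 5), rep(1, 5)), "alternate")
  sec3 <- data.frame(label = c("prep", "A_pre", "B", "A_post"),
                     duration = c(6, 14, -1, 14), room = c("A", "A", "B", "A"))
  expect_error(protocol_spec(sec3, ct, rep(1, 4), rep(1, 4)), "positive")
})

test_that("default grids reproduce the printed time-point counts", {
  p <- default_protocol()
  counts <- c(vas = 31L, skin = 34L, hr = 23L, hf = 23L, lfhf = 23L)
  for (m in names(counts))
    expect_equal(nrow(build_grid(p, m)$points), counts[[m]],
                 info = paste("modality", m))
  expect_equal(build_grid(p, "skin")$period, 8L)
  expect_equal(build_grid(p, "hf")$period, 6L)
  expect_error(build_grid(p, "ecg"), "arg")
})

test_that("grid midpoints increase strictly and lie inside their sections", {
  p <- default_protocol()
  starts <- cumsum(c(0, p$sections$duration[-nrow(p$sections)]))
  ends <- cumsum(p$sections$duration)
  for (m in c("vas", "skin", "hf")) {
    g <- build_grid(p, m)
    expect_true(all(diff(g$points$minutes) > 0))
    expect_equal(g$points$t, seq_len(nrow(g$points)))
    for (i in seq_len(nrow(g$points))) {
      s <- match(g$points$section[i], p$sections$label)
      # section labels repeat; locate by time instead
      s <- which(starts <= g$points$minutes[i] & g$points$minutes[i] <= ends)[1]
      expect_equal(p$sections$room[s], g$points$room[i])
    }
  }
})

test_that("grid sizes follow the counting rules for modified protocols", {
  ct <- list("T_26-26" = c(26, 26), "T_26-31" = c(26, 31),
             "T_26-36" = c(26, 36), "T_21-36" = c(21, 36))
  # no intermediate sections: 3 + 3 skin sub-ranges
  sec0 <- data.frame(label = c("prep", "A_pre", "A_post"),
                     duration = c(6, 14, 14), room = c("A", "A", "A"))
  p0 <- protocol_spec(sec0, ct, c(0, 1, 1), c(1, 1, 1))
  expect_equal(nrow(build_grid(p0, "skin")$points), 6L)
  # one intermediate B section: 3 + 4 + 3
  sec1 <- data.frame(label = c("prep", "A_pre", "B", "A_post"),
                     duration = c(6, 14, 21, 14), room = c("A", "A", "B", "A"))
  p1 <- protocol_spec(sec1, ct, c(0, 1, 3, 1), c(1, 1, 4, 1))
  expect_equal(nrow(build_grid(p1, "skin")$points), 10L)
  # generic rule: 3 per pre/post + 4 per intermediate; rest/questionnaire
  # grids count their blocks
  p <- default_protocol()
  n_mid <- sum(p$sections$label %in% c("A", "B"))
  expect_equal(nrow(build_grid(p, "skin")$points), 3L * 2L + 4L * n_mid)
  expect_equal(nrow(build_grid(p, "hr")$points), sum(p$rest_plan))
  expect_equal(nrow(build_grid(p, "vas")$points), sum(p$questionnaire_plan))
})

test_that("protocol specs round-trip through YAML", {
  p <- default_protocol()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_protocol(p, f)
  p2 <- read_protocol(f)
  expect_equal(p2$sections, p$sections)
  expect_equal(p2$rest_plan, p$rest_plan)
  expect_equal(p2$questionnaire_plan, p$questionnaire_plan)
  expect_equal(nrow(build_grid(p2, "skin")$points), 34L)
  df <- as.data.frame(build_grid(p2, "hf"))
  expect_named(df, c("modality", "t", "minutes", "section", "room"))
})
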