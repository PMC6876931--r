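test_that("row_std_profile matches the brute-force windowed sd", {
  # 7x4 toy with known values, plus random small images
  toy <- matrix(seq(0, 1, length.out = 28), 7, 4)
  expect_equal(as.numeric(row_std_profile(toy)), brute_row_sd_profile(toy),
               tolerance = 1e-12)
  set.seed(3)
  for (k in 1:4) {
    nr <- sample(5:32, 1); nc <- sample(5:32, 1)
    m <- matrix(runif(nr * nc), nr, nc)
    w <- sample(c(3L, 5L), 1)
    expect_equal(as.numeric(row_std_profile(m, w)),
                 brute_row_sd_profile(m, w), tolerance = 1e-12)
  }
})

test_that("row_std_profile handles constants, parameters, and length", {
  flat <- matrix(0.7, 20, 10)
  expect_true(all(row_std_profile(flat) == 0))
  expect_length(as.numeric(row_std_profile(flat)), 20L)
  expect_error(row_std_profile(flat, window = 4L), class = "ecg_param_error")
  expect_error(row_std_profile(flat, window = 21L), class = "ecg_param_error")
})

test_that("detect_profile_peaks applies half-max and spacing rules", {
  # half of the maximum: a profile peaking at 170 uses threshold 85
  p <- rep(1, 100)
  p[c(20, 50, 80)] <- c(170, 84, 90)
  got <- detect_profile_peaks(p)
  expect_equal(got, c(20L, 80L))  # 84 < 85 rejected

  # all-zero profile: no peaks, not an error
  expect_identical(detect_profile_peaks(rep(0, 50)), integer(0))

  # length-40 toy, two bumps closer than 5% x 40 = 2: higher one kept
  q <- rep(0.1, 40)
  q[c(10, 12, 30)] <- c(5, 6, 6)
  expect_equal(detect_profile_peaks(q), c(12L, 30L))
  expect_equal(detect_profile_peaks(q), brute_peak_suppression(q))

  # random profiles agree with the greedy suppression oracle
  set.seed(9)
  for (k in 1:10) {
    pr <- abs(stats::rnorm(60)) + 0.01 * seq_len(60)  # no exact ties
    expect_equal(detect_profile_peaks(pr), brute_peak_suppression(pr))
  }
})

test_that("every reported peak satisfies both constraints post-hoc", {
  set.seed(21)
  for (k in 1:10) {
    pr <- abs(stats::rnorm(80))
    pk <- detect_profile_peaks(pr)
    if (length(pk)) {
      expect_true(all(pr[pk] >= 0.5 * max(pr)))
      if (length(pk) > 1) expect_true(all(diff(pk) > 0.05 * 80))
    }
  }
})

test_that("left_margin finds the trace onset", {
  # dark column in an otherwise flat strip: agree with brute-force oracle,
  # and land within half a window of the dark column
  m <- matrix(1, 10, 100)
  m[, 5] <- 0
  prof <- sapply(1:10, function(c0) {
    cols <- max(1, c0 - 2):min(10, c0 + 2)
    stats::sd(as.vector(m[, cols]))
  })
  expect_equal(left_margin(m), which.max(prof))
  expect_lte(abs(left_margin(m) - 5), 2)

  # degenerate blank strip: column 1 with a warning
  expect_warning(got <- left_margin(matrix(1, 20, 100)),
                 class = "ecg_degenerate_warning")
  expect_equal(got, 1L)

  expect_error(left_margin(matrix(1, 10, 30)), class = "ecg_param_error")
})

test_that("left_margin recovers the rendered trace-onset column", {
  pg <- fixture_page()
  m <- unclass(pg$image)
  onset <- pg$truth$boxes$col_start[pg$truth$boxes$half == "left"][1]
  # the margin mask scans the first 10% of the full page's columns
  expect_lte(abs(left_margin(m) - onset), 5)
})

test_that("detect_lead_boxes recovers the rendered layout", {
  pg <- fixture_page()
  boxes <- fixture_digitization()$boxes
  truth <- pg$truth$boxes
  expect_equal(nrow(boxes), 13L)
  expect_equal(boxes$lead, truth$lead)
  expect_equal(boxes$half, truth$half)

  tol <- 0.02 * nrow(pg$image)
  # interior box boundaries sit at the band midpoints
  for (h in c("left", "right")) {
    bi <- boxes[boxes$half == h, ]
    ti <- truth[truth$half == h, ]
    expect_true(all(abs(bi$row_start[-1] - ti$row_start[-1]) <= tol))
    expect_true(all(abs(bi$row_end[-nrow(bi)] - ti$row_end[-nrow(ti)]) <= tol))
  }
  # outermost edges contain the leads' ink (they hug the profile support)
  top <- boxes[boxes$half == "left", ][1, ]
  ink_top <- min(pg$truth$per_col[["I"]]$row)
  expect_lte(top$row_start, ink_top)
  expect_gte(top$row_start, truth$row_start[1])
  # each lead's drawn trace lies inside its detected box
  for (i in seq_len(nrow(boxes))) {
    pc <- pg$truth$per_col[[boxes$lead[i]]]
    expect_true(all(pc$row >= boxes$row_start[i] - 1 &
                    pc$row <= boxes$row_end[i] + 1))
  }
})

test_that("detection errors name found vs expected counts", {
  err <- tryCatch(
    digitize_page(fixture_page()$image, layout = layout_config(12)),
    ecg_detection_error = function(e) conditionMessage(e))
  expect_match(err, "found 7.*expected 6")
})

test_that("mirror symmetry: detection on the flipped page maps back", {
  pg <- fixture_page()
  m <- unclass(denoise(pg$image))
  boxes <- detect_lead_boxes(m, layout_config())
  flipped <- m[, ncol(m):1]
  fboxes <- detect_lead_boxes(flipped, layout_config())
  # rows of the original right half equal rows of the flipped left half
  r_orig <- boxes[boxes$half == "right", c("row_start", "row_end")]
  r_flip <- fboxes[fboxes$half == "left", c("row_start", "row_end")]
  expect_equal(unname(as.matrix(r_orig)), unname(as.matrix(r_flip)))
  # column extent maps through col' = n_cols - col + 1
  c_orig <- boxes[boxes$half == "right", c("col_start", "col_end")][1, ]
  c_flip <- fboxes[fboxes$half == "left", c("col_start", "col_end")][1, ]
  expect_equal(c_orig$col_end, ncol(m) - c_flip$col_start + 1L)
})
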