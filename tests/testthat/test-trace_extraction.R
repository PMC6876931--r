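test_that("otsu_threshold maximizes between-class variance (oracle)", {
  set.seed(5)
  for (k in 1:8) {
    v <- switch(1 + k %% 3,
                runif(400),
                c(rnorm(300, 0.2, 0.05), rnorm(100, 0.8, 0.05)),
                sample(c(0.1, 0.5, 0.9), 200, TRUE, prob = c(.6, .1, .3)))
    v <- pmin(pmax(v, 0), 1)
    t_star <- otsu_threshold(v)
    sb <- brute_otsu_variances(v)
    k_star <- round(t_star * 255)
    expect_equal(sb[k_star + 1], max(sb), tolerance = 1e-9)
  }
  expect_error(otsu_threshold(rep(0.5, 100)), class = "ecg_degenerate_error")
})

test_that("binarize separates classes and applies the 1.2 scaling", {
  # two-valued {0,1}: mask is exactly the bright class
  m <- matrix(0, 20, 20); m[5:10, 5:10] <- 1
  expect_identical(binarize(m), m == 1)

  # 90% at 0.1, 10% at 0.9: t* falls between the classes; only 0.9 survives
  v <- matrix(c(rep(0.1, 90), rep(0.9, 10)), 10, 10)
  t_star <- otsu_threshold(v)
  expect_gt(t_star, 0.1); expect_lt(t_star, 0.9)
  expect_identical(binarize(v, otsu_scale = 1.2), v > 1.2 * t_star)
  expect_identical(unname(table(binarize(v, 1.2))["TRUE"]), 10L)

  # otsu_scale = 1.2 on t* = 0.5 means an effective threshold of 0.6
  two <- matrix(rep(c(0.25, 0.75), each = 50), 10, 10)
  ts <- otsu_threshold(two)       # plateau midpoint near 0.5
  expect_equal(ts, 0.5, tolerance = 0.01)
  expect_identical(binarize(two, 1.2), two > 1.2 * ts)
})

test_that("connected-component labeling agrees with flood fill", {
  set.seed(13)
  for (k in 1:6) {
    nr <- sample(5:32, 1); nc <- sample(5:32, 1)
    mask <- matrix(runif(nr * nc) < 0.35, nr, nc)
    expect_true(same_partition(label_components(mask), brute_flood_fill(mask)))
  }
})

test_that("remove_small_objects keeps the largest and applies min_frac", {
  mask <- matrix(FALSE, 40, 40)
  mask[2:21, 2:26] <- TRUE              # 500 px
  mask[30, 5:7] <- TRUE                 # 3 px
  mask[35:36, 30] <- TRUE               # 2 px
  out <- remove_small_objects(mask, min_frac = 0.02)
  expect_equal(sum(out), 500L)
  expect_true(all(out[2:21, 2:26]))

  # single component: unchanged
  single <- matrix(FALSE, 10, 10); single[3:5, 3:5] <- TRUE
  expect_identical(remove_small_objects(single, 0.5), single)

  # two equal components: both retained for any min_frac <= 1
  eq <- matrix(FALSE, 10, 20)
  eq[2:4, 2:4] <- TRUE; eq[7:9, 12:14] <- TRUE
  expect_identical(remove_small_objects(eq, 1), eq)

  expect_warning(remove_small_objects(matrix(FALSE, 5, 5)),
                 class = "ecg_degenerate_warning")
})

test_that("centerline finds near-horizontal line structure", {
  # one perfect horizontal row
  m <- matrix(FALSE, 30, 40); m[17, ] <- TRUE
  expect_equal(centerline(m), 17)

  # three horizontal segments at rows 10, 12, 40: median of the lines
  m3 <- matrix(FALSE, 50, 60)
  m3[10, ] <- TRUE; m3[12, ] <- TRUE; m3[40, ] <- TRUE
  expect_equal(centerline(m3), 12)

  # rendered flat-baseline lead: centerline within 2 px of the baseline
  pg <- fixture_page()
  d <- fixture_digitization()
  for (nm in c("II", "V5")) {
    base_rel <- pg$truth$baselines[[nm]] - d$leads[[nm]]$box$row_start + 1
    expect_lte(abs(d$leads[[nm]]$center_row - base_rel), 2)
  }

  expect_error(centerline(matrix(FALSE, 10, 10)),
               class = "ecg_extraction_error")
})

test_that("trace_path follows a connected curve exactly", {
  # 1-px-wide curve touching the centerline: recovered verbatim, all grown
  nr <- 30; nc <- 25
  # gentle slope: consecutive rows differ by at most 1, so the 1-px curve
  # is 8-connected as drawn
  rows_true <- round(15 + 3 * sin(seq(0, 2 * pi, length.out = nc)))
  mask <- matrix(FALSE, nr, nc)
  mask[cbind(rows_true, seq_len(nc))] <- TRUE
  tp <- trace_path(mask, center_row = 15)
  expect_length(tp$rows, nc)
  expect_true(all(tp$flags == "grown"))
  expect_equal(tp$rows, rows_true)
  expect_true(all(tp$rows >= 1 & tp$rows <= nr))
})

test_that("occlusion gaps are filled by exact linear interpolation", {
  # flanks at rows 20 and 26 with a 3-column gap -> 21.5, 23, 24.5
  mask <- matrix(FALSE, 40, 8)
  mask[20, 1:2] <- TRUE
  mask[26, 6:8] <- TRUE
  tp <- trace_path(mask, center_row = 20)
  expect_equal(tp$rows[3:5], c(21.5, 23, 24.5))
  expect_equal(tp$flags[3:5], rep("interpolated", 3))
  # the disconnected right flank is picked up by the farthest rule
  expect_equal(tp$flags[6:8], rep("farthest", 3))
  expect_equal(tp$rows[6:8], rep(26, 3))
})

test_that("trace_path errors and bounds", {
  expect_error(trace_path(matrix(FALSE, 10, 10), 5),
               class = "ecg_extraction_error")
  m <- matrix(FALSE, 10, 10); m[4, 2] <- TRUE
  expect_error(trace_path(m, 40), class = "ecg_param_error")
})

test_that("rendered leads are recovered within 1.5 px on average", {
  pg <- fixture_page()
  d <- fixture_digitization()
  for (nm in c("II", "V2", "aVR")) {
    ld <- d$leads[[nm]]
    pc <- pg$truth$per_col[[nm]]
    cols <- intersect(pc$col, ld$box$col_start:ld$box$col_end)
    rec_rows <- ld$center_row - ld$signal$v[cols - ld$box$col_start + 1] /
      d$scale$mv_per_px
    true_rows <- pc$row[match(cols, pc$col)] - ld$box$row_start + 1
    err <- rec_rows - true_rows
    expect_lte(mean(abs(err - stats::median(err))), 1.5)  # offset-free error
  }
})

test_that("smooth_trace averages with shrinking edges and spares peaks", {
  expect_equal(smooth_trace(rep(3.3, 9)), rep(3.3, 9))

  # big deviation from the median is copied through unchanged
  x <- c(0, 0, 0, 100, 0, 0, 0)
  expect_equal(smooth_trace(x)[4], 100)

  # 11-point hand computation with symmetric edge shrink (windows 1,3,5...)
  v <- seq(0.1, 1.1, by = 0.1)  # ramp: deviations stay below 5 x median dev
  sm <- smooth_trace(v, span = 5)
  hand <- sapply(1:11, function(i) {
    h <- min(2, i - 1, 11 - i)
    mean(v[(i - h):(i + h)])
  })
  expect_equal(sm, hand, tolerance = 1e-12)

  # contraction on non-peaks, identity on peaks
  set.seed(4)
  w <- rnorm(50)
  w[25] <- 40
  out <- smooth_trace(w)
  expect_equal(out[25], 40)
  expect_lte(max(abs(out)), max(abs(w)))

  expect_error(smooth_trace(numeric(0)), class = "ecg_param_error")
  expect_error(smooth_trace(1:5, span = 4), class = "ecg_param_error")
})

test_that("noiseless synthetic crops round-trip at rho >= 0.99", {
  pg <- render_ecg_page(synthetic_spec(seed = 7L, noise_sd = 0))
  d <- digitize_page(pg$image)
  rhos <- roundtrip_rhos(d, pg$truth)
  expect_true(all(rhos >= 0.99))
})
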