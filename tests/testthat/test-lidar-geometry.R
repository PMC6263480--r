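# Polar record decoding, mounting, FOV windowing, trimming and splitting.

test_that("decode_records follows the spinning-scanner spherical convention", {
  # channel elevations are the odd degrees -15..15; channel 1 deg stands in
  # for the on-axis ray of the textbook examples
  rec <- data.frame(omega_deg = c(1, 1, 15), azimuth_deg = c(0, 90, 0),
                    range_m = c(1, 1, 2))
  xyz <- decode_records(rec)
  co <- cos(pi / 180); so <- sin(pi / 180)
  expect_equal(unname(xyz[1, ]), c(0, co, so), tolerance = 1e-12)   # alpha 0
  expect_equal(unname(xyz[2, ]), c(co, 0, so), tolerance = 1e-12)   # quarter turn
  # hand trigonometry: (2 cos15, 2 sin15)
  expect_equal(unname(xyz[3, ]), c(0, 1.93185, 0.51764), tolerance = 1e-5)
})

test_that("decoding preserves range and validates records", {
  recs <- canopyscan:::with_seed(3, data.frame(
    omega_deg = sample(seq(-15, 15, 2), 200, replace = TRUE),
    azimuth_deg = stats::runif(200, 0, 360),
    range_m = stats::runif(200, 0.5, 90)))
  xyz <- decode_records(recs)
  expect_equal(sqrt(rowSums(xyz^2)), recs$range_m, tolerance = 1e-12)

  expect_error(decode_records(transform(recs[1, ], range_m = -1)), "range_m")
  expect_error(decode_records(transform(recs[1, ], omega_deg = 3.5)),
               "channel")
})

test_that("filter_fov windows azimuth half-open and commutes with decoding", {
  recs <- data.frame(omega_deg = 1, azimuth_deg = c(0, 90, 179.9, 180, 270),
                     range_m = 1)
  kept <- filter_fov(recs, 0, 180)
  expect_equal(kept$azimuth_deg, c(0, 90, 179.9))
  expect_identical(nrow(filter_fov(recs, 0, 360)), nrow(recs))
  expect_error(filter_fov(recs, 180, 90), "az_lo")

  # windowing then decoding equals decoding then filtering on the Cartesian
  # azimuth angle
  rnd <- canopyscan:::with_seed(5, data.frame(
    omega_deg = sample(seq(-15, 15, 2), 500, replace = TRUE),
    azimuth_deg = stats::runif(500, 0, 360),
    range_m = stats::runif(500, 1, 50)))
  a <- decode_records(filter_fov(rnd, 45, 200))
  all_xyz <- decode_records(rnd)
  az <- (atan2(all_xyz[, "x"], all_xyz[, "y"]) * 180 / pi) %% 360
  b <- all_xyz[az >= 45 & az < 200, , drop = FALSE]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("apply_mounting is a rigid transform with a group inverse", {
  pts <- unclass(random_cloud(50, seed = 2))
  expect_equal(unclass(apply_mounting(pts, list(rotation = diag(3),
                                                translation = c(0, 0, 0)))),
               pts, ignore_attr = TRUE)
  shifted <- apply_mounting(pts, list(rotation = diag(3),
                                      translation = c(0, 0, -1.7)))
  expect_equal(shifted[, "z"], pts[, "z"] - 1.7)
  expect_equal(shifted[, "x"], pts[, "x"])

  m <- default_mount()
  fwd <- apply_mounting(pts, m)
  back <- apply_mounting(unclass(fwd), list(rotation = t(m$rotation),
                                            translation = c(0, 0, 0)))
  expect_equal(unclass(back), pts, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(apply_mounting(pts, list(rotation = diag(3) * 2,
                                        translation = c(0, 0, 0))), "rigid")
})

test_that("the default mount points the on-axis ray downward", {
  device <- decode_records(data.frame(omega_deg = 1, azimuth_deg = 0,
                                      range_m = 1))
  cart <- apply_mounting(device)
  expect_lt(cart[1, "z"], -0.99)
})

test_that("trim_cloud keeps the closed +/-1.5 plot-width window", {
  w <- 1.524
  cloud <- point_cloud(cbind(x = c(0, 1.5 * w, -1.5 * w, 2.30, -2.30),
                             y = 0, z = 0))
  tr <- trim_cloud(cloud, w)
  expect_identical(nrow(tr), 3L)            # 2.30 > 2.286 removed both sides
  expect_true(all(abs(tr[, "x"]) <= 1.5 * w))
  expect_identical(frame_state(tr), "trimmed")
  expect_error(trim_cloud(cloud, 0), "plot_width")
  # empty input passes through
  empty <- point_cloud(matrix(numeric(0), ncol = 3))
  expect_identical(nrow(trim_cloud(empty, w)), 0L)
})

test_that("split_cloud partitions by the +/-0.5 plot-width borders", {
  w <- 1.524
  cloud <- point_cloud(cbind(x = c(0, -1.0, 1.0, 0.5 * w, -0.5 * w),
                             y = 0, z = 0))
  expect_error(split_cloud(cloud, w), "trimmed")
  parts <- split_cloud(trim_cloud(cloud, w), w)
  expect_identical(nrow(parts$middle), 3L)  # 0 and the two border points
  expect_identical(nrow(parts$left), 1L)
  expect_identical(nrow(parts$right), 1L)
  expect_identical(attr(parts$middle, "position"), "middle")
  expect_identical(attr(parts$left, "position"), "side")
})

test_that("trim then split conserves every point exactly once", {
  for (s in 1:25) {
    cl <- random_cloud(200, seed = s)
    tr <- trim_cloud(cl, 1.524)
    parts <- split_cloud(tr, 1.524)
    expect_identical(nrow(parts$left) + nrow(parts$middle) + nrow(parts$right),
                     nrow(tr))
    recombined <- rbind(unclass(parts$left), unclass(parts$middle),
                        unclass(parts$right))
    expect_equal(recombined[order(recombined[, "x"]), ],
                 unclass(tr)[order(tr[, "x"]), ], ignore_attr = TRUE)
  }
})

test_that("polar records and clouds round-trip through their CSV forms", {
  recs <- data.frame(omega_deg = c(1, -15), azimuth_deg = c(10.5, 350),
                     range_m = c(2, 30))
  p <- file.path(tempdir(), "recs.csv")
  utils::write.csv(recs, p, row.names = FALSE)
  expect_equal(read_lidar_records(p), recs)

  cl <- random_cloud(20, seed = 9)
  pp <- file.path(tempdir(), "cloud.ply")
  write_ply(cl, pp)
  back <- read_ply(pp)
  expect_cloud_equal(back, cl)
  expect_identical(frame_state(back), "raw")

  pc <- file.path(tempdir(), "cloud.csv")
  write_cloud_csv(cl, pc)
  expect_cloud_equal(read_cloud_csv(pc), cl)
})
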