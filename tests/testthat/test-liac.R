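# direct access to a band's charge plane for test setup
get_band <- function(state, b, ch = 1) {
  m <- state$q[[ch]][, , b, drop = FALSE]
  dim(m) <- dim(state$q[[ch]])[1:2]
  m
}

test_that("quantization maps intensities to uniform bands per channel", {
  px <- matrix(c(0L, 128L, 255L, 31L, 32L, 200L), 2, 3)
  expect_equal(liac_quantize(px, 8),
               matrix(c(0L, 4L, 7L, 0L, 1L, 6L), 2, 3))
  # channels quantize independently
  arr <- array(0L, c(2, 2, 3))
  arr[, , 1] <- 255L; arr[, , 2] <- 128L
  bm <- liac_quantize(arr, 8)
  expect_true(all(bm[, , 1] == 7L) && all(bm[, , 2] == 4L) &&
                all(bm[, , 3] == 0L))
})

test_that("charge update discharges, saturates and decrements as specified", {
  p <- liac_params(n_bands = 2, discharge = 50)
  st <- liac_init(2, 2, params = p)
  st$prev <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  st$q[[1]][, , 1] <- matrix(c(120, 200, 0, 30), 2, 2)
  st$q[[1]][, , 2] <- matrix(c(0, 0, 255, 30), 2, 2)
  # pixel (1,1) leaves band 0; (2,1) stays in 0; (1,2) enters 0; (2,2) stays in 1
  bm <- matrix(c(0L, 0L, 0L, 1L), 2, 2)
  st <- liac_update_charge(st, bm)
  b0 <- get_band(st, 1); b1 <- get_band(st, 2)
  expect_equal(b0[2, 1], 150)    # 200 - 50, still in band
  expect_equal(b0[1, 2], 255)    # entered the band: saturate
  expect_equal(b1[1, 2], 0)      # left band 1: discharge to q_min
  expect_equal(b1[2, 2], 0)      # 30 - 50 floors at q_min
  expect_equal(b1[1, 1], 0)      # never in band 1
  expect_identical(st$prev, bm)
})

test_that("first frame initialises without charging", {
  st <- liac_init(4, 4)
  out <- liac_step(st, video_frame(matrix(200L, 4, 4)))
  expect_true(all(out$fused == 0))
  expect_false(is.null(out$state$prev))
})

test_that("recharge propagates from saturated pixels and is blocked by
           discharged ones", {
  p <- liac_params(recharge = 50)
  st <- liac_init(1, 4, params = p)
  st$q[[1]][1, , 1] <- c(255, 100, 0, 100)
  out <- liac_recharge(st)
  expect_equal(out$q[[1]][1, , 1], c(255, 150, 0, 100))

  # all discharged: nothing to do; all saturated: nothing partial
  st$q[[1]][1, , 1] <- rep(0, 4)
  expect_equal(liac_recharge(st)$q[[1]][1, , 1], rep(0, 4))
  st$q[[1]][1, , 1] <- rep(255, 4)
  expect_equal(liac_recharge(st)$q[[1]][1, , 1], rep(255, 4))
})

test_that("recharge agrees with an igraph reachability oracle and fires at
           most once per pixel", {
  p <- liac_params(recharge = 40)
  for (seed in 1:20) {
    set.seed(seed)
    q <- random_charges(6, 6)
    st <- liac_init(6, 6, params = p)
    st$q[[1]][, , 1] <- q
    got <- get_band(liac_recharge(st), 1)
    reach <- oracle_reachable4(q == 255, q > 0 & q < 255)
    expected <- q
    sel <- reach & q > 0 & q < 255
    expected[sel] <- pmin(q[sel] + 40, 255)
    expect_equal(got, expected)
    # recharge-once: no pixel gains more than R; sources and opaque unchanged
    expect_true(all(got - q <= 40))
    expect_true(all(got[q == 255] == 255) && all(got[q == 0] == 0))
    expect_true(all(got >= 0 & got <= 255))
  }
})

test_that("homogenisation averages 4-connected components with floor", {
  p <- liac_params()
  st <- liac_init(1, 2, params = p)
  st$q[[1]][1, , 1] <- c(100, 200)
  expect_equal(liac_homogenize(st)$q[[1]][1, , 1], c(150, 150))

  st <- liac_init(1, 3, params = p)
  st$q[[1]][1, , 1] <- c(10, 250, 40)
  expect_equal(liac_homogenize(st)$q[[1]][1, , 1], rep(100, 3))  # floor(100)

  # isolated pixel keeps its value; sub-threshold pixels untouched
  p2 <- liac_params(hom_min = 50)
  st <- liac_init(3, 3, params = p2)
  st$q[[1]][2, 2, 1] <- 77
  st$q[[1]][1, 1, 1] <- 20
  out <- get_band(liac_homogenize(st), 1)
  expect_equal(out[2, 2], 77)
  expect_equal(out[1, 1], 20)
})

test_that("homogenisation matches a component oracle and conserves charge up
           to rounding", {
  p <- liac_params(hom_min = 30)
  for (seed in 1:20) {
    set.seed(100 + seed)
    q <- random_charges(7, 5)
    st <- liac_init(7, 5, params = p)
    st$q[[1]][, , 1] <- q
    got <- get_band(liac_homogenize(st), 1)
    lab <- oracle_label(q >= 30, connectivity = 4)
    expected <- q
    for (k in seq_len(max(lab, 0))) {
      sel <- lab == k
      expected[sel] <- floor(mean(q[sel]))
      # conservation within the component, floor rounding only
      expect_lte(abs(sum(got[sel]) - sum(q[sel])), sum(sel))
    }
    expect_equal(got, expected)
  }
})

test_that("band fusion is a pixelwise max and channel fusion a min", {
  st <- liac_init(1, 1, params = liac_params(n_bands = 3))
  st$q[[1]][1, 1, ] <- c(0, 180, 60)
  expect_equal(liac_fuse_bands(st)[[1]][1, 1], 180)
  st$q[[1]][1, 1, ] <- c(0, 0, 0)
  expect_equal(liac_fuse_bands(st)[[1]][1, 1], 0)
  st$q[[1]][1, 1, ] <- c(255, 0, 0)
  expect_equal(liac_fuse_bands(st)[[1]][1, 1], 255)

  imgs <- list(matrix(200, 2, 2), matrix(180, 2, 2), matrix(90, 2, 2))
  expect_true(all(liac_fuse_channels(imgs) == 90))
  imgs[[1]][1, 1] <- 0; imgs[[2]][1, 1] <- 255; imgs[[3]][1, 1] <- 255
  expect_equal(liac_fuse_channels(imgs)[1, 1], 0)
  expect_identical(liac_fuse_channels(imgs[1]), imgs[[1]])
  expect_error(liac_fuse_channels(imgs[1:2]), "1 or 3")
})

test_that("fused output dominates every band charge", {
  set.seed(42)
  st <- liac_init(6, 6)
  st <- liac_step(st, matrix(sample(0:255, 36, TRUE), 6, 6))$state
  out <- liac_step(st, matrix(sample(0:255, 36, TRUE), 6, 6))
  fused <- liac_fuse_channels(liac_fuse_bands(out$state))
  for (b in 1:8)
    expect_true(all(fused >= get_band(out$state, b)))
})

test_that("a jumping blob saturates both the entered and the vacated pixels", {
  a <- matrix(10L, 5, 5); a[1:2, 1:2] <- 200L
  b <- matrix(10L, 5, 5); b[4:5, 4:5] <- 200L
  st <- liac_init(5, 5)
  st <- liac_step(st, a)$state
  out <- liac_step(st, b)
  expect_true(all(out$fused[4:5, 4:5] == 255))  # entered the bright band
  expect_true(all(out$fused[1:2, 1:2] == 255))  # entered the background band
  expect_true(all(out$fused[3, ] < 255))
})

test_that("charges stay within bounds over randomized sequences", {
  set.seed(7)
  st <- liac_init(8, 8, channels = 1,
                  params = liac_params(discharge = 20, recharge = 60))
  for (i in 1:15) {
    st <- liac_step(st, matrix(sample(0:255, 64, TRUE), 8, 8))$state
    q <- st$q[[1]]
    expect_true(all(q >= 0 & q <= 255))
  }
})

test_that("a static scene extinguishes all charge within (q_max - q_min) / D
           steps", {
  p <- liac_params(discharge = 60)
  st <- liac_init(10, 10, params = p)
  set.seed(3)
  frame <- matrix(sample(0:255, 100, TRUE), 10, 10)
  moved <- frame; moved[3:6, 3:6] <- (frame[3:6, 3:6] + 128L) %% 256L
  st <- liac_step(st, frame)$state
  st <- liac_step(st, moved)$state   # inject motion, then hold still
  n_steps <- ceiling(255 / 60) + 1
  for (i in seq_len(n_steps)) {
    out <- liac_step(st, moved)
    st <- out$state
  }
  expect_true(all(out$fused == 0))
  expect_true(all(unlist(st$q) == 0))
})
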