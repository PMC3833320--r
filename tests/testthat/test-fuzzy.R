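fis <- fall_system()

iv_at <- function(whr = 0.3, hc = 1.0, hv = 0, vv = 0, dir = 0, pos = 0)
  data.frame(whr = whr, height_change = hc, h_vel = hv, v_vel = vv,
             direction = dir, position_change = pos)

test_that("fuzzification evaluates the decided term shapes with clamping", {
  mu <- fuzzify(fis, iv_at(hv = 0))$HorizontalVelocity
  expect_equal(unname(mu), c(1, 0, 0))

  mu <- fuzzify(fis, iv_at(hv = 0.30))$HorizontalVelocity
  expect_equal(mu[["LOW"]], 0.5)
  expect_equal(mu[["MEDIUM"]], 0.25)
  expect_equal(mu[["HIGH"]], 0)

  # WHR 4.22 sits on the HIGH plateau; 6.5 clamps to the domain edge
  expect_equal(fuzzify(fis, iv_at(whr = 4.22))$WidthToHeightRatio[["HIGH"]], 1)
  expect_equal(fuzzify(fis, iv_at(whr = 6.5))$WidthToHeightRatio[["HIGH"]], 1)
  # velocity 1.30 clamps to 1.25, still fully HIGH
  expect_equal(fuzzify(fis, iv_at(vv = 1.30))$VerticalVelocity[["HIGH"]], 1)

  # crisp inputs pass through
  m <- fuzzify(fis, iv_at(dir = 1, pos = 0))
  expect_identical(m$FallDirection, 1L)
  expect_identical(m$PositionChange, 0L)

  # all memberships lie in [0, 1] across random indicator rows
  set.seed(17)
  for (rep in 1:20) {
    m <- fuzzify(fis, iv_at(whr = runif(1, 0, 8), hc = runif(1, 0, 3),
                            hv = runif(1, 0, 2), vv = runif(1, 0, 2)))
    mus <- unlist(m[c("WidthToHeightRatio", "HeightChange",
                      "HorizontalVelocity", "VerticalVelocity")])
    expect_true(all(mus >= 0 & mus <= 1))
  }
})

test_that("the rule DSL parses clauses, negation and crisp values, and
           rejects unknowns with line numbers", {
  r <- parse_rules("IF HeightChange IS HIGH THEN Fall IS YES")
  expect_length(r, 1)
  expect_length(r[[1]]$antecedents, 1)
  expect_false(r[[1]]$antecedents[[1]]$negated)
  expect_equal(r[[1]]$consequent$term, "YES")

  r <- parse_rules(paste("IF WidthToHeightRatio IS NOT HIGH AND",
                         "HeightChange IS LOW THEN Fall IS NO"))
  expect_true(r[[1]]$antecedents[[1]]$negated)

  r <- parse_rules("if PositionChange is 1 then Fall is YES")  # keywords fold
  expect_equal(r[[1]]$antecedents[[1]]$value, 1L)

  expect_error(parse_rules("IF Foo IS HIGH THEN Fall IS YES"),
               "unknown variable 'Foo'")
  expect_error(parse_rules("IF HeightChange IS HUGE THEN Fall IS YES"),
               "unknown term 'HUGE'")
  expect_error(parse_rules("# only comments\n"), "empty rule base")
  expect_error(parse_rules("IF HeightChange HIGH THEN Fall IS YES\n"),
               "line 1")
  expect_error(
    parse_rules("# pad\nIF PositionChange IS 2 THEN Fall IS YES"),
    "line 2")
})

test_that("inference reproduces the worked fall and no-fall scores", {
  expect_equal(infer_fall(fis, row_standing_backward), 67.5, tolerance = 1e-8)
  expect_equal(infer_fall(fis, row_kneeling), 22.5, tolerance = 1e-8)

  # a rule base that cannot fire yields the decided default 0
  quiet <- fall_system(rules = "IF HeightChange IS HIGH THEN Fall IS YES")
  expect_equal(infer_fall(quiet, iv_at(hc = 0.5)), 0)
})

test_that("a single symmetrically clipped output term defuzzifies to its
           peak at any clip height", {
  yes_only <- fall_system(rules = "IF HeightChange IS HIGH THEN Fall IS YES")
  no_only <- fall_system(rules = "IF HeightChange IS LOW THEN Fall IS NO")
  # clip heights produced by intermediate HIGH/LOW memberships
  for (hc in c(1.32, 1.35, 1.40)) {
    mu <- fuzzify(fis, iv_at(hc = hc))$HeightChange[["HIGH"]]
    got <- infer_fall(yes_only, iv_at(hc = hc))
    expect_equal(got, oracle_fall_centroid(act_yes = mu), tolerance = 1e-3)
    if (mu > 0) expect_equal(got, 67.5, tolerance = 1e-8)
  }
  for (hc in c(0.8, 1.06, 1.09)) {
    mu <- fuzzify(fis, iv_at(hc = hc))$HeightChange[["LOW"]]
    got <- infer_fall(no_only, iv_at(hc = hc))
    expect_equal(got, oracle_fall_centroid(act_no = mu), tolerance = 1e-3)
    if (mu > 0) expect_equal(got, 22.5, tolerance = 1e-8)
  }
})

test_that("centroids are grid-stable and stay inside fired-term supports", {
  rows <- list(row_standing_backward, row_lying, row_kneeling,
               iv_at(whr = 2.3, hc = 1.25, hv = 0.3, vv = 0.4))
  for (iv in rows) {
    c1 <- infer_fall(fis, iv, step = 0.05)
    c2 <- infer_fall(fis, iv, step = 0.005)
    expect_lt(abs(c1 - c2), 0.05)
    expect_gte(c1, 0); expect_lte(c1, 100)
  }
  # mixed YES + NO activation lands strictly between the two peaks
  mixed <- infer_fall(fis, iv_at(whr = 2.3, hc = 1.25, hv = 0.05, vv = 0.05))
  expect_gt(mixed, 22.5); expect_lt(mixed, 67.5)
})

test_that("the fall decision threshold is the NO/YES overlap midpoint,
           exclusive", {
  expect_true(decide_fall(67.5))
  expect_false(decide_fall(22.5))
  expect_false(decide_fall(40.0))
  expect_true(decide_fall(40.0001))
})

test_that("pattern classification reproduces the worked labels and the
           decision tree", {
  expect_identical(classify_pattern(fis, row_standing_backward, TRUE), 1L)
  expect_identical(classify_pattern(fis, row_lying, TRUE), 7L)
  expect_identical(classify_pattern(fis, row_lying, FALSE), 0L)

  # lateral-right falls from standing and sitting
  expect_identical(classify_pattern(fis, iv_at(hc = 1.6, dir = 1), TRUE), 2L)
  expect_identical(classify_pattern(fis, iv_at(hc = 1.2, dir = 1), TRUE), 5L)
  # backward/forward from sitting
  expect_identical(classify_pattern(fis, iv_at(hc = 1.2), TRUE), 4L)
  # lateral-left labels need the signed displacement extension
  expect_identical(classify_pattern(fis, iv_at(hc = 1.6), TRUE, dx = -8), 3L)
  expect_identical(classify_pattern(fis, iv_at(hc = 1.2), TRUE, dx = -8), 6L)
})

test_that("raising the height change never lowers the fall score", {
  # from a configuration where no rule fires up to a fully YES-firing one
  hcs <- seq(1.12, 1.6, by = 0.04)
  scores <- vapply(hcs, function(hc)
    infer_fall(fis, iv_at(whr = 1.8, hc = hc, hv = 0.3, vv = 0.6)),
    numeric(1))
  expect_equal(scores[1], 0)
  expect_true(all(diff(scores) >= -1e-9))
  expect_gt(scores[length(scores)], 40)
})

test_that("predict() appends score, decision and pattern per row", {
  out <- predict(fis, rbind(row_standing_backward, row_kneeling))
  expect_equal(out$score, c(67.5, 22.5), tolerance = 1e-8)
  expect_equal(out$is_fall, c(TRUE, FALSE))
  expect_equal(out$pattern, c(1L, 0L))
})
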