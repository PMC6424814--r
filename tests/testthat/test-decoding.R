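test_that("design matrices have the documented layout and a clean split", {
  tr <- fixture_trajectory()
  counts1 <- matrix(rpois(18000, 0.2), ncol = 1)
  d1 <- build_design(counts1, tr)
  expect_equal(ncol(d1$F_train), 25)          # 1 + L
  expect_true(all(d1$F_train[, 1] == 1))
  counts20 <- matrix(rpois(18000 * 20, 0.2), ncol = 20)
  expect_equal(ncol(build_design(counts20, tr)$F_train), 481)  # 1 + 20*24

  # chronological split: no test frame enters a training window
  boundary <- floor(0.7 * 18000)
  n_train <- nrow(d1$F_train)
  expect_true(n_train + 24 - 1 <= boundary)
  expect_equal(nrow(d1$F_test) + boundary, 18000 - 24 + 1)
  expect_error(build_design(counts1[1:100, , drop = FALSE], tr), "align")
})

test_that("a noiseless single-tap cell is decoded exactly", {
  s <- fixture_trajectory()$steps[, 1]
  counts <- round((s - min(s)) / 7.5)  # linear readout of the current step
  d <- build_design(counts, s)
  fl <- fit_decoder(d)
  cf <- coef(fl)[, 1, 1]
  expect_equal(cf[1], 7.5, tolerance = 1e-6)      # delta at lag 0
  expect_lt(max(abs(cf[-1])), 1e-8)
  rec <- reconstruct(d, fl)
  expect_gt(cor(rec$U[, 1], rec$S_test[, 1]), 0.99)

  # training residuals are orthogonal to every regressor column
  resid <- d$S_train[, 1] - d$F_train %*% fl$B[, 1]
  expect_lt(max(abs(crossprod(d$F_train, resid))) / nrow(d$F_train), 1e-8)
})

test_that("degenerate designs fall back gracefully", {
  tr <- fixture_trajectory()
  s <- tr$steps[, 1]
  # all-zero counts: offset-only fit, offsets near the training mean (~0)
  d0 <- build_design(integer(18000), s)
  expect_warning(fl0 <- fit_decoder(d0), "pseudo-inverse")
  expect_equal(unname(fl0$B[-1, 1]), rep(0, 24))
  expect_equal(unname(fl0$offsets[1]), mean(d0$S_train), tolerance = 1e-9)
  rec0 <- reconstruct(d0, fl0)
  expect_equal(var(as.numeric(rec0$U)), 0)

  # duplicated cell triggers the pseudo-inverse and reproduces the
  # single-cell reconstruction
  cell <- model_cell(filters = list(motion_filter_template()),
                     nonlinearity_kind = "exponential")
  cm <- get_counts(simulate_population(list(cell), s, seed = 2))
  d1 <- build_design(cm, s)
  r1 <- reconstruct(d1, fit_decoder(d1))
  ddup <- build_design(cbind(cm[, 1], cm[, 1]), s)
  expect_warning(fdup <- fit_decoder(ddup), "pseudo-inverse")
  expect_true(fdup$pseudo_inverse)
  rdup <- reconstruct(ddup, fdup)
  expect_equal(as.numeric(rdup$U), as.numeric(r1$U), tolerance = 1e-6)
})

test_that("decoder filters match the time-reversed encoding filters of linear cells", {
  tr <- generate_trajectory(51, 54000)  # 30 min
  h <- motion_filter_template()
  cells <- list(model_cell(preferred_direction = 0,
                           nonlinearity_kind = "linear"),
                model_cell(preferred_direction = 120,
                           nonlinearity_kind = "linear"))
  cm <- get_counts(simulate_population(cells, tr, seed = 52))
  cf <- coef(fit_decoder(build_design(cm, tr)))
  for (i in 1:2) {
    th <- cells[[i]]$preferred_direction * pi / 180
    # decoder tap m multiplies the count m frames after the decoded step;
    # the tap at lag 0 carries no signal for a causal encoder
    ref <- c(c(0, rev(cos(th) * h)[1:23]), c(0, rev(sin(th) * h)[1:23]))
    expect_gt(cor(c(cf[, 1, i], cf[, 2, i]), ref), 0.9)
  }
})

test_that("reduced codes behave as scaled or differenced single responses", {
  pair <- fixture_opponent_pair("ushape")
  s <- pair$s
  cm <- pair$counts

  # identical cells: subtraction annihilates the response
  z <- reduce_pair(cm[, 1], cm[, 1], "subtract")
  expect_true(all(z == 0))
  # addition doubles the counts; the filter scale absorbs the factor
  a <- reduce_pair(cm[, 1], cm[, 1], "add")
  i_add <- decode_info(as.numeric(a), s)$info$total_rate
  i_single <- decode_info(cm[, 1], s)$info$total_rate
  expect_equal(i_add, i_single, tolerance = 1e-9)

  # subtractive code of the opponent U-shaped pair: monotonic nonlinearity
  d <- reduce_pair(cm[, 1], cm[, 2], "subtract")
  g <- ln_model_drive(s, motion_filter_template())
  u <- estimate_nonlinearity(g, d[25:length(d)])$ushape_index
  expect_lt(u, 0)
  expect_error(reduce_pair(cm[, 1], cm[1:10, 2]), "equal length")
})

test_that("the opponent axis is chosen by the larger STA peak difference", {
  L <- 24
  mk_sta <- function(ax, ay) {
    structure(list(ax = ax, ay = ay, a = c(ax, ay), L = L,
                   n_axes = 2), class = "motion_sta")
  }
  h <- as.numeric(motion_filter_template())
  zero <- rep(0, L)
  expect_equal(select_opponent_axis(mk_sta(h, zero), mk_sta(-h, zero)), "x")
  expect_equal(select_opponent_axis(mk_sta(zero, h), mk_sta(zero, -h)), "y")

  # 120-deg pair: compare against brute-force evaluation of both peaks
  th1 <- 90 * pi / 180; th2 <- 210 * pi / 180
  s1 <- mk_sta(cos(th1) * h, sin(th1) * h)
  s2 <- mk_sta(cos(th2) * h, sin(th2) * h)
  lag <- (L:1) / 30
  sel <- lag <= 0.3
  pk <- function(a) a[sel][which.max(abs(a[sel]))]
  brute <- if (abs(pk(s1$ax) - pk(s2$ax)) >= abs(pk(s1$ay) - pk(s2$ay)))
    "x" else "y"
  expect_equal(select_opponent_axis(s1, s2), brute)
})

test_that("adding a pure-noise cell does not inflate test-set information", {
  pair <- fixture_opponent_pair("exponential")
  s <- pair$s
  i1 <- decode_info(pair$counts[, 1], s)$info$total_rate
  noise <- with(list(), {set.seed(53); rpois(length(s), 0.15)})
  i_with_noise <- decode_info(cbind(pair$counts[, 1], noise),
                              s)$info$total_rate
  expect_lt(i_with_noise, i1 * 1.05 + 0.02)
})
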