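test_that("steady state matches the series-resistance closed form", {
  Q0 <- 5
  cfg <- tube_config(R1 = 1, R2 = 10, C = 0.02,
                     waveform = list(type = "table", t = c(0, 1),
                                     q = c(Q0, Q0)))
  net <- load_network(cfg)
  st <- solver_settings(mu = 0, tol = 1e-6, max_cycles = 40, n_store = 32)
  ws <- simulate_network(net, st)
  p_in <- mean(ws$samples[, 1])
  expect_lt(abs(p_in - Q0 * (1 + 10)) / (Q0 * 11), 0.01)
})

test_that("a network initialised at the outflow pressure stays at rest", {
  cfg <- tube_config(waveform = list(type = "table", t = c(0, 1),
                                     q = c(0, 0)), p_out = 50)
  net <- load_network(cfg)
  st <- solver_settings(p_init = 50, max_cycles = 5, min_cycles = 2,
                        tol = 1e-6, n_store = 32)
  ws <- simulate_network(net, st)
  expect_equal(range(ws$samples[, 1]), c(50, 50), tolerance = 1e-8)
  expect_equal(range(ws$samples[, 2]), c(0, 0), tolerance = 1e-8)
})

test_that("small pulses propagate at the linearised wave speed", {
  area <- 0.5; c0 <- 600; rho <- 1.06
  Zc <- rho * c0 / area / 1333.22
  sites <- list(
    list(name = "P1", side = "right", vessel = "tube", position = 0.2,
         quantity = "pressure"),
    list(name = "P2", side = "right", vessel = "tube", position = 0.8,
         quantity = "pressure"))
  cfg <- tube_config(length = 100, area = area, c0 = c0, R1 = Zc, R2 = 40,
                     C = 0.5, period = 1,
                     waveform = list(type = "table",
                                     t = c(0, .05, .1, .15, 1),
                                     q = c(0, 0, 1.0, 0, 0)),
                     sites = sites)
  net <- load_network(cfg)
  st <- solver_settings(n_store = 1024, max_cycles = 6, min_cycles = 3,
                        tol = 1e9, balance_tol = 1e9, ramp_cycles = 0,
                        p_init = 10, mu = 0)
  ws <- simulate_network(net, st, on_failure = "return")
  foot <- function(u) {
    ipk <- which.max(u)
    imin <- which.min(u[1:ipk])
    th <- u[imin] + 0.1 * (u[ipk] - u[imin])
    i <- imin + which(u[imin:ipk] > th)[1] - 1
    i - 1 + (th - u[i - 1]) / (u[i] - u[i - 1])
  }
  tt <- (foot(ws$samples[, 2]) - foot(ws$samples[, 1])) / 1024 * ws$period
  c_meas <- 60 / tt                       # 60 cm between the two sites
  expect_lt(abs(c_meas - c0) / c0, 0.05)
})

test_that("a matched terminal produces no secondary reflections", {
  area <- 0.5; c0 <- 600; rho <- 1.06
  Zc <- rho * c0 / area / 1333.22
  sites <- list(list(name = "P1", side = "right", vessel = "tube",
                     position = 0.5, quantity = "pressure"))
  cfg <- tube_config(length = 100, area = area, c0 = c0, R1 = Zc,
                     R2 = 1e5, C = 1e3, period = 1,
                     waveform = list(type = "table",
                                     t = c(0, .05, .1, .15, 1),
                                     q = c(0, 0, 1.0, 0, 0)),
                     sites = sites)
  net <- load_network(cfg)
  st <- solver_settings(n_store = 1024, max_cycles = 3, min_cycles = 2,
                        tol = 1e9, balance_tol = 1e9, ramp_cycles = 0,
                        p_init = 10, mu = 0)
  ws <- simulate_network(net, st, on_failure = "return")
  u <- ws$samples[, 1]
  base <- stats::median(u[1:50])
  amp <- max(u) - base
  idx <- (which.max(u) + round(0.15 * 1024)):1024
  expect_lt(max(abs(u[idx] - base)) / amp, 0.02)
})

test_that("waveforms converge under spatial refinement at order >= 1", {
  net <- load_network(tube_config())
  st <- function(dx) solver_settings(dx = dx, tol = 1e-5, max_cycles = 30)
  w1 <- simulate_network(net, st(1.0))
  w2 <- simulate_network(net, st(0.5))
  w3 <- simulate_network(net, st(0.25))
  e12 <- periodicity_residual(w2, w1)
  e23 <- periodicity_residual(w3, w2)
  expect_lt(e23, 1e-3)          # halving dx changes less than the tolerance
  expect_gt(e12 / e23, 2)       # observed order at least one
})

test_that("junction coupling conserves mass and splits symmetrically", {
  net <- load_network(y_network_config())
  ws <- simulate_network(net, solver_settings(tol = 1e-4, max_cycles = 30))
  expect_lt(ws$max_junction_mass_err, 1e-6)
  ql <- mean(ws$samples[, "Q2_R"]); qr <- mean(ws$samples[, "Q3_R"])
  expect_equal(ql, qr, tolerance = 1e-6)
  expect_equal(ql + qr, mean(ws$samples[, "Q1_R"]), tolerance = 0.02)
  # whole-network volume balance over the converged cycle
  expect_lt(ws$volume_balance, 0.02)
})

test_that("a stenosis reduces cycle-mean flow through its chain", {
  net <- default_network()
  healthy <- simulate_network(net)
  spec <- disease_spec("stenosis", 0.9, b = 0.2, e = 0.8, chain = "CA",
                       side = "right")
  sick <- simulate_network(apply_disease(net, spec))
  expect_lt(mean(sick$samples[, "Q1_R"]), mean(healthy$samples[, "Q1_R"]))
  # and the contralateral side is far less affected
  drop_r <- mean(healthy$samples[, "Q1_R"]) - mean(sick$samples[, "Q1_R"])
  drop_l <- abs(mean(healthy$samples[, "Q1_L"]) - mean(sick$samples[, "Q1_L"]))
  expect_gt(drop_r, drop_l)
})

test_that("periodicity residual measures scaled cycle differences", {
  net <- load_network(tube_config())
  ws <- simulate_network(net, solver_settings(max_cycles = 30, tol = 1e-4))
  expect_equal(periodicity_residual(ws, ws), 0)
  # shift one site by 1% of its amplitude
  ws2 <- ws
  amp <- diff(range(ws$samples[, 1]))
  ws2$samples[, 1] <- ws$samples[, 1] + 0.01 * amp
  expect_equal(periodicity_residual(ws, ws2), 0.01, tolerance = 1e-10)
  # random perturbation of known scaled magnitude
  set.seed(3)
  pert <- runif(nrow(ws$samples), -1, 1)
  pert <- pert / max(abs(pert)) * 0.05 * amp
  ws3 <- ws
  ws3$samples[, 1] <- ws$samples[, 1] + pert
  expect_equal(periodicity_residual(ws, ws3), 0.05, tolerance = 1e-10)
  # grid mismatch is an error
  ws4 <- ws; ws4$samples <- ws$samples[, 1, drop = FALSE]
  expect_error(periodicity_residual(ws, ws4), "match")
})

test_that("non-convergence is reported with the achieved residual", {
  net <- load_network(tube_config())
  st <- solver_settings(max_cycles = 2, min_cycles = 2, tol = 1e-12)
  err <- tryCatch(simulate_network(net, st), condition = identity)
  expect_s3_class(err, "hemoscreen_solver_failure")
  expect_true(is.finite(err$residual))
})
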