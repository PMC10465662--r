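test_that("assembled blocks have the documented structure", {
  w <- seg3_data(n_cycles = 3)
  prob <- assemble_ls(w, complex(real = c(-1.5, -8)))
  K1 <- length(w$pressure$values)
  expect_equal(dim(prob$Phi), c(K1, 3))
  expect_equal(dim(prob$Gamma), c(K1, 3))
  expect_equal(dim(prob$Theta), c(K1, 3))
  # raw columns are the signals themselves; Theta's raw column is ones
  expect_identical(prob$Phi[, 1], w$pressure$values)
  expect_identical(prob$Gamma[, 1], w$flow$values)
  expect_identical(prob$Theta[, 1], rep(1, K1))
  # identical input signals give identical blocks
  same <- hemo_waveforms(w$pressure,
                         time_series(w$pressure$values, dt = w$flow$dt,
                                     t0 = w$flow$t0, unit = "m3/s"))
  prob2 <- assemble_ls(same, complex(real = c(-1.5, -8)))
  expect_equal(prob2$Phi, prob2$Gamma)
  # duplicate trial poles are rejected
  expect_error(assemble_ls(w, complex(real = c(-2, -2))), "distinct")
})

test_that("data from a known model give an exact null vector", {
  wk <- seg3_wk()
  m <- wk_to_pole_residue(wk)
  w <- seg3_data(n_cycles = 5)
  a <- m$poles[1]
  prob <- assemble_ls(w, a)
  # x_true = [d0, d1, c0, c1, b0, b1] with D = 1, b = Pd * d
  x_true <- c(1, 0, m$c0, Re(m$residues[1]), wk$Pd, 0)
  A <- cbind(-prob$Phi, prob$Gamma, prob$Theta)
  resid <- max(abs(A %*% x_true))
  expect_lt(resid / max(abs(w$pressure$values)), 1e-10)
})

test_that("SVD solve recovers an exact null space and is scale invariant", {
  # matrix with a known null vector
  withr::local_seed(2)
  B <- matrix(rnorm(40 * 5), 40, 5)
  xn <- c(1, -2, 0.5, 3, -1)
  # project columns to make xn a null vector
  A <- B - (B %*% xn) %*% t(xn) / sum(xn^2)
  dec <- svd(A, nu = 0)
  v <- dec$v[, 5]
  expect_lt(dec$d[5], 1e-10)
  expect_equal(abs(sum(v * xn)) / sqrt(sum(xn^2)), 1, tolerance = 1e-8)

  # full-rank small case: solution is the least-singular-vector (brute force)
  M <- matrix(c(2, 0, 0, 0, 1, 0, 0, 0, 0.1, 1, 1, 1), 4, 3, byrow = FALSE)
  d3 <- svd(M)$d[3]
  x <- svd(M, nu = 0)$v[, 3]
  expect_equal(sqrt(sum((M %*% x)^2)), d3, tolerance = 1e-12)

  # scaling the pressure record leaves H and Pd unchanged
  w <- seg3_data(n_cycles = 5)
  w2 <- hemo_waveforms(time_series(w$pressure$values * 7.3,
                                   dt = w$pressure$dt, unit = "Pa"),
                       w$flow)
  cfg <- tdvf_config(order = 1, seed = 10)
  f1 <- fit_tdvf(w, cfg)
  f2 <- fit_tdvf(w2, cfg)
  s <- complex(imaginary = 2 * pi * seq(0.5, 20, length.out = 17))
  expect_rel_equal(Mod(eval_H(f2$model, s)), 7.3 * Mod(eval_H(f1$model, s)),
                   1e-6)
  expect_equal(f2$model$Pd, 7.3 * f1$model$Pd, tolerance = 1e-6)
})

test_that("pole relocation matches closed forms and brute-force rooting", {
  # n = 1: zero of d0 + d1/(s - a) is a - d1/d0
  blocks <- tdvfbc:::pole_blocks(complex(real = -2))
  sol <- structure(list(d = c(1.5, 0.75), blocks = blocks,
                        poles = complex(real = -2)),
                   class = "ls_solution")
  expect_equal(relocate_poles(sol), as.complex(-2 - 0.75 / 1.5))

  # vanishing d_1..d_n leaves the poles untouched (converged fixed point)
  p3 <- c(complex(real = -1, imaginary = 5), complex(real = -1, imaginary = -5),
          complex(real = -3))
  sol0 <- structure(list(d = c(2, 0, 0, 0),
                         blocks = tdvfbc:::pole_blocks(p3), poles = p3),
                    class = "ls_solution")
  expect_equal(sort_poles(relocate_poles(sol0)), sort_poles(p3),
               tolerance = 1e-12)

  # random order-3 denominators vs clearing denominators + polyroot
  withr::local_seed(21)
  for (rep in 1:5) {
    a <- c(complex(real = -runif(1, 1, 5), imaginary = runif(1, 5, 20)))
    a <- c(a, Conj(a), complex(real = -runif(1, 0.5, 3)))
    drep <- complex(real = runif(1, -2, 2), imaginary = runif(1, -2, 2))
    dre <- complex(real = runif(1, -2, 2))
    d0 <- runif(1, 0.5, 2)
    dcplx <- c(drep, Conj(drep), dre)   # aligned with a
    blocks <- tdvfbc:::pole_blocks(a)
    rep_c <- if (Im(a[1]) > 0) dcplx[1] else dcplx[2]
    dvec <- c(d0, 2 * Re(rep_c), -2 * Im(rep_c), Re(dre))
    sol <- structure(list(d = dvec, blocks = blocks, poles = a),
                     class = "ls_solution")
    got <- relocate_poles(sol)
    want <- denominator_zeros_bruteforce(d0, dcplx, a)
    expect_lt(match_dist(got, want), 1e-8 * max(Mod(want)))
  }
})

test_that("stability enforcement reflects right-half-plane zeros", {
  blocks <- tdvfbc:::pole_blocks(complex(real = -2))
  sol <- structure(list(d = c(1, -6), blocks = blocks,
                        poles = complex(real = -2)),
                   class = "ls_solution")
  expect_equal(Re(relocate_poles(sol)), 4)              # unstable zero
  expect_equal(Re(relocate_poles(sol, enforce_stability = TRUE)), -4)
})

test_that("order-1 identification recovers the generating Windkessel", {
  wk <- seg3_wk()
  w <- seg3_data(n_cycles = 10)
  fit <- fit_tdvf(w, tdvf_config(order = 1, seed = 7))
  expect_true(fit$converged)
  expect_lte(fit$iterations, 100)
  wk2 <- pole_residue_to_wk(fit$model)
  expect_rel_equal(wk2$R1, wk$R1, 0.01)
  expect_rel_equal(wk2$R2, wk$R2, 0.01)
  expect_rel_equal(wk2$C, wk$C, 0.01)
  expect_rel_equal(wk2$Pd, wk$Pd, 0.01)
})

test_that("starting from the true poles is a fixed point", {
  wk <- seg3_wk()
  m <- wk_to_pole_residue(wk)
  w <- seg3_data(n_cycles = 10)
  cfg <- tdvf_config(order = 1, init_poles = m$poles)
  fit <- fit_tdvf(w, cfg)
  expect_true(fit$converged)
  expect_equal(fit$iterations, 1L)
  moved <- Mod(fit$pole_history[[2]] - fit$pole_history[[1]]) / Mod(m$poles)
  expect_lt(moved, 1e-8)
})

test_that("mid-cycle truncation (non-zero initial conditions) changes nothing", {
  wk <- celiac_wk()
  spec <- short_spec(n_cycles = 12, co = 0.9)
  w <- synth_waveforms(spec, wk)
  k0 <- round(3.3 * spec$period / spec$dt)
  trunc <- hemo_waveforms(
    time_series(w$pressure$values[-seq_len(k0)], dt = spec$dt, unit = "Pa"),
    time_series(w$flow$values[-seq_len(k0)], dt = spec$dt, unit = "m3/s"))
  expect_gt(abs(trunc$pressure$values[1]), 0)
  f_full <- fit_tdvf(w, tdvf_config(order = 1, seed = 5))
  f_trunc <- fit_tdvf(trunc, tdvf_config(order = 1, seed = 5))
  s <- complex(imaginary = 2 * pi * seq(0.5, 25, length.out = 40))
  expect_rel_equal(Mod(eval_H(f_trunc$model, s)), Mod(eval_H(f_full$model, s)),
                   5e-3)
  expect_identical(f_trunc$pd_method, "bias")
  expect_rel_equal(f_trunc$model$Pd, wk$Pd, 0.01)
})

test_that("flow scaling rescales residues and leaves poles and Pd fixed", {
  w <- seg3_data(n_cycles = 6)
  w2 <- hemo_waveforms(w$pressure,
                       time_series(w$flow$values * 4, dt = w$flow$dt,
                                   unit = "m3/s"))
  cfg <- tdvf_config(order = 1, seed = 3)
  f1 <- fit_tdvf(w, cfg)
  f2 <- fit_tdvf(w2, cfg)
  expect_equal(sort_poles(f2$model$poles), sort_poles(f1$model$poles),
               tolerance = 1e-6)
  expect_equal(f2$model$c0, f1$model$c0 / 4, tolerance = 1e-6)
  expect_equal(Re(f2$model$residues), Re(f1$model$residues) / 4,
               tolerance = 1e-6)
  expect_equal(f2$model$Pd, f1$model$Pd, tolerance = 1e-6)
})

test_that("over-parameterized fits stay accurate", {
  w <- seg3_data(n_cycles = 10)
  # an extra pole makes the smallest singular pair nearly tied; expected
  fit2 <- suppressWarnings(fit_tdvf(w, tdvf_config(order = 2, seed = 11)))
  pm <- approx_response(fit2$model, w$flow)
  expect_lt(relative_error(w$pressure, pm,
                           period = short_spec()$period), 1e-3)
})

test_that("short records are rejected and non-convergence does not error", {
  w <- seg3_data(n_cycles = 3)
  p <- time_series(w$pressure$values[1:5], dt = w$pressure$dt, unit = "Pa")
  q <- time_series(w$flow$values[1:5], dt = w$flow$dt, unit = "m3/s")
  expect_error(solve_ls(assemble_ls(hemo_waveforms(p, q),
                                    complex(real = c(-1, -5)))),
               "too short")
  # one iteration with a far-off start: must return a result with
  # converged = FALSE rather than raise
  fit <- fit_tdvf(w, tdvf_config(order = 1, max_iter = 1,
                                 init_poles = complex(real = -500)))
  expect_false(fit$converged)
  expect_s3_class(fit$model, "pole_residue")
})
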