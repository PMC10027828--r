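# Quadrature oracle used to freeze expected OSI/TAWSS values: plain
# midpoint-rule integration at high resolution, independent of the
# package's trapezoidal implementation.
osi_oracle <- function(fx, fy, Tcyc, n = 1e5) {
  tm <- (seq_len(n) - 0.5) * Tcyc / n
  ix <- mean(fx(tm)) * Tcyc; iy <- mean(fy(tm)) * Tcyc
  imag <- mean(sqrt(fx(tm)^2 + fy(tm)^2)) * Tcyc
  0.5 * (1 - sqrt(ix^2 + iy^2) / imag)
}

test_that("OSI: constant direction 0, full reversal 0.5, oracle otherwise", {
  Tc <- 0.8
  t <- seq(0, Tc, length.out = 2001)
  # constant-direction shear: no oscillation
  expect_equal(osi(t, matrix(2, 2001), matrix(0.5, 2001)), 0,
               tolerance = 1e-14)
  # zero-mean sinusoid: full reversal
  expect_equal(osi(t, matrix(sin(2 * pi * t / Tc)), matrix(0, 2001)), 0.5,
               tolerance = 1e-6)
  # partially reversing shear against the quadrature oracle
  fx <- function(s) 1 + 2 * sin(2 * pi * s / Tc)
  fy <- function(s) rep(0, length(s))
  tq <- seq(0, Tc, length.out = 1e5 + 1)
  got <- osi(tq, matrix(fx(tq)), matrix(fy(tq)))
  expect_equal(got, osi_oracle(fx, fy, Tc), tolerance = 1e-5)
  # frozen: mean |1 + 2 sin| over a period is 1 + (2*sqrt(3) - 2*pi/3)/pi,
  # giving OSI = (1 - 1/1.43599)/2 = 0.15181
  expect_equal(got, 0.15181, tolerance = 1e-4)
})

test_that("TAWSS: constants exact, sinusoid matches quadrature", {
  Tc <- 0.8
  t <- seq(0, Tc, length.out = 1001)
  expect_equal(tawss(t, matrix(3, 1001), matrix(4, 1001)), 5,
               tolerance = 1e-14)
  expect_identical(tawss(t, matrix(0, 1001), matrix(0, 1001)), 0)
  fx <- function(s) 2 + sin(2 * pi * s / Tc)
  tq <- seq(0, Tc, length.out = 1e5 + 1)
  tm <- (seq_len(1e5) - 0.5) * Tc / 1e5
  expect_equal(tawss(tq, matrix(fx(tq)), matrix(0, 1e5 + 1)),
               mean(abs(fx(tm))), tolerance = 1e-6)
})

test_that("TAWSS dominates the mean shear magnitude on random series", {
  set.seed(7)
  t <- seq(0, 0.8, length.out = 201)
  for (rep in 1:10) {
    fx <- matrix(rnorm(201 * 5), 201)
    fy <- matrix(rnorm(201 * 5), 201)
    tw <- tawss(t, fx, fy)
    o <- osi(t, fx, fy)
    expect_true(all(o >= 0 & o <= 0.5))
    # independent trapezoid mean of the shear vector
    wts <- rep(t[2] - t[1], 201); wts[c(1, 201)] <- wts[1] / 2
    mean_mag <- sqrt(colSums(wts * fx)^2 + colSums(wts * fy)^2) / 0.8
    expect_true(all(tw >= mean_mag - 1e-12))
  }
})

test_that("wall aggregation is length-weighted with a brute-force oracle", {
  ch <- tiny_channel()
  wall <- aneuflow:::.wall_setup(ch)
  nf <- nrow(wall)
  # uniform field: max = avg = v
  ag <- aggregate_wall(rep(2.5, nf), ch, "WALL_VESSEL")
  expect_equal(unname(ag["max"]), 2.5)
  expect_equal(unname(ag["avg"]), 2.5)
  # single nonzero value on one facet: max = v, avg much smaller
  v1 <- numeric(nf); v1[3] <- 10
  ag1 <- aggregate_wall(v1, ch, "WALL_VESSEL")
  expect_equal(unname(ag1["max"]), 10)
  expect_lt(unname(ag1["avg"]), 1)
  # random field equals the explicit weighted loop
  set.seed(11)
  v <- runif(nf)
  sel <- wall$tag == "WALL_VESSEL"
  brute <- sum(v[sel] * wall$length[sel]) / sum(wall$length[sel])
  expect_equal(unname(aggregate_wall(v, ch, "WALL_VESSEL")["avg"]), brute,
               tolerance = 1e-14)
  expect_error(aggregate_wall(v, ch, "WALL_SAC"), "empty wall region")
})

test_that("wall shear is tangential, zero at rest, and matches the channel", {
  ch <- tiny_channel()
  n <- nrow(ch$nodes)
  rheo <- newtonian_params(0.0035)
  at_rest <- wall_shear(flow_state(0, numeric(n), numeric(n), numeric(n)),
                        ch, rheo)
  expect_true(all(at_rest$wss == 0))
  st <- cached("tiny_poiseuille", {
    solve_steady(ch, rheo, bc = bc_spec(), inlet_velocity = 0.01)
  })
  ws <- wall_shear(st, ch, rheo)
  # tangentiality: tau . n = 0 by construction
  expect_lt(max(abs(ws$tau_x * ws$nx + ws$tau_y * ws$ny)),
            1e-12 * max(ws$wss))
  # wall shear points streamwise on the bottom wall
  bot <- ws$y < 1e-6
  expect_true(all(ws$tau_x[bot] > 0))
})

test_that("indices report is deterministic and demands phase snapshots", {
  fl <- fixture_flow()
  r1 <- indices_report(fl)
  r2 <- indices_report(fl)
  expect_identical(r1, r2)
  expect_true(all(r1$per_facet$osi >= 0 & r1$per_facet$osi <= 0.5))
  expect_true(all(r1$per_facet$tawss >= r1$per_facet$mean_tau_mag - 1e-12))
  expect_true(all(r1$regions$avg_tawss <= r1$regions$max_tawss + 1e-12))
  expect_true(all(r1$regions$avg_osi <= r1$regions$max_osi + 1e-12))
  broken <- fl
  broken$phase_index <- fl$phase_index[0, ]
  expect_error(indices_report(broken), "phase snapshots missing")
})
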