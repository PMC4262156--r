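turtle_root <- calibration("Testudines", "uniform", t_l = 155.6, t_u = 251.4)

test_that("soft-bounded uniform density has the closed piecewise form", {
  expect_equal(dcal(150, turtle_root), 0)            # hard minimum
  expect_equal(dcal(200, turtle_root), 0.975 / 95.8) # interior plateau
  # density continuous at the soft maximum
  eps <- 1e-9
  expect_equal(dcal(251.4 - eps, turtle_root), dcal(251.4 + eps, turtle_root),
               tolerance = 1e-6)
  # exponential tail carries exactly the specified mass
  tail_mass <- integrate(function(t) dcal(t, turtle_root), 251.4, Inf)$value
  expect_equal(tail_mass, 0.025, tolerance = 1e-8)
})

test_that("truncated Cauchy peaks at t_L(1+p) and is hard below t_L", {
  cc <- calibration("X", "cauchy", t_l = 100, p = 0.1, c = 0.5)
  expect_equal(dcal(99.9, cc), 0)
  grid <- seq(100, 200, by = 0.01)
  expect_equal(grid[which.max(dcal(grid, cc))], 110, tolerance = 0.02)
  # mode independent of the scale parameter
  cc2 <- calibration("X", "cauchy", t_l = 100, p = 0.1, c = 2)
  expect_equal(grid[which.max(dcal(grid, cc2))], 110, tolerance = 0.02)
})

test_that("every constructible calibration integrates to one", {
  cases <- list(
    turtle_root,
    calibration("a", "uniform", t_l = 18, t_u = 22),
    calibration("b", "uniform", t_l = 5, t_u = 400, tail_r = 0.1),
    calibration("c", "uniform", t_l = 50, t_u = 80, tail_l = 0.05,
                tail_r = 0.025),
    calibration("d", "cauchy", t_l = 100, p = 0.1, c = 0.1),
    calibration("e", "cauchy", t_l = 11.6, p = 0.5, c = 2)
  )
  for (cal in cases) {
    lo <- if (cal$tail_l > 0) -Inf else cal$t_l
    splits <- if (cal$family == "uniform") c(cal$t_l, cal$t_u) else
      cal$t_l * (1 + cal$p)
    total <- integrate(function(t) dcal(t, cal), lo, splits[1])$value +
      sum(vapply(seq_along(splits)[-1], function(i) {
        integrate(function(t) dcal(t, cal), splits[i - 1], splits[i])$value
      }, numeric(1))) +
      integrate(function(t) dcal(t, cal), splits[length(splits)], Inf)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("cdf and quantile are mutual inverses with closed forms", {
  expect_equal(qcal(0, turtle_root), 155.6)     # hard-min support edge
  expect_equal(pcal(251.4, turtle_root), 0.975) # mass below the soft max
  for (cal in list(turtle_root,
                   calibration("x", "cauchy", t_l = 100, p = 0.1, c = 1))) {
    q <- c(0.01, 0.1, 0.5, 0.9, 0.975, 0.999)
    expect_equal(pcal(qcal(q, cal), cal), q, tolerance = 1e-8)
    t <- qcal(c(0.2, 0.6, 0.99), cal)
    expect_equal(qcal(pcal(t, cal), cal), t, tolerance = 1e-8)
  }
  expect_error(qcal(1.2, turtle_root), "\\[0, 1\\]")
})

test_that("truncated Cauchy median matches quadrature inversion", {
  cc <- calibration("x", "cauchy", t_l = 100, p = 0.1, c = 1)
  # independent oracle: numeric root of the integrated density
  oracle <- uniroot(function(m) {
    integrate(function(t) dcal(t, cc), 100, m, rel.tol = 1e-10)$value - 0.5
  }, c(100, 1e4), tol = 1e-8)$root
  expect_equal(qcal(0.5, cc), oracle, tolerance = 1e-6)
})

test_that("sampling is inverse-cdf, reproducible and distributed correctly", {
  n <- 1e5
  set.seed(42)
  x1 <- rcal(n, turtle_root)
  set.seed(42)
  x2 <- rcal(n, turtle_root)
  expect_identical(x1, x2)
  # KS distance against the analytic cdf at approx. the 1% level
  ks <- max(abs(pcal(sort(x1), turtle_root) - seq_len(n) / n))
  expect_lt(ks, 1.63 / sqrt(n))
  # soft-maximum exceedance fraction
  expect_lt(abs(mean(x1 > 251.4) - 0.025), 0.002)
  set.seed(7)
  y <- rcal(n, calibration("x", "cauchy", t_l = 100, p = 0.1, c = 0.5))
  expect_gte(min(y), 100)
})

test_that("the 97.5% quantile widens monotonically with the Cauchy scale", {
  for (p in c(0.1, 0.5)) {
    q975 <- vapply(c(0.1, 0.5, 1, 2), function(cc) {
      qcal(0.975, calibration("x", "cauchy", t_l = 100, p = p, c = cc))
    }, numeric(1))
    expect_true(all(diff(q975) > 0))
  }
})

test_that("calibration tables round-trip through TSV", {
  cs <- calibration_set(list(
    turtle_root,
    calibration("Pelomedusidae", "uniform", t_l = 18, t_u = 22),
    calibration("Chelidae", "cauchy", t_l = 65.2, p = 0.5, c = 2)
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calibration_table(cs, path)
  cs2 <- read_calibration_table(path)
  expect_equal(names(cs2), names(cs))
  for (nd in names(cs)) expect_equal(cs2[[nd]], cs[[nd]])
})

test_that("invalid calibrations are rejected loudly", {
  expect_error(calibration("x", "uniform", t_l = 10), "maximum")
  expect_error(calibration("x", "uniform", t_l = 10, t_u = 5), "exceed")
  expect_error(calibration("x", "uniform", t_l = -1, t_u = 5), "positive")
  expect_error(calibration("x", "cauchy", t_l = 10, p = -1), "p > 0")
  expect_error(
    calibration_set(list(calibration("x", "uniform", t_l = 1, t_u = 2),
                         calibration("x", "uniform", t_l = 2, t_u = 3))),
    "two calibrations")
})
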