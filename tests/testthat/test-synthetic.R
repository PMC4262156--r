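test_that("birth-death simulation is reproducible and structurally sound", {
  tr1 <- simulate_bd_tree(8, 1, 0.3, seed = 5)
  tr2 <- simulate_bd_tree(8, 1, 0.3, seed = 5)
  expect_identical(write_newick(tr1), write_newick(tr2))
  expect_equal(n_tips(tr1), 8L)
  expect_equal(n_internal(tr1), 7L)
  expect_equal(nrow(validate_order(tr1)), 0L)
  expect_error(simulate_bd_tree(1, 1), "two tips")
  expect_error(simulate_bd_tree(4, 1, 2), "birth > death")
})

test_that("Yule root ages match the closed-form expectation", {
  # E[root age] = (H_n - 1) / birth for the pure-birth process stopped at
  # the memoryless present after first passage to n lineages
  n <- 6
  birth <- 1
  expected <- sum(1 / (2:n)) / birth
  roots <- vapply(1:400, function(r) {
    root_age(simulate_bd_tree(n, birth, seed = r))
  }, numeric(1))
  se <- sd(roots) / sqrt(length(roots))
  expect_lt(abs(mean(roots) - expected), 3 * se)
})

test_that("generated calibrations bracket the true ages", {
  tr <- simulate_bd_tree(10, 0.05, seed = 9)
  ages <- node_ages(tr)
  cs <- generate_calibrations(tr, fraction_calibrated = 1, gap_rate = 0.1,
                              style = "min-max", family = "uniform",
                              seed = 10)
  expect_equal(length(cs), n_internal(tr))
  for (cal in cs) {
    expect_lt(cal$t_l, ages[[cal$node]])
    expect_gt(cal$t_u, ages[[cal$node]])
  }
  # the root is always calibrated with both bounds
  expect_true(names(ages)[1L] %in% names(cs))
  # reproducibility
  cs2 <- generate_calibrations(tr, fraction_calibrated = 1, gap_rate = 0.1,
                               style = "min-max", family = "uniform",
                               seed = 10)
  expect_equal(cs2, cs)
})

test_that("tight gap rates pin minima against the true ages", {
  tr <- simulate_bd_tree(6, 0.05, seed = 13)
  ages <- node_ages(tr)
  cs <- generate_calibrations(tr, fraction_calibrated = 1, gap_rate = 100,
                              style = "min-max", family = "uniform",
                              seed = 14)
  gaps <- vapply(cs, function(cal) ages[[cal$node]] - cal$t_l, numeric(1))
  expect_true(all(gaps > 0))
  expect_lt(max(gaps), 0.2)
})

test_that("a misleading node gets a minimum older than its true age", {
  tr <- simulate_bd_tree(8, 0.05, seed = 17)
  ages <- node_ages(tr)
  ml <- names(ages)[3L]
  cs <- generate_calibrations(tr, fraction_calibrated = 1, gap_rate = 0.1,
                              style = "min-max", family = "uniform",
                              mislead = ml, seed = 18)
  expect_gt(cs[[ml]]$t_l, ages[[ml]])
  honest <- setdiff(names(cs), ml)
  for (nd in honest) expect_lt(cs[[nd]]$t_l, ages[[nd]])
})

test_that("alignment simulation matches JC69 expectations", {
  tr <- parse_newick("(A:50,B:50)Root;")
  # zero-ish rate: sequences identical
  aln0 <- simulate_alignment(tr, rate = 1e-12, n_sites = 200, seed = 21)
  expect_identical(unclass(aln0)["A", ], unclass(aln0)["B", ])
  # expected pairwise differences: (3/4)(1 - exp(-8 r T / 3))
  rate <- 1e-3
  n_sites <- 1e4
  aln <- simulate_alignment(tr, rate = rate, n_sites = n_sites, seed = 22)
  p_exp <- 0.75 * (1 - exp(-8 * rate * 50 / 3))
  d <- mean(unclass(aln)["A", ] != unclass(aln)["B", ])
  se <- sqrt(p_exp * (1 - p_exp) / n_sites)
  expect_lt(abs(d - p_exp), 3 * se)
  # seed determinism
  aln2 <- simulate_alignment(tr, rate = rate, n_sites = n_sites, seed = 22)
  expect_identical(unclass(aln2), unclass(aln))
})

test_that("synthetic studies regenerate bit-identically from their seed", {
  s1 <- synthetic_study(n_tips = 5, n_sites = 100, seed = 77,
                        gap_rate = 0.1)
  s2 <- synthetic_study(n_tips = 5, n_sites = 100, seed = 77,
                        gap_rate = 0.1)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))
  expect_equal(s1$calibrations, s2$calibrations)
  expect_identical(unclass(s1$alignment), unclass(s2$alignment))
  expect_equal(nrow(validate_order(s1$tree)), 0L)
})

test_that("the turtle fixture serves both calibration eras", {
  pri <- turtle_fixture("priori")
  expect_equal(pri$calibrations[["Testudines"]]$t_l, 155.6)
  expect_equal(pri$calibrations[["Testudines"]]$t_u, 251.4)
  expect_equal(length(pri$calibrations), 22L)
  post <- turtle_fixture("posteriori")
  expect_equal(post$calibrations[["Pelomedusidae"]]$t_l, 18)
  expect_equal(post$calibrations[["Pelomedusidae"]]$t_u, 22.0)
  # posteriori root keeps its minimum but gains the informative maximum
  expect_equal(post$calibrations[["Testudines"]]$t_l, 210)
  expect_equal(post$calibrations[["Testudines"]]$t_u, 251.4)
  for (cal in c(pri$calibrations, post$calibrations)) {
    expect_lt(cal$t_l, cal$t_u)
  }
  # the unattached table row is carried but not turned into a calibration
  expect_true("Lindholmemydidae" %in% pri$table$node_label)
  expect_false("Lindholmemydidae" %in% names(pri$calibrations))
})
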