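# Monte Carlo generator: marginal dynamics, ground-truth bookkeeping,
# reproducibility, and convergence to the stationary distribution.

test_that("pure AR(1) series reproduce the closed-form lag-1 autocorrelation", {
  set.seed(11)
  p <- 4
  y <- simulate_svar(matrix(0, p, p), diag(0.6, p), 8000)
  ac <- vapply(seq_len(p), function(j)
    stats::cor(y[-1, j], y[-nrow(y), j]), 0)
  expect_true(all(abs(ac - 0.6) < 0.05))

  yw <- simulate_svar(matrix(0, p, p), matrix(0, p, p), 8000)
  acw <- vapply(seq_len(p), function(j)
    stats::cor(yw[-1, j], yw[-nrow(yw), j]), 0)
  expect_true(all(abs(acw) < 0.05))
})

test_that("default design encodes the reference simulation conditions", {
  des <- simulation_design()
  expect_equal(des$n_individuals, 100L)
  expect_equal(des$n_rois, 10L)
  expect_equal(des$n_timepoints, 200L)
  expect_equal(nrow(des$group_paths), 9L)
  for (s in seq_len(des$n_subgroups)) {
    tm <- true_maps(des, s)
    expect_equal(diag(tm$Phi), rep(0.6, 10))
    w <- tm$A[tm$A != 0]
    expect_equal(length(w), 9L)
    expect_equal(sum(abs(w - 0.5) < 1e-12), 6L)   # 6 paths at base weight
    expect_equal(sum(abs(abs(w - 0.5) - 0.2) < 1e-12), 3L)  # 3 deviants
  }
  # subgroup maps pairwise distinct
  sigs <- vapply(1:4, function(s) paste(true_maps(des, s)$A, collapse = ","),
                 "")
  expect_equal(anyDuplicated(sigs), 0L)
})

test_that("design invariants are enforced", {
  expect_error(simulation_design(ar_weight = 1.05), "unstable")
  expect_error(simulation_design(ar_weight = 1.05), "subgroup")
  bad_dev <- list(data.frame(path = c(1, 2), sign = c(1, -1)))
  expect_error(
    simulation_design(n_subgroups = 1, subgroup_sizes = 100,
                      subgroup_deviations = bad_dev),
    "exactly 3")
  expect_error(
    simulation_design(unique_paths = rbind(c(1, 2), c(5, 9), c(2, 6),
                                           c(4, 8))),
    "duplicates a group path")
  expect_error(simulation_design(n_individuals = 10, n_subgroups = 4),
               "divisible")
})

test_that("seeded panels are bit-identical and labels partition everyone", {
  des <- simulation_design(n_individuals = 8, subgroup_sizes = c(2, 2, 2, 2),
                           seed = 99)
  s1 <- generate_panel(des)
  s2 <- generate_panel(des)
  expect_identical(s1$panel$series, s2$panel$series)
  expect_identical(s1$truth$labels, s2$truth$labels)
  expect_equal(sort(unique(s1$truth$labels)), 1:4)
  expect_equal(length(s1$truth$labels), 8L)
  expect_equal(vapply(s1$panel$series, nrow, 0L), rep(200L, 8),
               ignore_attr = TRUE)
})

test_that("unique-path carriage is Bernoulli(unique_prob) within subgroups", {
  des <- simulation_design(n_individuals = 400,
                           subgroup_sizes = rep(100, 4), seed = 6)
  sim <- generate_panel(des)
  for (s in 1:4) {
    carried <- sum(sim$truth$has_unique[sim$truth$labels == s])
    expect_gt(stats::binom.test(carried, 100, p = 0.5)$p.value, 0.01)
    # carried unique path present in the true map, absent otherwise
    up <- des$unique_paths[s, ]
    i_in <- which(sim$truth$labels == s & sim$truth$has_unique)[1]
    i_out <- which(sim$truth$labels == s & !sim$truth$has_unique)[1]
    expect_equal(sim$truth$true_A[[i_in]][up["to"], up["from"]],
                 des$unique_beta, ignore_attr = TRUE)
    expect_identical(sim$truth$true_A[[i_out]][up["to"], up["from"]], 0)
  }
})

test_that("long series converge to the analytic stationary covariance", {
  des <- simulation_design(n_individuals = 4, subgroup_sizes = 4,
                           n_subgroups = 1, n_timepoints = 10000, seed = 22)
  tm <- true_maps(des, 1)
  set.seed(22)
  y <- simulate_svar(tm$A, tm$Phi, 10000)
  emp <- stats::cov(y)
  ana <- stationary_covariance(tm$A, tm$Phi)
  rel <- norm(emp - ana, "F") / norm(ana, "F")
  expect_lt(rel, 0.05)
  # bounded variance over time for a stable design (stationarity)
  v1 <- apply(y[1:2000, ], 2, stats::var)
  v2 <- apply(y[8001:10000, ], 2, stats::var)
  expect_true(all(v2 / v1 < 2 & v2 / v1 > 0.5))
})

test_that("simulation round-trips through delimited files", {
  des <- small_design(seed = 3, n_per_group = 2, T = 60)
  sim <- generate_panel(des)
  dir <- tempfile("simout")
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.tsv")))
  expect_true(file.exists(file.path(dir, "true_edges.tsv")))
  expect_true(file.exists(file.path(dir, "design.yaml")))
  panel <- load_panel(file.path(dir, "series"))
  expect_equal(length(panel), 4L)
  expect_equal(panel$series[[1]], sim$panel$series[[1]],
               tolerance = 1e-6, ignore_attr = TRUE)
  gt <- utils::read.delim(file.path(dir, "ground_truth.tsv"))
  expect_equal(gt$subgroup, sim$truth$labels)
})
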