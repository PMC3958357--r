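# uSEM estimation: lag embedding with placeholders, ML fit against the
# least-squares oracle, parameter recovery, score tests, fit indices.

test_that("lag embedding counts pairs and drops those spanning missing frames", {
  ts <- matrix(rnorm(400), 200, 2)
  emb <- embed_lag(ts)
  expect_equal(emb$n_used, 199L)

  ts5 <- ts
  ts5[5, ] <- NA
  expect_equal(embed_lag(ts5)$n_used, 197L)  # pairs (4,5) and (5,6) gone
  kept <- embed_lag(ts5)
  expect_false(anyNA(kept$x))
  expect_false(anyNA(kept$y))

  alt <- ts
  alt[seq(1, 200, by = 2), ] <- NA
  expect_error(embed_lag(alt), "usable frame pairs")
  expect_error(embed_lag(ts[1:15, ]), "usable frame pairs")
})

test_that("ML estimates equal per-equation least squares on recursive specs", {
  set.seed(31)
  p <- 5
  A <- matrix(0, p, p)
  A[2, 1] <- 0.5; A[3, 2] <- 0.4; A[4, 3] <- 0.6; A[5, 1] <- -0.3
  Phi <- diag(0.5, p)
  y <- simulate_svar(A, Phi, 500)
  spec <- usem_spec(p, free_A = A != 0)
  fit <- fit_usem(y, spec)
  emb <- embed_lag(y)
  for (i in seq_len(p)) {
    pred <- which(spec$free_A[i, ])
    X <- cbind(emb$y[, pred, drop = FALSE], emb$x[, i])
    b <- stats::coef(stats::lm(emb$y[, i] ~ X))[-1]
    if (length(pred))
      expect_equal(unname(fit$A_hat[i, pred]), unname(b[seq_along(pred)]),
                   tolerance = 1e-4)
    expect_equal(unname(fit$Phi_hat[i, i]), unname(b[length(b)]),
                 tolerance = 1e-4)
  }
})

test_that("true-mask fits recover generating weights within 0.05 at T = 2000", {
  des <- simulation_design(n_individuals = 4, subgroup_sizes = 4,
                           n_subgroups = 1, n_timepoints = 2000, seed = 41)
  tm <- true_maps(des, 1)
  set.seed(41)
  y <- simulate_svar(tm$A, tm$Phi, 2000)
  fit <- fit_usem(y, usem_spec(10, free_A = tm$A != 0))
  expect_lt(max(abs(fit$A_hat - tm$A)), 0.05)
  expect_lt(max(abs(fit$Phi_hat - tm$Phi)), 0.05)
  expect_true(fit$converged)
  expect_gte(fit$chi2, 0)
  expect_gte(fit$df, 0)
})

test_that("AR-only fit of white noise is null: AR near 0, chi2/df near 1", {
  set.seed(51)
  y <- matrix(rnorm(3000), 1000, 3)
  fit <- fit_usem(y, usem_spec(3))
  expect_lt(max(abs(diag(fit$Phi_hat))), 0.1)
  expect_gt(fit$chi2 / fit$df, 0.5)
  expect_lt(fit$chi2 / fit$df, 1.6)
})

test_that("the saturated model has zero discrepancy and undefined RMSEA", {
  set.seed(61)
  p <- 3
  y <- simulate_svar(matrix(c(0, 0.4, 0, 0, 0, 0.3, 0, 0, 0), 3, 3),
                     diag(0.5, 3), 400)
  # recursive saturated pattern: every lower-triangular contemporaneous
  # path plus the full lagged matrix -> df = 0
  spec <- usem_spec(p, free_A = lower.tri(matrix(0, p, p)),
                    free_Phi = matrix(TRUE, p, p))
  fit <- fit_usem(y, spec)
  expect_equal(fit$df, 0)
  expect_lt(abs(fit$F), 1e-8)
  expect_lt(fit$chi2, 1e-4)
  ix <- fit_indices(fit, fit_usem(y, usem_spec(p)))
  expect_false(ix$defined)
  expect_true(is.na(ix$rmsea))
  expect_lt(ix$srmr, 1e-4)
})

test_that("freeing a parameter never increases chi2 (nested monotonicity)", {
  set.seed(71)
  p <- 4
  A <- matrix(0, p, p); A[2, 1] <- 0.5; A[4, 3] <- 0.4
  y <- simulate_svar(A, diag(0.5, p), 300)
  mask <- matrix(FALSE, p, p)
  prev <- Inf
  for (cell in list(c(2, 1), c(4, 3), c(3, 1), c(4, 2))) {
    mask[cell[1], cell[2]] <- TRUE
    chi2 <- fit_usem(y, usem_spec(p, free_A = mask))$chi2
    expect_lte(chi2, prev + 1e-6)
    prev <- chi2
  }
})

test_that("optimization never worsens the least-squares starting value", {
  set.seed(81)
  p <- 4
  A <- matrix(0, p, p); A[2, 1] <- 0.5; A[1, 2] <- 0  # acyclic truth
  A[3, 1] <- 0.4
  y <- simulate_svar(A, diag(0.6, p), 250)
  spec <- usem_spec(p, free_A = A != 0)
  mom <- gimmeclust:::usem_moments(y)
  theta0 <- gimmeclust:::usem_start(spec, mom)
  g0 <- gimmeclust:::usem_objective(theta0, spec, mom)
  fit <- fit_usem(y, spec)
  gfit <- fit$F + mom$logdet_cond
  expect_lte(gfit, g0 + 1e-10)
})

test_that("modification indices behave as score tests", {
  # null element: MI below the chi2(1) 5% critical value in >= 90% of runs
  set.seed(90)
  p <- 3
  n_rep <- 20
  hits <- 0
  for (r in seq_len(n_rep)) {
    y <- simulate_svar(matrix(0, p, p), diag(0.5, p), 300)
    fit <- fit_usem(y, usem_spec(p))
    mi <- modification_indices(fit)
    m21 <- mi$mi[mi$type == "A" & mi$from == 1 & mi$to == 2]
    hits <- hits + (m21 < stats::qchisq(0.95, 1))
  }
  expect_gte(hits / n_rep, 0.9)

  # omitted true path at 0.5, T = 200: MI exceeds the Bonferroni critical
  # value and tops the candidate list with the right direction
  set.seed(92)
  A <- matrix(0, p, p); A[2, 1] <- 0.5
  y <- simulate_svar(A, diag(0.5, p), 200)
  fit0 <- fit_usem(y, usem_spec(p))
  mi <- modification_indices(fit0)
  crit <- stats::qchisq(1 - 0.05 / nrow(mi), 1)
  top <- mi[1, ]
  expect_gt(top$mi, crit)
  expect_equal(paste(top$type, top$from, top$to), "A 1 2")

  # MI approximates the brute-force chi2 drop for local misfits
  set.seed(93)
  for (w in c(0.1, 0.15)) {
    A <- matrix(0, p, p); A[3, 2] <- w
    y <- simulate_svar(A, diag(0.5, p), 3000)
    f_r <- fit_usem(y, usem_spec(p))
    f_f <- fit_usem(y, usem_spec(p, free_A = A != 0))
    drop <- f_r$chi2 - f_f$chi2
    mi <- modification_indices(f_r)
    m <- mi$mi[mi$type == "A" & mi$from == 2 & mi$to == 3]
    expect_lt(abs(m - drop) / drop, 0.20)
    # expected parameter change points at the omitted weight
    epc <- mi$epc[mi$type == "A" & mi$from == 2 & mi$to == 3]
    expect_lt(abs(epc - w), 0.05)
  }
})

test_that("fit indices follow their formulas and flag a well-fitting model", {
  set.seed(94)
  p <- 4
  A <- matrix(0, p, p); A[2, 1] <- 0.5; A[3, 2] <- 0.4
  y <- simulate_svar(A, diag(0.6, p), 2000)
  null_fit <- fit_usem(y, usem_spec(p))
  fit <- fit_usem(y, usem_spec(p, free_A = A != 0))
  ix <- fit_indices(fit, null_fit)
  expect_lte(ix$rmsea, 0.05)
  expect_gte(ix$cfi, 0.95)
  expect_true(excellent_fit(ix))
  expect_equal(ix$rmsea,
               sqrt(max(fit$chi2 - fit$df, 0) / (fit$df * (fit$n_used - 1))))
  # a model identical to the null has CFI 0
  ix0 <- fit_indices(null_fit, null_fit)
  expect_equal(ix0$cfi, 0)
  expect_false(excellent_fit(ix0))
})

test_that("standard errors agree with the regression oracle", {
  set.seed(95)
  p <- 3
  A <- matrix(0, p, p); A[2, 1] <- 0.5
  y <- simulate_svar(A, diag(0.5, p), 1000)
  fit <- fit_usem(y, usem_spec(p, free_A = A != 0))
  emb <- embed_lag(y)
  lmfit <- stats::lm(emb$y[, 2] ~ emb$y[, 1] + emb$x[, 2])
  se_lm <- sqrt(diag(stats::vcov(lmfit)))[2]
  expect_lt(abs(fit$se_A[2, 1] - se_lm) / se_lm, 0.1)
})
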