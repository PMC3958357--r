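#' Specify a unified SEM (lag-1 structural VAR) pattern
#'
#' A uSEM predicts each ROI at scan t from other ROIs at scan t
#' (contemporaneous matrix `A`, zero diagonal) and from all ROIs at scan
#' t-1 (lagged matrix `Phi`, whose diagonal holds the autoregressive
#' effects). The specification states which elements are free; all others
#' are fixed to zero.
#'
#' @param p number of ROIs.
#' @param free_A p x p logical mask of free contemporaneous paths
#'   (diagonal must be FALSE). Default: none free.
#' @param free_Phi p x p logical mask of free lagged paths. Default:
#'   diagonal (AR) only.
#' @return object of class `usem_spec`.
#' @export
usem_spec <- function(p, free_A = NULL, free_Phi = NULL) {
  p <- as.integer(p)
  if (is.null(free_A)) free_A <- matrix(FALSE, p, p)
  if (is.null(free_Phi)) free_Phi <- diag(p) == 1
  free_A <- matrix(as.logical(free_A), p, p)
  free_Phi <- matrix(as.logical(free_Phi), p, p)
  if (any(diag(free_A))) stop("diagonal of free_A must be FALSE")
  structure(list(p = p, free_A = free_A, free_Phi = free_Phi),
            class = "usem_spec")
}

#' Lag-embed a series with missing-frame placeholders
#'
#' Builds the matrix of `[y_{t-1}, y_t]` observation pairs used by the
#' uSEM likelihood. A pair is retained only when both frames are fully
#' observed, so pairs spanning a scrubbed (all-`NA` placeholder) frame are
#' dropped while temporal ordering is respected.
#'
#' @param ts T x p numeric matrix, `NA` marking missing frames.
#' @param min_pairs minimum usable pairs; defaults to `10 * p`. Fewer is
#'   an error (sample too small for stable estimation).
#' @return list with `x` (lagged frames), `y` (current frames), `n_used`.
#' @export
embed_lag <- function(ts, min_pairs = NULL) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2L) stop("need at least 2 frames to lag-embed")
  p <- ncol(ts)
  if (is.null(min_pairs)) min_pairs <- 10L * p
  ok <- stats::complete.cases(ts)
  keep <- which(ok[-length(ok)] & ok[-1L])
  n_used <- length(keep)
  if (n_used < min_pairs)
    stop("only ", n_used, " usable frame pairs (need >= ", min_pairs,
         "); series too short or too heavily scrubbed")
  list(x = ts[keep, , drop = FALSE], y = ts[keep + 1L, , drop = FALSE],
       n_used = n_used)
}

# Sample cross-moments of the lag-embedded pairs (ML divisor n).
usem_moments <- function(ts, standardize = FALSE, min_pairs = NULL) {
  ts <- as.matrix(ts)
  if (standardize) {
    mu <- colMeans(ts, na.rm = TRUE)
    sd <- apply(ts, 2, stats::sd, na.rm = TRUE)
    if (any(sd == 0 | is.na(sd))) stop("zero-variance ROI; cannot standardize")
    ts <- sweep(sweep(ts, 2, mu), 2, sd, "/")
  }
  emb <- embed_lag(ts, min_pairs = min_pairs)
  n <- emb$n_used
  xc <- scale(emb$x, scale = FALSE)
  yc <- scale(emb$y, scale = FALSE)
  S_xx <- crossprod(xc) / n
  S_yx <- crossprod(yc, xc) / n
  S_yy <- crossprod(yc) / n
  # log-determinant of the conditional (saturated) covariance S_y|x
  S_cond <- S_yy - S_yx %*% solve(S_xx, t(S_yx))
  ld <- determinant(S_cond, logarithm = TRUE)
  list(S_xx = S_xx, S_yx = S_yx, S_yy = S_yy, n_used = n,
       logdet_cond = as.numeric(ld$modulus), p = ncol(ts))
}

# ---- profile ML machinery -------------------------------------------------
#
# With diagonal residual variances Psi profiled out (psi_i = V_ii at the
# optimum), the ML discrepancy over the lag-embedded covariance reduces to
#   G(A, Phi) = sum_i log V_ii(A, Phi) - 2 log|det(I - A)|
# where V_ii is the variance of the i-th structural residual
# u = (I - A) y - Phi x under the sample moments. The full discrepancy is
# F = G - log|S_y|x| and chi2 = (n_used - 1) F. Parameters are packed as
# c(A[free_A], Phi[free_Phi]) in column-major mask order.

usem_unpack <- function(theta, spec) {
  p <- spec$p
  A <- matrix(0, p, p); Phi <- matrix(0, p, p)
  nA <- sum(spec$free_A)
  A[spec$free_A] <- theta[seq_len(nA)]
  Phi[spec$free_Phi] <- theta[nA + seq_len(sum(spec$free_Phi))]
  list(A = A, Phi = Phi)
}

usem_resid_var <- function(A, Phi, mom) {
  M <- diag(nrow(A)) - A
  MS <- M %*% mom$S_yy
  rowSums(MS * M) - 2 * rowSums((M %*% mom$S_yx) * Phi) +
    rowSums((Phi %*% mom$S_xx) * Phi)
}

usem_objective <- function(theta, spec, mom) {
  par <- usem_unpack(theta, spec)
  M <- diag(spec$p) - par$A
  dM <- det(M)
  if (!is.finite(dM) || abs(dM) < 1e-12) return(1e10)
  V <- usem_resid_var(par$A, par$Phi, mom)
  if (any(V <= 0)) return(1e10)
  sum(log(V)) - 2 * log(abs(dM))
}

# Gradient over the FULL parameter space (all off-diagonal A, all Phi),
# returned as two p x p matrices; callers subset by masks.
usem_gradient_full <- function(A, Phi, mom) {
  p <- nrow(A)
  M <- diag(p) - A
  V <- usem_resid_var(A, Phi, mom)
  R <- M %*% mom$S_yy - Phi %*% t(mom$S_yx)   # row i: (S_yy m_i - S_yx phi_i)'
  S <- Phi %*% mom$S_xx - M %*% mom$S_yx      # row i: (S_xx phi_i - S_yx' m_i)'
  Binv <- solve(M)
  gA <- -2 * R / V + 2 * t(Binv)              # d/dA_ij: +2 * Binv[j,i]
  gPhi <- 2 * S / V
  diag(gA) <- 0
  list(gA = gA, gPhi = gPhi, V = V, M = M, Binv = Binv, R = R, S = S)
}

usem_gradient <- function(theta, spec, mom) {
  par <- usem_unpack(theta, spec)
  M <- diag(spec$p) - par$A
  if (abs(det(M)) < 1e-12 || any(usem_resid_var(par$A, par$Phi, mom) <= 0))
    return(rep(0, length(theta)))  # paired with the 1e10 objective plateau
  g <- usem_gradient_full(par$A, par$Phi, mom)
  c(g$gA[spec$free_A], g$gPhi[spec$free_Phi])
}

# Parameter index bookkeeping over the full space: all off-diagonal A
# entries then all Phi entries, column-major. Returns row/col/type vectors.
usem_param_index <- function(p) {
  offdiag <- which(diag(p) == 0)
  iA <- ((offdiag - 1L) %% p) + 1L
  jA <- ((offdiag - 1L) %/% p) + 1L
  iP <- rep(seq_len(p), p)
  jP <- rep(seq_len(p), each = p)
  list(
    type = c(rep("A", length(offdiag)), rep("Phi", p * p)),
    row = c(iA, iP), col = c(jA, jP),
    lin = c(offdiag, seq_len(p * p)),  # linear index into the p x p matrix
    nA = length(offdiag))
}

# Analytic Hessian of G over the full parameter space.
usem_hessian_full <- function(A, Phi, mom) {
  p <- nrow(A)
  idx <- usem_param_index(p)
  npar <- length(idx$type)
  g <- usem_gradient_full(A, Phi, mom)
  V <- g$V
  H <- matrix(0, npar, npar)
  # per-row blocks from the log V_i terms
  for (i in seq_len(p)) {
    selA <- which(idx$type == "A" & idx$row == i)
    selP <- which(idx$type == "Phi" & idx$row == i)
    colsA <- idx$col[selA]; colsP <- idx$col[selP]
    # dV_i: wrt A_ij = -2 R[i,j]; wrt Phi_il = 2 S[i,l]
    dv <- c(-2 * g$R[i, colsA], 2 * g$S[i, colsP])
    # d2V_i: [A,A] = 2 S_yy; [A,Phi] = 2 S_yx; [Phi,Phi] = 2 S_xx
    d2v <- rbind(
      cbind(2 * mom$S_yy[colsA, colsA, drop = FALSE],
            2 * mom$S_yx[colsA, colsP, drop = FALSE]),
      cbind(2 * t(mom$S_yx)[colsP, colsA, drop = FALSE],
            2 * mom$S_xx[colsP, colsP, drop = FALSE]))
    blk <- d2v / V[i] - tcrossprod(dv) / V[i]^2
    sel <- c(selA, selP)
    H[sel, sel] <- H[sel, sel] + blk
  }
  # log-det coupling: d2(-2 log|det M|)/dA_ij dA_kl = 2 Binv[j,k] Binv[l,i]
  selA <- which(idx$type == "A")
  iA <- idx$row[selA]; jA <- idx$col[selA]
  Hld <- 2 * g$Binv[jA, iA, drop = FALSE] *
    t(g$Binv[jA, iA, drop = FALSE])
  # element (a,b) must be Binv[jA[a], iA[b]] * Binv[jA[b], iA[a]]:
  # Binv[jA, iA][a, b] = Binv[jA[a], iA[b]]; transpose gives the partner.
  H[selA, selA] <- H[selA, selA] + Hld
  H
}

#' Fit a unified SEM by maximum likelihood
#'
#' Estimates the free contemporaneous (`A`) and lagged (`Phi`) paths of a
#' lag-1 uSEM from the lag-embedded sample covariance, treating the lagged
#' block as saturated/exogenous, with diagonal residual variances. The
#' discrepancy minimized is the standard ML fit function; residual
#' variances are profiled out analytically and the remaining parameters
#' are optimized quasi-Newton (BFGS) with analytic gradients, started from
#' per-equation least squares.
#'
#' @param ts T x p series (NA placeholder rows allowed), or a
#'   precomputed moment list from the internal helper.
#' @param spec a [usem_spec()].
#' @param standardize center/scale each ROI to unit variance before
#'   fitting. Off by default (weights estimated on the observed scale);
#'   enable when ROI scales differ arbitrarily across individuals.
#' @param maxit maximum BFGS iterations.
#' @param reltol relative convergence tolerance on the discrepancy.
#' @return object of class `usem_fit`: estimates `A_hat`, `Phi_hat`,
#'   residual variances `psi_hat`, standard errors `se_A`/`se_Phi` (NA at
#'   fixed elements), `chi2`, `df`, `loglik`, `n_used`, `converged`, plus
#'   the moments and spec needed by [modification_indices()] and
#'   [fit_indices()].
#' @export
fit_usem <- function(ts, spec, standardize = FALSE, maxit = 500,
                     reltol = 1e-10) {
  mom <- if (is.list(ts) && !is.null(ts$S_xx)) ts
         else usem_moments(ts, standardize = standardize)
  p <- spec$p
  if (mom$p != p) stop("spec dimension (", p, ") != series ROI count (",
                       mom$p, ")")
  theta0 <- usem_start(spec, mom)
  npar <- length(theta0)
  if (npar == 0L) {
    opt <- list(par = numeric(0), value = usem_objective(numeric(0), spec, mom),
                convergence = 0L)
  } else {
    opt <- stats::optim(theta0, usem_objective, usem_gradient, spec = spec,
                        mom = mom, method = "BFGS",
                        control = list(maxit = maxit, reltol = reltol))
    # polish: a second pass occasionally shaves the last digits
    if (opt$convergence != 0L) {
      opt2 <- stats::optim(opt$par, usem_objective, usem_gradient, spec = spec,
                           mom = mom, method = "BFGS",
                           control = list(maxit = maxit, reltol = reltol))
      if (opt2$value <= opt$value) opt <- opt2
    }
  }
  if (opt$value >= 1e9)
    stop("uSEM estimation failed: singular (I - A) or non-positive ",
         "residual variance at the terminal step")
  par <- usem_unpack(opt$par, spec)
  V <- usem_resid_var(par$A, par$Phi, mom)
  n <- mom$n_used
  Fmin <- opt$value - mom$logdet_cond
  chi2 <- max((n - 1) * Fmin, 0)
  df <- usem_df(spec)
  # standard errors from the analytic Hessian restricted to free params
  se_A <- matrix(NA_real_, p, p); se_Phi <- matrix(NA_real_, p, p)
  if (npar > 0L) {
    Hfree <- usem_hessian_free(par$A, par$Phi, mom, spec)
    cv <- try(2 / (n - 1) * solve(Hfree), silent = TRUE)
    if (!inherits(cv, "try-error")) {
      se <- sqrt(pmax(diag(cv), 0))
      nA <- sum(spec$free_A)
      se_A[spec$free_A] <- se[seq_len(nA)]
      se_Phi[spec$free_Phi] <- se[nA + seq_len(sum(spec$free_Phi))]
    }
  }
  loglik <- -n / 2 * (sum(log(V)) - 2 * log(abs(det(diag(p) - par$A))) +
                        p * (1 + log(2 * pi)))
  structure(list(A_hat = par$A, Phi_hat = par$Phi, psi_hat = V,
                 se_A = se_A, se_Phi = se_Phi,
                 chi2 = chi2, df = df, F = Fmin, loglik = loglik,
                 n_used = n, converged = opt$convergence == 0L,
                 spec = spec, moments = mom),
            class = "usem_fit")
}

# Extract the rows of the analytic Hessian matching the free mask.
usem_hessian_free <- function(A, Phi, mom, spec) {
  p <- spec$p
  idx <- usem_param_index(p)
  H <- usem_hessian_full(A, Phi, mom)
  free <- c(spec$free_A[cbind(idx$row[idx$type == "A"],
                              idx$col[idx$type == "A"])],
            spec$free_Phi[cbind(idx$row[idx$type == "Phi"],
                                idx$col[idx$type == "Phi"])])
  H[free, free, drop = FALSE]
}

# Per-equation least-squares start: regress y_i on its free predictors.
usem_start <- function(spec, mom) {
  p <- spec$p
  A0 <- matrix(0, p, p); P0 <- matrix(0, p, p)
  Sfull <- rbind(cbind(mom$S_yy, mom$S_yx),
                 cbind(t(mom$S_yx), mom$S_xx))
  for (i in seq_len(p)) {
    predA <- which(spec$free_A[i, ])
    predP <- which(spec$free_Phi[i, ]) + p
    pred <- c(predA, predP)
    if (!length(pred)) next
    G <- Sfull[pred, pred, drop = FALSE]
    b <- tryCatch(solve(G, Sfull[pred, i]), error = function(e)
      rep(0, length(pred)))
    A0[i, predA] <- b[seq_along(predA)]
    P0[i, which(spec$free_Phi[i, ])] <- b[length(predA) + seq_along(predP)]
  }
  c(A0[spec$free_A], P0[spec$free_Phi])
}

# df of the model against the saturated (conditional-regression) model:
# p*p regression slopes + p(p+1)/2 residual (co)variances testable,
# minus free A, free Phi, and the p free residual variances.
usem_df <- function(spec) {
  p <- spec$p
  p * p + p * (p + 1) / 2 - (sum(spec$free_A) + sum(spec$free_Phi) + p)
}

#' Modification indices for fixed uSEM paths
#'
#' Score (Lagrange multiplier) tests for every currently-fixed
#' contemporaneous and lagged path: each MI approximates the drop in the
#' model chi-square that freeing that one element would produce, together
#' with the expected parameter change (EPC).
#'
#' @param fit a converged [fit_usem()] result.
#' @return data frame with columns `type` ("A"/"Phi"), `from`, `to`,
#'   `mi`, `epc`, sorted by decreasing MI.
#' @export
modification_indices <- function(fit) {
  stopifnot(inherits(fit, "usem_fit"))
  spec <- fit$spec; mom <- fit$moments; p <- spec$p
  idx <- usem_param_index(p)
  g <- usem_gradient_full(fit$A_hat, fit$Phi_hat, mom)
  gvec <- c(g$gA[cbind(idx$row[seq_len(idx$nA)], idx$col[seq_len(idx$nA)])],
            as.vector(g$gPhi))
  H <- usem_hessian_full(fit$A_hat, fit$Phi_hat, mom)
  isA <- idx$type == "A"
  free <- logical(length(gvec))
  free[isA] <- spec$free_A[cbind(idx$row[isA], idx$col[isA])]
  free[!isA] <- spec$free_Phi[cbind(idx$row[!isA], idx$col[!isA])]
  cand <- which(!free)
  if (!length(cand))
    return(data.frame(type = character(), from = integer(), to = integer(),
                      mi = numeric(), epc = numeric()))
  n <- mom$n_used
  if (any(free)) {
    HFF <- H[free, free, drop = FALSE]
    HcF <- H[cand, free, drop = FALSE]
    sol <- try(solve(HFF, t(HcF)), silent = TRUE)
    red <- if (inherits(sol, "try-error")) 0 else rowSums(HcF * t(sol))
  } else red <- 0
  htil <- diag(H)[cand] - red
  gc <- gvec[cand]
  mi <- ifelse(htil > 1e-10, (n - 1) * gc^2 / (2 * htil), 0)
  epc <- ifelse(htil > 1e-10, -gc / htil, NA_real_)
  out <- data.frame(type = idx$type[cand],
                    from = idx$col[cand], to = idx$row[cand],
                    mi = pmax(mi, 0), epc = epc)
  out[order(-out$mi), , drop = FALSE]
}

#' Fit indices for a uSEM
#'
#' RMSEA, SRMR, CFI and NNFI computed against an AR-only null model (the
#' conventional baseline for time-series SEM). With zero degrees of
#' freedom the incremental and RMSEA indices are flagged undefined.
#'
#' @param fit fitted model, a `usem_fit`.
#' @param null_fit baseline fit (AR-only uSEM on the same moments). If
#'   omitted it is fitted internally.
#' @return object of class `usem_fit_indices`: `rmsea`, `srmr`, `cfi`,
#'   `nnfi`, and `defined` (FALSE when df = 0).
#' @export
fit_indices <- function(fit, null_fit = NULL) {
  stopifnot(inherits(fit, "usem_fit"))
  mom <- fit$moments; p <- fit$spec$p; n <- fit$n_used
  if (is.null(null_fit))
    null_fit <- fit_usem(mom, usem_spec(p))
  chi2 <- fit$chi2; df <- fit$df
  chi2n <- null_fit$chi2; dfn <- null_fit$df
  defined <- df > 0
  rmsea <- if (defined) sqrt(max(chi2 - df, 0) / (df * (n - 1))) else NA_real_
  cfi <- if (defined) 1 - max(chi2 - df, 0) / max(chi2n - dfn, chi2 - df, 0)
         else NA_real_
  nnfi <- if (defined && dfn > 0 && chi2n / dfn > 1)
    ((chi2n / dfn) - (chi2 / df)) / ((chi2n / dfn) - 1) else NA_real_
  # SRMR over the standardized residuals of the implied y-side blocks
  M <- diag(p) - fit$A_hat
  B <- solve(M)
  Pi <- B %*% fit$Phi_hat
  Omega <- B %*% diag(fit$psi_hat, p) %*% t(B)
  Sig_yy <- Pi %*% mom$S_xx %*% t(Pi) + Omega
  Sig_yx <- Pi %*% mom$S_xx
  dyy <- (mom$S_yy - Sig_yy) /
    sqrt(tcrossprod(diag(mom$S_yy)))
  dyx <- (mom$S_yx - Sig_yx) /
    sqrt(outer(diag(mom$S_yy), diag(mom$S_xx)))
  res <- c(dyy[upper.tri(dyy, diag = TRUE)], as.vector(dyx))
  srmr <- sqrt(mean(res^2))
  structure(list(rmsea = rmsea, srmr = srmr, cfi = cfi, nnfi = nnfi,
                 defined = defined),
            class = "usem_fit_indices")
}

#' Excellent-fit rule
#'
#' Standard two-of-four convention: a model fits excellently when at least
#' `n_required` of rmsea <= .05, srmr <= .05, cfi >= .95, nnfi >= .95
#' hold. Undefined indices count as not met.
#'
#' @param ix a [fit_indices()] result.
#' @param n_required how many criteria must hold (default 2).
#' @param cutoffs named list overriding the four cutoffs.
#' @return logical.
#' @export
excellent_fit <- function(ix, n_required = 2,
                          cutoffs = list(rmsea = .05, srmr = .05,
                                         cfi = .95, nnfi = .95)) {
  met <- c(isTRUE(ix$rmsea <= cutoffs$rmsea),
           isTRUE(ix$srmr <= cutoffs$srmr),
           isTRUE(ix$cfi >= cutoffs$cfi),
           isTRUE(ix$nnfi >= cutoffs$nnfi))
  sum(met) >= n_required
}

#' @export
print.usem_fit <- function(x, ...) {
  cat("<usem_fit> p = ", x$spec$p, ", free A = ", sum(x$spec$free_A),
      ", free Phi = ", sum(x$spec$free_Phi), "\n", sep = "")
  cat("  chi2 = ", format(x$chi2, digits = 5), " on df = ", x$df,
      ", n_used = ", x$n_used,
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}
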