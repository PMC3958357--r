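#' Compare group-path weights across subgroups
#'
#' For every group-level contemporaneous path: a one-way omnibus ANOVA of
#' the beta weights across subgroups, followed by one contrast per
#' subgroup comparing its mean against the pooled members of all other
#' subgroups (two-sample pooled-variance t test). False discovery rate
#' control is applied jointly across all path x subgroup contrasts, and
#' each contrast receives a verdict: `higher` or `lower` when its q-value
#' is at or below `alpha` (signed by the mean difference), otherwise
#' `similar`.
#'
#' @param betas N x k matrix of group-path betas ([vectorize_betas()]).
#' @param partition subgroup assignment (`partition` or label vector).
#' @param alpha FDR level (default 0.05).
#' @param method FDR method passed to [fdr_correct()].
#' @return object of class `path_comparison`: data frame `contrasts`
#'   (path, subgroup, means, t, df, p, q, verdict) and data frame
#'   `anova` (path, F, df1, df2, p). Contrasts for singleton subgroups
#'   are flagged untestable (NA statistics, verdict `untestable`).
#' @export
compare_subgroup_paths <- function(betas, partition, alpha = 0.05,
                                   method = c("storey", "bh")) {
  method <- match.arg(method)
  betas <- as.matrix(betas)
  labels <- if (inherits(partition, "partition")) partition$membership
            else as.integer(as.factor(partition))
  if (length(labels) != nrow(betas))
    stop("partition length != number of individuals")
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need >= 2 subgroups to compare")
  paths <- colnames(betas)
  if (is.null(paths)) paths <- paste0("path", seq_len(ncol(betas)))

  an <- do.call(rbind, lapply(seq_len(ncol(betas)), function(k) {
    # anova on lm rather than oneway.test: tolerates singleton subgroups
    tab <- stats::anova(stats::lm(betas[, k] ~ factor(labels)))
    data.frame(path = paths[k], F = tab$`F value`[1],
               df1 = tab$Df[1], df2 = tab$Df[2], p = tab$`Pr(>F)`[1])
  }))

  rows <- list()
  for (k in seq_len(ncol(betas))) {
    for (g in groups) {
      ing <- betas[labels == g, k]
      outg <- betas[labels != g, k]
      if (length(ing) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          path = paths[k], subgroup = g, mean_subgroup = mean(ing),
          mean_others = mean(outg), t = NA_real_, df = NA_real_,
          p = NA_real_)
        next
      }
      tt <- stats::t.test(ing, outg, var.equal = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        path = paths[k], subgroup = g, mean_subgroup = mean(ing),
        mean_others = mean(outg), t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value)
    }
  }
  con <- do.call(rbind, rows)
  con$q <- NA_real_
  testable <- !is.na(con$p)
  con$q[testable] <- fdr_correct(con$p[testable], method = method)
  con$verdict <- ifelse(!testable, "untestable",
                 ifelse(con$q > alpha, "similar",
                 ifelse(con$mean_subgroup > con$mean_others,
                        "higher", "lower")))
  structure(list(contrasts = con, anova = an, alpha = alpha,
                 method = method),
            class = "path_comparison")
}

#' @export
print.path_comparison <- function(x, ...) {
  ns <- sum(x$contrasts$verdict %in% c("higher", "lower"))
  cat("<path_comparison> ", nrow(x$contrasts), " contrasts (",
      length(unique(x$contrasts$path)), " paths x ",
      length(unique(x$contrasts$subgroup)), " subgroups), ", ns,
      " significant at q <= ", x$alpha, " [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Two-group diagnostic comparison of path weights
#'
#' The conventional analysis that subgrouping is meant to improve on:
#' compare each path's betas between two a-priori diagnostic groups
#' (e.g. case vs control) with two-sample t tests and FDR correction
#' across paths.
#'
#' @param betas N x k beta matrix.
#' @param labels binary diagnostic label per individual (factor, logical
#'   or two-valued vector).
#' @param alpha FDR level.
#' @param method FDR method.
#' @return data frame: path, group means, t, df, p, q, significant.
#' @export
diagnostic_comparison <- function(betas, labels, alpha = 0.05,
                                  method = c("storey", "bh")) {
  method <- match.arg(method)
  betas <- as.matrix(betas)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("`labels` must have exactly 2 levels")
  paths <- colnames(betas)
  if (is.null(paths)) paths <- paste0("path", seq_len(ncol(betas)))
  out <- do.call(rbind, lapply(seq_len(ncol(betas)), function(k) {
    a <- betas[labels == levels(labels)[1], k]
    b <- betas[labels == levels(labels)[2], k]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(path = paths[k], mean_1 = mean(a), mean_2 = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  out$q <- fdr_correct(out$p, method = method)
  out$significant <- out$q <= alpha
  out
}

#' False discovery rate correction (Storey q-values)
#'
#' Converts p-values to q-values. The default is Storey's method with the
#' proportion of true nulls `pi0` estimated by the natural-spline
#' smoother over `lambda = 0.05, ..., 0.95`; `method = "bh"` gives
#' Benjamini-Hochberg (equivalent to `pi0 = 1`). With too few p-values
#' to smooth, `pi0` falls back to 1 (conservative).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param method `"storey"` (default) or `"bh"`.
#' @param lambda grid for the `pi0` smoother.
#' @return q-values in the order of the input, with attribute `pi0`.
#' @export
fdr_correct <- function(pvalues, method = c("storey", "bh"),
                        lambda = seq(0.05, 0.95, by = 0.05)) {
  method <- match.arg(method)
  p <- as.numeric(pvalues)
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  pi0 <- 1
  if (method == "storey" && m >= 2 * length(lambda)) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    fit <- try(stats::smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
    est <- if (inherits(fit, "try-error")) min(pi0_l)
           else stats::predict(fit, x = max(lambda))$y
    pi0 <- min(1, max(est, 1 / m))
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  structure(q, pi0 = pi0)
}
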