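#' Group-level iterative path search
#'
#' First stage of the GIMME procedure: starting from an autoregressive
#' baseline (AR paths freed a priori for everyone and never pruned), the
#' search looks across individuals to separate signal from noise.
#' Iteratively, every individual's uSEM is fitted under the current
#' pattern and modification indices are computed for each still-fixed
#' candidate path; the path whose MI exceeds the Bonferroni-corrected
#' chi-square(1) critical value for the largest number of individuals is
#' freed, provided that count reaches `gamma * N` (ties: larger summed
#' MI). The search stops when no candidate clears the majority criterion.
#' Freed group paths whose estimate is non-significant (at `alpha`) for
#' more than `(1 - gamma) * N` individuals are then pruned, refitting
#' after each removal.
#'
#' @param panel a [ts_panel()].
#' @param gamma majority proportion in (0.5, 1]; default 0.75.
#' @param alpha significance level for the MI criterion and pruning.
#' @param standardize standardize each ROI series to zero mean and unit
#'   variance before fitting. Off by default: raw weights keep the
#'   similarity features free of stationary-variance confounds; enable it
#'   when ROI scales are not comparable across individuals.
#' @param max_add safety cap on the number of freed paths.
#' @param verbose print progress?
#' @return object of class `group_map`: logical masks `free_A`,
#'   `free_Phi`, the add/prune history, and the IDs of any individuals
#'   excluded for persistent non-convergence.
#' @export
run_group_search <- function(panel, gamma = 0.75, alpha = 0.05,
                             standardize = FALSE, max_add = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(panel, "ts_panel"))
  if (length(panel) < 2L) stop("group search needs >= 2 individuals")
  if (gamma <= 0.5 || gamma > 1) stop("gamma must lie in (0.5, 1]")
  p <- panel$p
  if (is.null(max_add)) max_add <- p * (p - 1)

  moments <- list()
  excluded <- character(0)
  for (id in panel$ids) {
    mom <- try(usem_moments(panel$series[[id]], standardize = standardize),
               silent = TRUE)
    if (inherits(mom, "try-error")) {
      warning("individual ", id, " excluded: ",
              attr(mom, "condition")$message)
      excluded <- c(excluded, id)
    } else moments[[id]] <- mom
  }
  N <- length(moments)
  if (N < 2L) stop("fewer than 2 usable individuals")

  spec <- usem_spec(p)  # AR-only start
  history <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    n_cand <- sum(!spec$free_A) - p + sum(!spec$free_Phi)
    if (n_cand == 0L || sum(spec$free_A) + sum(spec$free_Phi) - p >= max_add)
      break
    crit <- stats::qchisq(1 - alpha / n_cand, df = 1)
    counts <- NULL; misum <- NULL; keys <- NULL
    for (id in names(moments)) {
      fit <- try(fit_usem(moments[[id]], spec), silent = TRUE)
      if (inherits(fit, "try-error")) next
      mi <- modification_indices(fit)
      key <- paste(mi$type, mi$from, mi$to)
      if (is.null(counts)) {
        keys <- key
        counts <- stats::setNames(numeric(length(key)), key)
        misum <- counts
        mi_meta <- mi[c("type", "from", "to")]
      }
      hit <- mi$mi > crit
      counts[key] <- counts[key] + hit
      misum[key] <- misum[key] + mi$mi
    }
    if (is.null(counts) || max(counts) < gamma * N) break
    top <- which(counts == max(counts))
    best <- top[which.max(misum[top])]
    # Reciprocal-pair rule: the two directions of one contemporaneous pair
    # may not both enter in one step. The count criterion establishes that
    # the pair carries signal for the majority; the orientation is then
    # decided by the larger summed MI across individuals, since both
    # directions tap the same missing covariance and the MI mass
    # concentrates on the generating direction.
    meta_key <- paste(mi_meta$type, mi_meta$from, mi_meta$to)
    sel <- match(names(counts)[best], meta_key)
    if (mi_meta$type[sel] == "A") {
      recip <- match(paste("A", mi_meta$to[sel], mi_meta$from[sel]), meta_key)
      if (!is.na(recip) && misum[recip] > misum[best]) {
        best <- recip
        sel <- match(names(counts)[best], meta_key)
      }
    }
    type <- mi_meta$type[sel]; from <- mi_meta$from[sel]; to <- mi_meta$to[sel]
    if (type == "A") spec$free_A[to, from] <- TRUE
    else spec$free_Phi[to, from] <- TRUE
    history[[length(history) + 1L]] <-
      data.frame(action = "add", type = type, from = from, to = to,
                 count = unname(counts[best]), iteration = iter)
    if (verbose)
      message("iter ", iter, ": freed ", type, " ", from, "->", to,
              " (", counts[best], "/", N, " individuals)")
  }

  # prune group paths non-significant for too many individuals
  repeat {
    cand <- group_path_list(spec)
    if (!nrow(cand)) break
    nonsig <- numeric(nrow(cand))
    for (id in names(moments)) {
      fit <- try(fit_usem(moments[[id]], spec), silent = TRUE)
      if (inherits(fit, "try-error")) next
      for (r in seq_len(nrow(cand))) {
        est <- if (cand$type[r] == "A") fit$A_hat[cand$to[r], cand$from[r]]
               else fit$Phi_hat[cand$to[r], cand$from[r]]
        se <- if (cand$type[r] == "A") fit$se_A[cand$to[r], cand$from[r]]
              else fit$se_Phi[cand$to[r], cand$from[r]]
        z <- if (is.na(se) || se == 0) 0 else est / se
        if (2 * stats::pnorm(-abs(z)) > alpha) nonsig[r] <- nonsig[r] + 1
      }
    }
    worst <- which.max(nonsig)
    if (nonsig[worst] <= (1 - gamma) * N) break
    r <- worst
    if (cand$type[r] == "A") spec$free_A[cand$to[r], cand$from[r]] <- FALSE
    else spec$free_Phi[cand$to[r], cand$from[r]] <- FALSE
    history[[length(history) + 1L]] <-
      data.frame(action = "prune", type = cand$type[r], from = cand$from[r],
                 to = cand$to[r], count = nonsig[r], iteration = iter)
    if (verbose)
      message("pruned ", cand$type[r], " ", cand$from[r], "->", cand$to[r],
              " (non-significant for ", nonsig[r], "/", N, ")")
  }

  structure(list(free_A = spec$free_A, free_Phi = spec$free_Phi,
                 add_history = if (length(history)) do.call(rbind, history)
                               else data.frame(),
                 gamma = gamma, alpha = alpha, excluded = excluded,
                 standardize = standardize),
            class = "group_map")
}

# Freed group paths other than the a-priori AR diagonal.
group_path_list <- function(spec) {
  a <- which(spec$free_A, arr.ind = TRUE)
  ph <- which(spec$free_Phi & !diag(nrow(spec$free_Phi)), arr.ind = TRUE)
  rbind(
    if (nrow(a)) data.frame(type = "A", from = a[, 2], to = a[, 1]),
    if (nrow(ph)) data.frame(type = "Phi", from = ph[, 2], to = ph[, 1]),
    data.frame(type = character(), from = integer(), to = integer()))
}

#' @export
print.group_map <- function(x, ...) {
  cat("<group_map> ", sum(x$free_A), " contemporaneous + ",
      sum(x$free_Phi & !diag(nrow(x$free_Phi))),
      " lagged group paths (+ AR diagonal)\n", sep = "")
  gp <- group_path_list(x)
  if (nrow(gp))
    cat("  ", paste0(gp$from, "->", gp$to,
                     ifelse(gp$type == "Phi", " (lag)", ""),
                     collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Individual-level path search
#'
#' Second stage of GIMME: starting from the group map, each individual's
#' model is augmented with the largest-MI candidate path exceeding the
#' Bonferroni-corrected chi-square(1) critical value, repeatedly, until
#' the model reaches excellent fit (two-of-four rule, see
#' [excellent_fit()]) or no candidate qualifies. Individual-level paths
#' (never group-level paths or the AR diagonal) that end up
#' non-significant are then pruned, least significant first.
#'
#' @param panel a [ts_panel()].
#' @param group_map a [run_group_search()] result.
#' @param alpha significance level.
#' @param max_add cap on individual-level additions per person.
#' @return object of class `connectivity_maps`: per-individual `usem_fit`
#'   list `fits`, masks of individual-specific paths, fit indices, and
#'   the group map.
#' @export
run_individual_search <- function(panel, group_map, alpha = 0.05,
                                  max_add = NULL) {
  stopifnot(inherits(panel, "ts_panel"), inherits(group_map, "group_map"))
  p <- panel$p
  if (is.null(max_add)) max_add <- p * (p - 1)
  ids <- setdiff(panel$ids, group_map$excluded)
  fits <- vector("list", length(ids)); names(fits) <- ids
  indiv_A <- vector("list", length(ids)); names(indiv_A) <- ids
  indiv_Phi <- vector("list", length(ids)); names(indiv_Phi) <- ids
  indices <- vector("list", length(ids)); names(indices) <- ids
  failed <- character(0)

  for (id in ids) {
    mom <- usem_moments(panel$series[[id]],
                        standardize = group_map$standardize)
    null_fit <- fit_usem(mom, usem_spec(p))
    spec <- usem_spec(p, free_A = group_map$free_A,
                      free_Phi = group_map$free_Phi)
    fit <- try(fit_usem(mom, spec), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning("individual ", id, " failed to fit under the group map; ",
              "excluded")
      failed <- c(failed, id)
      next
    }
    added <- 0L
    repeat {
      ix <- fit_indices(fit, null_fit)
      if (excellent_fit(ix) || added >= max_add) break
      mi <- modification_indices(fit)
      if (!nrow(mi)) break
      crit <- stats::qchisq(1 - alpha / nrow(mi), df = 1)
      mi <- mi[mi$mi > crit, , drop = FALSE]
      if (!nrow(mi)) break
      b <- mi[1L, ]  # already sorted by decreasing MI
      if (b$type == "A") spec$free_A[b$to, b$from] <- TRUE
      else spec$free_Phi[b$to, b$from] <- TRUE
      newfit <- try(fit_usem(mom, spec), silent = TRUE)
      if (inherits(newfit, "try-error")) {  # rescind the addition
        if (b$type == "A") spec$free_A[b$to, b$from] <- FALSE
        else spec$free_Phi[b$to, b$from] <- FALSE
        break
      }
      fit <- newfit
      added <- added + 1L
    }
    # prune non-significant individual-level paths
    repeat {
      extra_A <- spec$free_A & !group_map$free_A
      extra_P <- spec$free_Phi & !group_map$free_Phi
      pa <- which(extra_A, arr.ind = TRUE)
      pp <- which(extra_P, arr.ind = TRUE)
      if (!nrow(pa) && !nrow(pp)) break
      pv <- c(
        if (nrow(pa)) 2 * stats::pnorm(-abs(fit$A_hat[pa] / fit$se_A[pa])),
        if (nrow(pp)) 2 * stats::pnorm(-abs(fit$Phi_hat[pp] / fit$se_Phi[pp])))
      pv[is.na(pv)] <- 1
      if (max(pv) <= alpha) break
      w <- which.max(pv)
      if (w <= nrow(pa)) spec$free_A[pa[w, 1], pa[w, 2]] <- FALSE
      else {
        w2 <- w - nrow(pa)
        spec$free_Phi[pp[w2, 1], pp[w2, 2]] <- FALSE
      }
      fit <- fit_usem(mom, spec)
    }
    fits[[id]] <- fit
    indiv_A[[id]] <- spec$free_A & !group_map$free_A
    indiv_Phi[[id]] <- spec$free_Phi & !group_map$free_Phi
    indices[[id]] <- fit_indices(fit, null_fit)
  }
  keep <- setdiff(ids, failed)
  structure(list(fits = fits[keep], individual_A = indiv_A[keep],
                 individual_Phi = indiv_Phi[keep], fit_indices = indices[keep],
                 group_map = group_map, ids = keep,
                 excluded = c(group_map$excluded, failed)),
            class = "connectivity_maps")
}

#' @export
print.connectivity_maps <- function(x, ...) {
  nextra <- vapply(x$ids, function(id)
    sum(x$individual_A[[id]]) + sum(x$individual_Phi[[id]]), 0)
  cat("<connectivity_maps> ", length(x$ids), " individuals; ",
      sum(x$group_map$free_A), " group contemporaneous paths; ",
      "individual-level additions: median ", stats::median(nextra),
      " (range ", min(nextra), "-", max(nextra), ")\n", sep = "")
  invisible(x)
}

#' Run the full two-stage GIMME search
#'
#' Convenience wrapper: [run_group_search()] followed by
#' [run_individual_search()].
#'
#' @inheritParams run_group_search
#' @inheritParams run_individual_search
#' @return a `connectivity_maps` object.
#' @export
gimme <- function(panel, gamma = 0.75, alpha = 0.05, standardize = FALSE,
                  verbose = FALSE) {
  gm <- run_group_search(panel, gamma = gamma, alpha = alpha,
                         standardize = standardize, verbose = verbose)
  run_individual_search(panel, gm, alpha = alpha)
}

#' Score recovery of true connections
#'
#' Fraction of true generating connections (contemporaneous, lagged and
#' autoregressive) that the estimated maps recover with correct presence
#' and direction, pooled over all individuals of a panel.
#'
#' @param maps a `connectivity_maps` object.
#' @param truth a `sim_truth` object from [generate_panel()].
#' @return proportion in `[0, 1]`, with attribute `per_individual`.
#' @export
recovery_accuracy <- function(maps, truth) {
  stopifnot(inherits(maps, "connectivity_maps"), inherits(truth, "sim_truth"))
  ids <- maps$ids
  idx <- match(ids, truth$ids)
  if (anyNA(idx))
    stop("connectivity maps contain individuals absent from the ground truth")
  per <- numeric(length(ids))
  hit_total <- 0; n_total <- 0
  for (k in seq_along(ids)) {
    i <- idx[k]
    fit <- maps$fits[[k]]
    estA <- fit$spec$free_A
    estP <- fit$spec$free_Phi
    trueA <- truth$true_A[[i]] != 0
    trueP <- truth$true_Phi[[i]] != 0
    hits <- sum(estA & trueA) + sum(estP & trueP)
    n <- sum(trueA) + sum(trueP)
    per[k] <- hits / n
    hit_total <- hit_total + hits; n_total <- n_total + n
  }
  structure(hit_total / n_total, per_individual = per)
}
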