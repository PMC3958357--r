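#' Monte Carlo simulation design for subgroup-structured connectivity
#'
#' Describes a population of individuals whose region-of-interest (ROI)
#' time series arise from a structural vector autoregression
#' `y_t = A y_t + Phi y_{t-1} + zeta_t`: every ROI carries an
#' autoregressive effect (diagonal of `Phi`), a common set of
#' contemporaneous directed paths (entries of `A`) is shared by the whole
#' sample, each subgroup shifts three of those shared paths up or down by
#' `deviation`, and each subgroup additionally owns one unique
#' contemporaneous path that is present in any given member with
#' probability `unique_prob` (Bernoulli, adding individual-level
#' heterogeneity within subgroups).
#'
#' The defaults reproduce the reference Monte Carlo conditions: 100
#' individuals, 10 ROIs, series of 200 scans, autoregressive weight 0.60,
#' nine shared contemporaneous paths of weight 0.50, subgroup deviations of
#' +/- 0.20 on three paths each, and unique-path probability 0.5. The
#' number and size of subgroups are configurable; the default is four
#' equal subgroups.
#'
#' Paths are directed `from -> to` pairs, i.e. the value of ROI `from`
#' predicts ROI `to` at the same scan; the weight sits in row `to`,
#' column `from` of `A`.
#'
#' @param n_individuals number of individuals in the panel.
#' @param n_rois number of ROIs (p).
#' @param n_timepoints series length after burn-in (number of scans).
#' @param ar_weight autoregressive weight shared by all ROIs.
#' @param base_beta weight of the shared contemporaneous paths.
#' @param deviation absolute shift applied to a subgroup's deviant paths.
#' @param group_paths integer matrix with columns `from`, `to`: the
#'   contemporaneous paths present for every individual. The default is a
#'   nine-path chain `1 -> 2 -> ... -> 10`.
#' @param n_subgroups number of subgroups.
#' @param subgroup_sizes integer vector of subgroup sizes summing to
#'   `n_individuals`; default equal split.
#' @param subgroup_deviations list (one element per subgroup) of data
#'   frames with columns `path` (row index into `group_paths`) and `sign`
#'   (+1/-1). Exactly three deviant paths per subgroup. The default cycles
#'   consecutive triples of the shared paths with alternating sign
#'   patterns so that subgroups are pairwise distinct.
#' @param unique_paths integer matrix (`n_subgroups` x 2, columns
#'   `from`,`to`): each subgroup's unique contemporaneous path; must not be
#'   a shared path.
#' @param unique_prob probability that a subgroup member carries the
#'   subgroup's unique path.
#' @param unique_beta weight of the unique path (default `base_beta`).
#' @param noise_sd standard deviation of the Gaussian process noise.
#' @param burn_in number of initial samples discarded per series.
#' @param seed optional integer seed making `generate_panel()` reproducible.
#' @return An object of class `sim_design`.
#' @seealso [generate_panel()], [generate_individual()]
#' @export
simulation_design <- function(n_individuals = 100,
                              n_rois = 10,
                              n_timepoints = 200,
                              ar_weight = 0.60,
                              base_beta = 0.50,
                              deviation = 0.20,
                              group_paths = NULL,
                              n_subgroups = 4,
                              subgroup_sizes = NULL,
                              subgroup_deviations = NULL,
                              unique_paths = NULL,
                              unique_prob = 0.5,
                              unique_beta = base_beta,
                              noise_sd = 1.0,
                              burn_in = 200,
                              seed = NULL) {
  p <- as.integer(n_rois)
  if (is.null(group_paths)) {
    if (p < 10) stop("default group paths need >= 10 ROIs; supply `group_paths`")
    group_paths <- cbind(from = 1:9, to = 2:10)
  }
  group_paths <- as.matrix(group_paths)
  colnames(group_paths) <- c("from", "to")
  k <- nrow(group_paths)

  if (is.null(subgroup_sizes)) {
    if (n_individuals %% n_subgroups != 0)
      stop("n_individuals (", n_individuals, ") not divisible into ",
           n_subgroups, " equal subgroups; supply `subgroup_sizes`")
    subgroup_sizes <- rep(n_individuals / n_subgroups, n_subgroups)
  }
  if (sum(subgroup_sizes) != n_individuals)
    stop("subgroup_sizes must sum to n_individuals")

  if (is.null(subgroup_deviations))
    subgroup_deviations <- default_deviations(n_subgroups, k)
  if (is.null(unique_paths))
    unique_paths <- default_unique_paths(n_subgroups, p, group_paths,
                                         subgroup_deviations)
  unique_paths <- as.matrix(unique_paths)
  colnames(unique_paths) <- c("from", "to")

  design <- structure(
    list(n_individuals = as.integer(n_individuals), n_rois = p,
         n_timepoints = as.integer(n_timepoints), ar_weight = ar_weight,
         base_beta = base_beta, deviation = deviation,
         group_paths = group_paths, n_subgroups = as.integer(n_subgroups),
         subgroup_sizes = as.integer(subgroup_sizes),
         subgroup_deviations = subgroup_deviations,
         unique_paths = unique_paths, unique_prob = unique_prob,
         unique_beta = unique_beta, noise_sd = noise_sd,
         burn_in = as.integer(burn_in), seed = seed),
    class = "sim_design")
  validate_design(design)
  design
}

# Consecutive triples of shared-path indices (mod k) with alternating sign
# patterns; guarantees pairwise-distinct subgroups for up to 2*floor(k/3).
default_deviations <- function(n_subgroups, k) {
  lapply(seq_len(n_subgroups), function(s) {
    idx <- ((s - 1L) * 3L + 0:2) %% k + 1L
    sgn <- if (s %% 2 == 1) c(1, -1, 1) else c(-1, 1, -1)
    data.frame(path = idx, sign = sgn)
  })
}

# One unique ordered pair per subgroup, avoiding shared paths and their
# reciprocals. The target ROI is chosen so that no shared path incident to
# it is among that subgroup's own deviant paths: the unique path perturbs
# the (standardized) weights of paths flowing through its target, and the
# within-subgroup heterogeneity it encodes should not mask the features
# that define the subgroup. Sources sit >= 2 ROIs upstream, keeping the
# default system acyclic.
default_unique_paths <- function(n_subgroups, p, group_paths, deviations) {
  key <- function(f, t) paste(f, t, sep = ">")
  blocked <- c(key(group_paths[, 1], group_paths[, 2]),
               key(group_paths[, 2], group_paths[, 1]))
  out <- matrix(NA_integer_, n_subgroups, 2)
  taken_t <- integer(0)
  pick <- function(s, avoid_incident, distinct_target) {
    dev_idx <- deviations[[s]]$path
    for (t in p:1) {
      if (distinct_target && t %in% taken_t) next
      incident <- which(group_paths[, 1] == t | group_paths[, 2] == t)
      if (avoid_incident && any(incident %in% dev_idx)) next
      for (f in c(t - 4, t - 3, t - 2, t + 2, t + 3, t + 4)) {
        if (f < 1 || f > p || f == t) next
        if (key(f, t) %in% blocked) next
        return(c(f, t))
      }
    }
    NULL
  }
  for (s in seq_len(n_subgroups)) {
    cand <- pick(s, TRUE, TRUE)
    if (is.null(cand)) cand <- pick(s, TRUE, FALSE)
    if (is.null(cand)) cand <- pick(s, FALSE, FALSE)
    if (is.null(cand)) stop("no ordered ROI pair left for a unique path")
    out[s, ] <- cand
    taken_t <- c(taken_t, cand[2])
    blocked <- c(blocked, key(cand[1], cand[2]))
  }
  out
}

#' Build the true weight matrices for one subgroup
#'
#' @param design a `sim_design`.
#' @param subgroup subgroup index.
#' @param has_unique include the subgroup's unique path?
#' @return list with contemporaneous matrix `A` and lagged matrix `Phi`
#'   (weights in row `to`, column `from`).
#' @export
true_maps <- function(design, subgroup, has_unique = FALSE) {
  p <- design$n_rois
  A <- matrix(0, p, p)
  gp <- design$group_paths
  A[cbind(gp[, "to"], gp[, "from"])] <- design$base_beta
  dev <- design$subgroup_deviations[[subgroup]]
  for (r in seq_len(nrow(dev))) {
    pr <- gp[dev$path[r], ]
    A[pr["to"], pr["from"]] <- design$base_beta + dev$sign[r] * design$deviation
  }
  if (has_unique) {
    up <- design$unique_paths[subgroup, ]
    A[up["to"], up["from"]] <- design$unique_beta
  }
  Phi <- diag(design$ar_weight, p)
  list(A = A, Phi = Phi)
}

validate_design <- function(design) {
  k <- nrow(design$group_paths)
  p <- design$n_rois
  if (any(design$group_paths < 1L) || any(design$group_paths > p))
    stop("group_paths reference ROIs outside 1..", p)
  if (any(design$group_paths[, 1] == design$group_paths[, 2]))
    stop("group_paths may not be self-loops")
  if (length(design$subgroup_deviations) != design$n_subgroups)
    stop("need one deviation set per subgroup")
  gp_key <- paste(design$group_paths[, 1], design$group_paths[, 2])
  for (s in seq_len(design$n_subgroups)) {
    dev <- design$subgroup_deviations[[s]]
    if (nrow(dev) != 3L)
      stop("subgroup ", s, ": exactly 3 deviant paths required, got ",
           nrow(dev))
    if (any(dev$path < 1L | dev$path > k))
      stop("subgroup ", s, ": deviant paths must index group_paths")
    if (anyDuplicated(dev$path))
      stop("subgroup ", s, ": duplicated deviant path")
    up <- design$unique_paths[s, ]
    if (paste(up[1], up[2]) %in% gp_key)
      stop("subgroup ", s, ": unique path duplicates a group path")
    if (up[1] == up[2]) stop("subgroup ", s, ": unique path is a self-loop")
    for (hu in c(FALSE, TRUE)) {
      maps <- true_maps(design, s, has_unique = hu)
      M <- diag(p) - maps$A
      if (abs(det(M)) < 1e-10)
        stop("subgroup ", s, ": (I - A) is singular",
             if (hu) " once the unique path is included")
      rho <- max(Mod(eigen(solve(M, maps$Phi), only.values = TRUE)$values))
      if (rho >= 1)
        stop("subgroup ", s, ": unstable system (spectral radius ",
             signif(rho, 4), " >= 1)",
             if (hu) " once the unique path is included")
    }
  }
  # Pairwise-distinct subgroup maps
  sig <- vapply(seq_len(design$n_subgroups), function(s)
    paste(true_maps(design, s)$A, collapse = ","), "")
  if (anyDuplicated(sig))
    warning("some subgroups share identical true maps")
  invisible(design)
}

#' @export
print.sim_design <- function(x, ...) {
  cat("<sim_design> ", x$n_individuals, " individuals in ",
      x$n_subgroups, " subgroups (", paste(x$subgroup_sizes, collapse = "/"),
      "), ", x$n_rois, " ROIs, T = ", x$n_timepoints, "\n", sep = "")
  cat("  AR ", x$ar_weight, ", ", nrow(x$group_paths),
      " shared contemporaneous paths at ", x$base_beta,
      " (3/subgroup deviate by ±", x$deviation, "),\n", sep = "")
  cat("  one unique path per subgroup with probability ", x$unique_prob,
      "\n", sep = "")
  invisible(x)
}
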