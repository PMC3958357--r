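#' Simulate one individual's ROI time series
#'
#' Draws a series from the reduced form of the structural VAR,
#' `y_t = (I - A)^{-1} (Phi y_{t-1} + zeta_t)` with
#' `zeta_t ~ N(0, noise_sd^2 I)`, starting from a zero state and
#' discarding `design$burn_in` initial samples. Whether the individual
#' carries the subgroup's unique contemporaneous path is drawn with
#' probability `design$unique_prob` unless forced via `has_unique`.
#'
#' Uses R's global random number stream; seed upstream (or via
#' `design$seed` through [generate_panel()]) for reproducibility.
#'
#' @param design a [simulation_design()].
#' @param subgroup subgroup index of the individual.
#' @param has_unique logical; force unique-path presence instead of
#'   drawing it.
#' @return T x p numeric matrix with attributes `has_unique`, `A`, `Phi`
#'   (the generating weight matrices).
#' @export
generate_individual <- function(design, subgroup, has_unique = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (subgroup < 1L || subgroup > design$n_subgroups)
    stop("subgroup index out of range")
  if (is.null(has_unique))
    has_unique <- stats::runif(1) < design$unique_prob
  maps <- true_maps(design, subgroup, has_unique = has_unique)
  y <- simulate_svar(maps$A, maps$Phi, design$n_timepoints,
                     noise_sd = design$noise_sd, burn_in = design$burn_in)
  attr(y, "has_unique") <- has_unique
  attr(y, "A") <- maps$A
  attr(y, "Phi") <- maps$Phi
  y
}

#' Simulate a structural VAR series
#'
#' Low-level generator behind [generate_individual()]: no subgroup
#' machinery, just the recursion for given weight matrices. Rejects
#' unstable systems (spectral radius of `(I-A)^{-1} Phi` at or above 1).
#'
#' @param A,Phi p x p contemporaneous and lag-1 weight matrices.
#' @param n_timepoints retained series length.
#' @param noise_sd process-noise standard deviation.
#' @param burn_in discarded initial samples.
#' @return `n_timepoints` x p matrix.
#' @export
simulate_svar <- function(A, Phi, n_timepoints, noise_sd = 1, burn_in = 200) {
  p <- nrow(A)
  M <- diag(p) - A
  if (abs(det(M)) < 1e-10) stop("(I - A) is singular; cannot simulate")
  B <- solve(M)
  C <- B %*% Phi
  rho <- max(Mod(eigen(C, only.values = TRUE)$values))
  if (rho >= 1)
    stop("unstable system: spectral radius of (I-A)^{-1} Phi is ",
         signif(rho, 4), " >= 1")
  total <- n_timepoints + burn_in
  zeta <- matrix(stats::rnorm(total * p, sd = noise_sd), total, p)
  y <- matrix(0, total, p)
  prev <- numeric(p)
  for (t in seq_len(total)) {
    prev <- drop(C %*% prev + B %*% zeta[t, ])
    y[t, ] <- prev
  }
  y[(burn_in + 1):total, , drop = FALSE]
}

#' Simulate a full subgroup-structured panel
#'
#' Generates one series per individual under `design`, recording the
#' ground truth (subgroup labels, unique-path indicators, generating
#' weight matrices). Individuals are ordered by subgroup. Given
#' `design$seed`, repeated calls are bit-identical.
#'
#' @param design a [simulation_design()].
#' @return list with `panel` (a [ts_panel()]) and `truth` (class
#'   `sim_truth`): `labels`, `has_unique`, and per-individual `A`/`Phi`
#'   in `true_A`, `true_Phi`.
#' @export
generate_panel <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  labels <- rep(seq_len(design$n_subgroups), times = design$subgroup_sizes)
  n <- design$n_individuals
  series <- vector("list", n)
  has_unique <- logical(n)
  true_A <- vector("list", n)
  true_Phi <- vector("list", n)
  for (i in seq_len(n)) {
    y <- generate_individual(design, labels[i])
    has_unique[i] <- attr(y, "has_unique")
    true_A[[i]] <- attr(y, "A")
    true_Phi[[i]] <- attr(y, "Phi")
    attributes(y)[c("has_unique", "A", "Phi")] <- NULL
    series[[i]] <- y
  }
  panel <- ts_panel(series)
  truth <- structure(list(ids = panel$ids, labels = labels,
                          has_unique = has_unique,
                          true_A = true_A, true_Phi = true_Phi,
                          design = design),
                     class = "sim_truth")
  list(panel = panel, truth = truth)
}

#' Analytic stationary covariance of the reduced-form VAR
#'
#' Solves the discrete Lyapunov equation
#' `Sigma = C Sigma C' + B Psi B'` with `B = (I-A)^{-1}`, `C = B Phi`,
#' `Psi = noise_sd^2 I` by vectorization. Used to check that long
#' simulated series converge to their stationary distribution.
#'
#' @inheritParams simulate_svar
#' @return p x p stationary covariance matrix.
#' @export
stationary_covariance <- function(A, Phi, noise_sd = 1) {
  p <- nrow(A)
  B <- solve(diag(p) - A)
  C <- B %*% Phi
  W <- B %*% (noise_sd^2 * diag(p)) %*% t(B)
  vecS <- solve(diag(p * p) - kronecker(C, C), as.vector(W))
  matrix(vecS, p, p)
}

#' Write a simulated panel and its ground truth to disk
#'
#' One delimited text file per individual under `<dir>/series/` (rows =
#' scans, columns = ROIs) plus `ground_truth.tsv` (individual, subgroup,
#' unique-path indicator) and `true_edges.tsv` (individual, from, to,
#' lag, weight), and the design serialized to `design.yaml`. Reload the
#' panel with `load_panel(file.path(dir, "series"))`.
#'
#' @param sim result of [generate_panel()].
#' @param dir output directory (created if needed).
#' @param sep field separator for the series files.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, sep = "\t") {
  dir.create(file.path(dir, "series"), recursive = TRUE,
             showWarnings = FALSE)
  panel <- sim$panel; truth <- sim$truth
  for (i in seq_along(panel$ids)) {
    f <- file.path(dir, "series", paste0(panel$ids[i], ".tsv"))
    utils::write.table(panel$series[[i]], f, sep = sep, row.names = FALSE,
                       col.names = panel$roi_labels, quote = FALSE)
  }
  utils::write.table(
    data.frame(individual = panel$ids, subgroup = truth$labels,
               has_unique = truth$has_unique),
    file.path(dir, "ground_truth.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  edges <- do.call(rbind, lapply(seq_along(panel$ids), function(i) {
    e <- rbind(edge_table(truth$true_A[[i]], lag = 0L),
               edge_table(truth$true_Phi[[i]], lag = 1L))
    if (nrow(e)) cbind(individual = panel$ids[i], e)
  }))
  utils::write.table(edges, file.path(dir, "true_edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  d <- truth$design
  d$subgroup_deviations <- lapply(d$subgroup_deviations, as.list)
  d$group_paths <- apply(d$group_paths, 1, as.list)
  d$unique_paths <- apply(d$unique_paths, 1, as.list)
  yaml::write_yaml(unclass(d), file.path(dir, "design.yaml"))
  invisible(dir)
}

# Nonzero entries of a weight matrix as a from/to/lag/weight table.
edge_table <- function(W, lag) {
  idx <- which(W != 0, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(from = integer(), to = integer(), lag = integer(),
                      weight = numeric()))
  data.frame(from = idx[, "col"], to = idx[, "row"], lag = lag,
             weight = W[idx])
}
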