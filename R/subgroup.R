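#' Vectorize contemporaneous group-path betas
#'
#' Extracts, for every individual, the estimated weights of the
#' group-level contemporaneous paths into an N x k matrix — the features
#' on which individuals are compared. Lagged and individual-level paths
#' are excluded: the group-level contemporaneous weights are present for
#' everyone and (unlike the sparse individual-level paths) are
#' approximately normally distributed across individuals, which suits the
#' correlation similarity that follows. Columns follow row-major order
#' over the (to, from) ROI pairs of the group map.
#'
#' @param maps a `connectivity_maps` object from [run_individual_search()]
#'   or [gimme()].
#' @return N x k numeric matrix, rows named by individual ID, columns
#'   `to<i:from<j` style labels.
#' @export
vectorize_betas <- function(maps) {
  stopifnot(inherits(maps, "connectivity_maps"))
  gm <- maps$group_map
  sel <- which(t(gm$free_A), arr.ind = TRUE)  # row-major over (to, from)
  if (nrow(sel) < 2L)
    stop("group map has ", nrow(sel), " contemporaneous path(s); ",
         "need >= 2 to correlate individuals")
  to <- sel[, 2L]; from <- sel[, 1L]
  B <- t(vapply(maps$fits, function(f) f$A_hat[cbind(to, from)],
                numeric(length(to))))
  rownames(B) <- maps$ids
  colnames(B) <- paste0(from, "->", to)
  B
}

#' Inter-individual similarity network
#'
#' Pearson-correlates every individual's beta vector with every other
#' individual's, yielding the N x N similarity matrix X whose binarization
#' feeds community detection.
#'
#' @param beta_matrix N x k matrix from [vectorize_betas()] (k >= 2,
#'   no missing entries).
#' @return object of class `similarity_network` with element `X`
#'   (diagonal set to NA: self-similarity is undefined). Individuals whose
#'   beta vector has zero variance get NA correlations and are flagged in
#'   attribute `degenerate`.
#' @export
build_similarity <- function(beta_matrix) {
  beta_matrix <- as.matrix(beta_matrix)
  if (ncol(beta_matrix) < 2L) stop("need >= 2 beta columns")
  if (anyNA(beta_matrix)) stop("beta matrix contains missing entries")
  rv <- apply(beta_matrix, 1, stats::var)
  degenerate <- which(rv == 0)
  X <- suppressWarnings(stats::cor(t(beta_matrix)))
  if (length(degenerate)) {
    X[degenerate, ] <- NA_real_
    X[, degenerate] <- NA_real_
    warning("zero-variance beta vector(s) for individual(s) ",
            paste(degenerate, collapse = ", "),
            "; their similarities are undefined")
  }
  diag(X) <- NA_real_
  structure(list(X = X, n = nrow(X)), degenerate = degenerate,
            class = "similarity_network")
}

#' Binarize a similarity matrix at threshold r
#'
#' `A_ij = 1` when `X_ij >= r` (closed inequality) for `i != j`, else 0;
#' the diagonal is zero and NA similarities never connect.
#'
#' @param X N x N similarity matrix, or a `similarity_network`.
#' @param r threshold in `[0, 1]`.
#' @return N x N binary symmetric adjacency matrix with zero diagonal.
#' @export
binarize <- function(X, r) {
  if (inherits(X, "similarity_network")) X <- X$X
  if (r < 0 || r > 1) stop("threshold r must lie in [0, 1]")
  A <- (!is.na(X) & X >= r) * 1
  diag(A) <- 0
  A[] <- pmax(A, t(A))  # defensive symmetrization
  A
}

#' Mean reachability of a binary network
#'
#' For every node, the number of other nodes it can reach through any
#' path (its connected-component size minus one); returns the mean over
#' nodes. High reachability means the network is still well connected at
#' the current threshold.
#'
#' @param A binary adjacency matrix.
#' @return mean reachability (scalar).
#' @export
reachability <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
  comp <- igraph::components(g)
  mean(comp$csize[comp$membership] - 1)
}

#' Modularity-maximizing partition of a binary network
#'
#' One randomized run of Newman-modularity maximization (multi-level
#' local moving with random node visit order plus single-node
#' refinement). Because the visit order is random, repeated runs on
#' graphs with competing local optima return different partitions — the
#' run-to-run variability that the stability-based threshold selection
#' exploits. Results are reproducible under `set.seed()`.
#'
#' @param A binary symmetric adjacency matrix with zero diagonal.
#' @return object of class `partition`: `membership` (integer labels in
#'   order of first appearance), `Q` (modularity), `n_communities`.
#'   An edgeless network yields singleton communities with Q = 0 and a
#'   warning.
#' @export
modularity_partition <- function(A) {
  A <- as.matrix(A)
  if (sum(A) - sum(diag(A)) <= 0) {
    warning("network has no edges; every node is its own community, Q = 0")
    return(new_partition(seq_len(nrow(A)), 0))
  }
  res <- louvain_cpp(A)
  new_partition(canonical_labels(res$membership), res$Q)
}

new_partition <- function(membership, Q) {
  structure(list(membership = as.integer(membership), Q = Q,
                 n_communities = length(unique(membership))),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("<partition> ", x$n_communities, " communities, Q = ",
      format(x$Q, digits = 4), "; sizes: ",
      paste(tabulate(x$membership), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Relabel communities by order of first appearance so that identical
# groupings compare equal regardless of arbitrary label choice.
canonical_labels <- function(membership) {
  as.integer(factor(membership, levels = unique(membership)))
}

#' Evaluate modularity Q of a given partition
#'
#' Direct evaluation of `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m)
#' delta(c_i, c_j)`; used for cross-checking the maximizer and for
#' exhaustive-search oracles.
#'
#' @param A adjacency matrix.
#' @param membership community label per node.
#' @return Q value.
#' @export
modularity_q <- function(A, membership) {
  A <- as.matrix(A)
  diag(A) <- 0
  k <- rowSums(A)
  two_m <- sum(k)
  if (two_m == 0) return(0)
  same <- outer(membership, membership, "==")
  sum((A - outer(k, k) / two_m) * same) / two_m
}

#' Scan binarization thresholds for modularity stability
#'
#' For every threshold on the grid, binarizes the similarity matrix and
#' runs the randomized modularity maximization `runs` times, recording
#' all Q values, their standard deviation (the stability criterion), the
#' mean Q, and the mean reachability of the binarized network.
#'
#' @param X similarity matrix or `similarity_network`.
#' @param grid thresholds; default `seq(0, 1, by = 0.01)`.
#' @param runs modularity runs per threshold (default 100).
#' @return object of class `threshold_scan`: data frame `table` with
#'   columns `r`, `mean_q`, `sd_q`, `reach`, `edges`, plus matrix `Q`
#'   (`length(grid)` x `runs`) of raw values.
#' @export
scan_thresholds <- function(X, grid = seq(0, 1, by = 0.01), runs = 100) {
  if (inherits(X, "similarity_network")) X <- X$X
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  ng <- length(grid)
  Q <- matrix(NA_real_, ng, runs)
  reach <- numeric(ng)
  edges <- integer(ng)
  for (g in seq_len(ng)) {
    A <- binarize(X, grid[g])
    edges[g] <- sum(A) / 2
    reach[g] <- reachability(A)
    if (edges[g] > 0)
      for (j in seq_len(runs)) Q[g, j] <- louvain_cpp(A)$Q
  }
  tab <- data.frame(r = grid,
                    mean_q = rowMeans(Q),
                    sd_q = apply(Q, 1, stats::sd),
                    reach = reach, edges = edges)
  structure(list(table = tab, Q = Q, runs = runs), class = "threshold_scan")
}

#' Locate the drop in a reachability curve
#'
#' Draws the chord from the first to the last point of the mean
#' reachability curve (x = grid index) and returns the index at greatest
#' perpendicular distance from that chord — the elbow where reachability
#' begins to fall. Ties break to the smallest index; a flat/linear curve
#' has no drop and returns the last index with a warning.
#'
#' @param reach_curve numeric vector (length >= 3) of mean reachability
#'   per grid point.
#' @return integer index into `reach_curve`, with attribute `distances`.
#' @export
find_reachability_drop <- function(reach_curve) {
  y <- as.numeric(reach_curve)
  n <- length(y)
  if (n < 3L) stop("reachability curve needs >= 3 points")
  x <- seq_len(n)
  dx <- x[n] - x[1]; dy <- y[n] - y[1]
  d <- abs(dy * (x - x[1]) - dx * (y - y[1])) / sqrt(dx^2 + dy^2)
  if (max(d) < 1e-12) {
    warning("reachability curve is linear; no drop detected")
    idx <- n
  } else idx <- which.max(d)  # which.max returns the smallest tied index
  structure(as.integer(idx), distances = d)
}

#' Select the binarization threshold from a scan
#'
#' Among grid points strictly before the reachability drop (and whose
#' binarized network has at least one edge), picks the threshold with the
#' most stable modularity (smallest `sd(Q)`); ties break to the highest
#' `r`, then the highest mean Q.
#'
#' @param scan a [scan_thresholds()] result.
#' @return the selected threshold `r*`, with attributes `index` (grid
#'   position) and `drop_index`.
#' @export
select_threshold <- function(scan) {
  stopifnot(inherits(scan, "threshold_scan"))
  tab <- scan$table
  drop_idx <- find_reachability_drop(tab$reach)
  elig <- which(seq_len(nrow(tab)) < drop_idx & tab$edges > 0 &
                  !is.na(tab$sd_q))
  if (!length(elig))
    stop("no usable thresholds before the reachability drop (index ",
         drop_idx, "); similarity structure too degenerate")
  o <- elig[order(tab$sd_q[elig], -tab$r[elig], -tab$mean_q[elig])]
  best <- o[1L]
  structure(tab$r[best], index = best, drop_index = as.integer(drop_idx))
}

#' Detect subgroups from individual connectivity maps
#'
#' The full subgrouping pipeline: vectorize contemporaneous group-path
#' betas, build the correlation similarity network, scan binarization
#' thresholds for modularity stability, select the threshold before the
#' reachability drop, and return the final community assignment at the
#' selected threshold — the modal partition across `runs` randomized
#' maximization runs (ties broken by highest Q).
#'
#' @param maps a `connectivity_maps` object.
#' @param grid,runs see [scan_thresholds()].
#' @return list of class `subgroup_result`: `partition`, `r_star`,
#'   `scan`, `network`, `betas`.
#' @export
detect_subgroups <- function(maps, grid = seq(0, 1, by = 0.01), runs = 100) {
  betas <- vectorize_betas(maps)
  net <- build_similarity(betas)
  scan <- scan_thresholds(net, grid = grid, runs = runs)
  r_star <- select_threshold(scan)
  A <- binarize(net, r_star)
  part <- modal_partition(A, runs = runs)
  structure(list(partition = part, r_star = r_star, scan = scan,
                 network = net, betas = betas, adjacency = A,
                 ids = maps$ids),
            class = "subgroup_result")
}

# Modal (most frequent) partition across `runs` randomized maximization
# runs; ties broken by highest Q.
modal_partition <- function(A, runs = 100) {
  parts <- vector("list", runs)
  keys <- character(runs)
  qs <- numeric(runs)
  for (j in seq_len(runs)) {
    p <- modularity_partition(A)
    parts[[j]] <- p
    keys[j] <- paste(p$membership, collapse = ",")
    qs[j] <- p$Q
  }
  freq <- table(keys)
  top <- names(freq)[freq == max(freq)]
  if (length(top) > 1L) {
    qk <- vapply(top, function(k) max(qs[keys == k]), 0)
    top <- top[which.max(qk)]
  }
  parts[[which(keys == top)[1L]]]
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat("<subgroup_result> r* = ", format(unclass(x$r_star)), ": ", sep = "")
  print(x$partition)
  invisible(x)
}

#' Match detected communities to reference labels and score accuracy
#'
#' Maximum-weight one-to-one matching (Hungarian-type assignment on the
#' contingency table) between detected communities and reference
#' subgroups; members of unmatched communities count as incorrect.
#'
#' @param membership detected community labels (vector or `partition`).
#' @param reference true subgroup labels.
#' @return fraction of individuals placed with their true subgroup, with
#'   attribute `matching` (named vector: community -> reference label).
#' @export
subgroup_accuracy <- function(membership, reference) {
  if (inherits(membership, "partition")) membership <- membership$membership
  if (length(membership) != length(reference))
    stop("membership and reference must cover the same individuals")
  tab <- table(membership, reference)
  m <- max_assignment(tab)
  correct <- sum(tab[cbind(m$rows, m$cols)])
  structure(correct / length(membership),
            matching = stats::setNames(colnames(tab)[m$cols],
                                       rownames(tab)[m$rows]))
}

# Maximum-weight injective assignment of rows to columns of a weight
# matrix: exact bitmask dynamic program (vectorized over masks) with the
# mask on the column side; community counts here are small. Greedy
# fallback beyond 14 columns.
max_assignment <- function(W) {
  W <- as.matrix(W)
  flip <- nrow(W) > ncol(W)
  if (flip) W <- t(W)
  nr <- nrow(W); nc <- ncol(W)
  if (nc > 14L) return(greedy_assignment(W, flip))
  nmask <- 2L^nc
  allm <- 0:(nmask - 1L)
  bits <- 2L^(0:(nc - 1L))
  src <- lapply(bits, function(b) which(bitwAnd(allm, b) == 0L))  # 1-based
  f <- matrix(-Inf, nr + 1L, nmask)
  f[1L, 1L] <- 0
  choice <- matrix(NA_integer_, nr + 1L, nmask)
  for (i in seq_len(nr)) {
    fi <- f[i, ]
    for (j in seq_len(nc)) {
      s <- src[[j]]
      cand <- fi[s] + W[i, j]
      tgt <- s + bits[j]  # index of mask | bit_j
      better <- cand > f[i + 1L, tgt]
      if (any(better)) {
        f[i + 1L, tgt[better]] <- cand[better]
        choice[i + 1L, tgt[better]] <- j
      }
    }
  }
  mask <- which.max(f[nr + 1L, ]) - 1L
  rows <- seq_len(nr); cols <- integer(nr)
  for (i in nr:1) {
    j <- choice[i + 1L, mask + 1L]
    cols[i] <- j
    mask <- mask - bits[j]
  }
  if (flip) list(rows = cols, cols = rows) else list(rows = rows, cols = cols)
}

greedy_assignment <- function(W, flip) {
  nr <- nrow(W); nc <- ncol(W)
  rows <- integer(0); cols <- integer(0)
  used_r <- logical(nr); used_c <- logical(nc)
  o <- order(-as.vector(W))
  for (k in o) {
    i <- (k - 1L) %% nr + 1L; j <- (k - 1L) %/% nr + 1L
    if (!used_r[i] && !used_c[j]) {
      rows <- c(rows, i); cols <- c(cols, j)
      used_r[i] <- TRUE; used_c[j] <- TRUE
    }
  }
  if (flip) list(rows = cols, cols = rows) else list(rows = rows, cols = cols)
}
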