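# Independent oracles and small fixtures used across test files.

# All set partitions of n labeled items as membership vectors
# (restricted-growth-string enumeration).
enum_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L))
      rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive-search maximum modularity over every partition of the nodes.
best_q_exhaustive <- function(A) {
  parts <- enum_partitions(nrow(A))
  max(vapply(parts, function(m) modularity_q(A, m), 0))
}

adj_from_edges <- function(n, edges) {
  A <- matrix(0, n, n)
  for (e in edges) A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  A
}

# Small graphs with clear community structure: every single run of the
# maximizer must attain the exhaustive optimum on these.
oracle_graphs <- function() {
  list(
    two_triangles = adj_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3),
                                           c(4, 5), c(5, 6), c(4, 6))),
    bridged_triangles = adj_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3),
                                               c(4, 5), c(5, 6), c(4, 6),
                                               c(3, 4))),
    two_squares = adj_from_edges(8, list(c(1, 2), c(2, 3), c(3, 4), c(1, 4),
                                         c(1, 3),
                                         c(5, 6), c(6, 7), c(7, 8), c(5, 8),
                                         c(6, 8), c(4, 5))),
    star5 = adj_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  )
}

# Structureless graphs (paths, rings) have several competing near-optima;
# single runs legitimately vary, but the best of a few dozen randomized
# runs must still reach the exhaustive optimum.
ambiguous_graphs <- function() {
  list(
    path6 = adj_from_edges(6, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                                   c(5, 6))),
    ring8 = adj_from_edges(8, lapply(1:8, function(i) c(i, i %% 8 + 1)))
  )
}

# A compact simulation design used where the full 100 x 10 x 200 default
# would be wasteful: 2 subgroups of 6, 6 ROIs, 5 shared chain paths.
small_design <- function(seed = NULL, n_per_group = 6, T = 200) {
  simulation_design(
    n_individuals = 2 * n_per_group, n_rois = 6, n_timepoints = T,
    group_paths = cbind(from = 1:5, to = 2:6),
    n_subgroups = 2, subgroup_sizes = rep(n_per_group, 2),
    seed = seed)
}

# Minimal hand-built connectivity_maps carrying given betas on a given
# contemporaneous group map, for subgroup-detection unit tests that do not
# need the estimation stages.
fake_maps <- function(B, group_A = NULL, p = NULL) {
  N <- nrow(B); k <- ncol(B)
  if (is.null(p)) p <- k + 1
  if (is.null(group_A)) {
    group_A <- matrix(FALSE, p, p)
    group_A[cbind(2:(k + 1), 1:k)] <- TRUE  # chain-ish: path j -> j+1
  }
  sel <- which(t(group_A), arr.ind = TRUE)
  to <- sel[, 2]; from <- sel[, 1]
  ids <- sprintf("ind%03d", seq_len(N))
  fits <- lapply(seq_len(N), function(i) {
    A_hat <- matrix(0, p, p)
    A_hat[cbind(to, from)] <- B[i, ]
    list(A_hat = A_hat, Phi_hat = diag(0.5, p),
         spec = usem_spec(p, free_A = group_A))
  })
  names(fits) <- ids
  structure(list(fits = fits,
                 individual_A = rep(list(matrix(FALSE, p, p)), N),
                 individual_Phi = rep(list(matrix(FALSE, p, p)), N),
                 fit_indices = vector("list", N),
                 group_map = structure(list(free_A = group_A,
                                            free_Phi = diag(p) == 1,
                                            gamma = 0.75, alpha = 0.05,
                                            excluded = character(0),
                                            standardize = FALSE),
                                       class = "group_map"),
                 ids = ids, excluded = character(0)),
            class = "connectivity_maps")
}

# Block-structured beta matrix: `sizes[i]` individuals around center_i with
# isotropic noise; centers chosen well apart.
block_betas <- function(sizes, k = 6, sep = 1, noise = 0.05, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(length(sizes) * k, sd = sep),
                    length(sizes), k)
  do.call(rbind, lapply(seq_along(sizes), function(g)
    matrix(stats::rnorm(sizes[g] * k, mean = rep(centers[g, ],
                                                 each = sizes[g]),
                        sd = noise), sizes[g], k)))
}

# Brute-force maximum-weight assignment by enumerating permutations of the
# smaller dimension (oracle for the bitmask DP).
assignment_oracle <- function(W) {
  W <- as.matrix(W)
  flip <- nrow(W) > ncol(W)
  if (flip) W <- t(W)
  nr <- nrow(W); nc <- ncol(W)
  cols <- utils::combn(nc, nr, simplify = FALSE)
  best <- -Inf
  for (cc in cols) {
    perms <- perms_of(cc)
    for (pp in perms) best <- max(best, sum(W[cbind(seq_len(nr), pp)]))
  }
  best
}

perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_of(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
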