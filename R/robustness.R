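#' Degree-preserving random perturbation of a binary network
#'
#' Rewires approximately `alpha * m` of the `m` edges by double-edge
#' swaps: two edges (a-b, c-d) are replaced by (a-d, c-b), which
#' relocates edges while preserving every node's degree exactly (no
#' self-loops or multi-edges are created). At `alpha = 1` the result is
#' an approximately uniform draw from the graphs with the same degree
#' sequence; at `alpha = 0` the network is returned unchanged.
#'
#' @param A binary symmetric adjacency matrix, zero diagonal.
#' @param alpha perturbation level in `[0, 1]`.
#' @return perturbed adjacency matrix. If the graph is too sparse to
#'   complete the requested swaps, the partially rewired network is
#'   returned with a warning (attribute `swaps` records successes).
#' @export
perturb_network <- function(A, alpha) {
  A <- as.matrix(A)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  m <- sum(A != 0) / 2
  # Swaps draw edges with replacement, so s swaps relocate m(1 - e^(-2s/m))
  # distinct edges in expectation; invert that to make the expected number
  # of distinct relocated edges equal alpha * m. Level 1 gets enough swaps
  # to mix the graph fully (an approximately uniform draw from the graphs
  # with this degree sequence).
  nswap <- if (alpha >= 1) ceiling(5 * m)
           else round(-m / 2 * log(1 - alpha))
  if (nswap == 0) return(A)
  if (m < 2) {
    warning("graph has fewer than 2 edges; cannot rewire")
    return(structure(A, swaps = 0L))
  }
  res <- rewire_cpp((A != 0) * 1, as.integer(nswap))
  if (res$swaps < nswap)
    warning("only ", res$swaps, " of ", nswap,
            " requested edge swaps were possible (graph too constrained)")
  structure(res$adjacency, swaps = res$swaps)
}

#' Variation of information between two partitions
#'
#' Meila's information-theoretic distance
#' `VI = H(P) + H(P') - 2 I(P; P')`, computed over the empirical joint
#' label distribution, in bits by default. VI is a metric on partitions
#' of the same individual set and is bounded by `log2(N)` bits.
#'
#' @param p1,p2 community label vectors (or `partition` objects) over the
#'   same individuals.
#' @param base logarithm base: 2 for bits (default), `exp(1)` for nats.
#' @param normalize divide by `log(N, base)`?
#' @return VI distance (non-negative scalar).
#' @export
variation_of_information <- function(p1, p2, base = 2, normalize = FALSE) {
  if (inherits(p1, "partition")) p1 <- p1$membership
  if (inherits(p2, "partition")) p2 <- p2$membership
  if (length(p1) != length(p2))
    stop("partitions cover different individual sets (", length(p1),
         " vs ", length(p2), ")")
  n <- length(p1)
  joint <- table(p1, p2) / n
  px <- rowSums(joint); py <- colSums(joint)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p, base)) }
  hj <- ent(as.vector(joint))
  vi <- 2 * hj - ent(px) - ent(py)  # H(X|Y) + H(Y|X)
  vi <- max(vi, 0)
  if (normalize) vi <- vi / log(n, base)
  vi
}

#' Fraction of individuals whose community changed
#'
#' Matches the communities of `p2` one-to-one onto those of `p1` by
#' maximum overlap (Hungarian-type assignment on the contingency table)
#' and returns the fraction of individuals that fall outside their
#' matched community. A pure relabeling therefore scores 0.
#'
#' @inheritParams variation_of_information
#' @return proportion in `[0, 1]`.
#' @export
fraction_changed <- function(p1, p2) {
  if (inherits(p1, "partition")) p1 <- p1$membership
  if (inherits(p2, "partition")) p2 <- p2$membership
  if (length(p1) != length(p2))
    stop("partitions cover different individual sets")
  tab <- table(p1, p2)
  m <- max_assignment(tab)
  1 - sum(tab[cbind(m$rows, m$cols)]) / length(p1)
}

#' Robustness curve under degree-preserving perturbation
#'
#' Perturbs the network at each level `reps` times, re-runs the
#' randomized modularity maximization on every perturbed network, and
#' records the variation of information (and fraction of reassigned
#' vertices) against the original partition. A community structure that
#' is genuinely present stays near VI = 0 until substantial perturbation;
#' a structure fitted to noise (e.g. a matched random graph) degrades at
#' the slightest perturbation.
#'
#' @param A binary adjacency matrix at the selected threshold.
#' @param original the unperturbed network's partition (a `partition`
#'   or label vector); computed via [modularity_partition()] if NULL.
#' @param levels perturbation levels; default `seq(0, 1, by = 0.025)`.
#' @param reps perturbation replicates per level (default 100).
#' @return object of class `perturbation_curve`: data frame `table` with
#'   per-level mean/sd of VI (bits) and of the fraction of changed
#'   vertices, plus the `original` partition.
#' @export
robustness_curve <- function(A, original = NULL,
                             levels = seq(0, 1, by = 0.025), reps = 100) {
  A <- (as.matrix(A) != 0) * 1
  if (is.null(original)) original <- modularity_partition(A)
  orig <- if (inherits(original, "partition")) original$membership
          else as.integer(original)
  nl <- length(levels)
  mean_vi <- sd_vi <- mean_fc <- sd_fc <- numeric(nl)
  for (li in seq_len(nl)) {
    vi <- fc <- numeric(reps)
    for (j in seq_len(reps)) {
      Ap <- suppressWarnings(perturb_network(A, levels[li]))
      part <- suppressWarnings(modularity_partition(Ap))
      vi[j] <- variation_of_information(orig, part$membership)
      fc[j] <- fraction_changed(orig, part$membership)
    }
    mean_vi[li] <- mean(vi); sd_vi[li] <- stats::sd(vi)
    mean_fc[li] <- mean(fc); sd_fc[li] <- stats::sd(fc)
  }
  structure(list(table = data.frame(level = levels, mean_vi = mean_vi,
                                    sd_vi = sd_vi, mean_fc = mean_fc,
                                    sd_fc = sd_fc),
                 original = orig, reps = reps),
            class = "perturbation_curve")
}

#' Matched Erdos-Renyi baseline network
#'
#' A uniformly random graph with the same node and edge count as `A`;
#' its (noise-fitted) community structure provides the baseline against
#' which the robustness curve of a real similarity network is judged.
#'
#' @param A binary adjacency matrix to match.
#' @return adjacency matrix of the random graph.
#' @export
random_baseline <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  m <- sum(A != 0) / 2
  g <- igraph::sample_gnm(n, m)
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}
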