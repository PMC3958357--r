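# Similarity network, binarization, reachability, modularity maximization
# (with exhaustive oracle), data-driven threshold selection, detection.

test_that("beta vectorization extracts group contemporaneous paths only", {
  B <- matrix(seq_len(12) / 10, 3, 4)
  maps <- fake_maps(B)
  V <- vectorize_betas(maps)
  expect_equal(dim(V), c(3L, 4L))
  expect_equal(unname(V), unname(B))
  # a map with a single contemporaneous path cannot be correlated
  g1 <- matrix(FALSE, 5, 5); g1[2, 1] <- TRUE
  expect_error(vectorize_betas(fake_maps(B[, 1, drop = FALSE],
                                         group_A = g1, p = 5)),
               ">= 2")
})

test_that("similarity is the Pearson correlation of beta vectors", {
  B <- rbind(c(1, 2, 3, 4),
             c(1, 2, 3, 4),            # identical to row 1
             c(9, 7, 5, 3),            # perfect negative linear map
             c(0, 0, 0, 0))            # degenerate
  expect_warning(net <- build_similarity(B), "zero-variance")
  expect_equal(net$X[1, 2], 1)
  expect_equal(net$X[1, 3], -1)
  expect_true(all(is.na(net$X[4, ])))
  expect_true(is.na(net$X[1, 1]))
  # orthogonalized pair
  b1 <- c(1, -1, 1, -1)
  b2 <- c(1, 1, 1, 1) + c(-1, 1, 1, -1)  # orthogonal deviations
  net2 <- build_similarity(rbind(b1, b2, c(0.5, 1, 2, 3)))
  expect_lt(abs(net2$X[1, 2]), 1e-12)
})

test_that("binarization uses the closed >= threshold and zero diagonal", {
  X <- matrix(c(NA, 0.7, 0.6, 0.59,
                0.7, NA, 0.2, -0.5,
                0.6, 0.2, NA, 0.61,
                0.59, -0.5, 0.61, NA), 4, 4)
  A <- binarize(X, 0.6)
  expect_equal(A[1, 2], 1)   # .7 >= .6
  expect_equal(A[1, 3], 1)   # boundary: .6 >= .6
  expect_equal(A[1, 4], 0)   # .59 < .6
  expect_equal(A[2, 4], 0)
  expect_true(all(diag(A) == 0))
  expect_identical(A, t(A))
  expect_error(binarize(X, 1.2), "r must lie")
  # r = 0 connects all non-negative pairs
  A0 <- binarize(X, 0)
  expect_equal(A0[2, 4], 0)  # negative similarity never connects
  expect_equal(sum(A0) / 2, 5)
})

test_that("reachability is mean component size minus one", {
  expect_equal(reachability(matrix(1, 5, 5) - diag(5)), 4)
  expect_equal(reachability(matrix(0, 4, 4)), 0)
  A <- adj_from_edges(4, list(c(1, 2), c(2, 3)))
  expect_equal(reachability(A), 1.5)   # components {1,2,3} and {4}
})

test_that("modularity maximization attains the exhaustive optimum on small graphs", {
  gs <- oracle_graphs()
  for (nm in names(gs)) {
    A <- gs[[nm]]
    qstar <- best_q_exhaustive(A)
    set.seed(123)
    for (rep in 1:20) {
      part <- modularity_partition(A)
      expect_equal(part$Q, qstar, tolerance = 1e-12,
                   label = paste0("Q(", nm, ") run ", rep))
      expect_equal(part$Q, modularity_q(A, part$membership),
                   tolerance = 1e-12)
    }
  }
  # structureless graphs: single runs may settle on competing optima, but
  # the best of 50 randomized runs reaches the exhaustive optimum
  for (nm in names(ambiguous_graphs())) {
    A <- ambiguous_graphs()[[nm]]
    qstar <- best_q_exhaustive(A)
    set.seed(7)
    qs <- replicate(50, modularity_partition(A)$Q)
    expect_equal(max(qs), qstar, tolerance = 1e-12, label = paste0("max Q(", nm, ")"))
    expect_true(all(qs <= qstar + 1e-12))
  }
  # two disjoint triangles resolve into exactly the two triangles, Q = .5
  set.seed(5)
  part <- modularity_partition(gs$two_triangles)
  expect_equal(part$Q, 0.5)
  expect_equal(part$membership[1:3], rep(part$membership[1], 3))
  expect_equal(part$membership[4:6], rep(part$membership[4], 3))
  expect_equal(part$n_communities, 2L)
})

test_that("Q evaluation matches igraph and is relabeling-invariant", {
  set.seed(33)
  for (rep in 1:5) {
    g <- igraph::sample_gnp(12, 0.3)
    A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    if (sum(A) == 0) next
    memb <- sample(1:3, 12, replace = TRUE)
    expect_equal(modularity_q(A, memb), igraph::modularity(g, memb),
                 tolerance = 1e-12)
    # permutation equivariance
    perm <- sample(12)
    expect_equal(modularity_q(A[perm, perm], memb[perm]),
                 modularity_q(A, memb), tolerance = 1e-12)
    # trivial single community evaluates to zero
    expect_equal(modularity_q(A, rep(1, 12)), 0)
  }
})

test_that("an edgeless network yields singleton communities with a warning", {
  expect_warning(p <- modularity_partition(matrix(0, 4, 4)), "no edges")
  expect_equal(p$membership, 1:4)
  expect_equal(p$Q, 0)
})

test_that("threshold scans record stability and reachability per threshold", {
  # all-ones similarity: complete graph at every r, Q constant at 0
  X1 <- matrix(1, 6, 6); diag(X1) <- NA
  set.seed(3)
  scan <- scan_thresholds(X1, grid = seq(0, 1, by = 0.25), runs = 10)
  expect_true(all(scan$table$sd_q == 0))
  expect_true(all(scan$table$mean_q == 0))
  expect_true(all(scan$table$reach == 5))

  # two clear blocks: zero dispersion and 2 communities at separating r
  B <- block_betas(c(8, 8), sep = 2, noise = 0.03, seed = 4)
  X2 <- build_similarity(B)$X
  set.seed(4)
  scan2 <- scan_thresholds(X2, grid = seq(0, 0.9, by = 0.1), runs = 20)
  sep_rows <- which(scan2$table$r >= 0.3 & scan2$table$r <= 0.8)
  expect_true(all(scan2$table$sd_q[sep_rows] == 0))
  # reachability is monotone non-increasing in r
  expect_true(all(diff(scan2$table$reach) <= 1e-12))
  expect_error(scan_thresholds(X2, grid = c(0.2, 0.1)), "increasing")
})

test_that("when Q is stable the community structure repeats exactly", {
  B <- block_betas(c(8, 8), sep = 2, noise = 0.03, seed = 4)
  X <- build_similarity(B)$X
  A <- binarize(X, 0.5)
  set.seed(9)
  parts <- replicate(25, modularity_partition(A)$membership)
  expect_equal(nrow(unique(t(parts))), 1L)
})

test_that("the reachability drop sits at the analytic elbow", {
  d1 <- find_reachability_drop(c(10, 10, 10, 0, 0))
  expect_equal(as.integer(d1), 3L)
  expect_equal(attr(d1, "distances")[3], 20 / sqrt(116), tolerance = 1e-12)
  expect_equal(attr(d1, "distances")[2], 10 / sqrt(116), tolerance = 1e-12)
  expect_equal(as.integer(find_reachability_drop(c(99, 99, 0))), 2L)
  expect_warning(dflat <- find_reachability_drop(c(5, 4, 3, 2)), "linear")
  expect_equal(as.integer(dflat), 4L)
  expect_error(find_reachability_drop(c(1, 2)), ">= 3")
})

test_that("threshold selection prefers stability, then the highest r and Q", {
  mk_scan <- function(sd_q, mean_q, reach, edges = NULL) {
    n <- length(sd_q)
    if (is.null(edges)) edges <- rep(10L, n)
    structure(list(table = data.frame(r = seq(0, by = 0.1,
                                              length.out = n),
                                      mean_q = mean_q, sd_q = sd_q,
                                      reach = reach, edges = edges),
                   Q = matrix(0, n, 1), runs = 1),
              class = "threshold_scan")
  }
  reach <- c(9, 9, 9, 9, 0, 0)
  # several exactly-stable thresholds before the drop: largest r wins
  s1 <- mk_scan(sd_q = c(0, 0, 0, 0.2, 0, 0),
                mean_q = c(0.1, 0.5, 0.3, 0.6, 0.7, 0.7), reach = reach)
  r1 <- select_threshold(s1)
  expect_equal(as.numeric(r1), 0.2)
  expect_equal(attr(r1, "drop_index"), 4L)
  # a single minimal-sd threshold wins outright
  s2 <- mk_scan(sd_q = c(0.3, 0.01, 0.2, 0.2, 0, 0),
                mean_q = rep(0.5, 6), reach = reach)
  expect_equal(as.numeric(select_threshold(s2)), 0.1)
  # edgeless grid points are never selected
  s3 <- mk_scan(sd_q = c(0, 0.2, 0.3, 0.2, 0, 0),
                mean_q = rep(0.5, 6), reach = reach,
                edges = c(0L, rep(10L, 5)))
  expect_equal(as.numeric(select_threshold(s3)), 0.1)
  # nothing usable before the drop -> refusal
  s4 <- mk_scan(sd_q = rep(0, 3), mean_q = rep(0.2, 3), reach = c(9, 0, 0),
                edges = c(0L, 5L, 5L))
  expect_error(select_threshold(s4), "no usable thresholds")
})

test_that("detection recovers planted blocks exactly", {
  B <- block_betas(c(10, 10), k = 6, sep = 2, noise = 0.05, seed = 14)
  maps <- fake_maps(B, p = 7)
  set.seed(14)
  res <- detect_subgroups(maps, grid = seq(0, 1, by = 0.02), runs = 30)
  truth <- rep(1:2, each = 10)
  expect_equal(as.numeric(subgroup_accuracy(res$partition, truth)), 1)
  expect_equal(res$partition$n_communities, 2L)
  # a homogeneous pool collapses into one community
  Bh <- block_betas(c(16), k = 6, sep = 2, noise = 0.05, seed = 15)
  set.seed(15)
  resh <- detect_subgroups(fake_maps(Bh, p = 7),
                           grid = seq(0, 1, by = 0.02), runs = 30)
  expect_equal(resh$partition$n_communities, 1L)
})

test_that("accuracy scoring uses maximum-weight matching", {
  truth <- rep(1:3, each = 4)
  # pure relabeling scores perfectly
  relab <- c(3, 2, 1)[truth]
  expect_equal(as.numeric(subgroup_accuracy(relab, truth)), 1)
  # a split community loses only its smaller half
  split <- truth; split[1:2] <- 4
  expect_equal(as.numeric(subgroup_accuracy(split, truth)), 10 / 12)
  # the DP equals brute-force enumeration on random contingency tables
  set.seed(44)
  for (rep in 1:20) {
    W <- matrix(rpois(12, 4), sample(2:4, 1))
    m <- gimmeclust:::max_assignment(W)
    expect_equal(sum(W[cbind(m$rows, m$cols)]), assignment_oracle(W))
  }
})
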