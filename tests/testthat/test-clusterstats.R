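chain_adjacency <- function(n) {
  ch <- paste0("c", seq_len(n))
  adj <- lapply(seq_len(n), function(i) ch[setdiff(c(i - 1, i + 1),
                                                   c(0, n + 1))])
  names(adj) <- ch
  adj
}

test_that("cluster decomposition matches a brute-force connected-components oracle", {
  set.seed(41)
  n_ch <- 5; n_t <- 5; S <- 12
  adj <- chain_adjacency(n_ch)
  # plant two separated blobs of strong signal plus tiny noise
  diffs <- array(rnorm(S * n_ch * n_t, 0, 0.05),
                 dim = c(S, n_ch, n_t),
                 dimnames = list(NULL, names(adj), NULL))
  diffs[, 1:2, 1:2] <- diffs[, 1:2, 1:2] + 5
  diffs[, 4:5, 4:5] <- diffs[, 4:5, 4:5] - 5
  cl <- cluster_permutation(diffs, adj, n_perm = 100, seed = 42)
  tmap <- attr(cl, "t_map")
  labels <- attr(cl, "labels")
  tcrit <- attr(cl, "tcrit")
  mask <- is.finite(tmap) & abs(tmap) > tcrit
  adj_idx <- lapply(priomatch:::adjacency_index(adj, names(adj)),
                    function(v) v + 1L)
  oracle <- brute_components(mask, adj_idx)
  # same partition up to label renumbering (signs split blobs here anyway)
  expect_equal(labels > 0, oracle > 0)
  for (k in sort(unique(oracle[oracle > 0]))) {
    ids <- unique(labels[oracle == k])
    expect_length(ids, 1)
  }
  # every supra-threshold point is in exactly one cluster; masses add up
  expect_equal(sum(cl$n_points), sum(mask))
  for (i in cl$cluster) {
    expect_equal(cl$mass[cl$cluster == i], sum(tmap[labels == i]),
                 tolerance = 1e-10)
  }
  expect_setequal(cl$sign, c(1, -1))
})

test_that("sign-flipped input yields mirrored clusters with identical p-values", {
  set.seed(43)
  adj <- chain_adjacency(6)
  diffs <- array(rnorm(10 * 6 * 20), dim = c(10, 6, 20),
                 dimnames = list(NULL, names(adj), NULL))
  diffs[, 2:4, 5:12] <- diffs[, 2:4, 5:12] + 1.2
  c1 <- cluster_permutation(diffs, adj, n_perm = 200, seed = 44)
  c2 <- cluster_permutation(-diffs, adj, n_perm = 200, seed = 44)
  expect_equal(c1$mass, -c2$mass)
  expect_equal(c1$sign, -c2$sign)
  expect_equal(c1$p_perm, c2$p_perm)
  expect_true(all(c1$p_perm >= 1 / 201 & c1$p_perm <= 1))
})

test_that("degenerate-variance points are excluded from clusters", {
  set.seed(45)
  adj <- chain_adjacency(4)
  diffs <- array(rnorm(8 * 4 * 10), dim = c(8, 4, 10),
                 dimnames = list(NULL, names(adj), NULL))
  diffs[, 2, 3] <- 1 # zero variance across subjects
  cl <- cluster_permutation(diffs, adj, n_perm = 50, seed = 46)
  expect_true(is.nan(attr(cl, "t_map")[2, 3]))
  expect_equal(attr(cl, "labels")[2, 3], 0L)
})

test_that("pointwise correlation reports only runs meeting the length criterion", {
  set.seed(47)
  n <- 40; n_t <- 400
  scalar <- rnorm(n)
  make_signals <- function(len, at = 101) {
    sig <- matrix(rnorm(n * n_t, 0, 1), n, n_t)
    idx <- at:(at + len - 1)
    sig[, idx] <- sig[, idx] + 3 * scalar # strong planted coupling
    sig
  }
  long <- pointwise_correlation(make_signals(120), scalar, run_length = 100)
  expect_gte(nrow(long$runs), 1)
  expect_lte(long$runs$start[1], 110)
  expect_gte(long$runs$end[1], 210)
  # a sub-criterion run (95 < 100 consecutive points) is not reported
  short <- pointwise_correlation(make_signals(95), scalar, run_length = 100)
  expect_true(nrow(short$runs) == 0 || all(short$runs$start > 250))
  expect_error(pointwise_correlation(make_signals(10), rep(1, n)),
               "constant")
})

test_that("null pointwise correlations rarely produce qualifying runs", {
  set.seed(48)
  n <- 30
  hits <- vapply(1:20, function(r) {
    sig <- matrix(rnorm(n * 300), n, 300)
    nrow(pointwise_correlation(sig, rnorm(n), run_length = 100)$runs)
  }, numeric(1))
  expect_lte(mean(hits > 0), 0.1)
})

test_that("window correlation handles monotone, null and degenerate input", {
  x <- 1:20
  out <- window_correlation(x, -x)
  expect_equal(out$rho, -1)
  out2 <- window_correlation(x, x^3) # monotone increasing
  expect_equal(out2$rho, 1)
  expect_error(window_correlation(rep(1, 10), 1:10), "ties-only")
  p1 <- window_correlation(rnorm(30), rnorm(30), method = "permutation",
                           n_perm = 200, seed = 49)
  expect_true(p1$p.value >= 1 / 201 && p1$p.value <= 1)
})

test_that("group moderation flags slope differences and not shared slopes", {
  set.seed(50)
  n <- 60
  x <- rnorm(2 * n)
  g <- rep(c("FP", "SP"), each = n)
  y_same <- 0.5 * x + rnorm(2 * n, 0, 0.3)
  same <- group_moderation(x, y_same, g)
  expect_gt(same$p.value, 0.01)
  y_diff <- ifelse(g == "FP", -1, 1) * x + rnorm(2 * n, 0, 1e-3)
  diff <- group_moderation(x, y_diff, g)
  expect_lt(diff$p.value, 1e-10)
  expect_lt(diff$slope_1, 0)
  expect_gt(diff$slope_2, 0)
  expect_error(group_moderation(x, y_same, rep("FP", 2 * n)), "two levels")
})
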