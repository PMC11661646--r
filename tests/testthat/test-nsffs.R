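# helper: hand-built crossing statistics with the cold start satisfied
.stats_with <- function(obs_w, other_w, n_ifc = 3, n_bins = 4, iface = 2,
                        bin = 2, n_obs = 25) {
  w <- matrix(0, n_ifc, n_bins)
  n <- matrix(0L, n_ifc, n_bins)
  w[iface, ] <- other_w
  n[iface, ] <- 30L
  w[iface, bin] <- obs_w
  n[iface, bin] <- n_obs
  list(w = w, n = n)
}

test_that("branch decisions equalize flux and conserve weight in expectation", {
  cfg <- sampler_config(T_cum_target = 1, t_end_tree = 3600)
  # undersampled bin, factor 3 deficit -> 3 children each w/3
  st <- .stats_with(obs_w = 1, other_w = 3)
  d <- branch_decision(list(iface = 2, bin = 2, w = 0.6), st, cfg)
  expect_equal(d$n_children, 3L)
  expect_equal(d$child_weight, 0.2)
  expect_equal(d$n_children * d$child_weight, 0.6)
  # oversampled bin, factor 2 excess -> Russian roulette with q = 1/2
  st2 <- .stats_with(obs_w = 6, other_w = 3)
  dsurv <- branch_decision(list(iface = 2, bin = 2, w = 0.6), st2, cfg, u = 0.2)
  expect_equal(dsurv$q, 0.5)
  expect_equal(dsurv$n_children, 1L)
  expect_equal(dsurv$child_weight, 1.2)  # w / q keeps the estimate unbiased
  dprune <- branch_decision(list(iface = 2, bin = 2, w = 0.6), st2, cfg, u = 0.9)
  expect_equal(dprune$n_children, 0L)
  # balanced bin -> identity
  st3 <- .stats_with(obs_w = 3, other_w = 3)
  d3 <- branch_decision(list(iface = 2, bin = 2, w = 0.6), st3, cfg)
  expect_equal(d3$n_children, 1L)
  expect_equal(d3$child_weight, 0.6)
  expect_equal(d3$q, 1)
  # cold start -> identity regardless of imbalance
  st4 <- .stats_with(obs_w = 0.1, other_w = 5, n_obs = 3L)
  d4 <- branch_decision(list(iface = 2, bin = 2, w = 0.6), st4, cfg)
  expect_equal(d4$n_children, 1L)
  expect_equal(d4$child_weight, 0.6)
  # branching is capped at n_B_max and never overshoots by rounding
  st5 <- .stats_with(obs_w = 0.3, other_w = 3)
  d5 <- branch_decision(list(iface = 2, bin = 2, w = 0.6), st5, cfg)
  expect_lte(d5$n_children, cfg$n_B_max)
})

test_that("weight is conserved exactly at every branching node", {
  cfg <- sampler_config(interfaces = seq(9, 15) / 16, time_bin = 3,
                        t_chunk = 0.5, dt_measure = 1, n_B_max = 4,
                        t_end_tree = 15, T_cum_target = 3000, t_relax = 0,
                        cold_start_min = 10)
  set.seed(41)
  trees <- run_nsffs(bd_propagator(8, 1.2, 0.15, 16), cfg)
  crs <- trees$crossings
  br <- trees$branches
  branched <- crs[crs$n_children >= 1 & crs$q == 1, ]
  expect_gt(nrow(branched), 0)
  for (i in seq_len(nrow(branched))) {
    kids <- br[br$tree == branched$tree[i] &
               br$parent == branched$branch[i] &
               abs(br$t_birth - branched$t[i]) < 1e-9, ]
    # continuing parent + new children share the parent's weight exactly
    total <- branched$w[i] / branched$n_children[i] * 1 + sum(kids$w_birth)
    expect_equal(total, branched$w[i])
    expect_equal(nrow(kids), branched$n_children[i] - 1L)
  }
})

test_that("the degenerate sampler is plain direct simulation", {
  cfg <- sampler_config(interfaces = seq(9, 15) / 16, time_bin = 3,
                        t_chunk = 0.5, dt_measure = 1, n_B_max = 1,
                        t_end_tree = 15, T_cum_target = 600, t_relax = 0,
                        cold_start_min = 1e9)
  set.seed(42)
  trees <- run_nsffs(bd_propagator(8, 1.2, 0.15, 16), cfg)
  expect_equal(nrow(trees$branches), trees$n_trees)  # no branching at all
  expect_true(all(abs(trees$points$w - 1) < 1e-12))
  ws <- reweight(trees)
  expect_true(all(abs(ws$w - 1 / trees$n_trees) < 1e-12))
})

test_that("sampler first-passage estimate is unbiased on the toy model", {
  b <- 1.2; d <- 0.15; n0 <- 8; K <- 16; t_chunk <- 0.5; Tend <- 15
  set.seed(43)
  nrep <- 1e5
  hits <- altcushions:::.bd_fp_direct_cpp(n0, b, d, t_chunk,
                                          round(Tend / t_chunk), K, nrep)
  p_direct <- hits / nrep
  se_direct <- sqrt(p_direct * (1 - p_direct) / nrep)
  # dt_measure = t_chunk so recorded points and the oracle inspect the
  # trajectory at exactly the same times
  cfg <- sampler_config(interfaces = seq(9, 15) / K, time_bin = 3,
                        t_chunk = t_chunk, dt_measure = t_chunk, n_B_max = 4,
                        t_end_tree = Tend, T_cum_target = 25000, t_relax = 0,
                        cold_start_min = 20)
  set.seed(44)
  trees <- run_nsffs(bd_propagator(n0, b, d, K), cfg)
  fp <- first_passage_weight(trees, lambda_star = 1)
  se_comb <- sqrt(se_direct^2 + fp$se^2)
  expect_lt(abs(fp$estimate - p_direct), 3 * se_comb)
})

test_that("branching enhances coverage of the rare high-lambda region", {
  b <- 1.2; d <- 0.15; n0 <- 8; K <- 16
  count_far <- function(seed, n_B_max, cold) {
    cfg <- sampler_config(interfaces = seq(9, 15) / K, time_bin = 3,
                          t_chunk = 0.5, dt_measure = 0.5, n_B_max = n_B_max,
                          t_end_tree = 15, T_cum_target = 2000, t_relax = 0,
                          cold_start_min = cold)
    set.seed(seed)
    trees <- run_nsffs(bd_propagator(n0, b, d, K), cfg)
    sum(trees$points$lambda >= 13 / K)
  }
  seeds <- 1:10
  enhanced <- vapply(seeds, count_far, 0, n_B_max = 4, cold = 3)
  plain <- vapply(seeds + 100, count_far, 0, n_B_max = 1, cold = 1e9)
  expect_gt(sum(enhanced), sum(plain))
  expect_gt(mean(enhanced > plain), 0.5)
})

test_that("reweighting splits weights at branch points and normalizes roots", {
  # hand-built two-tree ensemble: tree 1 branches into 2 at t = 2
  points <- data.frame(
    tree = c(1L, 1L, 1L, 1L, 1L, 2L, 2L),
    branch = c(1L, 1L, 1L, 1L, 2L, 1L, 1L),
    t = c(0, 1, 2, 3, 3, 0, 1),
    lambda_AC = c(.3, .3, .5, .6, .55, .3, .3),
    lambda_BD = c(.3, .3, .3, .3, .3, .3, .3),
    lambda = c(.6, .6, .8, .9, .85, .6, .6),
    w = c(1, 1, 1, 0.5, 0.5, 1, 1),
    at_crossing = FALSE)
  branches <- data.frame(tree = c(1L, 1L, 2L), branch = c(1L, 2L, 1L),
                         parent = c(0L, 1L, 0L), t_birth = c(0, 2, 0),
                         w_birth = c(1, 0.5, 1))
  trees <- structure(list(points = points, branches = branches,
                          crossings = NULL, stats = NULL,
                          cfg = sampler_config(T_cum_target = 1),
                          T_cum = 10, n_trees = 2L),
                     class = "nsffs_trees")
  ws <- reweight(trees)
  expect_equal(ws$w[ws$tree == 1 & ws$t <= 2], rep(0.5, 3))
  expect_equal(ws$w[ws$tree == 1 & ws$t == 3], c(0.25, 0.25))
  expect_equal(sum(attr(ws, "branches")$w_birth[
    attr(ws, "branches")$parent == 0]), 1)
})

test_that("weighted time-t histogram matches direct simulation", {
  b <- 1.2; d <- 0.15; n0 <- 8; K <- 16; Tend <- 15
  set.seed(46)
  direct_n <- vapply(seq_len(4000), function(i)
    altcushions:::.bd_run_cpp(n0, b, d, Tend), 0L)
  cfg <- sampler_config(interfaces = seq(9, 15) / K, time_bin = 3,
                        t_chunk = 0.5, dt_measure = 1, n_B_max = 4,
                        t_end_tree = Tend, T_cum_target = 20000, t_relax = 0,
                        cold_start_min = 20)
  set.seed(47)
  trees <- run_nsffs(bd_propagator(n0, b, d, K), cfg)
  ws <- reweight(trees)
  fin <- ws[abs(ws$t - Tend) < 1e-9 & !ws$at_crossing, ]
  # counts back from lambda = n / K; compare per-bin probabilities with the
  # uncertainty of BOTH estimators (sampler SE from tree-to-tree scatter)
  nval <- round(fin$lambda * K)
  breaks <- c(-Inf, 4, 6, 8, 10, 12, Inf)
  bin_f <- cut(nval, breaks)
  n_trees <- attr(ws, "n_trees")
  d_tab <- table(cut(direct_n, breaks)) / length(direct_n)
  z <- vapply(levels(bin_f), function(lv) {
    per_tree <- vapply(seq_len(n_trees), function(tr)
      sum(fin$w[fin$tree == tr & bin_f == lv]) * n_trees, 0.0)
    pw <- mean(per_tree)
    se_w <- stats::sd(per_tree) / sqrt(n_trees)
    pd <- as.numeric(d_tab[lv])
    se_d <- sqrt(pd * (1 - pd) / length(direct_n))
    (pw - pd) / sqrt(se_w^2 + se_d^2 + 1e-12)
  }, 0.0)
  expect_lt(max(abs(z)), 4)  # no bin deviates beyond combined noise
})
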