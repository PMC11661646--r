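# synthetic weighted-sample builders ----------------------------------------

# independent lineages with given per-lineage trajectories (list of matrices
# with columns t, x, y), equal weights
.ws_from_paths <- function(paths) {
  as_weighted_samples(lapply(paths, function(m)
    data.frame(t = m[, 1], lambda_AC = m[, 2], lambda_BD = m[, 3])))
}

# 2D overdamped Langevin paths: x' = v + sqrt(2D) noise
.langevin_paths <- function(n_paths, n_steps, dt, v, D, x0_fn) {
  lapply(seq_len(n_paths), function(i) {
    x <- matrix(0, n_steps + 1, 3)
    x[1, ] <- c(0, x0_fn())
    for (k in seq_len(n_steps)) {
      x[k + 1, 1] <- k * dt
      x[k + 1, 2:3] <- x[k, 2:3] + v * dt + sqrt(2 * D * dt) * rnorm(2)
    }
    x
  })
}

test_that("weighted histograms are normalized and flat for uniform input", {
  b <- phase_bins(nx = 5)
  # all mass at one point
  ws1 <- .ws_from_paths(list(cbind(c(0, 1), 0.31, 0.31)))
  h1 <- weighted_histogram(ws1, t_center = 0.5, half_window = 1, bins = b)
  expect_equal(sum(h1$density), 1)
  expect_equal(max(h1$density), 1)
  # two equal-weight points in different bins
  ws2 <- .ws_from_paths(list(cbind(0, 0.11, 0.11), cbind(0, 0.51, 0.51)))
  h2 <- weighted_histogram(ws2, 0, half_window = 1, bins = b)
  expect_equal(sort(h2$density[h2$density > 0]), c(0.5, 0.5))
  # uniform samples -> flat within multinomial error
  set.seed(51)
  n <- 20000
  ws3 <- .ws_from_paths(list(cbind(0, runif(n), runif(n))))
  h3 <- weighted_histogram(ws3, 0, half_window = 1, bins = b)
  counts <- h3$density * n
  chi <- stats::chisq.test(as.vector(counts))
  expect_gt(chi$p.value, 0.01)
  expect_error(weighted_histogram(ws1, t_center = 100, half_window = 1,
                                  bins = b), "empty time window")
})

test_that("survival curve handles degenerate and exponential lineages", {
  # no lineage ever leaves -> S = 1 throughout
  ws <- .ws_from_paths(replicate(5, cbind(0:10, 0.3, 0.3), simplify = FALSE))
  S <- survival_probability(ws)
  expect_true(all(S$S == 1))
  expect_equal(fit_destruction_rate(S)$k_D, 0)
  # all lineages leave at t0 = 5 -> step function
  path <- cbind(0:10, c(rep(0.3, 5), rep(0.6, 6)), 0.3)
  Sstep <- survival_probability(.ws_from_paths(replicate(4, path,
                                                         simplify = FALSE)))
  expect_equal(Sstep$S[Sstep$t < 5], rep(1, sum(Sstep$t < 5)))
  expect_equal(Sstep$S[Sstep$t >= 5], rep(0, sum(Sstep$t >= 5)))
  # exponential exit times with rate k -> S(t) ~ exp(-k t) (KS test)
  set.seed(52)
  k <- 1 / 40
  n <- 400
  texit <- stats::rexp(n, k)
  paths <- lapply(texit, function(te) {
    tt <- 0:200
    cbind(tt, ifelse(tt < te, 0.30, 0.60), 0.30)
  })
  Sexp <- survival_probability(.ws_from_paths(paths))
  # recovered exits are exactly the generated times (rounded up to the grid)
  ev <- attr(Sexp, "exits")
  expect_equal(sort(ev$t), sort(ceiling(texit)[ceiling(texit) <= 200]))
  # and the curve agrees with the exponential law at mid-decay
  S40 <- Sexp$S[which.min(abs(Sexp$t - 40))]
  expect_equal(S40, exp(-k * 40), tolerance = 0.15)
  # monotone non-increasing by construction
  expect_true(all(diff(Sexp$S) <= 1e-12))
})

test_that("survival is branch-aware: descendants of an exited lineage do not recount", {
  points <- data.frame(
    tree = 1L,
    branch = c(1L, 1L, 1L, 2L, 2L, 1L),
    t = c(0, 1, 2, 2, 3, 3),
    lambda_AC = c(0.3, 0.3, 0.6, 0.6, 0.7, 0.65),
    lambda_BD = 0.3,
    lambda = 0.9,
    w = c(1, 1, 1, 0.5, 0.5, 0.5),
    at_crossing = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  branches <- data.frame(tree = 1L, branch = c(1L, 2L), parent = c(0L, 1L),
                         t_birth = c(0, 2), w_birth = c(1, 0.5))
  ws <- structure(points, branches = branches, n_trees = 1L,
                  class = c("weighted_samples", "data.frame"))
  S <- survival_probability(ws)
  ev <- attr(S, "exits")
  # one exit only, with the full pre-branching weight at the crossing
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$t, 2)
  expect_equal(ev$w, 1)
  expect_equal(S$S[S$t >= 2], rep(0, sum(S$t >= 2)))
})

test_that("lag-scan destruction-rate fit recovers known parameters", {
  tt <- seq(0, 4e4, by = 300)
  k_true <- 1e-4
  lag_true <- 4000
  S_exact <- data.frame(t = tt, S = ifelse(tt < lag_true, 1,
                                           exp(-k_true * (tt - lag_true))))
  fit <- fit_destruction_rate(S_exact, t_start_grid = seq(0, 2e4, by = 1000))
  expect_equal(fit$k_D, k_true, tolerance = 1e-6)
  expect_equal(fit$t_lag, lag_true, tolerance = 1e-2)
  expect_equal(fit$tau_D, 1 / k_true, tolerance = 1e-6)
  # 5% multiplicative noise: recovery within 10%
  set.seed(53)
  S_noisy <- S_exact
  S_noisy$S <- pmin(1, S_noisy$S * exp(rnorm(length(tt), 0, 0.05)))
  fitn <- fit_destruction_rate(S_noisy, t_start_grid = seq(0, 2e4, by = 1000))
  expect_lt(abs(fitn$k_D - k_true) / k_true, 0.1)
  # linear control fit agrees on shallow decay
  S_shallow <- data.frame(t = tt, S = 1 - 2e-6 * tt)
  fits <- fit_destruction_rate(S_shallow, t_start_grid = c(0, 5000))
  expect_equal(fits$linear_k_D, 2e-6, tolerance = 0.05)
})

test_that("average flux is the slope of the region occupation", {
  P1 <- data.frame(t = 0:100, P = 0.01 * (0:100))
  expect_equal(average_flux(P1), 0.01, tolerance = 1e-12)
  P2 <- data.frame(t = 0:100, P = 0.4)
  expect_equal(average_flux(P2), 0, tolerance = 1e-12)
  # probability conservation on synthetic data: fluxes into the three
  # destroyed-pattern regions balance the loss of S
  set.seed(54)
  n <- 600
  texit <- stats::rexp(n, 1 / 50)
  dest <- sample(c("R_ACdag", "R_BDdag", "R_ddag"), n, replace = TRUE,
                 prob = c(0.5, 0.3, 0.2))
  coords <- list(R_ACdag = c(0.55, 0.30), R_BDdag = c(0.30, 0.55),
                 R_ddag = c(0.55, 0.55))
  paths <- lapply(seq_len(n), function(i) {
    tt <- 0:150
    out <- coords[[dest[i]]]
    cbind(tt, ifelse(tt < texit[i], 0.30, out[1]),
          ifelse(tt < texit[i], 0.30, out[2]))
  })
  ws <- .ws_from_paths(paths)
  S <- survival_probability(ws)
  win <- c(0, 60)   # roughly linear early segment
  J <- vapply(c("R_ACdag", "R_BDdag", "R_ddag"), function(r)
    average_flux(region_occupation(ws, r,
                                   t_grid = seq(win[1], win[2])), 0), 0.0)
  dS <- -stats::coef(stats::lm(S ~ t, data = S[S$t <= win[2], ]))[[2]]
  expect_equal(sum(J), dS, tolerance = 0.1)
  expect_true(all(J >= 0))
})

test_that("drift and diffusion estimators recover a known Langevin generator", {
  set.seed(55)
  dt <- 1
  v <- c(-0.02, 0.015)
  D <- 2e-4
  paths <- .langevin_paths(300, 40, dt, v, D,
                           function() c(runif(1, 0.3, 0.5),
                                        runif(1, 0.3, 0.5)))
  ws <- .ws_from_paths(paths)
  b <- phase_bins(nx = 4, xlim = c(0, 1), ylim = c(0, 1))
  vf <- velocity_field(ws, dt, b)
  df <- phase_diffusion(ws, dt, b)
  occupied <- which(vf$n > 1000)
  expect_gt(length(occupied), 0)
  # PSU/h scaling: dt in s, field reported per 3600 s
  expect_equal(mean(vf$vx[occupied]), v[1] * 3600 / dt, tolerance = 0.05)
  expect_equal(mean(vf$vy[occupied]), v[2] * 3600 / dt, tolerance = 0.05)
  expect_equal(mean(df$D[occupied]), D * 3600, tolerance = 0.05)
  # deterministic straight lines: exact drift, zero dispersion
  lin <- .ws_from_paths(list(cbind(0:20, 0.3 + 0.01 * (0:20), 0.35)))
  vl <- velocity_field(lin, 1, b)
  occ <- which(vl$n > 0)
  expect_equal(unique(round(vl$vx[occ], 9)), 0.01 * 3600)
  dl <- phase_diffusion(lin, 1, b)
  expect_true(all(abs(dl$D[which(dl$n > 1)]) < 1e-12))
})

test_that("displacements never straddle branch points", {
  points <- data.frame(
    tree = 1L, branch = c(1L, 1L, 2L, 2L),
    t = c(0, 1, 1, 2),
    lambda_AC = c(0.30, 0.40, 0.40, 0.10),
    lambda_BD = 0.3, lambda = 0.6,
    w = c(1, 1, 0.5, 0.5), at_crossing = FALSE)
  branches <- data.frame(tree = 1L, branch = c(1L, 2L), parent = c(0L, 1L),
                         t_birth = c(0, 1), w_birth = c(1, 0.5))
  ws <- structure(points, branches = branches, n_trees = 1L,
                  class = c("weighted_samples", "data.frame"))
  d <- altcushions:::.displacements(ws, 1)
  # two within-branch pairs only; no pair from branch 1 to branch 2
  expect_equal(nrow(d), 2L)
  expect_setequal(round(d$dx, 6), c(0.1, -0.3))
})

test_that("median filtering removes spikes and preserves structure", {
  m <- matrix(1, 10, 10)
  m[5, 5] <- 100
  f <- median_filter2(m, 4)
  expect_true(all(f == 1))
  # two-Gaussian density: two minima of -log p separated by a saddle whose
  # height matches the analytic density ratio
  b <- phase_bins(nx = 40)
  xg <- b$xmid
  dens <- outer(xg, xg, function(x, y)
    exp(-((x - 0.3)^2 + (y - 0.3)^2) / 0.02) +
    exp(-((x - 0.7)^2 + (y - 0.7)^2) / 0.02))
  dens <- dens / sum(dens)
  set.seed(56)
  idx <- sample(length(dens), 2e5, replace = TRUE, prob = as.vector(dens))
  pts <- cbind(0, xg[(idx - 1) %% 40 + 1], xg[(idx - 1) %/% 40 + 1])
  ws <- .ws_from_paths(list(pts))
  pp <- pseudopotential(ws, bins = b, n_filt = 3)
  pot <- pp$potential
  # minima at the two modes; saddle on the diagonal between them
  i30 <- which.min(abs(xg - 0.3)); i70 <- which.min(abs(xg - 0.7))
  i50 <- which.min(abs(xg - 0.5))
  expect_lt(pot[i30, i30], pot[i50, i50])
  expect_lt(pot[i70, i70], pot[i50, i50])
  barrier <- pot[i50, i50] - pot[i30, i30]
  expected <- -log(dens[i50, i50] / dens[i30, i30])
  expect_equal(barrier, expected, tolerance = 0.25)
  # empty bins are masked, not zero
  expect_true(anyNA(pot))
})
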