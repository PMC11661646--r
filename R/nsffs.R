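#' Configuration of the non-stationary forward-flux sampler
#'
#' The sampler alternates fixed-duration simulator chunks with interface
#' checks on the progress coordinate lambda. Crossing statistics are
#' accumulated per (interface, time-bin); branching and pruning aim at
#' equalizing the weighted crossing flux across time bins.
#'
#' @param interfaces increasing interface positions in lambda; default
#'   0.50 to 0.84 in steps of 0.02.
#' @param time_bin width of the time bins for crossing statistics (s);
#'   default 900 (15 min).
#' @param t_chunk duration of one simulator chunk between interface checks
#'   (s); default 60.
#' @param dt_measure interval between stored phase points (s); must be a
#'   multiple of `t_chunk`; default 300.
#' @param n_B_max maximal branching number; default 4. `n_B_max = 1`
#'   degenerates the sampler into plain direct simulation.
#' @param t_end_tree duration of the time histogram: each trajectory tree is
#'   propagated from 0 to this time (s).
#' @param T_cum_target total simulated-time budget (s); new trees are started
#'   until it is exhausted (the last tree is always finished).
#' @param t_relax relaxation run prepended to each tree before its clock
#'   starts (s); default 1800.
#' @param cold_start_min minimum number of recorded crossings in a bin before
#'   branching/pruning decisions are made there; default 20.
#' @param max_active safety cap on simultaneously active branches per tree.
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(interfaces = seq(0.50, 0.84, by = 0.02),
                           time_bin = 900, t_chunk = 60, dt_measure = 300,
                           n_B_max = 4, t_end_tree = 3 * 3600,
                           T_cum_target = 1e5, t_relax = 1800,
                           cold_start_min = 20, max_active = 10000) {
  stopifnot(all(diff(interfaces) > 0), all(interfaces > 0), all(interfaces <= 1),
            t_chunk > 0, n_B_max >= 1, t_end_tree > 0, time_bin > 0)
  if (abs(dt_measure / t_chunk - round(dt_measure / t_chunk)) > 1e-9)
    stop("dt_measure must be a multiple of t_chunk")
  structure(list(interfaces = interfaces, time_bin = time_bin,
                 t_chunk = t_chunk, dt_measure = dt_measure,
                 n_B_max = n_B_max, t_end_tree = t_end_tree,
                 T_cum_target = T_cum_target, t_relax = t_relax,
                 cold_start_min = cold_start_min, max_active = max_active),
            class = "sampler_config")
}

#' Branching/pruning decision at an interface crossing
#'
#' Flux equalization rule: let `target` be the mean accumulated crossing
#' weight over the *other* time bins already touched at this interface and
#' `obs` the accumulated weight in the crossing's own bin. With `ratio = target / obs`:
#' undersampled bins (`ratio >= 1`) branch into
#' `n = min(round(ratio), n_B_max)` children of weight `w/n`; oversampled
#' bins (`ratio < 1`) apply Russian-roulette pruning with survival
#' probability `q = max(ratio, 1/2)`, the survivor continuing with weight
#' `w/q`. Until a bin has `cold_start_min` recorded crossings the identity
#' decision (one child, unchanged weight) is returned.
#'
#' @param crossing list with `iface` (interface index), `bin` (time-bin
#'   index) and `w` (weight of the crossing trajectory).
#' @param stats crossing statistics: list of matrices `w` and `n`
#'   (interfaces x bins) of accumulated weights and counts, already including
#'   this crossing.
#' @param cfg a [sampler_config].
#' @param u uniform random number used for the pruning draw (exposed for
#'   testing).
#' @return list `n_children` (0 = pruned), `child_weight`, `q` (survival
#'   probability used, 1 if none).
#' @export
branch_decision <- function(crossing, stats, cfg, u = stats::runif(1)) {
  i <- crossing$iface
  b <- crossing$bin
  other <- stats$n[i, ] > 0
  other[b] <- FALSE
  if (stats$n[i, b] < cfg$cold_start_min || !any(other))
    return(list(n_children = 1L, child_weight = crossing$w, q = 1))
  target <- mean(stats$w[i, other])
  obs <- stats$w[i, b]
  ratio <- target / obs
  if (ratio >= 1) {
    n <- max(1L, min(as.integer(round(ratio)), as.integer(cfg$n_B_max)))
    list(n_children = n, child_weight = crossing$w / n, q = 1)
  } else {
    q <- max(ratio, 0.5)
    if (u < q) list(n_children = 1L, child_weight = crossing$w / q, q = q)
    else list(n_children = 0L, child_weight = 0, q = q)
  }
}

#' Lattice propagator for the sampler
#'
#' Wraps the exact lattice simulator into the propagator interface used by
#' [run_nsffs()]: `init(t_relax)` builds and relaxes a fresh five-stripe
#' initial state, `step(state, t_dur)` advances it, `coords(state)` maps it
#' to (lambda_AC, lambda_BD, lambda).
#'
#' @param p an [ac_params] object.
#' @param copies_per_nucleus initial copies for [init_pattern()].
#' @return a propagator list.
#' @export
lattice_propagator <- function(p, copies_per_nucleus = 15) {
  list(
    init = function(t_relax = 0) {
      st <- init_pattern(p, copies_per_nucleus)
      if (t_relax > 0) st <- relax_state(st, p, t_relax)
      st$time <- 0
      st
    },
    step = function(state, t_dur) {
      ssa_run(state, p, state$time + t_dur, record = "none")$state
    },
    coords = function(state) {
      lam <- asymmetry_factors(state, p)
      c(lambda_AC = unname(lam[1]), lambda_BD = unname(lam[2]),
        lambda = unname(sum(lam)))
    })
}

#' Birth-death toy propagator
#'
#' One-species birth-death process (birth rate `b`, death rate `d * n`) used
#' to validate sampler unbiasedness against brute-force simulation. The
#' progress coordinate is `n / K`.
#'
#' @param n0 initial count.
#' @param b,d birth and death rates.
#' @param K threshold count defining lambda = 1.
#' @export
bd_propagator <- function(n0, b, d, K) {
  list(
    init = function(t_relax = 0) list(time = 0, n = n0),
    step = function(state, t_dur) {
      list(time = state$time + t_dur,
           n = .bd_run_cpp(state$n, b, d, t_dur))
    },
    coords = function(state) {
      lam <- state$n / K
      c(lambda_AC = lam, lambda_BD = 0, lambda = lam)
    })
}

#' Run the non-stationary forward-flux sampler
#'
#' Grows an ensemble of branched, weighted trajectory trees. Each tree starts
#' from a freshly initialized (and relaxed) state with root weight 1;
#' trajectories are propagated in chunks of `cfg$t_chunk`; whenever the
#' progress coordinate crosses an interface upwards for the first time in a
#' lineage, the crossing is recorded and [branch_decision()] may split the
#' trajectory into weight-sharing children or prune it (re-crossings by an
#' oscillating coordinate trigger no further decisions, which keeps weights
#' bounded). Phase points are stored at every crossing and every
#' `cfg$dt_measure`. New trees are started until the cumulative simulated
#' time (including relaxation) exceeds `cfg$T_cum_target`.
#'
#' @param propagator a propagator (see [lattice_propagator()],
#'   [bd_propagator()]).
#' @param cfg a [sampler_config].
#' @param verbose print per-tree progress.
#' @return an `nsffs_trees` object: data frames `points`, `branches`,
#'   `crossings`, the crossing `stats`, `T_cum` and `n_trees`.
#' @export
run_nsffs <- function(propagator, cfg, verbose = FALSE) {
  n_ifc <- length(cfg$interfaces)
  n_bins <- max(1L, ceiling(cfg$t_end_tree / cfg$time_bin))
  stats <- list(w = matrix(0, n_ifc, n_bins), n = matrix(0L, n_ifc, n_bins))
  # row buffers (numeric vectors; assembled into data frames at the end)
  pts <- list(); brs <- list(); crs <- list()
  T_cum <- 0
  tree <- 0L
  eps <- 1e-9

  while (T_cum < cfg$T_cum_target) {
    tree <- tree + 1L
    st0 <- propagator$init(cfg$t_relax)
    T_cum <- T_cum + cfg$t_relax
    next_branch <- 1L
    co0 <- propagator$coords(st0)
    active <- list(list(id = 1L, parent = 0L, t = 0, w = 1, state = st0,
                        lam = co0[["lambda"]],
                        seen = rep(FALSE, n_ifc)))
    brs[[length(brs) + 1L]] <- c(tree, 1, 0, 0, 1)
    pts[[length(pts) + 1L]] <- c(tree, 1, 0, co0[["lambda_AC"]],
                                 co0[["lambda_BD"]], co0[["lambda"]], 1, 0)
    while (length(active) > 0) {
      br <- active[[length(active)]]
      active[[length(active)]] <- NULL
      repeat {
        if (br$t >= cfg$t_end_tree - eps) break
        st <- propagator$step(br$state, cfg$t_chunk)
        T_cum <- T_cum + cfg$t_chunk
        br$t <- br$t + cfg$t_chunk
        br$state <- st
        co <- propagator$coords(st)
        lam_new <- co[["lambda"]]
        on_grid <- abs(br$t / cfg$dt_measure - round(br$t / cfg$dt_measure)) < 1e-6
        # first upward crossings of this lineage only: re-crossings by an
        # oscillating coordinate trigger no further decisions (keeps the
        # Russian-roulette weight variance bounded)
        crossed <- which(cfg$interfaces > br$lam + eps &
                         cfg$interfaces <= lam_new + eps &
                         !br$seen)
        if (length(crossed) || on_grid)
          pts[[length(pts) + 1L]] <- c(tree, br$id, br$t, co[["lambda_AC"]],
                                       co[["lambda_BD"]], lam_new, br$w,
                                       as.numeric(length(crossed) > 0))
        br$lam <- lam_new
        if (length(crossed)) {
          br$seen[crossed] <- TRUE
          bin <- min(n_bins, 1L + as.integer(br$t %/% cfg$time_bin))
          for (i in crossed) {
            stats$w[i, bin] <- stats$w[i, bin] + br$w
            stats$n[i, bin] <- stats$n[i, bin] + 1L
          }
          i_dec <- max(crossed)
          dec <- branch_decision(list(iface = i_dec, bin = bin, w = br$w),
                                 stats, cfg)
          crs[[length(crs) + 1L]] <- c(tree, br$id, br$t, i_dec, bin, br$w,
                                       dec$n_children, dec$q)
          if (dec$n_children == 0L) break
          br$w <- dec$child_weight
          if (dec$n_children > 1L) {
            if (length(active) + dec$n_children - 1L > cfg$max_active)
              stop("active branch cap exceeded; check sampler configuration")
            for (k in seq_len(dec$n_children - 1L)) {
              next_branch <- next_branch + 1L
              active[[length(active) + 1L]] <-
                list(id = next_branch, parent = br$id, t = br$t,
                     w = dec$child_weight, state = br$state, lam = br$lam,
                     seen = br$seen)
              brs[[length(brs) + 1L]] <- c(tree, next_branch, br$id, br$t,
                                           dec$child_weight)
            }
          }
        }
      }
      # branch finished (leaf) or pruned
    }
    if (verbose)
      message(sprintf("tree %d done, T_cum = %.3g s", tree, T_cum))
  }
  pm <- do.call(rbind, pts)
  points <- data.frame(tree = as.integer(pm[, 1]), branch = as.integer(pm[, 2]),
                       t = pm[, 3], lambda_AC = pm[, 4], lambda_BD = pm[, 5],
                       lambda = pm[, 6], w = pm[, 7],
                       at_crossing = pm[, 8] > 0)
  bm <- do.call(rbind, brs)
  branches <- data.frame(tree = as.integer(bm[, 1]), branch = as.integer(bm[, 2]),
                         parent = as.integer(bm[, 3]), t_birth = bm[, 4],
                         w_birth = bm[, 5])
  crossings <- NULL
  if (length(crs)) {
    cm <- do.call(rbind, crs)
    crossings <- data.frame(tree = as.integer(cm[, 1]), branch = as.integer(cm[, 2]),
                            t = cm[, 3], iface = as.integer(cm[, 4]),
                            bin = as.integer(cm[, 5]), w = cm[, 6],
                            n_children = as.integer(cm[, 7]), q = cm[, 8])
  }
  structure(list(points = points, branches = branches, crossings = crossings,
                 stats = stats, cfg = cfg, T_cum = T_cum, n_trees = tree),
            class = "nsffs_trees")
}

#' @export
print.nsffs_trees <- function(x, ...) {
  cat(sprintf("nsffs_trees: %d trees, %d branches, %d phase points, T_cum = %.4g s\n",
              x$n_trees, nrow(x$branches), nrow(x$points), x$T_cum))
  invisible(x)
}

#' Flatten trajectory trees into reweighted phase-space samples
#'
#' Applies the root normalization 1 / (number of trees) so that the weighted
#' sample stream is an unbiased estimate of the time-dependent phase-space
#' density of the unbiased dynamics.
#'
#' @param trees an `nsffs_trees` object.
#' @return a `weighted_samples` data frame (t, lambda_AC, lambda_BD, lambda,
#'   w, tree, branch, at_crossing) with the normalized branch table in
#'   attribute `"branches"`.
#' @export
reweight <- function(trees) {
  pts <- trees$points
  pts$w <- pts$w / trees$n_trees
  out <- pts[, c("t", "lambda_AC", "lambda_BD", "lambda", "w", "tree",
                 "branch", "at_crossing")]
  br <- trees$branches
  br$w_birth <- br$w_birth / trees$n_trees
  attr(out, "branches") <- br
  attr(out, "n_trees") <- trees$n_trees
  class(out) <- c("weighted_samples", "data.frame")
  out
}

#' Build weighted samples from independent direct trajectories
#'
#' Wraps a list of per-trajectory phase-point data frames (columns t,
#' lambda_AC, lambda_BD; e.g. from [phase_points()]) as an unbranched
#' `weighted_samples` object with equal weights, so that direct-simulation
#' ensembles can be analyzed with the same tools as sampler output.
#'
#' @param traj_list list of data frames.
#' @export
as_weighted_samples <- function(traj_list) {
  n <- length(traj_list)
  pts <- do.call(rbind, lapply(seq_len(n), function(i) {
    d <- traj_list[[i]]
    if (is.null(d$lambda)) d$lambda <- d$lambda_AC + d$lambda_BD
    data.frame(t = d$t, lambda_AC = d$lambda_AC, lambda_BD = d$lambda_BD,
               lambda = d$lambda, w = 1 / n, tree = i, branch = 1L,
               at_crossing = FALSE)
  }))
  br <- data.frame(tree = seq_len(n), branch = 1L, parent = 0L, t_birth = 0,
                   w_birth = 1 / n)
  attr(pts, "branches") <- br
  attr(pts, "n_trees") <- n
  class(pts) <- c("weighted_samples", "data.frame")
  pts
}

# First event per lineage: for each tree/branch, the first recorded point for
# which `outside` is TRUE, inherited along branch ancestry (descendants of a
# lineage that has already left contribute nothing further). Returns a data
# frame (tree, branch, t, w) of first-exit events.
.lineage_first_events <- function(ws, outside) {
  br <- attr(ws, "branches")
  stopifnot(!is.null(br))
  ev <- list()
  for (tr in unique(br$tree)) {
    b <- br[br$tree == tr, ]
    b <- b[order(b$t_birth, b$branch), ]
    p <- ws[ws$tree == tr, ]
    o <- outside[ws$tree == tr]
    exit_t <- rep(Inf, max(b$branch))
    for (k in seq_len(nrow(b))) {
      id <- b$branch[k]
      par <- b$parent[k]
      if (par > 0 && is.finite(exit_t[par]) && exit_t[par] <= b$t_birth[k] + 1e-9) {
        exit_t[id] <- exit_t[par]    # born after lineage already left
        next
      }
      sel <- p$branch == id & o
      if (any(sel)) {
        tts <- p$t[sel]
        j <- which.min(tts)
        exit_t[id] <- tts[j]
        ev[[length(ev) + 1L]] <- data.frame(tree = tr, branch = id,
                                            t = tts[j],
                                            w = p$w[sel][j])
      }
    }
  }
  if (length(ev)) do.call(rbind, ev)
  else data.frame(tree = integer(), branch = integer(), t = numeric(),
                  w = numeric())
}

#' Weighted first-passage probability over a lambda threshold
#'
#' Probability that the progress coordinate has reached `lambda_star` at one
#' of the observation times up to `t_max`, estimated from the weighted tree
#' ensemble (each lineage contributes the weight it carries at its first
#' crossing).
#'
#' @param trees an `nsffs_trees` object or `weighted_samples`.
#' @param lambda_star threshold.
#' @param t_max time horizon (default: end of the records).
#' @return list with `estimate`, per-tree estimates `per_tree`, and their
#'   standard error `se`.
#' @export
first_passage_weight <- function(trees, lambda_star, t_max = Inf) {
  ws <- if (inherits(trees, "nsffs_trees")) reweight(trees) else trees
  outside <- ws$lambda >= lambda_star - 1e-12 & ws$t <= t_max
  ev <- .lineage_first_events(ws, outside)
  n_trees <- attr(ws, "n_trees")
  per_tree <- vapply(seq_len(n_trees), function(tr)
    sum(ev$w[ev$tree == tr]) * n_trees, 0.0)
  list(estimate = sum(ev$w),
       per_tree = per_tree,
       se = stats::sd(per_tree) / sqrt(n_trees))
}
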