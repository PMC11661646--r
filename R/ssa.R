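#' Diffusive hop rate of the next-subvolume method
#'
#' Total per-particle hop propensity between lattice neighbours,
#' `k_diff = 4 * D_P / l^2`, split uniformly over the (up to four) existing
#' neighbours; axial moves off the lattice ends are absent (no-flux).
#'
#' @param p an [ac_params] object.
#' @return hop rate in 1/s.
#' @examples
#' hop_rate(default_params()) # ~0.0554 /s
#' @export
hop_rate <- function(p) {
  stopifnot(p$l > 0)
  4 * p$D_P / p$l^2
}

#' Create an empty lattice state
#'
#' @param p an [ac_params] object.
#' @param time initial time (s).
#' @return a `lattice_state`: per-nucleus monomer (`n1`) and free-dimer
#'   (`n2`) counts per gene (4 x Ncell integer matrices, rows named A-D),
#'   promoter occupancy `bnd` (target x repressor x nucleus 0/1 array), and
#'   lattice geometry. Nucleus `cell = (phi - 1) * N_z + z` (1-based).
#' @export
empty_state <- function(p, time = 0) {
  nc <- p$N_z * p$N_phi
  n1 <- matrix(0L, 4, nc, dimnames = list(ac_genes, NULL))
  n2 <- n1
  bnd <- array(0L, c(4, 4, nc), dimnames = list(ac_genes, ac_genes, NULL))
  structure(list(time = time, n1 = n1, n2 = n2, bnd = bnd,
                 N_z = p$N_z, N_phi = p$N_phi),
            class = "lattice_state")
}

#' Axial row index of each nucleus
#' @param state a `lattice_state`.
#' @return integer vector of 1-based z rows, one per nucleus column.
#' @export
state_rows <- function(state) {
  rep_len(seq_len(state$N_z), state$N_z * state$N_phi)
}

#' Standardized five-stripe initial pattern
#'
#' Five non-overlapping rectangular stripes in axial order A-B-C-D-A, each
#' occupying an equal share of the system length, with `copies_per_nucleus`
#' monomers of the stripe-owner gene in every nucleus (no dimers, all
#' promoter sites free). If `N_z` is not divisible by 5 the remainder is
#' distributed one row at a time starting from the anterior stripe.
#'
#' @param p an [ac_params] object.
#' @param copies_per_nucleus monomers per nucleus in each stripe (default 15,
#'   the target steady-state copy number).
#' @return a `lattice_state`.
#' @export
init_pattern <- function(p, copies_per_nucleus = 15) {
  st <- empty_state(p)
  w <- rep(p$N_z %/% 5L, 5L)
  rem <- p$N_z %% 5L
  if (rem > 0) w[seq_len(rem)] <- w[seq_len(rem)] + 1L
  owner <- c("A", "B", "C", "D", "A")
  gene_of_row <- rep(owner, times = w)
  z <- state_rows(st)
  for (cell in seq_along(z)) {
    st$n1[gene_of_row[z[cell]], cell] <- as.integer(copies_per_nucleus)
  }
  st
}

#' Total copy numbers per gene
#'
#' Total protein copies of each gene across the lattice, counting dimers
#' twice and including repressor dimers bound at promoters.
#'
#' @param state a `lattice_state`.
#' @param p an [ac_params] object.
#' @return named numeric vector (A, B, C, D).
#' @export
state_totals <- function(state, p) {
  .ssa_totals_cpp(unclass(state), .cpp_params(p))
}

#' Run the exact lattice simulation
#'
#' Gillespie direct-method simulation of the full reaction-diffusion lattice
#' from `state$time` to `t_end`, recording observables every `acq_dt`
#' seconds. Runs are reproducible: all randomness comes from R's RNG, so call
#' `set.seed()` first.
#'
#' @param state a `lattice_state` (see [init_pattern()]).
#' @param p an [ac_params] object.
#' @param t_end absolute end time (s); must be `>= state$time`.
#' @param acq_dt acquisition interval (s); `0` disables recording.
#' @param record one of `"totals"` (per-gene system totals), `"profile"`
#'   (adds circumferentially summed axial profiles), `"snapshot"` (adds full
#'   lattice snapshots), `"none"`.
#' @param max_events safety cap on the number of reaction events.
#' @return a `trajectory_record`: `times`, `totals` (4 x n matrix),
#'   optionally `profiles` / `snapshots`, the final `state`, `n_events`, and
#'   `absorbed` (TRUE if an all-zero-propensity state was reached).
#' @export
ssa_run <- function(state, p, t_end, acq_dt = 60,
                    record = c("totals", "profile", "snapshot", "none"),
                    max_events = Inf) {
  record <- match.arg(record)
  if (t_end < state$time) stop("t_end must be >= state$time")
  lvl <- switch(record, none = 0L, totals = 1L, profile = 2L, snapshot = 3L)
  res <- .ssa_run_cpp(unclass(state), .cpp_params(p), t_end,
                      if (lvl > 0) acq_dt else 0,
                      lvl, if (is.finite(max_events)) max_events else 1e18)
  res$state <- .restore_state(res$state)
  rownames(res$totals) <- ac_genes
  if (!is.null(res$profiles))
    res$profiles <- lapply(res$profiles, function(m) {
      colnames(m) <- ac_genes
      m
    })
  if (!is.null(res$snapshots))
    res$snapshots <- lapply(res$snapshots, .restore_state)
  class(res) <- "trajectory_record"
  res
}

# reattach gene dimnames and class to a state coming back from the C++ core
.restore_state <- function(st) {
  dimnames(st$n1) <- list(ac_genes, NULL)
  dimnames(st$n2) <- list(ac_genes, NULL)
  dimnames(st$bnd) <- list(ac_genes, ac_genes, NULL)
  structure(st, class = "lattice_state")
}

#' Advance the simulation by exactly one reaction event
#'
#' @inheritParams ssa_run
#' @return list with the updated `state`, the waiting time `dt` of the event,
#'   and `absorbed` (TRUE if no channel had positive propensity, in which
#'   case the state is returned unchanged).
#' @export
ssa_step <- function(state, p) {
  res <- .ssa_run_cpp(unclass(state), .cpp_params(p), Inf, 0, 0L, 1)
  st <- .restore_state(res$state)
  list(state = st, dt = st$time - state$time, absorbed = res$absorbed)
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf("trajectory_record: %d records to t = %.6g s, %g events%s\n",
              length(x$times), x$state$time, x$n_events,
              if (isTRUE(x$absorbed)) " (absorbed)" else ""))
  invisible(x)
}

#' Circumferentially averaged expression profile
#'
#' @param state a `lattice_state`.
#' @param p an [ac_params] object.
#' @return data frame (z, gene, total_copies): per-row total copies (dimers
#'   twice, bound repressors included at the nucleus where they are bound).
#' @export
axial_profile <- function(state, p) {
  nz <- state$N_z
  z <- state_rows(state)
  tot <- state$n1 + 2L * state$n2
  bound_by_rep <- apply(state$bnd, c(2, 3), sum)  # repressor x cell
  tot <- tot + 2L * bound_by_rep
  out <- expand.grid(z = seq_len(nz), gene = ac_genes,
                     stringsAsFactors = FALSE)
  # columns of sapply() are genes, rows are z: matches expand.grid order
  out$total_copies <- as.vector(sapply(ac_genes, function(g)
    tapply(tot[g, ], z, sum)))
  out[order(out$z, match(out$gene, ac_genes)), ]
}

#' Write recorded snapshots as TSV
#'
#' Long-format table with columns time_s, z, phi, gene, monomers, dimers,
#' bound_sites (repressor dimers of that gene bound in that nucleus).
#'
#' @param rec a `trajectory_record` produced with `record = "snapshot"`.
#' @param path output file.
#' @export
write_snapshots_tsv <- function(rec, path) {
  if (is.null(rec$snapshots)) stop("record was not run with record = 'snapshot'")
  rows <- lapply(seq_along(rec$snapshots), function(i) {
    st <- rec$snapshots[[i]]
    nc <- ncol(st$n1)
    z <- rep_len(seq_len(st$N_z), nc)
    phi <- rep(seq_len(st$N_phi), each = st$N_z)
    bound_by_rep <- apply(st$bnd, c(2, 3), sum)
    do.call(rbind, lapply(seq_len(4), function(g)
      data.frame(time_s = rec$times[i], z = z, phi = phi, gene = ac_genes[g],
                 monomers = st$n1[g, ], dimers = st$n2[g, ],
                 bound_sites = bound_by_rep[g, ])))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Relax an initial pattern into the metastable basin
#'
#' Convenience wrapper: run the simulator for `t_relax` seconds (default 30
#' simulated minutes) without recording and return the final state.
#'
#' @inheritParams ssa_run
#' @param t_relax relaxation duration (s).
#' @export
relax_state <- function(state, p, t_relax = 1800) {
  ssa_run(state, p, state$time + t_relax, record = "none")$state
}
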