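#' Perturbation experiment protocol
#'
#' Defaults follow the standard protocol: perturbation severities of 4, 8 or
#' 12 rows, 30 min relaxation before perturbing, 20 h of re-simulation with
#' snapshots every 10 min, 10 independent samples.
#'
#' @param kind `"C_expansion"` (central C domain expanded posteriorly at the
#'   expense of the posterior A domain) or `"A_expansion"` (anterior A domain
#'   expanded at the expense of C).
#' @param delta perturbation severity in rows (>= 1; `0` is the identity).
#' @param t_relax relaxation time before perturbing (s).
#' @param t_sim simulation time after perturbing (s).
#' @param snapshot_dt snapshot interval (s).
#' @param n_samples number of independently perturbed replicates.
#' @return a `perturbation_protocol` list.
#' @export
perturbation_protocol <- function(kind = c("C_expansion", "A_expansion"),
                                  delta = 8, t_relax = 1800,
                                  t_sim = 20 * 3600, snapshot_dt = 600,
                                  n_samples = 10) {
  kind <- match.arg(kind)
  stopifnot(delta >= 0, t_relax >= 0, t_sim > 0, snapshot_dt > 0,
            n_samples >= 1)
  structure(list(kind = kind, delta = as.integer(delta), t_relax = t_relax,
                 t_sim = t_sim, snapshot_dt = snapshot_dt,
                 n_samples = as.integer(n_samples)),
            class = "perturbation_protocol")
}

# copy the full nucleus configuration (counts and promoter occupancy) of
# column `from` onto column `to`
.copy_nucleus <- function(state, orig, to, from) {
  state$n1[, to] <- orig$n1[, from]
  state$n2[, to] <- orig$n2[, from]
  state$bnd[, , to] <- orig$bnd[, , from]
  state
}

#' Apply a copy-shift perturbation to a relaxed lattice state
#'
#' Deterministic domain-expansion edit. With 1-based axial rows and
#' mid-embryo row `m = N_z / 2`:
#'
#' * `C_expansion`: the source ring is the row just posterior to mid-embryo,
#'   `m + 1`. Every row `z` in `(m + 1, N_z - 1]` receives the original
#'   configuration of row `max(z - delta, m + 1)` (so the first `delta` rows
#'   replicate the source ring and the rest shift back by `delta`). The
#'   posterior-most row is exempt, preserving pinning.
#' * `A_expansion`: same procedure with source row 5, applied only to rows
#'   `z` in `(5, m]`.
#'
#' Each circumferential position copies its own column, and the full nucleus
#' configuration (monomers, dimers, bound repressor sites) is moved, so
#' promoter bookkeeping stays valid.
#'
#' @param state a relaxed `lattice_state`.
#' @param proto a [perturbation_protocol].
#' @return the perturbed `lattice_state`.
#' @export
perturb <- function(state, proto) {
  d <- proto$delta
  if (d == 0) return(state)
  nz <- state$N_z
  m <- nz %/% 2L
  if (proto$kind == "C_expansion") {
    src <- m + 1L
    rows <- seq(src + 1L, nz - 1L)
  } else {
    src <- 5L
    rows <- seq(src + 1L, m)
  }
  if (d >= length(rows) + 1L)
    stop("invalid protocol: delta leaves no source rows")
  z <- state_rows(state)
  orig <- state
  for (zi in rows) {
    zfrom <- max(zi - d, src)
    to_cells <- which(z == zi)
    from_cells <- which(z == zfrom)
    for (k in seq_along(to_cells))
      state <- .copy_nucleus(state, orig, to_cells[k], from_cells[k])
  }
  state
}

#' Run a perturbation experiment ensemble
#'
#' For each replicate: relax a fresh five-stripe pattern for
#' `proto$t_relax`, apply the perturbation, re-simulate for `proto$t_sim`,
#' and record the centre of mass of each expression domain (A split into
#' anterior and posterior halves) every `proto$snapshot_dt`.
#'
#' @param p an [ac_params] object.
#' @param proto a [perturbation_protocol].
#' @param copies_per_nucleus initial copies for [init_pattern()].
#' @param verbose print per-sample progress.
#' @return list with `series` (data frame: time_s, sample_id, domain,
#'   z_com) and `mean` (ensemble mean per domain and time).
#' @export
run_experiment <- function(p, proto, copies_per_nucleus = 15,
                           verbose = FALSE) {
  nz <- p$N_z
  half_ant <- seq_len(nz %/% 2L)
  half_post <- seq(nz %/% 2L + 1L, nz)
  doms <- c("A_ant", "B", "C", "D", "A_post")
  rows <- list()
  for (s in seq_len(proto$n_samples)) {
    st <- init_pattern(p, copies_per_nucleus)
    if (proto$t_relax > 0) st <- relax_state(st, p, proto$t_relax)
    st <- perturb(st, proto)
    st$time <- 0
    rec <- ssa_run(st, p, proto$t_sim, acq_dt = proto$snapshot_dt,
                   record = "snapshot")
    for (i in seq_along(rec$times)) {
      snap <- structure(rec$snapshots[[i]], class = "lattice_state")
      com <- c(
        suppressWarnings(center_of_mass(snap, p, "A", half_ant)),
        suppressWarnings(center_of_mass(snap, p, "B")),
        suppressWarnings(center_of_mass(snap, p, "C")),
        suppressWarnings(center_of_mass(snap, p, "D")),
        suppressWarnings(center_of_mass(snap, p, "A", half_post)))
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = rec$times[i], sample_id = s, domain = doms, z_com = com)
    }
    if (verbose) message(sprintf("sample %d/%d done", s, proto$n_samples))
  }
  series <- do.call(rbind, rows)
  agg <- stats::aggregate(z_com ~ time_s + domain, data = series,
                          FUN = mean, na.rm = TRUE, na.action = NULL)
  list(series = series, mean = agg[order(agg$domain, agg$time_s), ])
}

#' Write centre-of-mass series as TSV
#'
#' @param exp_out output of [run_experiment()].
#' @param path base path; per-sample series go to `path`, ensemble means to
#'   `paste0(path, ".mean.tsv")`.
#' @export
write_com_tsv <- function(exp_out, path) {
  utils::write.table(exp_out$series, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(exp_out$mean, paste0(path, ".mean.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
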