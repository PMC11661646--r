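#' Pattern asymmetry factors
#'
#' The two order parameters that track destruction of the five-stripe
#' pattern: for each strongly repressing (next-nearest-neighbour) pair, the
#' copy-number fraction of its dominant member,
#' `lambda_AC = max(A_tot, C_tot) / N` and
#' `lambda_BD = max(B_tot, D_tot) / N`, where totals count dimers twice and
#' `N` is the total over all four genes. A well-ordered pattern sits near
#' (0.25, 0.25); loss of a domain drives the corresponding factor towards
#' 0.5.
#'
#' If both members of a pair are absent the factor is defined as 0 and
#' flagged via the `"degenerate"` attribute.
#'
#' @param x either a named numeric vector of per-gene totals
#'   (`c(A=,B=,C=,D=)`) or a `lattice_state` (then `p` is required).
#' @param p an [ac_params] object (for the `lattice_state` method).
#' @return named vector `c(lambda_AC=, lambda_BD=)`.
#' @export
asymmetry_factors <- function(x, p = NULL) {
  tot <- .gene_totals(x, p)
  N <- sum(tot)
  if (N <= 0) stop("undefined state: no proteins present")
  pair <- function(a, b) {
    if (tot[a] + tot[b] == 0) return(structure(0, degenerate = TRUE))
    max(tot[a], tot[b]) / N
  }
  lac <- pair("A", "C")
  lbd <- pair("B", "D")
  out <- c(lambda_AC = as.numeric(lac), lambda_BD = as.numeric(lbd))
  deg <- c(isTRUE(attr(lac, "degenerate")), isTRUE(attr(lbd, "degenerate")))
  if (any(deg)) attr(out, "degenerate") <- c("AC", "BD")[deg]
  out
}

.gene_totals <- function(x, p) {
  if (inherits(x, "lattice_state")) {
    if (is.null(p)) stop("p required for a lattice_state")
    state_totals(x, p)
  } else {
    if (is.null(names(x))) names(x) <- ac_genes
    x[ac_genes]
  }
}

#' Progress coordinate for pattern breakdown
#'
#' `lambda = lambda_AC + lambda_BD`; around 0.5 for intact five-stripe
#' patterns and above 0.75 when a domain has been lost.
#'
#' @inheritParams asymmetry_factors
#' @export
progress_coordinate <- function(x, p = NULL) {
  unname(sum(asymmetry_factors(x, p)))
}

#' Shifted difference coordinates
#'
#' Signed alternative to the asymmetry factors:
#' `delta_AC = (A_tot - C_tot) / (2 N) + 1/2` (and likewise for B, D). The
#' intact symmetric pattern maps to (1/2, 1/2); the sign records which member
#' of the strongly competing pair dominates.
#'
#' @inheritParams asymmetry_factors
#' @return named vector `c(delta_AC=, delta_BD=)`.
#' @export
shifted_differences <- function(x, p = NULL) {
  tot <- .gene_totals(x, p)
  N <- sum(tot)
  if (N <= 0) stop("undefined state: no proteins present")
  c(delta_AC = unname((tot["A"] - tot["C"]) / (2 * N) + 0.5),
    delta_BD = unname((tot["B"] - tot["D"]) / (2 * N) + 0.5))
}

#' Phase-space region labels
#' @export
ac_regions <- c("R_S", "R_ACdag", "R_BDdag", "R_ddag")

#' Classify a phase-space point into pattern-integrity regions
#'
#' Partition of the (lambda_AC, lambda_BD) plane:
#' `R_S` (intact five-stripe patterns, lambda_AC <= 0.45 and
#' lambda_BD <= 0.43), `R_ACdag` (A or C domain lost), `R_BDdag` (B or D
#' lost), `R_ddag` (both pairs decided). Boundary points belong to the `<=`
#' side.
#'
#' @param lambda_AC,lambda_BD coordinates in `[0, 1]` (vectorized).
#' @param thresholds the (lambda_AC, lambda_BD) region boundaries, default
#'   `c(0.45, 0.43)`.
#' @return factor with levels [ac_regions].
#' @export
classify_region <- function(lambda_AC, lambda_BD, thresholds = c(0.45, 0.43)) {
  stopifnot(length(thresholds) == 2)
  hi_ac <- lambda_AC > thresholds[1]
  hi_bd <- lambda_BD > thresholds[2]
  lab <- ifelse(hi_ac & hi_bd, "R_ddag",
                ifelse(hi_ac, "R_ACdag",
                       ifelse(hi_bd, "R_BDdag", "R_S")))
  factor(lab, levels = ac_regions)
}

#' Centre of mass of an expression domain
#'
#' Count-weighted mean axial row of a gene's total copies (dimers twice,
#' bound repressors included), over an axial window. The A domain is split in
#' two, so its centre is evaluated separately on the anterior and posterior
#' halves.
#'
#' @param state a `lattice_state`.
#' @param p an [ac_params] object.
#' @param gene gene label.
#' @param z_window integer vector of 1-based axial rows (default: all).
#' @return centre of mass in row units, or `NA` (with a warning) if the gene
#'   has no copies in the window.
#' @export
center_of_mass <- function(state, p, gene, z_window = seq_len(state$N_z)) {
  prof <- axial_profile(state, p)
  prof <- prof[prof$gene == gene & prof$z %in% z_window, ]
  tot <- sum(prof$total_copies)
  if (tot <= 0) {
    warning("zero copies of ", gene, " in window: centre of mass undefined")
    return(NA_real_)
  }
  sum(prof$z * prof$total_copies) / tot
}

#' Phase points of a recorded trajectory
#'
#' Maps a `trajectory_record` (run with totals recording) onto the reduced
#' phase space.
#'
#' @param rec a `trajectory_record`.
#' @param weight statistical weight attached to each point (default 1).
#' @return data frame (t, lambda_AC, lambda_BD, lambda, delta_AC, delta_BD,
#'   w).
#' @export
phase_points <- function(rec, weight = 1) {
  tot <- rec$totals
  N <- colSums(tot)
  data.frame(
    t = rec$times,
    lambda_AC = pmax(tot["A", ], tot["C", ]) / N,
    lambda_BD = pmax(tot["B", ], tot["D", ]) / N,
    lambda = (pmax(tot["A", ], tot["C", ]) + pmax(tot["B", ], tot["D", ])) / N,
    delta_AC = (tot["A", ] - tot["C", ]) / (2 * N) + 0.5,
    delta_BD = (tot["B", ] - tot["D", ]) / (2 * N) + 0.5,
    w = weight)
}

#' Write a stream of phase points as TSV
#'
#' @param pts data frame as returned by [phase_points()] or [reweight()].
#' @param path output file.
#' @export
write_phase_points_tsv <- function(pts, path) {
  utils::write.table(pts, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
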