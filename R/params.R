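#' Gene labels of the alternating-cushions network
#'
#' The four genes are arranged axially in the stripe order A-B-C-D-A.
#' Next-nearest-neighbour (NNN) pairs \{A,C\} and \{B,D\} repress each other
#' strongly; the four nearest-neighbour (NN) pairs \{A,B\}, \{B,C\}, \{C,D\},
#' \{D,A\} repress each other weakly.
#' @export
ac_genes <- c("A", "B", "C", "D")

#' Repression class of an ordered gene pair
#'
#' @param repressor,target gene labels (see [ac_genes])
#' @return `"strong"` for next-nearest-neighbour pairs (\{A,C\}, \{B,D\}),
#'   `"weak"` for nearest-neighbour pairs.
#' @export
pair_type <- function(repressor, target) {
  i <- match(repressor, ac_genes)
  j <- match(target, ac_genes)
  if (anyNA(c(i, j))) stop("unknown gene label")
  if (any(i == j)) stop("a gene does not repress itself (invalid pair)")
  ifelse(bitwXor(i - 1L, j - 1L) == 2L, "strong", "weak")
}

#' Model parameters of the spatial-stochastic simulator
#'
#' Constructs and validates the full microscopic parameter set. All rates are
#' per second; lengths in micrometres; volumes in cubic micrometres.
#'
#' @param beta production rate per active promoter (proteins/s).
#' @param mu_M,mu_D monomer and (free) dimer degradation rates (1/s).
#' @param kon_D dimerization forward rate (um^3/s); propensity
#'   `kon_D * n1 * (n1 - 1) / (2 * V_N)`.
#' @param koff_D dedimerization rate (1/s); constrained to `kon_D / V_N`.
#' @param sigma_R,D_N repressor target radius (um) and intranuclear diffusion
#'   coefficient (um^2/s); the repressor binding rate is diffusion limited,
#'   `kon_R = 4 * pi * sigma_R * D_N`.
#' @param koff_s strong (NNN) repressor unbinding rate (1/s).
#' @param kappa weak-to-strong repression ratio `koff_w / koff_s` (>= 1);
#'   `Inf` removes the weak (NN) repressor sites entirely.
#' @param D_P internuclear protein diffusion coefficient (um^2/s).
#' @param l lattice spacing between nuclei (um).
#' @param N_z,N_phi axial and circumferential lattice dimensions (nuclei).
#' @param V_N nuclear reaction volume (um^3).
#' @param pinned if `TRUE`, the A promoter carries no repressor sites in the
#'   first and last axial rings, so A production there is constitutive.
#' @return an object of class `ac_params` (a validated named list with the
#'   derived fields `kon_R` and `koff_w`).
#' @seealso [default_params()] for the calibrated defaults.
#' @export
ac_params <- function(beta, mu_M, mu_D, kon_D, koff_D, sigma_R, D_N, koff_s,
                      kappa, D_P, l, N_z, N_phi, V_N, pinned = TRUE) {
  p <- list(beta = beta, mu_M = mu_M, mu_D = mu_D, kon_D = kon_D,
            koff_D = koff_D, sigma_R = sigma_R, D_N = D_N,
            kon_R = 4 * pi * sigma_R * D_N, koff_s = koff_s, kappa = kappa,
            D_P = D_P, l = l, N_z = as.integer(N_z), N_phi = as.integer(N_phi),
            V_N = V_N, pinned = isTRUE(pinned))
  rates <- c(p$beta, p$mu_M, p$mu_D, p$kon_D, p$koff_D, p$kon_R, p$koff_s)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rates must be strictly positive and finite")
  if (!(is.finite(p$kappa) && p$kappa >= 1) && !identical(p$kappa, Inf))
    stop("kappa must be >= 1 or Inf")
  if (p$D_P < 0 || p$l <= 0 || p$V_N <= 0) stop("invalid geometry")
  if (p$N_z < 2 || p$N_phi < 1) stop("lattice must be at least 2 x 1")
  if (abs(p$koff_D - p$kon_D / p$V_N) > 1e-8 * p$koff_D)
    stop("koff_D must equal kon_D / V_N")
  p$koff_w <- if (is.finite(p$kappa)) p$kappa * p$koff_s else Inf
  class(p) <- "ac_params"
  p
}

#' Default model parameters
#'
#' The absolute microscopic rates are reconstructed from the quantities the
#' model is calibrated to: an effective protein lifetime `t_eff = 100` s, a
#' mean total copy number of about 15 proteins per expressing nucleus, a
#' strong repression constant `K_s = koff_s / kon_R = 0.003` um^-3, an
#' effective production-to-degradation concentration `H / gamma = 0.228`
#' um^-3, a characteristic interaction length `lambda = sqrt(D / gamma) =
#' 8.62` um, protein diffusion `D_P = 1` um^2/s, lattice spacing `l = 8.5` um
#' and a 40 x 8 cylindrical lattice.
#'
#' The derivation (with monomer-equivalent dimer concentration `X2`, i.e.
#' dimers counted twice, and the stationary monomer-to-dimer ratio
#' `r`, equal to `X1/X2`):
#' `gamma = (mu_D + mu_M * r)/(1 + r)` and `D = D_P/(1 + r)`, so with equal
#' monomer and dimer degradation rates `mu_M = mu_D = 1/t_eff` the lifetime
#' constraint fixes `gamma = 0.01`/s and the interaction length fixes
#' the ratio to `D_P * t_eff / lambda^2 - 1`. The copy-number constraint
#' then fixes
#' `V_N = 15 / ((H/gamma) * (1 + r))` and `beta = 15 / t_eff`; the
#' dimerization rate follows from the stationary dimer balance, with
#' `koff_D = kon_D / V_N` and `kon_R = kon_D / 2` (dimerization is twice the
#' diffusion-limited repressor binding rate, both partners diffusing).
#'
#' @param kappa repression strength ratio; default 31.6, the stability
#'   optimum of the pinned system.
#' @param pinned pin A expression at the axial boundary rings (default TRUE).
#' @param N_z,N_phi lattice dimensions, default 40 x 8.
#' @return an [ac_params] object.
#' @export
default_params <- function(kappa = 31.6, pinned = TRUE, N_z = 40, N_phi = 8) {
  t_eff <- 100
  n_tot <- 15
  Hgamma <- 0.228
  Ks <- 0.003
  lambda <- 8.62
  D_P <- 1
  mu <- 1 / t_eff
  r <- D_P * t_eff / lambda^2 - 1
  V_N <- n_tot / (Hgamma * (1 + r))
  beta <- n_tot / t_eff
  X2 <- Hgamma
  X1 <- r * X2
  # stationary dimer balance X2 = kon_D X1^2 / (koff_D + mu_D), koff_D = kon_D/V_N
  kon_D <- mu * X2 / (X1^2 - X2 / V_N)
  koff_D <- kon_D / V_N
  kon_R <- kon_D / 2
  sigma_R <- 0.01
  D_N <- kon_R / (4 * pi * sigma_R)
  koff_s <- Ks * kon_R
  ac_params(beta = beta, mu_M = mu, mu_D = mu, kon_D = kon_D, koff_D = koff_D,
            sigma_R = sigma_R, D_N = D_N, koff_s = koff_s, kappa = kappa,
            D_P = D_P, l = 8.5, N_z = N_z, N_phi = N_phi, V_N = V_N,
            pinned = pinned)
}

#' @export
print.ac_params <- function(x, ...) {
  cat("Alternating-cushions model parameters\n")
  cat(sprintf("  lattice   : %d x %d nuclei, l = %g um%s\n", x$N_z, x$N_phi,
              x$l, if (x$pinned) ", A pinned at boundary rings" else ""))
  cat(sprintf("  kappa     : %s (koff_w = %s /s, koff_s = %.4g /s)\n",
              format(x$kappa), format(signif(x$koff_w, 4)), x$koff_s))
  cat(sprintf("  production: beta = %.4g /s; decay mu_M = %.3g, mu_D = %.3g /s\n",
              x$beta, x$mu_M, x$mu_D))
  cat(sprintf("  dimer     : kon_D = %.4g um^3/s, koff_D = %.4g /s, V_N = %.4g um^3\n",
              x$kon_D, x$koff_D, x$V_N))
  cat(sprintf("  repressor : kon_R = %.4g um^3/s (diffusion limited)\n", x$kon_R))
  cat(sprintf("  transport : D_P = %g um^2/s, hop rate %.4g /s\n",
              x$D_P, hop_rate(x)))
  invisible(x)
}

#' Repressor unbinding rate for an ordered gene pair
#'
#' Strong (NNN) pairs unbind at `koff_s`; weak (NN) pairs at
#' `kappa * koff_s`. With `kappa = Inf` the weak repressor sites are absent
#' and `NA` is returned with a warning-free sentinel attribute.
#'
#' @param repressor,target gene labels.
#' @param p an [ac_params] object.
#' @return unbinding rate (1/s), or `NA_real_` when the site does not exist
#'   (`kappa = Inf`, weak pair).
#' @export
repressor_offrate <- function(repressor, target, p) {
  type <- pair_type(repressor, target)
  out <- ifelse(type == "strong", p$koff_s,
                if (is.finite(p$kappa)) p$kappa * p$koff_s else NA_real_)
  out
}

#' Reaction channels of one nucleus
#'
#' Builds the explicit channel list of the per-nucleus reaction network:
#' production under OR-logic repression (blocked if any repressor site is
#' occupied), monomer/dimer degradation, dimerization and dedimerization, and
#' repressor binding/unbinding per promoter site. This R-level description is
#' the reference used to cross-check the compiled simulator; propensities are
#' closures over a nucleus state.
#'
#' A nucleus state here is a list with `n1`, `n2` (named counts per gene) and
#' `bnd` (4 x 4 0/1 matrix, rows = target promoter, cols = repressor).
#'
#' @param p an [ac_params] object.
#' @param nucleus_is_boundary logical; if `TRUE` and `p$pinned`, the A
#'   promoter has no repressor sites and produces constitutively.
#' @return a list of channels, each with `name`, `propensity(ns)` and
#'   `apply(ns)`.
#' @export
build_reactions <- function(p, nucleus_is_boundary = FALSE) {
  site_exists <- function(target, repressor) {
    if (target == repressor) return(FALSE)
    if (p$pinned && nucleus_is_boundary && target == "A") return(FALSE)
    if (pair_type(repressor, target) == "weak" && !is.finite(p$kappa)) return(FALSE)
    TRUE
  }
  channels <- list()
  add <- function(name, propensity, apply) {
    channels[[length(channels) + 1L]] <<- list(name = name,
                                               propensity = propensity,
                                               apply = apply)
  }
  for (g in ac_genes) {
    local({
      gg <- g
      sites <- ac_genes[vapply(ac_genes, function(r) site_exists(gg, r), TRUE)]
      add(paste0("prod_", gg), function(ns) {
        active <- length(sites) == 0 || all(ns$bnd[gg, sites] == 0)
        if (active) p$beta else 0
      }, function(ns) { ns$n1[gg] <- ns$n1[gg] + 1L; ns })
      add(paste0("mdecay_", gg),
          function(ns) p$mu_M * ns$n1[gg],
          function(ns) { ns$n1[gg] <- ns$n1[gg] - 1L; ns })
      add(paste0("ddecay_", gg),
          function(ns) p$mu_D * ns$n2[gg],
          function(ns) { ns$n2[gg] <- ns$n2[gg] - 1L; ns })
      add(paste0("dim_", gg),
          function(ns) p$kon_D * ns$n1[gg] * (ns$n1[gg] - 1) / (2 * p$V_N),
          function(ns) { ns$n1[gg] <- ns$n1[gg] - 2L; ns$n2[gg] <- ns$n2[gg] + 1L; ns })
      add(paste0("dedim_", gg),
          function(ns) p$koff_D * ns$n2[gg],
          function(ns) { ns$n2[gg] <- ns$n2[gg] - 1L; ns$n1[gg] <- ns$n1[gg] + 2L; ns })
    })
  }
  for (tgt in ac_genes) for (rep_ in ac_genes) {
    if (!site_exists(tgt, rep_)) next
    local({
      tg <- tgt; rp <- rep_
      koff <- if (pair_type(rp, tg) == "strong") p$koff_s else p$kappa * p$koff_s
      add(paste0("bind_", rp, "_on_", tg), function(ns) {
        if (ns$bnd[tg, rp] == 0) p$kon_R * ns$n2[rp] / p$V_N else 0
      }, function(ns) { ns$bnd[tg, rp] <- 1L; ns$n2[rp] <- ns$n2[rp] - 1L; ns })
      add(paste0("unbind_", rp, "_on_", tg), function(ns) {
        if (ns$bnd[tg, rp] == 1) koff else 0
      }, function(ns) { ns$bnd[tg, rp] <- 0L; ns$n2[rp] <- ns$n2[rp] + 1L; ns })
    })
  }
  channels
}

#' Read / write a flat key-value parameter file
#'
#' The file format is one `key = value` pair per line (TOML-style scalars,
#' `#` comments allowed); `kappa` accepts the literal `inf`.
#'
#' @param path file path.
#' @return [read_params()] returns an [ac_params] object.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed parameter file (expect key = value)")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  num <- function(v) if (tolower(v) %in% c("inf", "infinity")) Inf else as.numeric(v)
  pl <- stats::setNames(lapply(vals, num), keys)
  need <- c("beta", "mu_M", "mu_D", "kon_D", "koff_D", "sigma_R", "D_N",
            "koff_s", "kappa", "D_P", "l", "N_z", "N_phi", "V_N", "pinned")
  missing <- setdiff(need, keys)
  if (length(missing)) stop("parameter file missing keys: ",
                            paste(missing, collapse = ", "))
  ac_params(beta = pl$beta, mu_M = pl$mu_M, mu_D = pl$mu_D, kon_D = pl$kon_D,
            koff_D = pl$koff_D, sigma_R = pl$sigma_R, D_N = pl$D_N,
            koff_s = pl$koff_s, kappa = pl$kappa, D_P = pl$D_P, l = pl$l,
            N_z = pl$N_z, N_phi = pl$N_phi, V_N = pl$V_N,
            pinned = pl$pinned != 0)
}

#' @rdname read_params
#' @param p an [ac_params] object.
#' @export
write_params <- function(p, path) {
  fmt <- function(v) {
    if (identical(v, Inf)) "inf"
    else if (is.logical(v)) as.character(as.integer(v))
    else format(v, digits = 17)
  }
  keys <- c("beta", "mu_M", "mu_D", "kon_D", "koff_D", "sigma_R", "D_N",
            "koff_s", "kappa", "D_P", "l", "N_z", "N_phi", "V_N", "pinned")
  writeLines(sprintf("%s = %s", keys,
                     vapply(p[keys], fmt, "")), path)
  invisible(path)
}

# parameter list passed to the C++ core
.cpp_params <- function(p) {
  p[c("beta", "mu_M", "mu_D", "kon_D", "koff_D", "kon_R", "koff_s", "kappa",
      "V_N", "D_P", "l", "N_z", "N_phi", "pinned")]
}
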