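# Shared fixtures built in code.

# parameters with negligible repressor binding and diffusion: the four genes
# decouple into independent single-gene birth/dimerization systems
isolated_gene_params <- function(N_z = 2, N_phi = 1) {
  update_params(default_params(), sigma_R = 1e-12, D_P = 1e-12,
                N_z = N_z, N_phi = N_phi)
}

# pure-transport parameters: all reaction rates negligibly small
transport_only_params <- function(N_z = 41, N_phi = 1, D_P = 1) {
  p0 <- default_params()
  update_params(p0, beta = 1e-12, mu_M = 1e-12, mu_D = 1e-12,
                kon_D = 1e-12, koff_D = 1e-12 / p0$V_N, sigma_R = 1e-12,
                koff_s = 1e-12, D_P = D_P, N_z = N_z, N_phi = N_phi)
}

# single-nucleus state (2 x 1 lattice, D_P ~ 0) with given counts for one gene
single_nucleus_state <- function(p, gene = "A", n1 = 0, n2 = 0) {
  st <- empty_state(p)
  st$n1[gene, 1] <- as.integer(n1)
  st$n2[gene, 1] <- as.integer(n2)
  st
}

# nucleus state in the representation used by build_reactions()
reaction_nucleus <- function(n1 = stats::setNames(rep(0L, 4), ac_genes),
                             n2 = stats::setNames(rep(0L, 4), ac_genes),
                             bnd = NULL) {
  if (is.null(bnd))
    bnd <- matrix(0L, 4, 4, dimnames = list(ac_genes, ac_genes))
  list(n1 = n1, n2 = n2, bnd = bnd)
}
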