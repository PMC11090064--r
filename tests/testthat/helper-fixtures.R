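# Shared fixtures: a protein-like and a lipid-like solute component, and
# builders for binary mixtures used across the MC / uncertainty tests.

water <- solvent() # n1 = 1.3330, rho1 = 0.997

protein_comp <- function(dalpha = 0.004, dtheta = 0.012)
  list(name = "protein", alpha = 0.197, theta = 0.734,
       dalpha = dalpha, dtheta = dtheta)

triolein_comp <- function() {
  m <- material("triolein", n = 1.4676, rho = 0.9078)
  list(name = "triolein", alpha = alpha_biot(m$theta, m$n, water$n1),
       theta = m$theta, dalpha = 0, dtheta = 0)
}

binary_spec <- function(x_lip = 0.5, x_sd = 0, phi1 = 0.9, phi1_sd = 0,
                        N0 = 1e4, Nv = 1000, ns_model = "mass_fluctuation",
                        dm_rel = 0, seed = 1L, dalpha = 0.004, dtheta = 0.012) {
  comp <- solute_composition(list(protein_comp(dalpha, dtheta), triolein_comp()),
                             c(1 - x_lip, x_lip), water)
  mixture_spec(comp, phi1_mean = phi1, phi1_sd = phi1_sd, x_sd = x_sd,
               N0 = N0, Nv = Nv, ns_model = ns_model, dm_rel = dm_rel,
               seed = seed)
}

zebrafish_spec <- function() {
  read_mixture_spec(system.file("extdata", "zebrafish_trunk.yaml",
                                package = "ridens"))
}

write_toy_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  lines <- as.character(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))))
  writeLines(lines, path)
  path
}
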