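# Small fixtures shared across tests; everything is generated in code.

# Compact recovery-study configuration: 4 x 4 degree domain so the
# kappa = 7.33 Matern range (~0.39 deg) is resolvable by ~300 clusters.
recovery_config <- function(seed, n_clusters = 300, children = 20) {
  sim_config(seed = seed, n_clusters = n_clusters, n_admin1 = 4,
             n_admin2_per_admin1 = 3, children_per_cluster = children,
             children_jitter = FALSE, covariates = "diarrhoea",
             domain_bbox = c(6, 10, 7, 11))
}

recovery_mesh_args <- list(max_edge = c(0.3, 0.8), cutoff = 0.12)

# Child table expanded from stunted / not-stunted counts.
table_from_counts <- function(stunted_n, not_stunted_n, label = "x") {
  data.frame(
    grp = label,
    stunted = c(rep(1L, stunted_n), rep(0L, not_stunted_n)),
    stringsAsFactors = FALSE)
}

# A minimal hand-made unit-square mesh for projector/FEM checks.
unit_square_mesh <- function(n = 5) {
  g <- as.matrix(expand.grid(seq(0, 1, length.out = n),
                             seq(0, 1, length.out = n)))
  build_mesh(g, cutoff = 0, boundary_extension = 0)
}
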