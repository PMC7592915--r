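# Programmatic fixtures shared across test files.

# a noiseless (or lognormal-noised) measurement curve from known parameters
make_curve <- function(id, temps_C, b0 = 0.5, e = 0.65, t_pk = 306.15,
                       e_d = 3, noise_sd = 0, seed = NULL,
                       species = paste0("sp_", id)) {
  p <- tpc_parameters(b0, e, t_pk, e_d)
  tk <- celsius_to_kelvin(temps_C)
  y <- sharpe_schoolfield(p, tk)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y * exp(rnorm(length(y), 0, noise_sd))
  }
  tpc_curve(id, species, tk, y)
}

# six curves exercising every per-parameter filter rule plus the R2 gate;
# expected acceptance patterns are asserted in the filter tests
filter_fixture <- function() {
  list(
    all_ok = make_curve("all_ok", c(13, 17, 21, 25, 29, 31, 35, 38, 41, 44)),
    few_below = make_curve("few_below", c(23, 27, 31, 35, 37, 39, 41, 43)),
    high_e = make_curve("high_e", c(21, 23, 25, 27, 29, 31, 35, 37),
                        e = 4.5, e_d = 6),
    one_above = make_curve("one_above", c(13, 16, 19, 22, 25, 28, 31, 35)),
    one_below = make_curve("one_below", c(31, 35, 37, 39, 41, 43)),
    low_r2 = tpc_curve("low_r2", "sp_low_r2",
                       celsius_to_kelvin(seq(13, 41, by = 4)),
                       c(1, 0.1, 1, 0.1, 1, 0.1, 1, 0.1))
  )
}

# small reference tree with known structure:
# ((A:0.4,B:0.4):0.6,(C:0.7,D:0.7):0.3); height 1, ultrametric
small_tree <- function() {
  ape::read.tree(text = "((A:0.4,B:0.4):0.6,(C:0.7,D:0.7):0.3);")
}

# dense brute-force GLS ancestral states: joint MVN of tips and internal
# nodes under BM, conditioning internal nodes on the tips
bruteforce_ancestral <- function(tree, x) {
  n_tip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  all_ids <- seq_len(n_tip + tree$Nnode)
  Cfull <- matrix(depth[M[all_ids, all_ids]], length(all_ids))
  C <- Cfull[seq_len(n_tip), seq_len(n_tip)]
  x <- x[tree$tip.label]
  Ci <- solve(C)
  one <- rep(1, n_tip)
  a <- drop(t(one) %*% Ci %*% x) / drop(t(one) %*% Ci %*% one)
  nodes <- (n_tip + 1):(n_tip + tree$Nnode)
  vapply(nodes, function(v) {
    cv <- Cfull[v, seq_len(n_tip)]
    a + drop(t(cv) %*% Ci %*% (x - a))
  }, numeric(1))
}
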