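## Synthetic-data generators: birth-death trees, TPC parameters evolving
## along them (Brownian motion, optionally with jumps and/or a directional
## trend), noisy measurement tables, and latitudes linked to thermal
## sensitivity. Every generator is a pure function of its inputs and seed,
## and ground truth is retained for recovery tests.

#' Simulate a relative-time birth-death tree
#'
#' A birth-death tree conditioned on the number of extant tips
#' (via [ape::rphylo]), rescaled to unit root-to-tip height so branch
#' lengths are in relative time.
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth,death Speciation and extinction rates; `birth > death >= 0`.
#' @param seed Integer seed.
#' @return An ultrametric ape `phylo` tree of unit height, tips labelled
#'   `sp_001`, `sp_002`, ...
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, seed = 1L) {
  if (n_tips < 3) stop("n_tips must be at least 3")
  if (!(birth > death && death >= 0)) stop("need birth > death >= 0")
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_tips, birth = birth, death = death)
  tree$tip.label <- sprintf("sp_%03d", seq_len(n_tips))
  normalize_tree_height(tree)
}

#' Describe how TPC parameters evolve along the tree
#'
#' The four Sharpe-Schoolfield parameters evolve independently on their
#' analysis scales: ln B0, ln E and ln E_D on the log scale, T_pk in
#' Kelvin (its evolution is gradual and strongly heritable, so it stays
#' untransformed). `model = "BM+jumps"` superimposes Poisson-timed
#' Normal jumps — bursts of adaptive evolution — on the parameters listed
#' in `jump_on` (by default thermal sensitivity only); `"BM+trend"` adds a
#' deterministic drift `trend * time` to the parameters in `trend_on`.
#'
#' @param model `"BM"`, `"BM+jumps"` or `"BM+trend"`.
#' @param rates Named Brownian variances per unit (relative) time for
#'   `ln_b0`, `ln_e`, `t_pk`, `ln_e_d`.
#' @param roots Named root states on the same scales.
#' @param jump_intensity Expected jumps per unit branch length.
#' @param jump_sd Standard deviation of a jump.
#' @param jump_on Parameters receiving jumps (default `"ln_e"`).
#' @param trend Drift per unit relative time.
#' @param trend_on Parameters receiving the trend (default `"ln_e"`).
#' @return List of class `"evolution_scenario"`.
#' @export
evolution_scenario <- function(model = c("BM", "BM+jumps", "BM+trend"),
                               rates = c(ln_b0 = 0.5, ln_e = 0.2,
                                         t_pk = 25, ln_e_d = 0.05),
                               roots = c(ln_b0 = log(0.1),
                                         ln_e = log(0.65),
                                         t_pk = 298.15,
                                         ln_e_d = log(3)),
                               jump_intensity = 0.5, jump_sd = 1,
                               jump_on = "ln_e",
                               trend = -0.5, trend_on = "ln_e") {
  model <- match.arg(model)
  par_names <- c("ln_b0", "ln_e", "t_pk", "ln_e_d")
  stopifnot(all(par_names %in% names(rates)),
            all(par_names %in% names(roots)),
            all(rates >= 0), jump_intensity >= 0, jump_sd >= 0)
  structure(list(model = model, rates = rates[par_names],
                 roots = roots[par_names],
                 jump_intensity = jump_intensity, jump_sd = jump_sd,
                 jump_on = jump_on, trend = trend, trend_on = trend_on),
            class = "evolution_scenario")
}

#' Evolve TPC parameters along a tree
#'
#' Preorder simulation of the four transformed parameters under the given
#' scenario. Increments violating the model constraints at a node
#' (`E >= E_D`, or `T_pk` at or below the reference temperature) are
#' resampled up to 100 times before erroring.
#'
#' @param tree An ape `phylo` tree (unit height recommended).
#' @param scenario An [evolution_scenario].
#' @param seed Integer seed.
#' @param t_ref Reference temperature (K) used for the constraint check.
#' @return List with `tips` (data.frame: `species_id`, natural-scale `b0`,
#'   `e`, `t_pk`, `e_d` and the transformed values) and `nodes`
#'   (data.frame of true internal-node states with node ages).
#' @export
evolve_parameters <- function(tree, scenario, seed = 1L,
                              t_ref = t_ref_default) {
  stopifnot(inherits(scenario, "evolution_scenario"))
  .check_tree(tree)
  set.seed(as.integer(seed))
  tree <- stats::reorder(tree, "cladewise")
  n_tip <- ape::Ntip(tree)
  par_names <- names(scenario$rates)
  state <- matrix(NA_real_, n_tip + tree$Nnode, length(par_names),
                  dimnames = list(NULL, par_names))
  state[n_tip + 1, ] <- scenario$roots

  ok <- function(s) {
    exp(s["ln_e"]) < exp(s["ln_e_d"]) && s["t_pk"] > t_ref + 1
  }
  if (!ok(state[n_tip + 1, ])) stop("root state violates TPC constraints")

  draw_increment <- function(len) {
    inc <- stats::rnorm(length(par_names), 0,
                        sqrt(scenario$rates * len))
    names(inc) <- par_names
    if (scenario$model == "BM+jumps" && scenario$jump_intensity > 0) {
      for (pp in scenario$jump_on) {
        nj <- stats::rpois(1, scenario$jump_intensity * len)
        if (nj > 0)
          inc[pp] <- inc[pp] + sum(stats::rnorm(nj, 0, scenario$jump_sd))
      }
    }
    if (scenario$model == "BM+trend") {
      inc[scenario$trend_on] <- inc[scenario$trend_on] +
        scenario$trend * len
    }
    inc
  }

  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1]
    ch <- tree$edge[i, 2]
    len <- tree$edge.length[i]
    for (try in 1:100) {
      cand <- state[par, ] + draw_increment(len)
      if (ok(cand)) break
      if (try == 100)
        stop("could not satisfy TPC parameter constraints after 100 ",
             "resamples on an edge")
    }
    state[ch, ] <- cand
  }

  depth <- ape::node.depth.edgelength(tree)
  tips <- data.frame(species_id = tree$tip.label,
                     ln_b0 = state[seq_len(n_tip), "ln_b0"],
                     ln_e = state[seq_len(n_tip), "ln_e"],
                     t_pk = state[seq_len(n_tip), "t_pk"],
                     ln_e_d = state[seq_len(n_tip), "ln_e_d"],
                     stringsAsFactors = FALSE, row.names = NULL)
  tips$b0 <- exp(tips$ln_b0)
  tips$e <- exp(tips$ln_e)
  tips$e_d <- exp(tips$ln_e_d)
  node_ids <- (n_tip + 1):(n_tip + tree$Nnode)
  nodes <- data.frame(node = node_ids, age = depth[node_ids],
                      state[node_ids, , drop = FALSE], row.names = NULL)
  list(tips = tips, nodes = nodes)
}

#' Measurement design for synthetic TPC tables
#'
#' @param temperatures_C Measurement temperatures in Celsius.
#' @param noise_sd Lognormal noise SD on the log scale (e.g. 0.05 for
#'   roughly 5% multiplicative noise).
#' @param reps Measurements per temperature.
#' @param seed Integer seed.
#' @return List of class `"measurement_design"`.
#' @export
measurement_design <- function(temperatures_C = seq(5, 45, by = 4),
                               noise_sd = 0.05, reps = 1, seed = 1L) {
  stopifnot(length(temperatures_C) >= 2, noise_sd >= 0, reps >= 1)
  structure(list(temperatures_C = sort(temperatures_C),
                 noise_sd = noise_sd, reps = reps,
                 seed = as.integer(seed)),
            class = "measurement_design")
}

#' Generate noisy TPC measurement tables from known parameters
#'
#' Evaluates the Sharpe-Schoolfield curve of each species on the design's
#' temperature grid and multiplies by lognormal noise. Species whose grid
#' gives fewer than 4 points below or 2 points above the true peak are
#' flagged (`deficient`), which the filter tests exploit deliberately.
#'
#' @param tip_params data.frame with `species_id`, `b0`, `e`, `t_pk`,
#'   `e_d` (natural scales), e.g. `evolve_parameters(...)$tips`.
#' @param design A [measurement_design].
#' @param trait_name Trait label for the emitted rows.
#' @param t_ref Reference temperature (K).
#' @return data.frame in the TPC CSV schema (`curve_id`, `species_id`,
#'   `trait_name`, `temperature_C`, `trait_value`, `latitude`), with a
#'   `deficient` attribute naming flagged species.
#' @export
generate_measurements <- function(tip_params, design,
                                  trait_name = "r_max",
                                  t_ref = t_ref_default) {
  stopifnot(inherits(design, "measurement_design"))
  need <- c("species_id", "b0", "e", "t_pk", "e_d")
  stopifnot(all(need %in% names(tip_params)))
  set.seed(design$seed)
  temps_K <- celsius_to_kelvin(rep(design$temperatures_C,
                                   each = design$reps))
  rows <- vector("list", nrow(tip_params))
  deficient <- character(0)
  for (i in seq_len(nrow(tip_params))) {
    p <- tip_params[i, ]
    pars <- tpc_parameters(p$b0, p$e, p$t_pk, p$e_d, t_ref)
    mu <- sharpe_schoolfield(pars, temps_K)
    noise <- exp(stats::rnorm(length(mu), 0, design$noise_sd))
    if (sum(temps_K < p$t_pk) < 4 || sum(temps_K > p$t_pk) < 2)
      deficient <- c(deficient, p$species_id)
    rows[[i]] <- data.frame(
      curve_id = paste0(p$species_id, "_c1"),
      species_id = p$species_id,
      trait_name = trait_name,
      temperature_C = kelvin_to_celsius(temps_K),
      trait_value = mu * noise,
      latitude = NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  attr(out, "deficient") <- unique(deficient)
  out
}

#' Assign latitudes linked to thermal sensitivity
#'
#' Inverts the linear model `ln E = intercept + slope * |lat| + noise` to
#' draw an absolute latitude consistent with each species' ln E, clamped
#' to \[0, 66\] (the latitudinal span of typical microbial datasets), with
#' a random hemisphere sign. With `slope = 0` the latitudes are drawn
#' uniformly, independent of the trait (null construction).
#'
#' @param tip_ln_e Named vector of ln E values per species.
#' @param slope Slope of ln E on absolute latitude (per degree).
#' @param intercept Intercept (ln E at the equator).
#' @param noise_sd SD of the noise term.
#' @param seed Integer seed.
#' @return Named vector of signed latitudes (decimal degrees).
#' @export
assign_latitudes <- function(tip_ln_e, slope = -0.01,
                             intercept = log(0.65), noise_sd = 0.1,
                             seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(tip_ln_e)
  if (slope == 0) {
    abs_lat <- stats::runif(n, 0, 66)
  } else {
    eps <- stats::rnorm(n, 0, noise_sd)
    abs_lat <- (tip_ln_e - intercept - eps) / slope
    n_out <- sum(abs_lat < 0 | abs_lat > 66)
    if (n_out > 0)
      message(n_out, " implied latitude(s) outside [0, 66]: truncated")
    abs_lat <- pmin(pmax(abs_lat, 0), 66)
  }
  sign <- sample(c(-1, 1), n, replace = TRUE)
  stats::setNames(sign * abs_lat, names(tip_ln_e))
}
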