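## Phylogenetic comparative machinery: variance-covariance matrices,
## Pagel's lambda (phylogenetic heritability), Brownian-motion simulation,
## disparity-through-time with a rank-envelope test, ancestral states,
## trend regression over tips + ancestors, Mantel test, and a per-branch
## evolutionary-rate proxy.

.check_tree <- function(tree, ultrametric = FALSE, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (ultrametric && !ape::is.ultrametric(tree, tol = tol))
    stop("tree must be ultrametric (relative-time chronogram) for this ",
         "analysis")
  invisible(tree)
}

#' Normalize a tree to unit root-to-tip height
#'
#' Resolves polytomies deterministically into zero-length branches and
#' rescales all branch lengths so that the maximum root-to-tip distance is
#' 1 ("relative time").
#'
#' @param tree An ape `phylo` tree with branch lengths.
#' @return The rescaled binary tree.
#' @export
normalize_tree_height <- function(tree) {
  .check_tree(tree)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  h <- max(ape::node.depth.edgelength(tree))
  if (h <= 0) stop("tree has zero height")
  tree$edge.length <- tree$edge.length / h
  tree
}

## named vector of trait values from either a named numeric vector or a
## trait table (species_id/variable/value data.frame)
.as_trait_vector <- function(traits, variable = NULL) {
  if (is.numeric(traits)) {
    if (is.null(names(traits))) stop("trait vector must be named by species")
    return(traits)
  }
  if (is.data.frame(traits)) {
    df <- traits
    if (!is.null(variable) && "variable" %in% names(df))
      df <- df[df$variable == variable, , drop = FALSE]
    if (!all(c("species_id", "value") %in% names(df)))
      stop("trait table needs 'species_id' and 'value' columns")
    if (anyDuplicated(df$species_id))
      stop("one value per species required (run best_fit_per_species first)")
    return(stats::setNames(df$value, df$species_id))
  }
  stop("traits must be a named numeric vector or a trait table data.frame")
}

## align trait vector with tree tips, erroring informatively
.match_tips <- function(x, tree) {
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss))
    stop("no trait value for tips: ", paste(miss, collapse = ", "))
  x[tree$tip.label]
}

#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the branch-length path shared from the root by tips i and
#' j; the diagonal holds root-to-tip distances. Under Brownian motion the
#' trait covariance among species is proportional to this matrix.
#'
#' @param tree A rooted ape `phylo` tree with branch lengths.
#' @return A symmetric positive semidefinite matrix with tip labels as
#'   dimnames.
#' @export
phylo_vcv <- function(tree) {
  .check_tree(tree)
  if (ape::Ntip(tree) < 2) stop("need at least 2 tips")
  ape::vcv.phylo(tree)
}

## Gaussian phylogenetic log-likelihood pieces for a fixed covariance V0,
## profiling the root state; returns loglik, root, sigma2 (scale of V0)
.bm_profile_loglik <- function(y, V0) {
  n <- length(y)
  L <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(L)) return(list(loglik = -Inf, root = NA_real_,
                              sigma2 = NA_real_))
  logdet <- 2 * sum(log(diag(L)))
  iV1 <- backsolve(L, forwardsolve(t(L), rep(1, n)))
  iVy <- backsolve(L, forwardsolve(t(L), y))
  root <- sum(iVy) / sum(iV1)
  r <- y - root
  iVr <- backsolve(L, forwardsolve(t(L), r))
  s2 <- sum(r * iVr) / n
  if (s2 <= 0) s2 <- .Machine$double.eps
  ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + logdet + n)
  list(loglik = ll, root = root, sigma2 = s2)
}

#' Maximum-likelihood Pagel's lambda (phylogenetic heritability)
#'
#' Scales the off-diagonal elements of the phylogenetic covariance by
#' `lambda` and maximises the Gaussian likelihood over `lambda` in \[0, 1\]
#' (and the Brownian rate and root state, which are profiled out). A value
#' of 1 means trait covariance matches the Brownian-motion expectation of
#' shared ancestry; 0 means trait values are independent of the phylogeny.
#' Known per-species measurement variances can be added to the diagonal.
#'
#' @param traits Named numeric vector of one value per species, or a trait
#'   table (see [transform_parameters]).
#' @param tree A rooted ultrametric ape `phylo` tree.
#' @param measurement_var Optional named vector of measurement-error
#'   variances added to the diagonal of the covariance.
#' @param variable Optional variable name to select from a trait table.
#' @return List with `lambda`, `sigma2`, `root`, `loglik`, `ci`
#'   (95% profile-likelihood interval, clamped to \[0, 1\]) and `n`.
#' @export
pagels_lambda <- function(traits, tree, measurement_var = NULL,
                          variable = NULL) {
  .check_tree(tree, ultrametric = TRUE)
  x <- .as_trait_vector(traits, variable)
  x <- x[names(x) %in% tree$tip.label]
  if (length(x) < 3) stop("need at least 3 species with trait values")
  if (length(x) < 10)
    warning("fewer than 10 species: lambda estimate will be imprecise")
  if (length(x) < ape::Ntip(tree))
    tree <- ape::keep.tip(tree, names(x))
  x <- .match_tips(x, tree)
  C <- phylo_vcv(tree)
  dC <- diag(C)
  mv <- rep(0, length(x))
  if (!is.null(measurement_var)) {
    idx <- match(names(x), names(measurement_var))
    mv <- ifelse(is.na(idx), 0, measurement_var[idx])
  }

  V_of <- function(lambda) {
    V <- lambda * C
    diag(V) <- dC
    V
  }
  if (all(mv == 0)) {
    prof <- function(lambda) .bm_profile_loglik(x, V_of(lambda))$loglik
    opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-8)
    # guard against boundary optima that optimize() cannot land on exactly
    cand <- c(opt$maximum, 0, 1)
    ll <- vapply(cand, prof, numeric(1))
    lam <- cand[which.max(ll)]
    best <- .bm_profile_loglik(x, V_of(lam))
  } else {
    # measurement error breaks the scale profiling: optimise (lambda,
    # log sigma2) jointly
    nll <- function(par) {
      lambda <- par[1]
      s2 <- exp(par[2])
      V <- s2 * V_of(lambda)
      diag(V) <- diag(V) + mv
      -.bm_profile_loglik_fixed(x, V)$loglik
    }
    s2_0 <- .bm_profile_loglik(x, V_of(1))$sigma2
    opt <- stats::optim(c(0.5, log(s2_0)), nll, method = "L-BFGS-B",
                        lower = c(0, log(s2_0) - 20),
                        upper = c(1, log(s2_0) + 20))
    lam <- opt$par[1]
    V <- exp(opt$par[2]) * V_of(lam)
    diag(V) <- diag(V) + mv
    fx <- .bm_profile_loglik_fixed(x, V)
    best <- list(loglik = fx$loglik, root = fx$root,
                 sigma2 = exp(opt$par[2]))
    prof <- function(lambda) {
      f <- function(ls2) {
        V <- exp(ls2) * V_of(lambda)
        diag(V) <- diag(V) + mv
        -.bm_profile_loglik_fixed(x, V)$loglik
      }
      -stats::optimize(f, log(s2_0) + c(-20, 20))$objective
    }
  }

  # 95% profile-likelihood interval
  cut <- best$loglik - stats::qchisq(0.95, 1) / 2
  lo <- 0
  hi <- 1
  if (lam > 1e-8 && prof(0) < cut)
    lo <- stats::uniroot(function(l) prof(l) - cut, c(0, lam),
                         tol = 1e-6)$root
  if (lam < 1 - 1e-8 && prof(1) < cut)
    hi <- stats::uniroot(function(l) prof(l) - cut, c(lam, 1),
                         tol = 1e-6)$root
  list(lambda = lam, sigma2 = best$sigma2, root = best$root,
       loglik = best$loglik, ci = c(lower = lo, upper = hi),
       n = length(x))
}

## loglik with fully specified covariance (no scale profiling)
.bm_profile_loglik_fixed <- function(y, V) {
  n <- length(y)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(list(loglik = -Inf, root = NA_real_))
  logdet <- 2 * sum(log(diag(L)))
  iV1 <- backsolve(L, forwardsolve(t(L), rep(1, n)))
  iVy <- backsolve(L, forwardsolve(t(L), y))
  root <- sum(iVy) / sum(iV1)
  r <- y - root
  iVr <- backsolve(L, forwardsolve(t(L), r))
  ll <- -0.5 * (n * log(2 * pi) + logdet + sum(r * iVr))
  list(loglik = ll, root = root)
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Preorder recursion over the edges: each child state is the parent state
#' plus a Normal(0, rate * branch length) increment.
#'
#' @param tree A rooted ape `phylo` tree with branch lengths.
#' @param rate Brownian variance per unit branch length (> 0).
#' @param root Root state.
#' @param seed Optional integer seed.
#' @param internal If `TRUE`, also return internal-node states.
#' @return Named numeric vector of tip states (tips first, then internal
#'   nodes when `internal = TRUE`).
#' @export
simulate_bm <- function(tree, rate = 1, root = 0, seed = NULL,
                        internal = FALSE) {
  .check_tree(tree)
  if (rate <= 0) stop("rate must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  state <- numeric(n_tip + n_node)
  state[n_tip + 1] <- root
  inc <- stats::rnorm(nrow(tree$edge), 0, sqrt(rate * tree$edge.length))
  for (i in seq_len(nrow(tree$edge)))
    state[tree$edge[i, 2]] <- state[tree$edge[i, 1]] + inc[i]
  tips <- stats::setNames(state[seq_len(n_tip)], tree$tip.label)
  if (!internal) return(tips)
  nodes <- stats::setNames(state[(n_tip + 1):(n_tip + n_node)],
                           (n_tip + 1):(n_tip + n_node))
  c(tips, nodes)
}

## average squared pairwise distance of a numeric vector (= 2 * sample
## variance); 0 for fewer than two values
.disparity <- function(v) {
  if (length(v) < 2) return(0)
  2 * stats::var(v)
}

#' Mean subclade disparity through time
#'
#' At each internal-node time (chronological from the root), the tree is
#' cut into the lineages present just before that node splits; the
#' disparity of each lineage's tip values (average squared pairwise
#' distance; single tips contribute 0) is averaged and divided by the
#' disparity across all tips. Values near 0 mean subclades occupy small,
#' distinct parts of trait space; values near or above 1 mean subclades
#' overlap strongly (evolutionary convergence).
#'
#' @param tree A rooted ultrametric ape `phylo` tree.
#' @param traits Named trait vector or trait table (one value per tip).
#' @param variable Optional variable name to select from a trait table.
#' @return data.frame with columns `time` (node ages, root = 0) and
#'   `disparity`.
#' @export
mean_subclade_disparity <- function(tree, traits, variable = NULL) {
  .check_tree(tree, ultrametric = TRUE)
  if (ape::Ntip(tree) < 3) stop("need at least 3 tips")
  x <- .as_trait_vector(traits, variable)
  x <- .match_tips(x, tree)
  sl <- .dtt_slices(tree)
  data.frame(time = sl$ages, disparity = .dtt_curve(sl, unname(x)))
}

## precompute, per internal-node time slice, the tip-index sets of the
## lineages crossing just before that node splits (root slice = whole tree)
.dtt_slices <- function(tree) {
  n_tip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  node_age <- depth[(n_tip + 1):(n_tip + tree$Nnode)]
  ages <- sort(node_age)
  desc <- .tip_masks(tree)
  tol <- 1e-9 * max(depth, 1)
  slices <- vector("list", length(ages))
  for (i in seq_along(ages)) {
    a <- ages[i]
    if (a <= tol) {
      slices[[i]] <- list(seq_len(n_tip))
      next
    }
    crossing <- depth[tree$edge[, 1]] < a - tol &
      depth[tree$edge[, 2]] >= a - tol
    slices[[i]] <- desc[tree$edge[crossing, 2]]
  }
  list(ages = ages, slices = slices, n_tip = n_tip)
}

## evaluate the mean-subclade-disparity curve for tip values x (in tip
## order) on a precomputed slice structure
.dtt_curve <- function(sl, x) {
  total <- .disparity(x)
  if (total <= 0) return(numeric(length(sl$ages)))
  vapply(sl$slices, function(lineages) {
    mean(vapply(lineages, function(idx) .disparity(x[idx]), numeric(1)))
  }, numeric(1)) / total
}

## list indexed by node id of integer vectors of descendant tip indices
.tip_masks <- function(tree) {
  n_tip <- ape::Ntip(tree)
  tree_pw <- stats::reorder(tree, "postorder")
  masks <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) masks[[i]] <- i
  for (i in seq_len(nrow(tree_pw$edge))) {
    par <- tree_pw$edge[i, 1]
    ch <- tree_pw$edge[i, 2]
    masks[[par]] <- c(masks[[par]], masks[[ch]])
  }
  masks
}

#' Disparity-through-time with a rank-envelope test
#'
#' Compares the observed mean-subclade-disparity curve against `n_sim`
#' curves from Brownian-motion simulations on the same tree (rate set to
#' the ML Brownian rate of the observed data). The test statistic is the
#' extreme pointwise two-sided rank of each curve among all `n_sim + 1`;
#' ties make the p value an interval \[p_lower, p_upper\] (liberal and
#' conservative bounds). A pointwise 95% envelope and the median simulated
#' curve are included for display.
#'
#' @inheritParams mean_subclade_disparity
#' @param n_sim Number of Brownian simulations (>= 100; the study-scale
#'   default is 10,000).
#' @param seed Integer seed for the simulations.
#' @return Object of class `"dtt_profile"`: list with `time`, `observed`,
#'   `env_lo`, `env_hi`, `sim_median`, `p_lower`, `p_upper`, `n_sim`,
#'   `rate`.
#' @export
dtt_rank_envelope <- function(tree, traits, n_sim = 10000, seed = 1L,
                              variable = NULL) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  .check_tree(tree, ultrametric = TRUE)
  x <- .as_trait_vector(traits, variable)
  x <- .match_tips(x, tree)
  sl <- .dtt_slices(tree)
  obs <- data.frame(time = sl$ages,
                    disparity = .dtt_curve(sl, unname(x)))
  if (all(obs$disparity == 0))
    stop("observed disparity is identically zero (constant trait)")
  C <- phylo_vcv(tree)
  ml <- .bm_profile_loglik(x, C)
  # preorder edge structure reused across simulations
  tree_cw <- stats::reorder(tree, "cladewise")
  n_tip <- ape::Ntip(tree)
  sd_edge <- sqrt(ml$sigma2 * tree_cw$edge.length)
  set.seed(as.integer(seed))
  sims <- matrix(NA_real_, n_sim, nrow(obs))
  for (j in seq_len(n_sim)) {
    for (attempt in 1:10) {
      state <- numeric(n_tip + tree_cw$Nnode)
      state[n_tip + 1] <- ml$root
      inc <- stats::rnorm(length(sd_edge), 0, sd_edge)
      for (i in seq_along(inc))
        state[tree_cw$edge[i, 2]] <- state[tree_cw$edge[i, 1]] + inc[i]
      y <- state[seq_len(n_tip)]
      if (.disparity(y) > 0) break
      message("degenerate Brownian simulation (zero disparity): resampling")
    }
    sims[j, ] <- .dtt_curve(sl, y)
  }
  Y <- rbind(obs$disparity, sims)  # row 1 = observed
  N <- nrow(Y)
  r_point <- matrix(NA_real_, N, ncol(Y))
  for (k in seq_len(ncol(Y))) {
    le <- rank(Y[, k], ties.method = "max")
    ge <- N + 1 - rank(Y[, k], ties.method = "min")
    r_point[, k] <- pmin(le, ge)
  }
  R <- apply(r_point, 1, min)
  p_upper <- mean(R <= R[1])
  p_lower <- (sum(R < R[1]) + 1) / N
  structure(list(time = obs$time, observed = obs$disparity,
                 env_lo = apply(sims, 2, stats::quantile, 0.025),
                 env_hi = apply(sims, 2, stats::quantile, 0.975),
                 sim_median = apply(sims, 2, stats::median),
                 p_lower = p_lower, p_upper = p_upper,
                 n_sim = n_sim, rate = ml$sigma2),
            class = "dtt_profile")
}

#' @export
print.dtt_profile <- function(x, ...) {
  cat(sprintf("Disparity-through-time: %d time slices, %d simulations\n",
              length(x$time), x$n_sim))
  cat(sprintf("  rank envelope p in [%.4g, %.4g]\n", x$p_lower, x$p_upper))
  invisible(x)
}

#' Brownian-motion ancestral states with conditional variances
#'
#' Generalised least squares under Brownian motion: the root state is the
#' phylogenetic mean `(1'C^-1 y) / (1'C^-1 1)`, and each internal node's
#' state is the conditional expectation given the tip values, with the
#' prediction variance including the uncertainty of the root estimate.
#'
#' @inheritParams mean_subclade_disparity
#' @return data.frame with columns `node` (ape node ids), `age` (distance
#'   from root), `state`, `variance`.
#' @export
ancestral_states_bm <- function(tree, traits, variable = NULL) {
  .check_tree(tree)
  x <- .as_trait_vector(traits, variable)
  x <- .match_tips(x, tree)
  n_tip <- ape::Ntip(tree)
  C <- phylo_vcv(tree)
  ml <- .bm_profile_loglik(x, C)
  a <- ml$root
  s2 <- ml$sigma2
  depth <- ape::node.depth.edgelength(tree)
  Ci <- solve(C)
  iC1 <- Ci %*% rep(1, n_tip)
  denom <- sum(iC1)
  iCr <- Ci %*% (x - a)
  nodes <- (n_tip + 1):(n_tip + tree$Nnode)
  # Cov(node v, tip i) = depth of mrca(v, i)
  M <- ape::mrca(tree, full = TRUE)
  st <- numeric(length(nodes))
  vr <- numeric(length(nodes))
  for (j in seq_along(nodes)) {
    v <- nodes[j]
    cv <- depth[M[v, seq_len(n_tip)]]
    st[j] <- a + drop(t(cv) %*% iCr)
    q <- drop(t(cv) %*% Ci %*% cv)
    b <- 1 - drop(t(cv) %*% iC1)
    vr[j] <- s2 * (depth[v] - q + b^2 / denom)
    if (vr[j] < 0 && vr[j] > -1e-10) vr[j] <- 0
  }
  data.frame(node = nodes, age = depth[nodes], state = st, variance = vr)
}

#' Trend regression of a trait over evolutionary time
#'
#' Regresses the combined set of tip values and Brownian ancestral states
#' against node time (root = 0) by generalised least squares, with the
#' Brownian shared-path covariance among *all* nodes (tips and internal)
#' as the error structure. The intercept is the log of the central value
#' `theta`; the slope captures a putative directional trend. A tiny ridge
#' (1e-10 of the mean diagonal) regularises the covariance, which is
#' singular at the root (zero depth); a larger jitter is applied with a
#' warning if factorisation still fails.
#'
#' On an ultrametric tree all tips sit at the same depth, so a linear time
#' trend is confounded with the root state in the tip data: ancestral
#' states reconstructed from the tips under trend-free Brownian motion
#' cannot restore that information, and the default regression then has
#' essentially no power against a true trend (its null behaviour remains
#' calibrated). Supplying externally inferred ancestral states via
#' `node_states` — e.g. reconstructions from a heavy-tailed evolutionary
#' model, or a simulator's true states — makes the trend identifiable.
#'
#' @inheritParams mean_subclade_disparity
#' @param node_states Optional internal-node states to use instead of the
#'   Brownian reconstruction: a data.frame with columns `node` (ape node
#'   ids) and `state`, or a vector named by node id.
#' @return List with `log_theta`, `theta`, `slope`, `ci_log_theta`,
#'   `ci_slope` (95%), `sigma2`, `n_nodes`, and the node-level data used.
#' @export
trend_regression <- function(tree, traits, variable = NULL,
                             node_states = NULL) {
  .check_tree(tree)
  x <- .as_trait_vector(traits, variable)
  if (length(x) < 10) stop("need at least 10 tips for the trend regression")
  x <- .match_tips(x, tree)
  n_tip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  if (is.null(node_states)) {
    anc <- ancestral_states_bm(tree, x)
  } else {
    if (is.data.frame(node_states)) {
      anc <- data.frame(node = as.integer(node_states$node),
                        state = node_states$state)
    } else {
      anc <- data.frame(node = as.integer(names(node_states)),
                        state = unname(node_states))
    }
    want <- (n_tip + 1):(n_tip + tree$Nnode)
    if (!setequal(anc$node, want))
      stop("node_states must cover every internal node id")
    anc <- anc[match(want, anc$node), , drop = FALSE]
    anc$age <- depth[anc$node]
  }
  y <- c(unname(x), anc$state)
  tt <- c(depth[seq_len(n_tip)], anc$age)
  M <- ape::mrca(tree, full = TRUE)
  all_ids <- c(seq_len(n_tip), anc$node)
  Cfull <- matrix(depth[M[all_ids, all_ids]], length(all_ids))
  ridge <- 1e-10 * mean(diag(Cfull))
  V <- Cfull + diag(ridge, nrow(Cfull))
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) {
    warning("near-singular node covariance: applying larger ridge jitter")
    V <- Cfull + diag(1e-6 * mean(diag(Cfull)), nrow(Cfull))
    L <- chol(V)
  }
  X <- cbind(intercept = 1, time = tt)
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  beta <- fit$coefficients
  df <- length(y) - 2
  s2 <- sum(fit$residuals^2) / df
  XtX_inv <- chol2inv(chol(crossprod(Xw)))
  se <- sqrt(s2 * diag(XtX_inv))
  tq <- stats::qt(0.975, df)
  list(log_theta = unname(beta[1]), theta = exp(unname(beta[1])),
       slope = unname(beta[2]),
       ci_log_theta = unname(beta[1] + c(-1, 1) * tq * se[1]),
       ci_slope = unname(beta[2] + c(-1, 1) * tq * se[2]),
       sigma2 = s2, n_nodes = length(y),
       nodes = data.frame(time = tt, value = y))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles, with a one-sided permutation
#' p value obtained by jointly permuting rows and columns of the second
#' matrix: `p = (1 + #{permuted r >= observed r}) / (n_perm + 1)`.
#'
#' @param d1,d2 Square symmetric matrices with zero diagonals (or `dist`
#'   objects) over the same objects.
#' @param n_perm Number of permutations (default 9,999).
#' @param seed Integer seed.
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = 1L) {
  if (inherits(d1, "dist")) d1 <- as.matrix(d1)
  if (inherits(d2, "dist")) d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) stop("distance matrices differ in size")
  if (any(abs(d1 - t(d1)) > 1e-8) || any(abs(d2 - t(d2)) > 1e-8))
    stop("distance matrices must be symmetric")
  if (any(abs(diag(d1)) > 1e-12) || any(abs(diag(d2)) > 1e-12))
    stop("distance matrices must have zero diagonals")
  n <- nrow(d1)
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  v2 <- d2[lt]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("constant lower triangle: Mantel r undefined")
  r_obs <- stats::cor(v1, v2)
  # permutation nulls: the mean and sd of the permuted lower triangle are
  # invariant, so only the cross-product changes
  m1 <- mean(v1); m2 <- mean(v2)
  ss1 <- sum((v1 - m1)^2); ss2 <- sum((v2 - m2)^2)
  npair <- length(v1)
  v1mat <- d1
  set.seed(as.integer(seed))
  r_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    s_full <- sum(v1mat * d2[p, p]) / 2  # symmetric, zero diagonal
    r_perm[i] <- (s_full - npair * m1 * m2) / sqrt(ss1 * ss2)
  }
  p_val <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  list(r = r_obs, p = p_val, n_perm = n_perm)
}

#' Per-branch relative evolutionary rate proxy
#'
#' The squared difference between the parent and child states of each
#' branch (tip values at tips, Brownian ancestral states at internal
#' nodes), divided by branch length and min-max normalised to \[0, 1\].
#' Branches with near-zero length inherit the parent branch's rate with a
#' warning.
#'
#' @inheritParams mean_subclade_disparity
#' @return data.frame with `parent`, `child`, `length`, `rate` (normalised)
#'   per edge.
#' @export
branch_rate_proxy <- function(tree, traits, variable = NULL) {
  .check_tree(tree)
  x <- .as_trait_vector(traits, variable)
  x <- .match_tips(x, tree)
  n_tip <- ape::Ntip(tree)
  anc <- ancestral_states_bm(tree, x)
  state <- numeric(n_tip + tree$Nnode)
  state[seq_len(n_tip)] <- unname(x)
  state[anc$node] <- anc$state
  len <- tree$edge.length
  raw <- (state[tree$edge[, 1]] - state[tree$edge[, 2]])^2 / len
  zero <- !is.finite(raw)
  if (any(zero)) {
    warning(sum(zero), " zero-length branch(es): rate taken from parent")
    # fill in preorder (shallow edges first) so parents resolve first
    for (i in order(ape::node.depth.edgelength(tree)[tree$edge[, 2]])) {
      if (!is.finite(raw[i])) {
        par_edge <- which(tree$edge[, 2] == tree$edge[i, 1])
        raw[i] <- if (length(par_edge) && is.finite(raw[par_edge]))
          raw[par_edge] else 0
      }
    }
  }
  rng <- range(raw)
  rate <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else rep(0, length(raw))
  data.frame(parent = tree$edge[, 1], child = tree$edge[, 2],
             length = len, rate = rate)
}
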