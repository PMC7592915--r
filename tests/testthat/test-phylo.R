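test_that("phylogenetic covariance reads shared path lengths", {
  # two tips splitting at 0.4 on a height-1 tree
  tr2 <- ape::read.tree(text = "((A:0.6,B:0.6):0.4,C:1.0);")
  C <- phylo_vcv(tr2)
  expect_equal(C["A", "B"], 0.4)
  expect_equal(diag(C), c(A = 1, B = 1, C = 1))
  # star tree (resolved with zero-length branches): no shared history
  star <- ape::multi2di(ape::read.tree(text = "(A:1,B:1,C:1,D:1);"),
                        random = FALSE)
  Cs <- phylo_vcv(star)
  expect_true(all(Cs[upper.tri(Cs)] == 0))
  # Gram structure: positive semidefinite on a random tree
  tr <- simulate_tree(30, seed = 4)
  ev <- eigen(phylo_vcv(tr), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
})

test_that("lambda separates Brownian from phylogeny-free traits", {
  tr <- simulate_tree(80, seed = 21)
  x <- simulate_bm(tr, rate = 0.3, root = 1, seed = 22)
  h <- pagels_lambda(x, tr)
  expect_gt(h$lambda, 0.85)
  expect_true(h$ci[1] <= h$lambda && h$lambda <= h$ci[2])
  set.seed(23)
  xs <- setNames(sample(x), names(x))
  expect_lt(pagels_lambda(xs, tr)$lambda, 0.1)
  # independent implementation agrees
  ph <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(h$lambda, ph$lambda, tolerance = 1e-3)
  expect_equal(h$loglik, ph$logL, tolerance = 1e-4)
})

test_that("lambda is invariant to affine trait transformation", {
  tr <- simulate_tree(60, seed = 31)
  x <- simulate_bm(tr, 0.5, 0, seed = 32)
  h1 <- pagels_lambda(x, tr)
  h2 <- pagels_lambda(3.7 * x + 11, tr)
  expect_equal(h1$lambda, h2$lambda, tolerance = 1e-5)
})

test_that("the lambda = 0 profile is the independent-sample Gaussian likelihood", {
  tr <- simulate_tree(40, seed = 41)
  x <- simulate_bm(tr, 0.3, 0, seed = 42)
  x <- x[tr$tip.label]
  C <- phylo_vcv(tr)
  ll0 <- thermevol:::.bm_profile_loglik(unname(x), diag(diag(C)))
  # iid ML: mean and biased variance
  mu <- mean(x); s2 <- mean((x - mu)^2)
  expect_equal(ll0$loglik, sum(dnorm(x, mu, sqrt(s2), log = TRUE)),
               tolerance = 1e-8)
})

test_that("measurement error can be folded into the heritability model", {
  tr <- simulate_tree(50, seed = 51)
  x <- simulate_bm(tr, 0.3, 0, seed = 52)
  mv <- setNames(rep(0.05, length(x)), names(x))
  h <- pagels_lambda(x, tr, measurement_var = mv)
  expect_true(h$lambda >= 0 && h$lambda <= 1)
  expect_true(is.finite(h$loglik))
})

test_that("Brownian simulator has the right moments and is seeded", {
  tr <- small_tree()
  a <- simulate_bm(tr, 1, 5, seed = 3)
  b <- simulate_bm(tr, 1, 5, seed = 3)
  expect_identical(a, b)
  # zero branch lengths pin every tip at the root state
  tr0 <- tr; tr0$edge.length[] <- 0
  expect_true(all(simulate_bm(tr0, 1, 2.5, seed = 1) == 2.5))
  # tip variance ~ rate * depth, mean ~ root
  reps <- vapply(1:3000, function(r) simulate_bm(tr, 0.7, 1, seed = r)["A"],
                 numeric(1))
  expect_equal(mean(reps), 1, tolerance = 0.05)
  expect_equal(var(reps), 0.7, tolerance = 0.05 * 0.7 + 0.03)
})

test_that("mean subclade disparity follows its definition", {
  expect_equal(thermevol:::.disparity(c(0, 2)), 4)  # single squared pair
  tr <- small_tree()
  x <- c(A = 1, B = 3, C = 0, D = 10)
  d <- mean_subclade_disparity(tr, x)
  expect_equal(d$disparity[1], 1)          # root slice: whole tree
  expect_equal(d$time[1], 0)
  # hand computation at the second slice (t = 0.3): lineages (A,B) and
  # (C,D): mean(disp(1,3), disp(0,10)) / disp(all)
  expect_equal(d$disparity[2],
               mean(c(4, 100)) / thermevol:::.disparity(x),
               tolerance = 1e-12)
  # constant trait: identically zero
  expect_true(all(mean_subclade_disparity(tr, c(A = 2, B = 2, C = 2,
                                                D = 2))$disparity == 0))
  # ratio definition: invariant to affine transformation of the trait
  tr50 <- simulate_tree(50, seed = 61)
  y <- simulate_bm(tr50, 0.3, 0, seed = 62)
  d1 <- mean_subclade_disparity(tr50, y)
  d2 <- mean_subclade_disparity(tr50, 3 * y + 7)
  expect_equal(d1$disparity, d2$disparity, tolerance = 1e-12)
})

test_that("rank envelope flags convergence and is reproducible", {
  tr <- simulate_tree(50, seed = 7)
  # adjacent tips alternate between two values: subclades overlap almost
  # completely at every slice, far above any Brownian simulation
  x <- setNames(rep(c(-1, 1), length.out = 50), tr$tip.label)
  pr <- dtt_rank_envelope(tr, x, n_sim = 200, seed = 3)
  expect_equal(pr$p_lower, 1 / 201)  # tied-most-extreme rank
  expect_lt(pr$p_upper, 0.15)
  expect_true(pr$p_lower <= pr$p_upper)
  pr2 <- dtt_rank_envelope(tr, x, n_sim = 200, seed = 3)
  expect_identical(pr[c("observed", "p_lower", "p_upper", "env_lo")],
                   pr2[c("observed", "p_lower", "p_upper", "env_lo")])
  # a Brownian trait is typically unremarkable
  y <- simulate_bm(tr, 0.3, 0, seed = 71)
  pry <- dtt_rank_envelope(tr, y, n_sim = 200, seed = 72)
  expect_gt(pry$p_upper, 0.05)
})

test_that("ancestral states equal the dense GLS solution", {
  tr <- small_tree()
  x <- c(A = 0.3, B = 1.1, C = -0.4, D = 2.2)
  anc <- ancestral_states_bm(tr, x)
  expect_equal(anc$state, bruteforce_ancestral(tr, x), tolerance = 1e-8)
  # root equals the phylogenetic mean
  C <- phylo_vcv(tr)
  Ci <- solve(C)
  a <- drop(rep(1, 4) %*% Ci %*% x[tr$tip.label]) /
    drop(rep(1, 4) %*% Ci %*% rep(1, 4))
  expect_equal(anc$state[anc$age == 0], a, tolerance = 1e-10)
  # constant tips: every node at the constant with zero variance
  anc_c <- ancestral_states_bm(tr, c(A = 4, B = 4, C = 4, D = 4))
  expect_equal(anc_c$state, rep(4, 3), tolerance = 1e-10)
  expect_equal(anc_c$variance, rep(0, 3), tolerance = 1e-10)
  # larger tree: agrees with an independent implementation
  tr6 <- simulate_tree(6, seed = 81)
  y <- simulate_bm(tr6, 1, 0, seed = 82)
  expect_equal(ancestral_states_bm(tr6, y)$state,
               bruteforce_ancestral(tr6, y), tolerance = 1e-8)
  fa <- phytools::fastAnc(tr6, y)
  expect_equal(ancestral_states_bm(tr6, y)$state, as.numeric(fa),
               tolerance = 1e-6)
})

test_that("trend regression: degenerate input and identifiable trend", {
  tr <- simulate_tree(40, seed = 91)
  const <- setNames(rep(1.5, 40), tr$tip.label)
  fit <- trend_regression(tr, const)
  expect_equal(fit$slope, 0, tolerance = 1e-10)
  # the response is already on the log scale: the central value is the
  # constant itself
  expect_equal(fit$log_theta, 1.5, tolerance = 1e-10)
  # with true ancestral states the simulated trend is detected
  ev <- evolve_parameters(tr, evolution_scenario("BM+trend", trend = -0.5),
                          seed = 92)
  fit2 <- trend_regression(tr, setNames(ev$tips$ln_e, ev$tips$species_id),
                           node_states = setNames(ev$nodes$ln_e,
                                                  ev$nodes$node))
  expect_lt(fit2$ci_slope[2], 0)
})

test_that("Mantel test: exact self-comparison, seeding, error paths", {
  set.seed(5)
  d1 <- as.matrix(dist(rnorm(20)))
  m <- mantel_test(d1, d1, n_perm = 999, seed = 1)
  expect_equal(m$r, 1)
  expect_equal(m$p, 1 / 1000)  # no permutation can beat identity
  d2 <- as.matrix(dist(rnorm(20)))
  ma <- mantel_test(d1, d2, n_perm = 499, seed = 9)
  mb <- mantel_test(d1, d2, n_perm = 499, seed = 9)
  expect_identical(ma, mb)
  # statistic agrees with the community implementation
  expect_equal(ma$r, unname(vegan::mantel(d1, d2,
                                          permutations = 9)$statistic),
               tolerance = 1e-10)
  expect_error(mantel_test(matrix(0, 3, 3), d1[1:3, 1:3]), "constant")
  expect_error(mantel_test(d1, d2[1:5, 1:5]), "size")
})

test_that("branch rates highlight a constructed jump", {
  tr <- simulate_tree(50, seed = 7)
  y <- simulate_bm(tr, 0.01, 0, seed = 4)
  clade <- 60  # an internal node; its stem branch receives the jump
  tips_in <- thermevol:::.tip_masks(tr)[[clade]]
  y[tips_in] <- y[tips_in] + 10
  br <- suppressWarnings(branch_rate_proxy(tr, y))
  expect_equal(br$child[which.max(br$rate)], clade)
  expect_equal(max(br$rate), 1)
  expect_true(all(br$rate >= 0 & br$rate <= 1))
  # constant trait: all rates zero
  br0 <- branch_rate_proxy(tr, setNames(rep(2, 50), tr$tip.label))
  expect_true(all(br0$rate == 0))
})
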