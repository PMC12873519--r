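test_that("Newick ingestion validates shape and round-trips", {
  tr <- read_tree("(A:1,B:1):0;")
  expect_equal(length(tr$tip.label), 2)
  rep <- attr(tr, "tree_report")
  expect_true(rep$ultrametric)
  expect_true(rep$binary)

  tr4 <- polytomy_tree(4)  # 3-tip stars are binary as unrooted trees
  tr4b <- read_tree(ape::write.tree(tr4))
  expect_false(attr(tr4b, "tree_report")$binary)

  # round trip preserves topology and patristic structure
  big <- generate_tree(30, seed = 2)
  rt <- read_tree(ape::write.tree(big))
  expect_setequal(rt$tip.label, big$tip.label)
  d0 <- ape::cophenetic.phylo(big)
  d1 <- ape::cophenetic.phylo(rt)[rownames(d0), colnames(d0)]
  expect_equal(d1, d0, tolerance = 1e-8)

  expect_error(read_tree("not newick at all"), "parse")
  expect_error(read_tree("((A:1,A:1):1,B:2);"), "duplicate")
  expect_error(read_tree("((A,B),C);"), "branch lengths")
})

test_that("polytomies resolve randomly while preserving tip depths", {
  bin <- generate_tree(10, seed = 1)
  expect_identical(resolve_polytomies(bin, 1), bin)

  p4 <- polytomy_tree(4)
  r4 <- resolve_polytomies(p4, seed = 2)
  expect_true(ape::is.binary(r4))
  expect_equal(r4$Nnode - p4$Nnode, 2)  # 4-way polytomy adds 2 internal nodes
  expect_equal(ape::node.depth.edgelength(r4)[1:4], rep(1, 4),
               tolerance = 1e-12)
  expect_true(ape::is.ultrametric(r4, option = 2, tol = 1e-9))
  expect_identical(ape::write.tree(resolve_polytomies(p4, seed = 2)),
                   ape::write.tree(r4))

  p5 <- polytomy_tree(5)
  topos <- unique(sapply(1:30, function(s)
    ape::write.tree(ape::rotateConstr(resolve_polytomies(p5, seed = s),
                                      sort(p5$tip.label)))))
  expect_gte(length(topos), 2)

  nonultra <- ape::read.tree(text = "((A:1,B:2):1,C:2);")
  expect_error(resolve_polytomies(nonultra), "ultrametric")
})

test_that("covariance matrices match hand calculations for each structure", {
  tr <- hand_tree3()  # ((A:1,B:1):1,C:2); depth 2

  wn <- covariance_matrix(tr, "WN")
  expect_equal(unname(wn), diag(3))

  bm <- covariance_matrix(tr, "BM")
  expect_equal(bm["A", "A"], 2)
  expect_equal(bm["A", "B"], 1)   # shared ancestor depth
  expect_equal(bm["A", "C"], 0)

  # patristic distances: A-B = 2, A-C = B-C = 4
  ou <- covariance_matrix(tr, correlation_structure("OU", alpha = 1))
  expect_equal(diag(ou), c(A = 1, B = 1, C = 1))
  expect_equal(ou["A", "B"], exp(-2))
  expect_equal(ou["A", "C"], exp(-4))
  ou2 <- covariance_matrix(tr, correlation_structure("OU", alpha = 0.3))
  expect_equal(ou2["A", "B"], exp(-0.6))

  lam <- covariance_matrix(tr, correlation_structure("lambda", lambda = 0.4))
  expect_equal(lam["A", "B"], 0.4 * bm["A", "B"])
  expect_equal(diag(lam), diag(bm))
  expect_equal(covariance_matrix(tr, correlation_structure("lambda", lambda = 1)),
               bm)
  # lambda = 0 is phylogenetic independence (identity correlation)
  lam0 <- covariance_matrix(tr, correlation_structure("lambda", lambda = 0))
  expect_equal(unname(stats::cov2cor(lam0)), diag(3))

  # OU -> identity as alpha -> infinity
  ouinf <- covariance_matrix(tr, correlation_structure("OU", alpha = 1e6))
  expect_equal(unname(ouinf), diag(3), tolerance = 1e-12)

  # tip subsetting and unknown-tip validation
  sub <- covariance_matrix(tr, "BM", tips = c("C", "A"))
  expect_equal(rownames(sub), c("C", "A"))
  expect_error(covariance_matrix(tr, "BM", tips = c("A", "Z")), "Z")
})

test_that("covariance matrices are symmetric PSD on random trees", {
  for (s in 1:25) {
    tr <- generate_tree(sample(5:40, 1), seed = s)
    for (kind in c("BM", "OU")) {
      C <- covariance_matrix(tr, correlation_structure(kind, alpha = 1))
      expect_true(isSymmetric(C))
      expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-8)
    }
  }
})

test_that("GLS with identity covariance reproduces OLS exactly", {
  tab <- generate_traits(generative_config(n_species = 50, seed = 21))
  ols <- fit_loglog(tab, "d_pet_um", "leaf_length_cm")
  g <- gls_fit(log10(tab$d_pet_um), cbind(slope = log10(tab$leaf_length_cm)),
               diag(50), structure_name = "WN")
  expect_equal(unname(coef(g)), unname(c(ols$intercept, ols$slope)),
               tolerance = 1e-10)
  expect_equal(unname(g$se), unname(c(ols$intercept_se, ols$slope_se)),
               tolerance = 1e-10)
  expect_equal(unname(g$ci["slope", ]), ols$slope_ci, tolerance = 1e-10)
})

test_that("GLS matches explicit linear algebra and the Gaussian density", {
  # 3-observation hand instance
  y <- c(1.2, 0.7, -0.3)
  X <- cbind(1, c(0.5, 1.5, 2.5))
  C <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3)
  g <- gls_fit(y, X, C, intercept = FALSE)
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
  expect_equal(unname(coef(g)), as.numeric(beta), tolerance = 1e-10)

  # log-likelihood equals the multivariate normal density at the ML solution
  r <- y - X %*% beta
  s2 <- as.numeric(t(r) %*% Ci %*% r) / 3
  ll_direct <- -0.5 * (3 * log(2 * pi) + log(det(s2 * C)) +
                         as.numeric(t(r) %*% solve(s2 * C) %*% r))
  expect_equal(g$logLik, ll_direct, tolerance = 1e-8)

  expect_error(gls_fit(y, X, C[1:2, 1:2], intercept = FALSE), "dimension")
})

test_that("GLS agrees with an independent implementation under BM and OU", {
  tr <- generate_tree(40, seed = 6)
  cfg <- generative_config(n_species = 40, seed = 6,
                           residual_mode = "brownian")
  tab <- generate_traits(cfg, tr)
  d <- data.frame(y = log10(tab$d_pet_um), x = log10(tab$leaf_length_cm),
                  sp = tab$species)
  rownames(d) <- d$sp
  for (setup in list(
    list(C = covariance_matrix(tr, "BM", tips = tab$species),
         cs = ape::corBrownian(1, tr, form = ~sp)),
    list(C = covariance_matrix(tr, correlation_structure("OU", alpha = 1),
                               tips = tab$species),
         cs = ape::corMartins(1, tr, form = ~sp, fixed = TRUE)))) {
    ours <- gls_fit(d$y, cbind(slope = d$x), setup$C)
    ref <- nlme::gls(y ~ x, data = d, correlation = setup$cs, method = "ML")
    expect_equal(unname(coef(ours)), unname(coef(ref)), tolerance = 1e-8)
    expect_equal(ours$logLik, as.numeric(stats::logLik(ref)),
                 tolerance = 1e-8)
  }
})

test_that("AICc ranking has the right penalty and recovers BM residuals", {
  # formula edge: n = k + 2 makes the correction term 2k(k+1)/1
  y <- c(0.1, 0.9, 2.2, 2.8, 4.1)
  g <- gls_fit(y, cbind(x = 1:5), diag(5))
  k <- 3
  expect_equal(g$AICc - g$AIC, 2 * k * (k + 1) / 1)

  tr <- generate_tree(88, seed = 14)
  wins <- sapply(1:40, function(s) {
    cfg <- generative_config(seed = s, residual_mode = "brownian")
    tab <- generate_traits(cfg, tr)
    ms <- select_model(log10(tab$d_pet_um),
                       cbind(slope = log10(tab$leaf_length_cm)),
                       tr, tips = tab$species)
    c(best = ms$best,
      bm_beats_wn = ms$fits$BM$logLik >= ms$fits$WN$logLik)
  })
  expect_gte(mean(wins["bm_beats_wn", ] == "TRUE"), 0.9)
  # full 200-simulation selection rates are exercised in the acceptance suite
  expect_gte(mean(wins["best", ] == "BM"), 0.7)
})

test_that("lambda and K detect simulated Brownian signal and match phytools", {
  skip_if_not_installed("phytools")
  tr <- generate_tree(60, seed = 30)
  set.seed(30)
  y <- as.numeric(crossprod(chol(covariance_matrix(tr, "BM")), rnorm(60)))
  names(y) <- tr$tip.label
  s <- phylo_signal(y, tr, n_perm = 199, seed = 1)
  ref_l <- phytools::phylosig(tr, y, method = "lambda", test = FALSE)
  ref_k <- phytools::phylosig(tr, y, method = "K")
  expect_equal(s$lambda, ref_l$lambda, tolerance = 1e-3)
  expect_equal(s$lambda_logL, ref_l$logL, tolerance = 1e-5)
  expect_equal(s$K, as.numeric(ref_k), tolerance = 1e-8)
  expect_lt(s$lambda_p, 0.05)
  expect_lt(s$K_p, 0.05)

  # ML lambda is high for BM traits across replicate simulations
  lams <- sapply(1:30, function(s) {
    set.seed(1000 + s)
    yy <- as.numeric(crossprod(chol(covariance_matrix(tr, "BM")), rnorm(60)))
    names(yy) <- tr$tip.label
    phylo_signal(yy, tr, statistic = "lambda")$lambda
  })
  expect_gte(median(lams), 0.8)
})

test_that("phylo_signal rejects degenerate input and is seed-stable", {
  tr <- generate_tree(10, seed = 2)
  const <- stats::setNames(rep(1, 10), tr$tip.label)
  expect_error(phylo_signal(const, tr), "constant")
  y <- stats::setNames(rnorm(10), tr$tip.label)
  s1 <- phylo_signal(y, tr, n_perm = 199, seed = 9)
  s2 <- phylo_signal(y, tr, n_perm = 199, seed = 9)
  expect_identical(s1$K_p, s2$K_p)
  expect_error(phylo_signal(unname(y), tr), "named")
  expect_error(phylo_signal(stats::setNames(y, paste0("x", 1:10)), tr),
               "not in tree")
  expect_error(phylo_signal(y, tr, n_perm = 10), "99")
})

test_that("pgls_scaling intersects table and tree and reports both intercept scales", {
  tr <- generate_tree(30, seed = 44)
  tab <- generate_traits(generative_config(n_species = 30, seed = 44))
  tab$species <- tr$tip.label
  tab_plus <- rbind(tab, tab[1, ])
  tab_plus$species[31] <- "not_on_tree"
  expect_message(ms <- pgls_scaling(tab_plus, tr, "d_pet_um",
                                    "leaf_length_cm"), "dropping 1")
  expect_equal(ms$summary$n, 30)
  expect_equal(ms$summary$intercept_backtransformed,
               10^ms$summary$intercept_log10)
  expect_true(ms$summary$model %in% c("WN", "BM", "OU"))
  expect_equal(nrow(ms$ranking), 3)
  expect_true(all(diff(ms$ranking$AICc) >= 0))
})
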