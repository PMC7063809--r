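test_that("eigengene of a rank-1 module is the shared profile", {
  set.seed(30)
  base <- rnorm(20)
  expr <- t(sapply(1:6, function(i) 2 * base + 5))   # identical up to scaling
  rownames(expr) <- sprintf("g%d", 1:6)
  colnames(expr) <- sprintf("S%d", 1:20)
  e <- module_eigengene(expr, rownames(expr))
  zs <- scale(base)[, 1]
  expect_equal(abs(stats::cor(e$eigengene, zs)), 1, tolerance = 1e-10)
  expect_equal(e$variance_explained, 1, tolerance = 1e-10)
  ## unit norm, zero mean, positive orientation to members
  expect_equal(sum(e$eigengene^2), 1, tolerance = 1e-10)
  expect_equal(mean(e$eigengene), 0, tolerance = 1e-10)
  expect_gt(mean(stats::cor(e$eigengene, t(expr))), 0)
  expect_error(module_eigengene(expr, "g1"), ">= 2 genes")
})

test_that("uncorrelated-noise module explains ~ 1/size of the variance", {
  ve <- vapply(1:40, function(s) {
    set.seed(3100 + s)
    expr <- matrix(rnorm(8 * 400), 8,
                   dimnames = list(sprintf("g%d", 1:8), sprintf("S%d", 1:400)))
    module_eigengene(expr, rownames(expr))$variance_explained
  }, 0)
  ## the leading sample eigenvalue of a null correlation matrix sits at
  ## (1 + sqrt(p/n))^2, so the share is slightly above 1/p
  expect_gt(mean(ve), 1 / 8)
  expect_lt(mean(ve), (1 + sqrt(8 / 400))^2 / 8 + 0.02)
})

test_that("noiseless factor module recovers the latent factor with + sign", {
  d <- generate_dataset(simulation_config(
    n_samples = 30, module_sizes = 12, within_module_cor = 1, seed = 31))
  e <- module_eigengene(d$expr, names(d$truth$planted_labels))
  expect_equal(stats::cor(e$eigengene, d$truth$factors[, 1]), 1,
               tolerance = 1e-10)
})

test_that("eigengene is invariant to gene order within the module", {
  d <- planted_dataset(32, sizes = c(20, 20), wmc = 0.7, n_background = 0)
  genes <- names(d$truth$planted_labels)[d$truth$planted_labels == 1]
  e1 <- module_eigengene(d$expr, genes)
  e2 <- module_eigengene(d$expr[rev(rownames(d$expr)), ], rev(genes))
  expect_equal(e1$eigengene, e2$eigengene, tolerance = 1e-9)
})

test_that("module membership equals looped gene-eigengene correlations", {
  d <- planted_dataset(33, sizes = c(15, 15), wmc = 0.6, n_background = 0)
  eig <- eigengene_set(d$expr, d$truth$planted_labels)
  kme <- module_membership(d$expr, eig)
  for (g in rownames(d$expr)[c(1, 8, 30)]) for (m in rownames(eig$eigengenes))
    expect_equal(kme[g, m],
                 stats::cor(d$expr[g, ], eig$eigengenes[m, ]),
                 tolerance = 1e-12)
  ## a gene equal to an eigengene has kME 1
  expr2 <- rbind(d$expr, ghost = eig$eigengenes[1, ])
  expect_equal(module_membership(expr2, eig)["ghost", 1], 1,
               tolerance = 1e-10)
})

test_that("gene significance is |cor| with the trait and validates input", {
  d <- planted_dataset(34, sizes = 20, wmc = 0.8, n_background = 20,
                       n_samples = 30)
  trait <- d$expr[1, ]                       # trait equal to a gene profile
  gs <- gene_significance(d$expr, trait)
  expect_equal(unname(gs[1]), 1, tolerance = 1e-12)
  expect_true(all(gs >= 0 & gs <= 1))
  expect_error(gene_significance(d$expr, rep(2, 30)), "zero variance")
  expect_error(gene_significance(d$expr[, 1:2], trait[1:2]), "3 overlapping")
})

test_that("module genes carry higher gene significance than background", {
  wins <- vapply(1:40, function(s) {
    cfg <- simulation_config(n_samples = 26, module_sizes = 30,
                             within_module_cor = 0.6, n_background = 100,
                             trait_specs = list(trait_spec("T", list(c(1, 1)))),
                             seed = 6000 + s)
    d <- generate_dataset(cfg)
    gs <- gene_significance(d$expr, stats::setNames(d$traits$T,
                                                    d$traits$sample_id))
    lab <- d$truth$planted_labels
    mean(gs[lab == 1]) > mean(gs[lab == 0])
  }, NA)
  expect_gte(mean(wins), 0.95)
})

test_that("trait residualization removes covariate effects", {
  set.seed(35)
  n <- 50
  sex <- rep(0:1, n / 2)
  ## perfectly collinear trait -> zero residuals
  r0 <- adjust_trait(2 * sex + 3, data.frame(sex = sex))
  expect_equal(unname(r0), rep(0, n), tolerance = 1e-10)
  ## orthogonal covariate -> centered trait unchanged
  y <- rnorm(n)
  cov_orth <- rep(c(1, -1), n / 2)
  y_orth <- y - mean(y) - stats::cov(y, cov_orth) / stats::var(cov_orth) *
    (cov_orth - mean(cov_orth))
  r1 <- adjust_trait(y_orth, data.frame(z = cov_orth))
  expect_equal(unname(r1), unname(y_orth - mean(y_orth)), tolerance = 1e-10)
  ## missing values propagate
  y2 <- y; y2[3] <- NA
  r2 <- adjust_trait(y2, data.frame(sex = sex))
  expect_true(is.na(r2[3]) && !anyNA(r2[-3]))
  expect_error(adjust_trait(y, data.frame(a = sex, b = sex)),
               "rank-deficient")
})

test_that("residualization recovers the confounder-free correlation", {
  ## trait = 2*sex + f + noise: partialling out sex recovers cor with f
  res <- vapply(1:200, function(s) {
    set.seed(6500 + s)
    n <- 26
    sex <- rbinom(n, 1, 0.5)
    f <- rnorm(n)
    y <- 2 * sex + f + rnorm(n, sd = 0.5)
    stats::cor(adjust_trait(y, data.frame(sex = sex)), f)
  }, 0)
  pop_r <- 1 / sqrt(1 + 0.25)
  expect_equal(mean(res), pop_r, tolerance = 0.03)
})

test_that("BH adjustment matches the hand example and the step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.005, 0.04, 0.03)),
               c(0.015, 0.04, 0.04), tolerance = 1e-12)
  expect_equal(benjamini_hochberg(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(benjamini_hochberg(0.7), 0.7)
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "p-values")
  set.seed(36)
  for (rep in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("module-trait correlation applies adjustment, t-test p and FDR", {
  d <- planted_dataset(37, n_samples = 26, sizes = c(20, 20, 20), wmc = 0.8,
                       n_background = 0)
  eig <- eigengene_set(d$expr, d$truth$planted_labels)
  ## trait built equal to the first eigengene -> r = 1, p ~ 0
  traits <- data.frame(sample_id = colnames(d$expr),
                       hit = eig$eigengenes[1, ],
                       null1 = rnorm(26), null2 = rnorm(26))
  mt <- module_trait_correlation(eig, trait_table(traits))
  hit <- mt[mt$module == rownames(eig$eigengenes)[1] & mt$trait == "hit", ]
  expect_equal(hit$r, 1, tolerance = 1e-8)
  expect_lt(hit$p, 1e-12)
  expect_true(hit$significant)
  ## r = 0 -> p = 1 via the t transform
  e <- eig$eigengenes[1, ]
  orth <- rnorm(26)
  orth <- resid(lm(orth ~ e))
  traits2 <- data.frame(sample_id = colnames(d$expr), flat = orth)
  mt2 <- module_trait_correlation(eig, trait_table(traits2))
  row <- mt2[mt2$module == rownames(eig$eigengenes)[1], ]
  expect_equal(row$r, 0, tolerance = 1e-10)
  expect_equal(row$p, 1, tolerance = 1e-8)
  ## p_adj >= p always; BH across the whole matrix
  expect_true(all(mt$p_adj >= mt$p - 1e-15))
  expect_equal(mt$p_adj, benjamini_hochberg(mt$p), tolerance = 1e-12)
})

test_that("covariate-confounded trait is adjusted before correlation", {
  cfg <- simulation_config(
    n_samples = 40, module_sizes = c(25, 25), within_module_cor = 0.8,
    trait_specs = list(trait_spec("WT_BL", list(c(1, 1.2)),
                                  sex_effect = 3, race_effect = 2)),
    seed = 38)
  d <- generate_dataset(cfg)
  eig <- eigengene_set(d$expr, d$truth$planted_labels)
  tt <- trait_table(d$traits)
  expect_identical(trait_covariates(tt, "WT_BL"), c("sex", "race"))
  mt <- module_trait_correlation(eig, tt)
  expect_identical(unique(mt$covariates_adjusted), "sex;race")
  ## adjusted correlation should track the planted factor effect
  hit <- mt[mt$module == "turquoise" & mt$trait == "WT_BL", ]
  expect_gt(abs(hit$r), 0.5)
})

test_that("planted module-trait effect is estimated without bias at n = 26", {
  eff <- 0.75 / sqrt(1 - 0.75^2)
  rs <- vapply(1:300, function(s) {
    cfg <- simulation_config(n_samples = 26, module_sizes = 25,
                             within_module_cor = 0.8,
                             trait_specs = list(trait_spec("T",
                                                           list(c(1, eff)))),
                             seed = 7500 + s)
    d <- generate_dataset(cfg)
    eig <- eigengene_set(d$expr, d$truth$planted_labels)
    stats::cor(eig$eigengenes[1, ], d$traits$T)
  }, 0)
  ## slight attenuation from eigengene estimation; Fisher-z mean within MC error
  expect_equal(mean(atanh(rs)), atanh(0.75), tolerance = 0.05)
})
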