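test_that("partition_ss matches a hand-expanded 2x2 oracle and edge cases", {
  m <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  tab <- partition_ss(m, reps = 1)
  # brute force over the 4 cells: mu = .5, all margins .5
  expect_equal(tab$ss[tab$source == "Genotypes"], 0)
  expect_equal(tab$ss[tab$source == "Environments"], 0)
  expect_equal(tab$ss[tab$source == "Genotype x Environment"], 4 * 0.5^2)
  # constant matrix: no variation anywhere
  const <- matrix(3, 3, 4, dimnames = list(letters[1:3], LETTERS[1:4]))
  expect_true(all(partition_ss(const, 2)$ss == 0))
  expect_error(partition_ss(m, reps = 0), class = "metstab_validation_error")
})

test_that("partition SS are additive, scale linearly in r, and percentages close", {
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(rnorm(30, 5), 6, 5,
                dimnames = list(paste0("g", 1:6), paste0("e", 1:5)))
    t1 <- partition_ss(m, 1)
    # additivity against the total treatment SS computed directly
    mu <- mean(m)
    expect_equal(sum(t1$ss), sum((m - mu)^2), tolerance = 1e-9)
    expect_equal(sum(t1$pct_explained), 100)
    t3 <- partition_ss(m, 3)
    expect_equal(t3$ss, 3 * t1$ss, tolerance = 1e-12)
    expect_equal(t3$pct_explained, t1$pct_explained, tolerance = 1e-12)
  }
})

test_that("replicated ANOVA matches brute-force summation and stats::aov", {
  set.seed(8)
  obs <- simulate_met(met_sim_spec(G = 5, E = 4, R = 3, sigma_err = 0.4,
                                   sigma_block = 0.2,
                                   gei_singular_values = c(1, 0.5),
                                   seed = 8))$observations
  tab <- met_anova(obs)
  get <- function(s) tab$ss[tab$source == s]

  # brute-force nested-loop oracle
  mu <- mean(obs$yield)
  ss <- c(e = 0, rep = 0, g = 0, ge = 0)
  for (ev in unique(obs$environment)) {
    de <- obs$yield[obs$environment == ev]
    ss["e"] <- ss["e"] + length(de) * (mean(de) - mu)^2
    for (r in unique(obs$replicate)) {
      dr <- obs$yield[obs$environment == ev & obs$replicate == r]
      ss["rep"] <- ss["rep"] + length(dr) * (mean(dr) - mean(de))^2
    }
  }
  for (g in unique(obs$genotype)) {
    dg <- obs$yield[obs$genotype == g]
    ss["g"] <- ss["g"] + length(dg) * (mean(dg) - mu)^2
    for (ev in unique(obs$environment)) {
      dc <- obs$yield[obs$genotype == g & obs$environment == ev]
      de <- obs$yield[obs$environment == ev]
      ss["ge"] <- ss["ge"] +
        length(dc) * (mean(dc) - mean(dg) - mean(de) + mu)^2
    }
  }
  expect_equal(get("Environments"), ss[["e"]], tolerance = 1e-9)
  expect_equal(get("Replication (Environment)"), ss[["rep"]], tolerance = 1e-9)
  expect_equal(get("Genotypes"), ss[["g"]], tolerance = 1e-9)
  expect_equal(get("Genotype x Environment"), ss[["ge"]], tolerance = 1e-9)

  # independent route: base aov on the factorial formula
  d <- transform(obs, genotype = factor(genotype),
                 environment = factor(environment),
                 replicate = factor(replicate))
  a <- summary(stats::aov(yield ~ environment + environment:replicate +
                            genotype + genotype:environment, data = d))[[1]]
  ss_aov <- setNames(a[["Sum Sq"]], trimws(rownames(a)))
  expect_equal(get("Environments"), ss_aov[["environment"]], tolerance = 1e-8)
  expect_equal(get("Genotypes"), ss_aov[["genotype"]], tolerance = 1e-8)
  expect_equal(get("Replication (Environment)"),
               ss_aov[["environment:replicate"]], tolerance = 1e-8)
  expect_equal(get("Genotype x Environment"),
               ss_aov[["environment:genotype"]], tolerance = 1e-8)
  expect_equal(get("Residuals"), ss_aov[["Residuals"]], tolerance = 1e-8)
  expect_equal(tab$df[1:5], c(3L, 8L, 4L, 12L, 32L))

  # treatment rows agree with partition_ss on the cell means
  part <- partition_ss(cell_means(obs), 3)
  for (s in c("Genotypes", "Environments", "Genotype x Environment"))
    expect_equal(get(s), part$ss[part$source == s], tolerance = 1e-9)
})

test_that("replicated ANOVA rejects unbalanced data and zero noise gives zero error", {
  obs <- simulate_met(met_sim_spec(G = 4, E = 3, R = 2, sigma_err = 0,
                                   sigma_block = 0, seed = 1,
                                   gei_singular_values = c(1, 0.5)))$observations
  tab <- met_anova(obs)
  expect_equal(tab$ss[tab$source == "Residuals"], 0, tolerance = 1e-9)
  expect_error(met_anova(obs[-1, ]), class = "metstab_validation_error")
})

test_that("LSD and CV match the textbook formulas", {
  spec <- met_sim_spec(G = 6, E = 2, R = 3, sigma_err = 0.5,
                       sigma_block = 0.3, gei_singular_values = numeric(0),
                       seed = 31)
  all_obs <- simulate_met(spec)$observations
  obs <- all_obs[all_obs$environment == "E01", ]
  out <- lsd_cv(obs, alpha = 0.05)
  # independent oracle: error MS from base aov, then the formula
  d <- transform(obs, genotype = factor(genotype), replicate = factor(replicate))
  a <- summary(stats::aov(yield ~ genotype + replicate, data = d))[[1]]
  ms <- a[["Mean Sq"]][trimws(rownames(a)) == "Residuals"]
  df <- (6 - 1) * (3 - 1)
  expect_equal(out$ms_error, ms, tolerance = 1e-9)
  expect_equal(out$lsd, qt(0.975, df) * sqrt(2 * ms / 3), tolerance = 1e-9)
  expect_equal(out$cv, 100 * sqrt(ms) / mean(obs$yield), tolerance = 1e-9)
  # zero residual variance: LSD and CV collapse to 0
  obs0 <- simulate_met(met_sim_spec(G = 4, E = 2, R = 2, sigma_err = 0,
                                    sigma_block = 0.2,
                                    gei_singular_values = numeric(0),
                                    seed = 2))$observations
  out0 <- lsd_cv(obs0)
  expect_equal(out0$lsd, c(0, 0), tolerance = 1e-7)
  expect_equal(out0$cv, c(0, 0), tolerance = 1e-6)
  # CV invariant to genotype relabeling
  obs_perm <- obs
  obs_perm$genotype <- factor(obs$genotype,
                              labels = rev(sort(unique(obs$genotype))))
  obs_perm$genotype <- as.character(obs_perm$genotype)
  expect_equal(lsd_cv(obs_perm)$cv, out$cv)
  # single replicate has no error df
  expect_error(lsd_cv(obs[obs$replicate == 1, ]), "replicates")
})

test_that("Bartlett statistic matches hand evaluation and base bartlett.test", {
  # equality: statistic 0, p 1
  h <- homogeneity_test(c(2, 2, 2), c(5, 5, 5))
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)
  # two variances (1, 4) with df (10, 10): hand-evaluated formula
  N <- 20; sp2 <- (10 * 1 + 10 * 4) / N
  C <- 1 + (1 / 10 + 1 / 10 - 1 / N) / 3
  stat_hand <- (N * log(sp2) - 10 * log(1) - 10 * log(4)) / C
  h2 <- homogeneity_test(c(1, 4), c(10, 10))
  expect_equal(h2$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(h2$p_value, pchisq(stat_hand, 1, lower.tail = FALSE))
  # scale invariance
  h3 <- homogeneity_test(c(2, 8), c(10, 10))
  expect_equal(h3$statistic, h2$statistic, tolerance = 1e-12)
  # against stats::bartlett.test on raw groups (df = n_k - 1, s2 = var)
  set.seed(5)
  y <- rnorm(60, sd = rep(c(1, 1.5, 3), each = 20))
  grp <- rep(1:3, each = 20)
  ref <- stats::bartlett.test(y, grp)
  mine <- homogeneity_test(tapply(y, grp, var), rep(19, 3))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-10)
  expect_error(homogeneity_test(c(1, 0), c(5, 5)),
               class = "metstab_validation_error")
  expect_error(homogeneity_test(1, 5), class = "metstab_validation_error")
})

test_that("trial-level homogeneity wrappers run on replicated data", {
  obs <- simulate_met(met_sim_spec(seed = 17))$observations
  hb <- met_homogeneity(obs)
  expect_equal(hb$df, 8L)
  expect_true(hb$p_value > 0 && hb$p_value <= 1)
  hl <- met_homogeneity(obs, method = "levene")
  expect_true(hl$p_value > 0 && hl$p_value <= 1)
  skip_if_not_installed("car")
  # oracle: car::leveneTest on the same site-RCBD residuals (signed; the
  # per-environment residual means are exactly zero, so Levene's centring
  # step reduces to taking absolute values)
  res <- unlist(lapply(unique(obs$environment), function(ev) {
    d <- obs[obs$environment == ev, ]
    stats::residuals(stats::lm(yield ~ factor(genotype) +
                                 factor(replicate), data = d))
  }))
  grp <- factor(rep(unique(obs$environment), each = 24))
  ref <- car::leveneTest(res ~ grp, center = mean)
  expect_equal(hl$statistic, ref[["F value"]][1], tolerance = 1e-8)
  expect_equal(hl$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-8)
})
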