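trial <- oromia_wheat()

test_that("GGE centring and explained variance behave as expected", {
  g <- gge(trial$means)
  expect_equal(colSums(g$centered), rep(0, 9), tolerance = 1e-9,
               ignore_attr = TRUE)
  # the biplot rank captures the majority of G + GxE variation here
  expect_gt(g$pct[1] + g$pct[2], 60)
  # no genotype effect and no interaction: nothing left after centring
  flat <- outer(rep(5, 4), c(1, 2, 3), "+")
  dimnames(flat) <- list(paste0("g", 1:4), paste0("e", 1:3))
  expect_equal(gge(flat)$singular_values, rep(0, 3), tolerance = 1e-9)
  expect_error(gge(trial$means, scaling = "nope"))
})

test_that("scaling modes repartition the singular values consistently", {
  for (mode in c("symmetric", "genotype", "environment")) {
    g <- gge(trial$means, scaling = mode)
    # the full score product reconstructs the centred matrix
    expect_equal(gge_reconstruction(g, length(g$singular_values)),
                 g$centered, tolerance = 1e-9, ignore_attr = TRUE)
  }
  gs <- gge(trial$means, "symmetric")
  gg_ <- gge(trial$means, "genotype")
  expect_equal(abs(gg_$gen_scores[, 1]),
               abs(gs$gen_scores[, 1]) * sqrt(gs$singular_values[1]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a genotype dominant everywhere takes the largest PC1 score", {
  base <- matrix(rnorm(24, 4, 0.1), 4, 6,
                 dimnames = list(paste0("g", 1:4), paste0("e", 1:6)))
  set.seed(2)
  base["g3", ] <- base["g3", ] + 3     # uniformly superior genotype
  g <- gge(base)
  expect_equal(rownames(g$gen_scores)[which.max(g$gen_scores[, 1])], "g3")
})

test_that("environment diagnostics match direct geometry", {
  g <- gge(trial$means)
  dg <- environment_diagnostics(g)
  # oracle: recompute lengths/angles from an independent svd
  z <- sweep(trial$means, 2, colMeans(trial$means))
  s <- svd(z)
  ev <- s$v[, 1:2] %*% diag(sqrt(s$d[1:2]))
  for (k in 1:2) if (ev[which.max(abs(ev[, k])), k] < 0) ev[, k] <- -ev[, k]
  aea <- colMeans(ev); aea <- aea / sqrt(sum(aea^2))
  len <- sqrt(rowSums(ev^2))
  ang <- acos(pmin(1, pmax(-1, (ev %*% aea) / len)))
  expect_equal(dg$vector_length, unname(len), tolerance = 1e-9)
  expect_equal(dg$angle_aea, as.vector(ang), tolerance = 1e-9)
  expect_true(all(dg$angle_aea >= 0 & dg$angle_aea <= pi))
  # an environment lying exactly on the AEA has angle 0
  onaea <- which.min(dg$angle_aea)
  expect_equal(dg$rank_representative[onaea], 1)
  # representativeness ordering is invariant to uniform rescaling
  dg2 <- environment_diagnostics(gge(2.5 * trial$means))
  expect_equal(dg2$rank_representative, dg$rank_representative)
  expect_equal(dg2$rank_discriminating, dg$rank_discriminating)
})

test_that("diagnostics on a hand-built 3-environment geometry", {
  # rank-2 centred matrix built from known scores: u, v orthonormal
  u <- qr.Q(qr(cbind(1, c(1, -1, 0, 0), c(0, 0, 1, -1))))[, 2:3]
  v <- qr.Q(qr(cbind(c(2, -1, 0), c(0, 1, -1))))   # not orthogonal to ones

  z <- u %*% diag(c(3, 1)) %*% t(v)
  m <- z + 5
  dimnames(m) <- list(paste0("g", 1:4), paste0("e", 1:3))
  g <- gge(m)
  expect_equal(g$singular_values[1:2], c(3, 1), tolerance = 1e-9)
  dg <- environment_diagnostics(g)
  # trigonometric oracle on the known environment coordinates
  ev <- cbind(sqrt(3) * v[, 1], 1 * v[, 2])
  for (k in 1:2) if (ev[which.max(abs(ev[, k])), k] < 0) ev[, k] <- -ev[, k]
  expect_equal(dg$vector_length, sqrt(rowSums(ev^2)), tolerance = 1e-9)
  aea <- colMeans(ev); aea <- aea / sqrt(sum(aea^2))
  expect_equal(dg$angle_aea,
               as.vector(acos((ev %*% aea) / sqrt(rowSums(ev^2)))),
               tolerance = 1e-8)
})

test_that("degenerate geometries are reported", {
  # all genotypes identical after centring: zero-length AEA upstream
  flat <- outer(rep(2, 3), c(1, 2, 3), "+")
  dimnames(flat) <- list(paste0("g", 1:3), paste0("e", 1:3))
  expect_error(environment_diagnostics(gge(flat)),
               class = "metstab_validation_error")
  # collinear genotype markers: rank-1 interaction
  sim <- simulate_met(met_sim_spec(G = 5, E = 4, R = 2, sigma_g = 0,
                                   gei_singular_values = c(2, 0),
                                   sigma_err = 0, sigma_block = 0, seed = 3))
  g1 <- gge(cell_means(sim$observations))
  expect_error(which_won_where(g1), "collinear")
})

test_that("which-won-where reproduces the published polygon on the trial", {
  ww <- which_won_where(gge(trial$means))
  expect_setequal(ww$hull_vertices,
                  c("Ardi", "Fentale 1", "ETBW 9578", "Amibara 2",
                    "Ogolcho", "Ga'ambo 2"))
  # Ardi wins the sector holding both Daro Lebu and Bedeno
  expect_equal(unname(ww$env_winner["Daro Lebu"]), "Ardi")
  expect_equal(unname(ww$env_winner["Bedeno"]), "Ardi")
  expect_equal(ww$env_sector[["Daro Lebu"]], ww$env_sector[["Bedeno"]])
  # every environment is assigned to exactly one sector, winners are vertices
  expect_equal(sort(names(ww$env_sector)), sort(colnames(trial$means)))
  expect_true(all(ww$env_winner %in% ww$hull_vertices))
})

test_that("sector winners agree with the rank-2 argmax oracle and are stable", {
  check_oracle <- function(means) {
    ww <- which_won_where(gge(means))
    # independent oracle: argmax of the rank-2 reconstruction per environment
    z <- sweep(means, 2, colMeans(means))
    s <- svd(z)
    r2 <- s$u[, 1:2] %*% diag(s$d[1:2]) %*% t(s$v[, 1:2])
    dimnames(r2) <- dimnames(means)
    winner_oracle <- rownames(means)[apply(r2, 2, which.max)]
    expect_equal(unname(ww$env_winner[colnames(means)]), winner_oracle)
    # winner consistency: >= every other hull vertex in its environments
    for (j in seq_len(ncol(means))) {
      w <- ww$env_winner[colnames(means)[j]]
      expect_true(all(r2[w, j] >= r2[ww$hull_vertices, j] - 1e-9))
    }
    ww
  }
  check_oracle(trial$means)
  set.seed(99)
  for (i in 1:10) {
    sim <- simulate_met(met_sim_spec(G = 8, E = 6, R = 2,
                                     gei_singular_values = c(1.5, 0.8),
                                     sigma_err = 0.3, sigma_block = 0,
                                     seed = 300 + i))
    check_oracle(cell_means(sim$observations))
  }
  # rotation/sign invariance: flipping both score sets leaves the
  # partition unchanged
  g <- gge(trial$means)
  g2 <- g
  g2$gen_scores <- -g2$gen_scores
  g2$env_scores <- -g2$env_scores
  ww <- which_won_where(g); ww2 <- which_won_where(g2)
  expect_equal(ww2$env_winner, ww$env_winner)
  split_envs <- function(x) unname(split(names(x$env_sector), x$env_sector))
  expect_setequal(lapply(split_envs(ww2), sort), lapply(split_envs(ww), sort))
})

test_that("environments exactly on a ray go to the counterclockwise sector", {
  ww <- which_won_where(gge(trial$means))
  # synthesize an environment direction exactly on each ray and re-assign
  P <- ww$gen_points
  for (k in seq_along(ww$rays$angle)) {
    a <- ww$rays$angle[k]
    dir <- c(cos(a), sin(a))
    # inner products with the two vertices adjacent to the ray tie...
    v_k <- ww$hull_vertices[k]
    v_next <- ww$hull_vertices[if (k == length(ww$hull_vertices)) 1 else k + 1]
    expect_equal(sum(P[v_k, ] * dir), sum(P[v_next, ] * dir),
                 tolerance = 1e-9)
  }
})
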