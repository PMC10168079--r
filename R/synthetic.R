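# seeded generator of replicated RCBD trial data with a known low-rank
# genotype-by-environment interaction; used to validate every analysis
# stage against ground truth

#' Specify a synthetic multi-environment trial
#'
#' Defines the generating model for [simulate_met()]:
#' \deqn{Y_{ijr} = \mu + g_i + e_j + \sum_n \lambda_n u_{ni} v_{nj}
#'       + b_{jr} + \varepsilon_{ijr}}
#' with centred additive genotype effects \eqn{g_i} and environment
#' effects \eqn{e_j}, an exactly low-rank interaction built from
#' orthonormal score vectors \eqn{u_n, v_n} (each orthogonal to the
#' all-ones vector, so the term is exactly what an AMMI fit estimates),
#' block (replicate-within-environment) effects \eqn{b_{jr}} centred
#' within each environment, and homoscedastic Gaussian plot error.
#'
#' The defaults mirror the bundled Oromia wheat trial: 12 genotypes,
#' 9 environments, 2 replicates, grand mean 3.14 t/ha, and effect scales
#' matched to the magnitudes estimated from that trial.
#'
#' @param G,E,R counts of genotypes, environments and replicates.
#' @param mu grand mean (t/ha).
#' @param sigma_g,sigma_e standard deviations of the additive genotype
#'   and environment effects (t/ha).
#' @param gei_singular_values non-increasing, non-negative singular
#'   values \eqn{\lambda_n} of the interaction term on the cell-mean
#'   scale; length at most `min(G-1, E-1)`.
#' @param sigma_err plot-level residual standard deviation (t/ha).
#' @param sigma_block standard deviation of block effects (t/ha).
#' @param env_var_mult optional length-`E` positive multipliers applied
#'   to `sigma_err` per environment (mild heteroscedasticity); default
#'   none.
#' @param seed integer seed; one seed drives every draw.
#' @return an object of class `met_sim_spec`.
#' @seealso [simulate_met()], [ground_truth_ss()]
#' @export
met_sim_spec <- function(G = 12L, E = 9L, R = 2L, mu = 3.14,
                         sigma_g = 0.25, sigma_e = 0.95,
                         gei_singular_values = c(2.9, 2.1, 1.6),
                         sigma_err = 0.5, sigma_block = 0.05,
                         env_var_mult = NULL, seed = 1L) {
  if (G < 2L || E < 2L) stop_validation("need G >= 2 and E >= 2")
  if (R < 1L) stop_validation("need R >= 1")
  lam <- as.numeric(gei_singular_values)
  if (any(lam < 0)) stop_validation("singular values must be non-negative")
  if (is.unsorted(rev(lam))) stop_validation("singular values must be non-increasing")
  if (length(lam) > min(G - 1L, E - 1L))
    stop_validation("requested interaction rank ", length(lam),
                    " exceeds min(G-1, E-1) = ", min(G - 1L, E - 1L))
  if (any(c(sigma_g, sigma_e, sigma_err, sigma_block) < 0))
    stop_validation("standard deviations must be non-negative")
  if (!is.null(env_var_mult)) {
    if (length(env_var_mult) != E || any(env_var_mult <= 0))
      stop_validation("env_var_mult must be ", E, " positive values")
  }
  structure(list(G = as.integer(G), E = as.integer(E), R = as.integer(R),
                 mu = mu, sigma_g = sigma_g, sigma_e = sigma_e,
                 gei_singular_values = lam, sigma_err = sigma_err,
                 sigma_block = sigma_block, env_var_mult = env_var_mult,
                 seed = as.integer(seed)),
            class = "met_sim_spec")
}

# columns orthonormal and orthogonal to the all-ones vector, obtained by
# QR-orthogonalizing standard-normal draws against 1
orthonormal_scores <- function(n, k) {
  if (k == 0L) return(matrix(numeric(0), n, 0L))
  raw <- matrix(stats::rnorm(n * k), n, k)
  q <- qr.Q(qr(cbind(rep(1 / sqrt(n), n), raw)))[, -1L, drop = FALSE]
  q
}

#' Generate replicated trial data from a synthetic specification
#'
#' Draws one realization of the model described in [met_sim_spec()].
#' Additive effects are re-centred to sum exactly to zero after
#' sampling, and block effects are centred within each environment, so
#' the realized effects induce exactly the sums of squares returned by
#' [ground_truth_ss()] (no leakage between ANOVA strata). The same seed
#' always reproduces the same dataset.
#'
#' @param spec a [met_sim_spec()] object.
#' @return an object of class `met_sim`: a list with
#'   \describe{
#'     \item{observations}{`met_trial` data frame of
#'       `G * E * R` plot records.}
#'     \item{truth}{realized `mu`, `g`, `e`, score matrices `u`
#'       (G x N) and `v` (E x N), `lambda`, block matrix `b` (E x R),
#'       and the noise-free cell-mean matrix `expected_means`.}
#'     \item{spec}{the input specification.}
#'   }
#' @export
#' @examples
#' sim <- simulate_met(met_sim_spec(G = 4, E = 3, R = 2, seed = 42))
#' cell_means(sim$observations)
simulate_met <- function(spec) {
  stopifnot(inherits(spec, "met_sim_spec"))
  G <- spec$G; E <- spec$E; R <- spec$R
  lam <- spec$gei_singular_values
  N <- length(lam)
  set.seed(spec$seed)

  g <- stats::rnorm(G, 0, spec$sigma_g); g <- g - mean(g)
  e <- stats::rnorm(E, 0, spec$sigma_e); e <- e - mean(e)
  u <- orthonormal_scores(G, N)
  v <- orthonormal_scores(E, N)
  gei <- if (N > 0L) u %*% (lam * t(v)) else matrix(0, G, E)

  b <- matrix(stats::rnorm(E * R, 0, spec$sigma_block), E, R)
  b <- b - rowMeans(b)                      # centred within environment
  err_sd <- spec$sigma_err * (spec$env_var_mult %||% rep(1, E))

  g_lab <- sprintf("G%02d", seq_len(G))
  e_lab <- sprintf("E%02d", seq_len(E))
  grid <- expand.grid(replicate = seq_len(R), environment = seq_len(E),
                      genotype = seq_len(G))
  mean_part <- spec$mu + g[grid$genotype] + e[grid$environment] +
    gei[cbind(grid$genotype, grid$environment)] +
    b[cbind(grid$environment, grid$replicate)]
  yield <- mean_part + stats::rnorm(nrow(grid), 0, err_sd[grid$environment])

  obs <- data.frame(genotype = g_lab[grid$genotype],
                    environment = e_lab[grid$environment],
                    replicate = as.integer(grid$replicate),
                    yield = yield, stringsAsFactors = FALSE)
  class(obs) <- c("met_trial", "data.frame")

  expected <- spec$mu + outer(g, e, "+") + gei
  dimnames(expected) <- list(g_lab, e_lab)
  rownames(u) <- g_lab; rownames(v) <- e_lab; rownames(b) <- e_lab

  structure(list(observations = obs,
                 truth = list(mu = spec$mu, g = g, e = e, u = u, v = v,
                              lambda = lam, b = b, expected_means = expected),
                 spec = spec),
            class = "met_sim")
}

#' Exact sums of squares implied by realized synthetic effects
#'
#' Computes, in closed form from the ground-truth effects of a
#' [simulate_met()] draw, the treatment and block sums of squares that a
#' balanced combined ANOVA would recover if the plot error were zero:
#' \eqn{SS_G = E R \sum_i g_i^2}, \eqn{SS_E = G R \sum_j e_j^2},
#' \eqn{SS_{GEI} = R \sum_n \lambda_n^2} (orthonormality makes the
#' interaction SS the sum of squared singular values), and
#' \eqn{SS_{rep(env)} = G \sum_{jr} b_{jr}^2}.
#'
#' @param sim a `met_sim` object.
#' @return named numeric vector with elements `ss_g`, `ss_e`, `ss_gei`,
#'   `ss_rep_env`.
#' @export
ground_truth_ss <- function(sim) {
  stopifnot(inherits(sim, "met_sim"))
  t <- sim$truth; s <- sim$spec
  c(ss_g = s$E * s$R * sum(t$g^2),
    ss_e = s$G * s$R * sum(t$e^2),
    ss_gei = s$R * sum(t$lambda^2),
    ss_rep_env = s$G * sum(t$b^2))
}
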