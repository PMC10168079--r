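# the AMMI model: additive main effects by ANOVA, multiplicative
# interaction by SVD of the double-centred means matrix

#' Double-centre a means matrix
#'
#' Removes additive genotype and environment effects, leaving the pure
#' interaction: \eqn{Z_{ij} = Y_{ij} - \bar g_i - \bar e_j + \mu}.
#' Every row and column of the result sums to zero.
#'
#' @param means genotype x environment means matrix.
#' @return matrix of the same dimension with zero margins.
#' @export
double_center <- function(means) {
  check_means_matrix(means)
  means - outer(rowMeans(means), colMeans(means), "+") + mean(means)
}

#' Fit the AMMI model to a genotype x environment means matrix
#'
#' Additive Main effects and Multiplicative Interaction: the grand mean
#' and centred genotype/environment effects are estimated by ANOVA, and
#' the double-centred residual \eqn{Z} is decomposed by singular value
#' decomposition,
#' \deqn{Y_{ij} = \mu + g_i + e_j + \sum_n \lambda_n \alpha_{ni}
#'       \gamma_{nj} + R_{ij},}
#' where \eqn{\lambda_n} is the n-th singular value of \eqn{Z} and
#' \eqn{\alpha, \gamma} are the orthonormal genotype and environment
#' score vectors. Scores are reported with symmetric scaling — both
#' sides carry \eqn{\sqrt{\lambda_n}} — so the product of a genotype and
#' an environment score reconstructs \eqn{\lambda_n \alpha_{ni}
#' \gamma_{nj}} directly and the squared scores on either side sum to
#' \eqn{\lambda_n} per axis.
#'
#' Sign convention: SVD signs are arbitrary, so each axis is flipped to
#' make its largest-magnitude environment score positive. All stability
#' statistics are invariant to per-axis sign flips.
#'
#' Decomposition arithmetic is on the cell-mean scale; interaction sums
#' of squares are multiplied by `reps` at reporting time (`ss_ipca`) so
#' they are comparable to a replicated ANOVA.
#'
#' @param means genotype x environment means matrix.
#' @param reps number of replicates behind each cell mean (scales
#'   reported SS only).
#' @param n_axes number of multiplicative axes kept in the model term;
#'   default all `min(G-1, E-1)` axes (then the residual is zero).
#' @return an object of class `ammi_fit`: list with `mu`, `g_effects`,
#'   `e_effects`, `singular_values`, `gen_scores` (G x M), `env_scores`
#'   (E x M), `pct` (per-axis percentage of interaction SS), `ss_ipca`
#'   (replicated scale), `residual`, `n_axes`, `reps`, `means`.
#' @export
#' @examples
#' fit <- ammi(oromia_wheat()$means, reps = 2)
#' fit
ammi <- function(means, reps = 1L, n_axes = NULL) {
  check_means_matrix(means)
  if (reps < 1L) stop_validation("reps must be >= 1")
  G <- nrow(means); E <- ncol(means)
  M <- min(G - 1L, E - 1L)
  n_axes <- as.integer(n_axes %||% M)
  if (n_axes < 1L || n_axes > M)
    stop_validation("n_axes must be between 1 and min(G-1, E-1) = ", M)

  mu <- mean(means)
  g_eff <- rowMeans(means) - mu
  e_eff <- colMeans(means) - mu
  z <- double_center(means)
  s <- svd(z, nu = M, nv = M)
  d <- s$d[seq_len(M)]
  u <- s$u; v <- s$v
  # sign convention: largest-|.| environment loading positive per axis
  for (k in seq_len(M)) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) { v[, k] <- -v[, k]; u[, k] <- -u[, k] }
  }
  gen_scores <- sweep(u, 2L, sqrt(d), "*")
  env_scores <- sweep(v, 2L, sqrt(d), "*")
  dimnames(gen_scores) <- list(rownames(means), paste0("IPCA", seq_len(M)))
  dimnames(env_scores) <- list(colnames(means), paste0("IPCA", seq_len(M)))
  kept <- seq_len(n_axes)
  residual <- z - gen_scores[, kept, drop = FALSE] %*%
    t(env_scores[, kept, drop = FALSE])

  structure(list(mu = mu, g_effects = g_eff, e_effects = e_eff,
                 singular_values = d,
                 gen_scores = gen_scores, env_scores = env_scores,
                 pct = 100 * d^2 / sum(d^2),
                 ss_ipca = reps * d^2,
                 residual = residual, n_axes = n_axes, reps = reps,
                 means = means),
            class = "ammi_fit")
}

#' @export
print.ammi_fit <- function(x, ...) {
  M <- length(x$singular_values)
  cat("AMMI fit:", length(x$g_effects), "genotypes x",
      length(x$e_effects), "environments, grand mean",
      round(x$mu, 3), "\n")
  cat("Interaction axes (", x$n_axes, " kept of ", M, "):\n", sep = "")
  tab <- data.frame(axis = paste0("IPCA", seq_len(M)),
                    singular_value = round(x$singular_values, 4),
                    pct_of_GxE = round(x$pct, 2),
                    cum_pct = round(cumsum(x$pct), 2),
                    df_gollob = vapply(seq_len(M), gollob_df,
                                       integer(1),
                                       G = length(x$g_effects),
                                       E = length(x$e_effects)))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Gollob degrees of freedom for an interaction axis
#'
#' The conventional df assigned to the n-th multiplicative axis of a
#' G x E interaction: \eqn{G + E - 1 - 2n}.
#'
#' @param n axis index, `1 <= n <= min(G-1, E-1)`.
#' @param G,E numbers of genotypes and environments.
#' @return integer degrees of freedom.
#' @export
gollob_df <- function(n, G, E) {
  if (n < 1L || n > min(G - 1L, E - 1L))
    stop_validation("axis index must be between 1 and min(G-1, E-1) = ",
                    min(G - 1L, E - 1L))
  as.integer(G + E - 1L - 2L * n)
}

#' Significance table for AMMI interaction axes
#'
#' Reports per-axis SS (replicated scale), Gollob df, mean squares, and
#' — when an error mean square from replicate-level data is supplied —
#' F statistics against it. With means-only input no error stratum
#' exists and the F and p columns are `NA`.
#'
#' @param fit an [ammi()] fit.
#' @param ms_error pooled error mean square from [met_anova()], or
#'   `NULL`.
#' @param df_error its degrees of freedom.
#' @return data frame with one row per axis.
#' @export
ammi_axis_table <- function(fit, ms_error = NULL, df_error = NULL) {
  stopifnot(inherits(fit, "ammi_fit"))
  G <- length(fit$g_effects); E <- length(fit$e_effects)
  M <- length(fit$singular_values)
  df <- vapply(seq_len(M), gollob_df, integer(1), G = G, E = E)
  ms <- fit$ss_ipca / df
  out <- data.frame(axis = paste0("IPCA", seq_len(M)), df = df,
                    ss = fit$ss_ipca, ms = ms, pct = fit$pct,
                    f = NA_real_, p = NA_real_)
  if (!is.null(ms_error)) {
    if (is.null(df_error)) stop_config("df_error must accompany ms_error")
    out$f <- ms / ms_error
    out$p <- stats::pf(out$f, df, df_error, lower.tail = FALSE)
  }
  out
}

#' AMMI1 biplot coordinates
#'
#' Point sets for the classical first biplot: mean yield on the
#' abscissa against the IPCA1 score on the ordinate, for genotypes and
#' environments, with the grand mean as vertical reference.
#'
#' @param fit an [ammi()] fit.
#' @return list with data frames `genotypes` and `environments`
#'   (columns `label`, `mean`, `ipca1`) and the scalar `grand_mean`.
#' @export
ammi1_coordinates <- function(fit) {
  stopifnot(inherits(fit, "ammi_fit"))
  list(genotypes = data.frame(label = names(fit$g_effects),
                              mean = fit$mu + fit$g_effects,
                              ipca1 = fit$gen_scores[, 1L],
                              row.names = NULL, stringsAsFactors = FALSE),
       environments = data.frame(label = names(fit$e_effects),
                                 mean = fit$mu + fit$e_effects,
                                 ipca1 = fit$env_scores[, 1L],
                                 row.names = NULL, stringsAsFactors = FALSE),
       grand_mean = fit$mu)
}
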