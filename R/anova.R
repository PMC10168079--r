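# combined-trial ANOVA: sum-of-squares partitioning, F tests,
# per-environment LSD/CV, and homogeneity of error variance

met_anova_row <- function(source, df, ss, f = NA_real_, p = NA_real_,
                          pct = NA_real_) {
  data.frame(source = source, df = as.integer(df), ss = ss,
             ms = ifelse(df > 0, ss / df, NA_real_),
             f = f, p = p, pct_explained = pct,
             stringsAsFactors = FALSE)
}

#' Partition treatment sums of squares from a means matrix
#'
#' Splits the variation among the `G * E` cell means into genotype,
#' environment and interaction components on the replicated scale:
#' \eqn{SS_G = E r \sum_i (\bar g_i - \mu)^2},
#' \eqn{SS_E = G r \sum_j (\bar e_j - \mu)^2},
#' \eqn{SS_{GEI} = r \sum_{ij} (Y_{ij} - \bar g_i - \bar e_j + \mu)^2}.
#' The percentage explained uses the treatment total
#' \eqn{SS_G + SS_E + SS_{GEI}} as denominator (replication and error
#' strata are excluded), so the three percentages sum to exactly 100.
#'
#' With means-only input no error stratum exists; the F statistics
#' reported for genotypes and environments use the interaction mean
#' square as denominator and are flagged as such via the table's
#' `f_denominator` attribute. Use [met_anova()] on replicate-level data
#' for tests against pooled error.
#'
#' @param means genotype x environment means matrix.
#' @param reps number of replicates behind each cell mean.
#' @return a `data.frame` of class `met_anova` with columns `source`,
#'   `df`, `ss`, `ms`, `f`, `p`, `pct_explained`.
#' @export
#' @examples
#' trial <- oromia_wheat()
#' partition_ss(trial$means, trial$reps)
partition_ss <- function(means, reps = 1L) {
  check_means_matrix(means)
  if (reps < 1L) stop_validation("reps must be >= 1")
  G <- nrow(means); E <- ncol(means)
  mu <- mean(means)
  gm <- rowMeans(means); em <- colMeans(means)
  ss_g <- E * reps * sum((gm - mu)^2)
  ss_e <- G * reps * sum((em - mu)^2)
  z <- means - outer(gm, em, "+") + mu
  ss_gei <- reps * sum(z^2)
  tot <- ss_g + ss_e + ss_gei
  ms_gei <- ss_gei / ((G - 1) * (E - 1))
  tab <- rbind(
    met_anova_row("Genotypes", G - 1, ss_g,
                  f = (ss_g / (G - 1)) / ms_gei, pct = 100 * ss_g / tot),
    met_anova_row("Environments", E - 1, ss_e,
                  f = (ss_e / (E - 1)) / ms_gei, pct = 100 * ss_e / tot),
    met_anova_row("Genotype x Environment", (G - 1) * (E - 1), ss_gei,
                  pct = 100 * ss_gei / tot))
  tab$p <- ifelse(is.na(tab$f), NA_real_,
                  stats::pf(tab$f, tab$df, (G - 1) * (E - 1), lower.tail = FALSE))
  structure(tab, class = c("met_anova", "data.frame"), reps = reps,
            f_denominator = "interaction mean square (no error stratum)")
}

# balance check: every g x e x r combination present exactly once
check_balanced <- function(obs) {
  n <- table(obs$genotype, obs$environment, obs$replicate)
  if (any(n != 1L))
    stop_validation("data are not balanced: every genotype x environment x ",
                    "replicate combination must occur exactly once")
  invisible(obs)
}

#' Combined ANOVA for a balanced replicated multi-environment trial
#'
#' Full sum-of-squares decomposition for genotypes tested in randomized
#' complete blocks at several environments: environments,
#' replication-within-environment, genotypes, genotype x environment
#' interaction, and pooled error (by subtraction from the total).
#' Degrees of freedom follow the standard combined-RCBD layout:
#' `E-1`, `E(r-1)`, `G-1`, `(G-1)(E-1)`, and `E(G-1)(r-1)`.
#' F statistics for all treatment strata use the pooled error mean
#' square.
#'
#' @param obs balanced replicate-level data (`genotype`, `environment`,
#'   `replicate`, `yield`).
#' @return a `data.frame` of class `met_anova`.
#' @seealso [partition_ss()] for means-only input.
#' @export
met_anova <- function(obs) {
  check_balanced(obs)
  g_lev <- unique(obs$genotype); e_lev <- unique(obs$environment)
  G <- length(g_lev); E <- length(e_lev)
  R <- length(unique(obs$replicate))
  if (R < 2L) stop_validation("replicated ANOVA needs at least 2 replicates")
  mu <- mean(obs$yield)
  means <- cell_means(obs, g_lev, e_lev)
  em <- colMeans(means)
  # replicate-within-environment means over genotypes
  rep_means <- tapply(obs$yield, list(factor(obs$environment, e_lev),
                                      factor(obs$replicate)), mean)
  ss_rep_env <- G * sum((rep_means - em[rownames(rep_means)])^2)
  part <- partition_ss(means, R)
  ss_total <- sum((obs$yield - mu)^2)
  ss_err <- ss_total - sum(part$ss) - ss_rep_env
  ss_err <- max(ss_err, 0)               # guard tiny negative round-off
  df_err <- E * (G - 1) * (R - 1)
  ms_err <- ss_err / df_err

  tab <- rbind(
    met_anova_row("Environments", E - 1, part$ss[part$source == "Environments"],
                  pct = part$pct_explained[part$source == "Environments"]),
    met_anova_row("Replication (Environment)", E * (R - 1), ss_rep_env),
    met_anova_row("Genotypes", G - 1, part$ss[part$source == "Genotypes"],
                  pct = part$pct_explained[part$source == "Genotypes"]),
    met_anova_row("Genotype x Environment", (G - 1) * (E - 1),
                  part$ss[part$source == "Genotype x Environment"],
                  pct = part$pct_explained[part$source == "Genotype x Environment"]),
    met_anova_row("Residuals", df_err, ss_err),
    met_anova_row("Total", G * E * R - 1, ss_total))
  test_rows <- tab$source %in% c("Environments", "Replication (Environment)",
                                 "Genotypes", "Genotype x Environment")
  if (ms_err > 0) {
    tab$f[test_rows] <- tab$ms[test_rows] / ms_err
    tab$p[test_rows] <- stats::pf(tab$f[test_rows], tab$df[test_rows],
                                  df_err, lower.tail = FALSE)
  }
  structure(tab, class = c("met_anova", "data.frame"), reps = R,
            f_denominator = "pooled error mean square")
}

#' @export
print.met_anova <- function(x, ...) {
  cat("Combined multi-environment trial ANOVA (r =", attr(x, "reps"), ")\n")
  out <- data.frame(Source = x$source, Df = x$df,
                    SS = round(x$ss, 3), MS = round(x$ms, 3),
                    F = round(x$f, 2),
                    `Pr(>F)` = signif(x$p, 3),
                    `SS%` = round(x$pct_explained, 1),
                    check.names = FALSE)
  print(out, row.names = FALSE, na.print = "")
  cat("F denominator:", attr(x, "f_denominator"), "\n")
  invisible(x)
}

#' Per-environment least significant difference and coefficient of variation
#'
#' For each environment, fits the single-site RCBD decomposition
#' (genotype + block), pools the residual, and reports
#' \eqn{LSD = t_{1-\alpha/2, df} \sqrt{2 MS_{err} / r}} and
#' \eqn{CV = 100 \sqrt{MS_{err}} / \bar y}. Requires at least two
#' replicates (otherwise there are no error degrees of freedom).
#'
#' @param obs balanced replicate-level data; may hold one or several
#'   environments.
#' @param alpha significance level for the LSD (default 0.05).
#' @return data frame with one row per environment: `environment`,
#'   `reps`, `df_error`, `ms_error`, `lsd`, `cv`.
#' @export
lsd_cv <- function(obs, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  check_balanced(obs)
  envs <- unique(obs$environment)
  out <- lapply(envs, function(ev) {
    d <- obs[obs$environment == ev, ]
    G <- length(unique(d$genotype)); R <- length(unique(d$replicate))
    if (R < 2L)
      stop_validation("environment ", ev,
                      ": LSD/CV need >= 2 replicates (no error df with r = 1)")
    mu <- mean(d$yield)
    gm <- tapply(d$yield, factor(d$genotype), mean)
    bm <- tapply(d$yield, factor(d$replicate), mean)
    ss_tot <- sum((d$yield - mu)^2)
    ss_g <- R * sum((gm - mu)^2)
    ss_b <- G * sum((bm - mu)^2)
    df_err <- (G - 1) * (R - 1)
    ms_err <- max(ss_tot - ss_g - ss_b, 0) / df_err
    data.frame(environment = ev, reps = R, df_error = df_err,
               ms_error = ms_err,
               lsd = stats::qt(1 - alpha / 2, df_err) * sqrt(2 * ms_err / R),
               cv = 100 * sqrt(ms_err) / mu,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bartlett's test of variance homogeneity from variance summaries
#'
#' The classical pre-combined-ANOVA check that per-environment error
#' variances may be pooled. Operates on (variance, df) pairs so it can
#' be applied to the error lines of separately fitted site analyses:
#' \deqn{T = \left[N \ln s_p^2 - \sum_k n_k \ln s_k^2\right] / C}
#' with \eqn{N = \sum n_k}, pooled variance \eqn{s_p^2}, and the usual
#' correction \eqn{C = 1 + (\sum 1/n_k - 1/N) / (3(k-1))}; `T` is
#' referred to a chi-square with `k - 1` df.
#'
#' @param variances per-group error variances (all positive).
#' @param df error degrees of freedom per group (each >= 1).
#' @return list with `statistic`, `df`, `p_value`, `method`.
#' @seealso [met_homogeneity()] to run the check directly on
#'   replicate-level trial data.
#' @export
homogeneity_test <- function(variances, df) {
  k <- length(variances)
  if (k < 2L) stop_validation("need variances from at least 2 groups")
  if (length(df) != k) stop_validation("variances and df differ in length")
  if (any(df < 1)) stop_validation("every group needs df >= 1")
  if (any(variances <= 0))
    stop_validation("non-positive variance(s); Bartlett's statistic is undefined")
  N <- sum(df)
  sp2 <- sum(df * variances) / N
  C <- 1 + (sum(1 / df) - 1 / N) / (3 * (k - 1))
  stat <- (N * log(sp2) - sum(df * log(variances))) / C
  stat <- max(stat, 0)
  list(statistic = stat, df = k - 1L,
       p_value = stats::pchisq(stat, k - 1L, lower.tail = FALSE),
       method = "Bartlett")
}

#' Homogeneity of per-environment error variance from trial data
#'
#' Fits each environment's RCBD separately, extracts the error variances
#' and their df, and tests their homogeneity. `method = "bartlett"`
#' (default) applies [homogeneity_test()] to the variance summaries;
#' `method = "levene"` runs the more outlier-robust Levene procedure: a
#' one-way ANOVA of the absolute within-cell residuals on environment.
#'
#' @inheritParams lsd_cv
#' @param method `"bartlett"` or `"levene"`.
#' @return list with `statistic`, `df` (length 1 or 2), `p_value`,
#'   `method`.
#' @export
met_homogeneity <- function(obs, method = c("bartlett", "levene")) {
  method <- match.arg(method)
  site <- lsd_cv(obs)            # validates balance and r >= 2
  if (method == "bartlett")
    return(homogeneity_test(site$ms_error, site$df_error))
  # Levene: one-way ANOVA of |residual from the site RCBD fit| on environment
  res <- unlist(lapply(unique(obs$environment), function(ev) {
    d <- obs[obs$environment == ev, ]
    mu <- mean(d$yield)
    gm <- tapply(d$yield, factor(d$genotype), mean)
    bm <- tapply(d$yield, factor(d$replicate), mean)
    abs(d$yield - gm[d$genotype] - bm[as.character(d$replicate)] + mu)
  }))
  grp <- factor(rep(unique(obs$environment),
                    each = nrow(obs) / length(unique(obs$environment))))
  fit <- stats::aov(res ~ grp)
  a <- stats::anova(fit)
  list(statistic = a[["F value"]][1L],
       df = c(a$Df[1L], a$Df[2L]),
       p_value = a[["Pr(>F)"]][1L],
       method = "Levene (absolute residuals)")
}
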