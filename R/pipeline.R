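# end-to-end pipeline: data in, tables + figures + log out

#' Run the full stability analysis pipeline
#'
#' Executes, in order: cell-mean table, combined ANOVA, AMMI fit with
#' scores and the AMMI1 biplot, per-genotype stability table, and the
#' GGE analyses (diagnostics, which-won-where, biplots). Every numeric
#' table is written as tab-delimited text; figures are written as PDF
#' alongside their coordinate tables, so no result exists only as a
#' picture. A run log records the configuration and session.
#'
#' Exactly one data source must be given: `input` (long-format
#' replicate-level file), `means` together with `reps` (means matrix,
#' either a file path or a matrix), `fixture = TRUE` (the bundled
#' Oromia wheat trial), or `sim_spec` (a [met_sim_spec()] to simulate).
#' Replicate-level sources additionally produce the replicated ANOVA
#' with pooled error, per-environment LSD/CV, and the homogeneity
#' check.
#'
#' @param outdir output directory; created if missing.
#' @param input path to a long-format delimited file, or `NULL`.
#' @param means means matrix or path to one, or `NULL`.
#' @param reps replicate count behind a supplied means matrix.
#' @param fixture use the bundled trial.
#' @param sim_spec a [met_sim_spec()] for a synthetic run.
#' @param alpha significance level for LSD (default 0.05).
#' @param scaling GGE score scaling (see [gge()]).
#' @param write_plots set `FALSE` to skip PDF figures (tables are
#'   always written).
#' @return invisibly, a list with the fitted objects (`means`, `anova`,
#'   `ammi`, `stability`, `gge`, `diagnostics`, `sectors`, and for
#'   replicate-level sources `anova_replicated`, `lsd_cv`,
#'   `homogeneity`).
#' @export
run_met_pipeline <- function(outdir, input = NULL, means = NULL, reps = NULL,
                             fixture = FALSE, sim_spec = NULL, alpha = 0.05,
                             scaling = "symmetric", write_plots = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  n_sources <- sum(!is.null(input), !is.null(means), isTRUE(fixture),
                   !is.null(sim_spec))
  if (n_sources != 1L)
    stop_config("give exactly one of: input, means, fixture = TRUE, sim_spec")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(paste0("stage '", name, "': ", conditionMessage(e)),
                          class = c(class(e)[1L], "error")))
    })
  }
  tsv <- function(df, file)
    utils::write.table(df, file.path(outdir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  obs <- NULL
  if (!is.null(input)) {
    obs <- stage("read", read_met_long(input))
  } else if (!is.null(sim_spec)) {
    obs <- stage("simulate", simulate_met(sim_spec))$observations
    stage("simulate", write_met_long(obs, file.path(outdir, "simulated_long.tsv")))
  } else if (isTRUE(fixture)) {
    fx <- oromia_wheat(); means <- fx$means; reps <- fx$reps
  } else if (is.character(means)) {
    means <- stage("read", read_means_matrix(means))
  }
  if (!is.null(obs)) {
    means <- stage("cell_means", cell_means(obs))
    reps <- length(unique(obs$replicate))
  }
  if (is.null(reps))
    stop_config("a means matrix needs `reps` (replicates behind each cell mean)")
  check_means_matrix(means)

  res <- list(means = means, reps = reps)
  tsv(data.frame(genotype = rownames(means), means, check.names = FALSE),
      "means_matrix.tsv")
  mt <- rbind(data.frame(label = rownames(means), set = "genotype",
                         mean = rowMeans(means)),
              data.frame(label = colnames(means), set = "environment",
                         mean = colMeans(means)))
  tsv(mt, "marginal_means.tsv")

  if (!is.null(obs)) {
    res$anova_replicated <- stage("anova", met_anova(obs))
    tsv(res$anova_replicated, "anova_replicated.tsv")
    res$lsd_cv <- stage("anova", lsd_cv(obs, alpha))
    tsv(res$lsd_cv, "lsd_cv.tsv")
    res$homogeneity <- stage("anova", met_homogeneity(obs))
  }
  res$anova <- stage("anova", partition_ss(means, reps))
  tsv(res$anova, "anova_partition.tsv")

  res$ammi <- stage("ammi", ammi(means, reps))
  tsv(data.frame(genotype = rownames(res$ammi$gen_scores),
                 res$ammi$gen_scores, check.names = FALSE),
      "ammi_genotype_scores.tsv")
  tsv(data.frame(environment = rownames(res$ammi$env_scores),
                 res$ammi$env_scores, check.names = FALSE),
      "ammi_environment_scores.tsv")
  co <- ammi1_coordinates(res$ammi)
  tsv(rbind(cbind(co$genotypes, set = "genotype"),
            cbind(co$environments, set = "environment")),
      "ammi1_coordinates.tsv")

  res$stability <- stage("stability", stability_table(res$ammi))
  tsv(res$stability, "stability_table.tsv")

  res$gge <- stage("gge", gge(means, scaling = scaling))
  tsv(data.frame(label = c(rownames(res$gge$gen_scores),
                           rownames(res$gge$env_scores)),
                 set = rep(c("genotype", "environment"),
                           c(nrow(res$gge$gen_scores),
                             nrow(res$gge$env_scores))),
                 rbind(res$gge$gen_scores[, 1:2],
                       res$gge$env_scores[, 1:2])),
      "gge_scores.tsv")
  res$diagnostics <- stage("gge", environment_diagnostics(res$gge))
  tsv(res$diagnostics, "gge_environment_diagnostics.tsv")
  res$sectors <- stage("gge", which_won_where(res$gge))
  tsv(data.frame(environment = names(res$sectors$env_sector),
                 sector = unname(res$sectors$env_sector),
                 winner = unname(res$sectors$env_winner)),
      "gge_sectors.tsv")

  if (isTRUE(write_plots)) {
    save_pdf <- function(p, file) {
      grDevices::pdf(file.path(outdir, file), width = 7, height = 6)
      on.exit(grDevices::dev.off())
      print(p)
    }
    stage("plots", {
      save_pdf(ammi1_biplot(res$ammi), "ammi1_biplot.pdf")
      save_pdf(gge_biplot(res$gge, "scores"), "gge_biplot.pdf")
      save_pdf(gge_biplot(res$gge, "discrimination"),
               "gge_discrimination.pdf")
      save_pdf(gge_biplot(res$gge, "which-won-where"),
               "gge_which_won_where.pdf")
    })
  }

  log_lines <- c(
    paste("metstab", as.character(utils::packageVersion("metstab"))),
    paste("R", getRversion()),
    paste("source:",
          if (!is.null(input)) paste("long-format file", input)
          else if (!is.null(sim_spec)) paste("simulation, seed", sim_spec$seed)
          else if (isTRUE(fixture)) "bundled Oromia wheat trial"
          else "means matrix"),
    paste("genotypes:", nrow(means), " environments:", ncol(means),
          " reps:", reps),
    paste("alpha:", alpha, " gge scaling:", scaling))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(res)
}
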