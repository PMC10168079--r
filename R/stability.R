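# AMMI stability value, yield/stability ranks, genotype selection index

#' AMMI stability value
#'
#' Weighted distance of a genotype's first two interaction scores from
#' the origin:
#' \deqn{ASV = \sqrt{(w \cdot IPCA1)^2 + IPCA2^2}, \quad
#'       w = SS_{IPCA1} / SS_{IPCA2}.}
#' The first axis carries more of the interaction SS, so its score is
#' up-weighted by the SS ratio. Small ASV means a stable genotype.
#' The value is invariant to sign flips of either score.
#'
#' @param ipca1,ipca2 numeric vectors of genotype scores on the first
#'   two interaction axes.
#' @param ss_ipca1,ss_ipca2 interaction sums of squares of the two axes
#'   (any common scale; only their ratio enters).
#' @return non-negative numeric vector.
#' @export
#' @examples
#' asv(3, 4, 1, 1)   # weight 1: plain Euclidean norm, 5
asv <- function(ipca1, ipca2, ss_ipca1, ss_ipca2) {
  if (ss_ipca2 <= 0)
    stop_validation("SS of IPCA2 must be positive; the decomposition is ",
                    "degenerate (fewer than 2 informative axes)")
  w <- ss_ipca1 / ss_ipca2
  sqrt((w * ipca1)^2 + ipca2^2)
}

#' Rank genotypes by mean yield (rYSI)
#'
#' Highest mean yield receives rank 1; ties share the average rank.
#'
#' @param mean_yields named numeric vector of genotype means.
#' @return numeric vector of ranks, same names.
#' @export
rank_yield <- function(mean_yields) rank(-mean_yields, ties.method = "average")

#' Rank genotypes by AMMI stability value (rASV)
#'
#' Smallest ASV (most stable) receives rank 1; ties share the average
#' rank.
#'
#' @param asvs named numeric vector of ASVs.
#' @return numeric vector of ranks, same names.
#' @export
rank_asv <- function(asvs) rank(asvs, ties.method = "average")

#' Genotype selection index
#'
#' \eqn{GSI = rASV + rYSI}: the rank sum combining stability and yield
#' into one criterion; lower is better (simultaneously stable and
#' high-yielding). Both rank vectors must cover the same genotypes.
#'
#' @param r_asv,r_ysi rank vectors from [rank_asv()] and
#'   [rank_yield()], named by genotype.
#' @return numeric vector of rank sums, named by genotype.
#' @export
gsi <- function(r_asv, r_ysi) {
  if (is.null(names(r_asv)) || is.null(names(r_ysi)) ||
      !setequal(names(r_asv), names(r_ysi)) ||
      length(r_asv) != length(r_ysi))
    stop_validation("rASV and rYSI must be named and cover the same genotype set")
  r_asv + r_ysi[names(r_asv)]
}

#' Stability report for all genotypes
#'
#' Assembles the per-genotype stability table from an AMMI fit: mean
#' yield, first two interaction scores, ASV (weight
#' \eqn{w = \lambda_1^2 / \lambda_2^2} from the fitted decomposition),
#' ranks, and the genotype selection index. Rows are sorted by GSI
#' ascending (most stable and high-yielding first), ties broken by mean
#' yield descending.
#'
#' @param fit an [ammi()] fit with at least 2 informative axes.
#' @return a `data.frame` of class `stability_table` with columns
#'   `genotype`, `mean_yield`, `asv`, `r_asv`, `r_ysi`, `gsi`, `ipca1`,
#'   `ipca2`.
#' @export
#' @examples
#' trial <- oromia_wheat()
#' stability_table(ammi(trial$means, trial$reps))
stability_table <- function(fit) {
  stopifnot(inherits(fit, "ammi_fit"))
  if (length(fit$singular_values) < 2L ||
      fit$singular_values[2L] < 1e-9 * fit$singular_values[1L])
    stop_validation("stability table needs at least 2 informative interaction axes")
  means <- fit$mu + fit$g_effects
  a <- asv(fit$gen_scores[, 1L], fit$gen_scores[, 2L],
           fit$ss_ipca[1L], fit$ss_ipca[2L])
  r_a <- rank_asv(a); r_y <- rank_yield(means)
  out <- data.frame(genotype = names(fit$g_effects),
                    mean_yield = unname(means), asv = unname(a),
                    r_asv = unname(r_a), r_ysi = unname(r_y),
                    gsi = unname(gsi(r_a, r_y)),
                    ipca1 = unname(fit$gen_scores[, 1L]),
                    ipca2 = unname(fit$gen_scores[, 2L]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gsi, -out$mean_yield), ]
  rownames(out) <- NULL
  structure(out, class = c("stability_table", "data.frame"),
            asv_weight = fit$ss_ipca[1L] / fit$ss_ipca[2L])
}

#' @export
print.stability_table <- function(x, ...) {
  cat("Genotype stability (ASV weight w =",
      round(attr(x, "asv_weight"), 3), "; low GSI = stable & high-yielding)\n")
  out <- data.frame(Genotype = x$genotype,
                    Mean = round(x$mean_yield, 2),
                    ASV = round(x$asv, 4),
                    rASV = x$r_asv, rYSI = x$r_ysi, GSI = x$gsi,
                    IPCA1 = round(x$ipca1, 4), IPCA2 = round(x$ipca2, 4))
  print(out, row.names = FALSE)
  invisible(x)
}
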