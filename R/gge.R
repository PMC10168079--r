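# GGE: genotype main effect + genotype-by-environment interaction,
# obtained by centring the means matrix on environments only, and the
# biplot geometry built on its first two principal components

#' Fit the GGE decomposition
#'
#' Singular value decomposition of the environment-centred matrix
#' \eqn{Y_{ij} - \bar e_j}, which retains genotype main effects plus
#' interaction (the two sources relevant to genotype evaluation) while
#' removing the environment main effect. Scores are returned under the
#' requested singular-value partitioning:
#' `"symmetric"` (both sides carry \eqn{\sqrt{\lambda}}; default),
#' `"genotype"` (genotype-metric preserved: genotypes carry
#' \eqn{\lambda}), or `"environment"` (environment-metric preserved).
#' The same sign convention as [ammi()] is applied (largest-magnitude
#' environment loading positive per axis).
#'
#' @param means genotype x environment means matrix.
#' @param scaling singular-value partitioning for the reported scores.
#' @param scale_env if `TRUE`, each centred column is also divided by
#'   its standard deviation before decomposition (data standardization);
#'   default `FALSE`, i.e. plain environment-centring.
#' @return an object of class `gge_fit`: list with `centered`,
#'   `singular_values`, `gen_scores`, `env_scores` (all axes), `pct`,
#'   `scaling`, `means`.
#' @export
#' @examples
#' g <- gge(oromia_wheat()$means)
#' g$pct[1:2]
gge <- function(means, scaling = c("symmetric", "genotype", "environment"),
                scale_env = FALSE) {
  scaling <- match.arg(scaling)
  check_means_matrix(means)
  z <- sweep(means, 2L, colMeans(means))
  if (scale_env) {
    s <- apply(z, 2L, stats::sd)
    if (any(s == 0))
      stop_validation("cannot standardize: environment(s) with zero variance: ",
                      paste(colnames(means)[s == 0], collapse = ", "))
    z <- sweep(z, 2L, s, "/")
  }
  M <- min(nrow(z) - 1L, ncol(z))
  s <- svd(z, nu = M, nv = M)
  d <- s$d[seq_len(M)]
  u <- s$u; v <- s$v
  for (k in seq_len(M)) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) { v[, k] <- -v[, k]; u[, k] <- -u[, k] }
  }
  a <- switch(scaling, symmetric = 0.5, genotype = 1, environment = 0)
  gen_scores <- sweep(u, 2L, d^a, "*")
  env_scores <- sweep(v, 2L, d^(1 - a), "*")
  dimnames(gen_scores) <- list(rownames(means), paste0("PC", seq_len(M)))
  dimnames(env_scores) <- list(colnames(means), paste0("PC", seq_len(M)))
  structure(list(centered = z, singular_values = d,
                 gen_scores = gen_scores, env_scores = env_scores,
                 pct = 100 * d^2 / sum(s$d^2),
                 scaling = scaling, scale_env = scale_env, means = means),
            class = "gge_fit")
}

#' @export
print.gge_fit <- function(x, ...) {
  cat("GGE fit (", x$scaling, " scaling", if (x$scale_env) ", standardized",
      "): ", nrow(x$gen_scores), " genotypes x ", nrow(x$env_scores),
      " environments\n", sep = "")
  cat("PC1 ", round(x$pct[1L], 1), "%, PC2 ", round(x$pct[2L], 1),
      "% of G + GxE variation\n", sep = "")
  invisible(x)
}

#' Rank-k reconstruction of the environment-centred matrix
#'
#' @param fit a [gge()] fit.
#' @param n_axes number of axes used (default 2, the biplot rank).
#' @return G x E matrix approximating `fit$centered`.
#' @export
gge_reconstruction <- function(fit, n_axes = 2L) {
  stopifnot(inherits(fit, "gge_fit"))
  k <- seq_len(n_axes)
  fit$gen_scores[, k, drop = FALSE] %*% t(fit$env_scores[, k, drop = FALSE])
}

#' Environment discrimination and representativeness diagnostics
#'
#' In the 2-component GGE biplot, the length of an environment's score
#' vector measures its discriminating ability (longer = better at
#' separating genotypes), and its angle with the Average-Environment
#' Axis (AEA — the direction of the mean environment score vector)
#' measures representativeness (smaller = more representative of the
#' whole set of environments).
#'
#' @param fit a [gge()] fit.
#' @return data frame with one row per environment: `environment`,
#'   `pc1`, `pc2`, `vector_length`, `angle_aea` (radians, in
#'   \eqn{[0, \pi]}), `rank_discriminating` (longest = 1),
#'   `rank_representative` (smallest angle = 1).
#' @export
environment_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "gge_fit"))
  ev <- fit$env_scores[, 1:2, drop = FALSE]
  aea <- colMeans(ev)
  n_aea <- sqrt(sum(aea^2))
  if (n_aea < 1e-12)
    stop_validation("degenerate geometry: the average environment vector has zero length")
  aea <- aea / n_aea
  len <- sqrt(rowSums(ev^2))
  cosang <- as.vector(ev %*% aea) / len
  ang <- acos(pmin(1, pmax(-1, cosang)))
  data.frame(environment = rownames(ev), pc1 = ev[, 1L], pc2 = ev[, 2L],
             vector_length = len, angle_aea = ang,
             rank_discriminating = rank(-len, ties.method = "average"),
             rank_representative = rank(ang, ties.method = "average"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Which-won-where sector partition
#'
#' The classical mega-environment construction on the 2-component GGE
#' biplot: the convex hull of the genotype markers is drawn, and rays
#' from the origin perpendicular to each hull edge partition the plane
#' into sectors, one per hull vertex. Every environment falls in
#' exactly one sector, and the vertex genotype of that sector is the
#' winner (highest rank-2 reconstructed value) in all its environments.
#' An environment lying exactly on a ray is assigned to the sector
#' counterclockwise of the ray.
#'
#' @param fit a [gge()] fit with at least 3 non-collinear genotypes.
#' @return an object of class `sector_partition`: list with
#'   \describe{
#'     \item{hull_vertices}{genotype labels on the hull, counterclockwise.}
#'     \item{rays}{data frame of sector-boundary ray angles (radians),
#'       one per hull edge.}
#'     \item{env_sector}{named integer: sector index per environment.}
#'     \item{sector_winner}{character: winning genotype per sector index.}
#'     \item{env_winner}{named character: winner per environment.}
#'     \item{gen_points, env_points}{the 2-D score coordinates used.}
#'   }
#' @export
#' @examples
#' which_won_where(gge(oromia_wheat()$means))
which_won_where <- function(fit) {
  stopifnot(inherits(fit, "gge_fit"))
  P <- fit$gen_scores[, 1:2, drop = FALSE]
  EV <- fit$env_scores[, 1:2, drop = FALSE]
  if (nrow(P) < 3L)
    stop_validation("which-won-where needs at least 3 genotypes")
  d <- fit$singular_values
  if (length(d) < 2L || d[2L] < 1e-9 * d[1L])
    stop_validation("degenerate geometry: genotype markers are collinear in PC space")

  hull <- grDevices::chull(P)                  # vertex subscripts
  theta <- atan2(P[hull, 2L], P[hull, 1L]) %% (2 * pi)
  hull <- hull[order(theta)]                   # counterclockwise about origin
  m <- length(hull)
  V <- P[hull, , drop = FALSE]

  # outward normal of each edge (k -> k+1); its angle is the boundary ray
  nxt <- c(seq_len(m)[-1L], 1L)
  ray_angle <- numeric(m)
  for (k in seq_len(m)) {
    edge <- V[nxt[k], ] - V[k, ]
    n1 <- c(edge[2L], -edge[1L])
    if (sum(n1 * V[k, ]) < 0) n1 <- -n1       # point away from the origin
    ray_angle[k] <- atan2(n1[2L], n1[1L]) %% (2 * pi)
  }

  # sector of vertex k spans [ray_{k-1}, ray_k); membership by the ray
  # most recently passed moving counterclockwise to the environment
  psi <- atan2(EV[, 2L], EV[, 1L]) %% (2 * pi)
  env_sector <- vapply(psi, function(a) {
    gap <- (a - ray_angle) %% (2 * pi)
    j <- which.min(gap)                        # last ray at or before `a`
    if (j == m) 1L else j + 1L                 # its CCW vertex
  }, integer(1))
  names(env_sector) <- rownames(EV)

  winners <- rownames(V)
  structure(list(hull_vertices = rownames(V),
                 rays = data.frame(after_vertex = rownames(V),
                                   angle = ray_angle),
                 env_sector = env_sector,
                 sector_winner = winners,
                 env_winner = stats::setNames(winners[env_sector],
                                              rownames(EV)),
                 gen_points = P, env_points = EV),
            class = "sector_partition")
}

#' @export
print.sector_partition <- function(x, ...) {
  cat("Which-won-where partition\n")
  cat("Hull vertices (CCW):", paste(x$hull_vertices, collapse = ", "), "\n")
  occ <- sort(unique(x$env_sector))
  for (s in occ) {
    envs <- names(x$env_sector)[x$env_sector == s]
    cat(sprintf("  sector %d (winner %s): %s\n", s, x$sector_winner[s],
                paste(envs, collapse = ", ")))
  }
  invisible(x)
}
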