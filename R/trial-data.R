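# readers/writers and cell-mean aggregation for replicate-level trial data

#' Read replicate-level trial data from delimited text
#'
#' Reads long-format yield records (one row per genotype x environment x
#' replicate plot) from a comma- or tab-delimited file. The delimiter is
#' taken from the file extension (`.csv` is comma, anything else tab)
#' unless `sep` is given. Column names are configurable through
#' `columns`; the returned data frame always uses the canonical names
#' `genotype`, `environment`, `replicate`, `yield`.
#'
#' Labels are matched exactly (case-sensitive) after stripping leading
#' and trailing whitespace. Yields are in tonnes per hectare and must be
#' non-negative; `(genotype, environment, replicate)` triples must be
#' unique.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field delimiter; `NULL` (default) infers it from the
#'   file extension.
#' @param columns named character vector mapping the canonical names
#'   `genotype`, `environment`, `replicate`, `yield` to the column names
#'   used in the file.
#' @param allow_negative if `TRUE`, negative yields are accepted (useful
#'   for reading back simulated data where Gaussian noise may undershoot
#'   zero); real trial data should keep the default `FALSE`.
#' @return a `data.frame` of class `met_trial` with columns `genotype`,
#'   `environment` (character), `replicate` (integer), `yield` (numeric).
#' @seealso [write_met_long()], [cell_means()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("genotype,environment,replicate,yield",
#'              "A,E1,1,4.0", "A,E1,2,4.4"), f)
#' read_met_long(f)
read_met_long <- function(path, sep = NULL,
                          columns = c(genotype = "genotype",
                                      environment = "environment",
                                      replicate = "replicate",
                                      yield = "yield"),
                          allow_negative = FALSE) {
  if (!file.exists(path))
    stop_validation("input file not found: ", path)
  canonical <- c("genotype", "environment", "replicate", "yield")
  cols <- columns[canonical]
  if (anyNA(cols) || any(!nzchar(cols)))
    stop_config("`columns` must name all of: ",
                paste(canonical[is.na(cols) | !nzchar(cols)], collapse = ", "))
  raw <- utils::read.table(path, header = TRUE, sep = infer_sep(path, sep),
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, quote = "\"", comment.char = "")
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols))
    stop_config("column(s) not found in ", path, ": ",
                paste(missing_cols, collapse = ", "),
                " (available: ", paste(names(raw), collapse = ", "), ")")
  obs <- data.frame(genotype    = strip_ws(raw[[cols[["genotype"]]]]),
                    environment = strip_ws(raw[[cols[["environment"]]]]),
                    stringsAsFactors = FALSE)

  rep_chr <- strip_ws(raw[[cols[["replicate"]]]])
  rep_num <- suppressWarnings(as.numeric(rep_chr))
  bad <- which(is.na(rep_num) | rep_num < 1 | rep_num != round(rep_num))
  if (length(bad))
    stop_validation("replicate must be a positive integer; offending line(s): ",
                    paste(bad + 1L, collapse = ", "))
  obs$replicate <- as.integer(rep_num)

  yld_chr <- strip_ws(raw[[cols[["yield"]]]])
  yld <- suppressWarnings(as.numeric(yld_chr))
  bad <- which(is.na(yld))
  if (length(bad))
    stop_validation("non-numeric yield value(s) ",
                    paste(sprintf("'%s'", yld_chr[bad]), collapse = ", "),
                    " at line(s): ", paste(bad + 1L, collapse = ", "))
  if (!allow_negative && any(yld < 0))
    stop_validation("negative yield at line(s): ",
                    paste(which(yld < 0) + 1L, collapse = ", "))
  obs$yield <- yld

  key <- paste(obs$genotype, obs$environment, obs$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- obs[duplicated(key), c("genotype", "environment", "replicate")]
    stop_validation("duplicate (genotype, environment, replicate) record(s): ",
                    paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "))
  }
  class(obs) <- c("met_trial", "data.frame")
  obs
}

#' Write replicate-level trial data as delimited text
#'
#' Inverse of [read_met_long()]: writes the canonical four columns with a
#' header. Reading the file back reproduces every record.
#'
#' @param obs data frame with columns `genotype`, `environment`,
#'   `replicate`, `yield`.
#' @param path output path; extension decides the delimiter unless `sep`
#'   is given.
#' @param sep field delimiter; `NULL` infers from the extension.
#' @return `path`, invisibly.
#' @export
write_met_long <- function(obs, path, sep = NULL) {
  utils::write.table(obs[, c("genotype", "environment", "replicate", "yield")],
                     path, sep = infer_sep(path, sep), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Aggregate replicate-level records to a genotype x environment means matrix
#'
#' Averages plot yields over replicates within each genotype x
#' environment cell. Every cell must contain at least one observation:
#' the downstream decompositions require a complete two-way table and no
#' imputation is attempted.
#'
#' @param obs data frame with columns `genotype`, `environment`,
#'   `replicate`, `yield` (e.g. from [read_met_long()]).
#' @param genotypes,environments optional character vectors fixing the
#'   row/column order; default is first-appearance order in `obs`.
#' @return numeric G x E matrix of cell means with genotype row names
#'   and environment column names.
#' @export
cell_means <- function(obs, genotypes = NULL, environments = NULL) {
  g_lev <- genotypes %||% unique(obs$genotype)
  e_lev <- environments %||% unique(obs$environment)
  if (!all(obs$genotype %in% g_lev) || !all(obs$environment %in% e_lev))
    stop_validation("`genotypes`/`environments` do not cover all labels present in the data")
  gf <- factor(obs$genotype, levels = g_lev)
  ef <- factor(obs$environment, levels = e_lev)
  counts <- table(gf, ef)
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)
    stop_validation("empty genotype x environment cell(s): ",
                    paste(g_lev[empty[, 1]], e_lev[empty[, 2]],
                          sep = "/", collapse = ", "))
  }
  m <- tapply(obs$yield, list(gf, ef), mean)
  m <- matrix(m, nrow = length(g_lev), ncol = length(e_lev),
              dimnames = list(g_lev, e_lev))
  check_means_matrix(m)
  m
}

#' Read a genotype x environment means matrix from delimited text
#'
#' Expects genotype labels in the first column and environment labels in
#' the header row. Because replicate information is lost in a means
#' matrix, the replicate count must be supplied separately to any
#' function that reports sums of squares on the replicated scale.
#'
#' @inheritParams read_met_long
#' @return numeric matrix with genotype row names and environment column
#'   names.
#' @export
read_means_matrix <- function(path, sep = NULL) {
  if (!file.exists(path))
    stop_validation("input file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = infer_sep(path, sep),
                           check.names = FALSE, strip.white = TRUE,
                           quote = "\"", comment.char = "")
  labels <- strip_ws(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop_validation("non-numeric cell(s) in means matrix ", path)
  rownames(m) <- labels
  colnames(m) <- strip_ws(colnames(m))
  check_means_matrix(m)
  m
}

#' Write a means matrix as delimited text
#'
#' @param means numeric matrix with genotype row names and environment
#'   column names.
#' @inheritParams write_met_long
#' @return `path`, invisibly.
#' @export
write_means_matrix <- function(means, path, sep = NULL) {
  check_means_matrix(means)
  df <- data.frame(genotype = rownames(means), means,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = infer_sep(path, sep), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
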