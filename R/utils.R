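# internal helpers shared across modules

# validation failures get their own condition class so callers (and the
# command-line wrapper) can distinguish bad input from computation errors
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("metstab_validation_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("metstab_config_error", "error")))
}

# a means matrix is a plain numeric G x E matrix with unique dimnames and
# no missing cells; every decomposition in the package consumes one
check_means_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_validation("means matrix must be a numeric matrix")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop_validation("means matrix needs at least 2 genotypes and 2 environments, got ",
                    nrow(x), " x ", ncol(x))
  if (anyNA(x))
    stop_validation("means matrix has missing cells; AMMI/GGE require a complete two-way table")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_validation("means matrix must carry genotype row names and environment column names")
  if (anyDuplicated(rownames(x)))
    stop_validation("duplicate genotype labels: ",
                    paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop_validation("duplicate environment labels: ",
                    paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  invisible(x)
}

# delimiter from file extension unless given explicitly
infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

strip_ws <- function(x) trimws(as.character(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
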