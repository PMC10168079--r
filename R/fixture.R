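# the bundled irrigated lowland wheat trial

#' Oromia irrigated lowland bread wheat trial (2021)
#'
#' Cell-mean grain yields (t/ha) of 12 released bread wheat varieties
#' grown under irrigation at 9 lowland locations of the Oromia region of
#' Ethiopia in the 2021 off-season, in a randomized complete block
#' design with 2 replications. Only the 12 x 9 matrix of means over the
#' two replicates is available; the replicate-level plot data were not
#' published, so per-environment LSD and CV cannot be recomputed from
#' this object (use [simulate_met()] data to exercise those).
#'
#' The grand mean of the 108 cells is 3.14 t/ha; cell values range from
#' 1.40 (Ogolcho at Girja) to 6.55 (Ardi at Daro Lebu).
#'
#' @return a list with components
#'   \describe{
#'     \item{means}{12 x 9 numeric matrix, varieties in rows and
#'       locations in columns.}
#'     \item{reps}{number of replicates behind each cell mean (2).}
#'   }
#' @seealso [oromia_wheat_aliases] for variant spellings of the labels.
#' @export
#' @examples
#' trial <- oromia_wheat()
#' round(mean(trial$means), 2)
oromia_wheat <- function() {
  path <- system.file("extdata", "oromia_wheat_means.tsv",
                      package = "metstab", mustWork = TRUE)
  means <- read_means_matrix(path)
  stopifnot(nrow(means) == 12L, ncol(means) == 9L)
  list(means = means, reps = 2L)
}

#' Label aliases for the Oromia wheat trial
#'
#' The source report spells several labels inconsistently ("Daro Labu" /
#' "Daro Lebu", "Ga'ambo-2" / "Ga 'ambo 2", a stray "ETBW 9573",
#' "Sawena"). This named vector maps each variant spelling to the
#' canonical label used by [oromia_wheat()]; apply it with
#' [normalize_labels()] when merging external records.
#'
#' @format named character vector: names are variant spellings, values
#'   the canonical labels.
#' @export
oromia_wheat_aliases <- c(
  "Daro Labu"  = "Daro Lebu",
  "Daro labu"  = "Daro Lebu",
  "Daro lebu"  = "Daro Lebu",
  "Sawena"     = "Sewena",
  "Ga'ambo-2"  = "Ga'ambo 2",
  "Ga 'ambo 2" = "Ga'ambo 2",
  "Amibara-2"  = "Amibara 2",
  "ETBW 9573"  = "ETBW 9578",
  "ETBW9578"   = "ETBW 9578"
)

#' Canonicalize labels through an alias table
#'
#' Replaces each label that appears in `aliases` (after whitespace
#' stripping) by its canonical form; all other labels pass through
#' unchanged. Matching is exact and case-sensitive by design — silent
#' fuzzy matching would hide data errors.
#'
#' @param x character vector of labels.
#' @param aliases named character vector mapping variants to canonical
#'   labels, e.g. [oromia_wheat_aliases].
#' @return character vector of the same length.
#' @export
normalize_labels <- function(x, aliases = oromia_wheat_aliases) {
  x <- strip_ws(x)
  hit <- x %in% names(aliases)
  x[hit] <- unname(aliases[x[hit]])
  x
}
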