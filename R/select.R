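#' Small-study selection filter (publication-bias proxy)
#'
#' Emulates selective publication by dropping the studies ranked lowest on
#' both size and true exposure effect.  Each study receives an ascending
#' rank on `n_patients` and an ascending rank on its true exposure slope
#' `beta1_true`; the composite score is the sum of the two ranks, and the
#' `floor(fraction * k)` studies with the smallest composite are removed
#' (ties broken towards the smaller study id).  Because the filter uses
#' the generating truth it is deterministic given the dataset — it acts at
#' generation time, before any model sees the data.  Survivors are
#' re-indexed `1..k'`; the original ids of dropped and surviving studies
#' are retained in attributes.
#'
#' @param dataset An `ipd_dataset` carrying its per-study truth table.
#' @param fraction Fraction of studies to drop, in `[0, 1)`.  `0` returns
#'   the dataset unchanged.
#' @return The filtered `ipd_dataset`, with attributes `dropped_studies`
#'   (original ids removed) and, in the truth table, `orig_study_id`.
#' @export
apply_small_study_filter <- function(dataset, fraction) {
  stopifnot(inherits(dataset, "ipd_dataset"))
  if (fraction < 0 || fraction >= 1)
    stop("`fraction` must lie in [0, 1)", call. = FALSE)
  if (fraction == 0) return(dataset)
  st <- study_truth(dataset)
  k <- nrow(st)
  n_drop <- floor(fraction * k)
  if (n_drop < 1) return(dataset)
  if (k - n_drop < 2)
    stop("filter would leave fewer than 2 studies", call. = FALSE)
  composite <- rank(st$n_patients) + rank(st$beta1_true)
  drop_ids <- st$study_id[order(composite, st$study_id)][seq_len(n_drop)]
  keep <- !(st$study_id %in% drop_ids)
  st_new <- st[keep, , drop = FALSE]
  st_new$orig_study_id <- st_new$study_id
  st_new$study_id <- seq_len(nrow(st_new))
  rows <- dataset[dataset$study_id %in% st$study_id[keep], , drop = FALSE]
  rows$study_id <- match(rows$study_id, st_new$orig_study_id)
  rownames(rows) <- NULL
  rownames(st_new) <- NULL
  structure(rows, scenario = attr(dataset, "scenario"), studies = st_new,
            dropped_studies = drop_ids,
            class = c("ipd_dataset", "data.frame"))
}
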