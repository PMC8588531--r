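# Best-band-set selection by rejection: a handful of random candidate
# band sets is scored on a held-out selection split and the worst are
# discarded. The point is not to find a near-optimal set -- rankings
# transfer weakly between datasets in the low-RMSE plateau -- but the few
# very bad sets (e.g. all bands clustered in a narrow visible range) are
# rejected reliably.

#' Score candidate band sets on a selection dataset
#'
#' Each candidate is used to measure and reconstruct every pixel of the
#' selection split with the given method context; its score is the median
#' per-pixel RMSE. Scores are returned ascending, ties broken by the
#' band sets' lexicographic order.
#'
#' @param selection Spectra tibble of the band-selection split.
#' @param candidates Non-empty list of band sets.
#' @param context A `ksvd_dictionary` or `updm_bases`.
#' @param ... Passed to the reconstruction routine.
#' @return Tibble with `rank`, `median_rmse`, `method`, `bands`
#'   (list-column of integer vectors), sorted by score.
#' @export
score_band_sets <- function(selection, candidates, context, ...) {
  if (length(candidates) == 0) stop("no candidate band sets",
                                    call. = FALSE)
  sm <- as_spectra_matrix(selection)
  if (length(sm$ids) == 0) stop("empty selection set", call. = FALSE)
  scores <- vapply(candidates, function(bs) {
    est <- reconstruct_with(context, sm$values, bs, ...)
    stats::median(rmse_cols(est, sm$values))
  }, numeric(1))
  lex <- vapply(candidates, function(b) {
    paste(sprintf("%04d", as.integer(b)), collapse = ",")
  }, character(1))
  ord <- order(scores, lex)
  tibble::tibble(
    rank = seq_along(ord),
    median_rmse = scores[ord],
    method = method_tag(context),
    bands = lapply(candidates[ord], as.integer)
  )
}

#' Keep the best-scoring band sets
#'
#' @param scores Score tibble from [score_band_sets()].
#' @param keep Number of sets to keep (default 3).
#' @param n_bands Grid length, to re-attach the band-set metadata.
#' @return List of the `keep` lowest-RMSE band sets, best first.
#' @export
select_best <- function(scores, keep = 3, n_bands = NULL) {
  stopifnot(keep >= 1)
  if (keep > nrow(scores)) {
    warning("keep exceeds the number of scored sets; returning all",
            call. = FALSE)
    keep <- nrow(scores)
  }
  lapply(scores$bands[seq_len(keep)], function(b) {
    band_set(b, n_bands %||% max(b))
  })
}

#' Draw, score and keep best band sets in one step
#'
#' @param selection Spectra tibble of the band-selection split.
#' @param context Method context.
#' @param m Bands per set.
#' @param n_candidates Number of random candidates (default 20).
#' @param keep Sets kept (default 3).
#' @param seed Master seed for the candidate draws.
#' @param ... Passed to [score_band_sets()].
#' @return List with `scores` (tibble) and `best` (list of band sets).
#' @export
best_band_sets <- function(selection, context, m, n_candidates = 20,
                           keep = 3, seed = 1, ...) {
  n <- length(spectra_grid(selection))
  seeds <- derive_seeds(seed, "bbs-candidates", n_candidates)
  candidates <- lapply(seeds, function(s) random_band_set(n, m, s))
  scores <- score_band_sets(selection, candidates, context, ...)
  list(scores = scores, best = select_best(scores, keep, n_bands = n))
}
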