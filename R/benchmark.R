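#' Overlap score of a reference complex against reported sets
#'
#' The maximum, over all reported co-complex sets, of the number of
#' reference subunits shared, divided by the reference size.
#'
#' @param reference character vector of reference subunits (non-empty).
#' @param reported list of reported subunit sets.
#' @return Proportion in [0, 1].
#' @export
overlap_score <- function(reference, reported) {
  if (length(reference) == 0L) stop("empty reference complex")
  if (length(reported) == 0L) return(0)
  max(vapply(reported, function(s)
    length(intersect(reference, s)), 0L)) / length(reference)
}

#' Count recovered reference complexes
#'
#' A reference complex counts as recovered when its [overlap_score()]
#' reaches `min_overlap`. Whether the comparison is `>=` (default) or
#' strict `>` is configurable.
#'
#' @param references list of reference subunit sets.
#' @param reported list of reported subunit sets.
#' @param min_overlap recovery threshold (default 0.5).
#' @param strict use strict `>` instead of `>=`.
#' @return Integer count.
#' @export
count_recovered <- function(references, reported, min_overlap = 0.5,
                            strict = FALSE) {
  sc <- vapply(references, overlap_score, 0, reported = reported)
  if (strict) sum(sc > min_overlap) else sum(sc >= min_overlap)
}

#' Performance against a manual annotation
#'
#' Compares automatically detected queries with a manually curated
#' classification of each query into high-quality positive, low-quality
#' positive, or negative. Reports
#' `TPR_all = TP_all / (P_high + P_low)`,
#' `TPR_high = TP_high / P_high`, and
#' `FDR_manual = (T_all - TP_all) / T_all`, where `T_all` is the number
#' of auto-detected queries and `TP_all` / `TP_high` are the detected
#' queries annotated as any positive / high-quality positive. Empty
#' denominators give `NA`, not 0.
#'
#' @param auto_detected character vector of query ids with a detected
#'   feature.
#' @param manual `data.frame(query_id, class)` with class in
#'   `high`, `low`, `negative`; must cover every auto-detected query.
#' @return List with the counts and the three performance measures.
#' @export
manual_benchmark <- function(auto_detected, manual) {
  manual <- as.data.frame(manual)
  missing <- setdiff(auto_detected, manual$query_id)
  if (length(missing))
    stop("manual annotation missing for: ", paste(missing, collapse = ", "))
  cls <- setNames(manual$class, manual$query_id)
  if (!all(cls %in% c("high", "low", "negative")))
    stop("manual classes must be high, low, or negative")
  P_high <- sum(cls == "high"); P_low <- sum(cls == "low")
  T_all <- length(auto_detected)
  det_cls <- cls[auto_detected]
  TP_all <- sum(det_cls %in% c("high", "low"))
  TP_high <- sum(det_cls == "high")
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(T_all = T_all, TP_all = TP_all, TP_high = TP_high,
       P_high = P_high, P_low = P_low,
       TPR_all = safe_div(TP_all, P_high + P_low),
       TPR_high = safe_div(TP_high, P_high),
       FDR_manual = safe_div(T_all - TP_all, T_all))
}
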