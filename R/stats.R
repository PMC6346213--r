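#' Co-elution score of a feature
#'
#' A bounded composite of correlation quality and subunit coverage:
#' `max(0, peak_corr) * completeness`, in [0, 1]. The same formula is
#' applied to target and decoy features, so the downstream target-decoy
#' machinery is agnostic to its exact form.
#'
#' @param feature a feature table (or single row) with `peak_corr` and
#'   `completeness` columns.
#' @return Numeric score vector.
#' @export
coelution_score <- function(feature) {
  pmax(0, feature$peak_corr) * feature$completeness
}

#' Decoy-based p-values, Storey pi0 and q-values
#'
#' Empirical p-value of a target score s against the decoy score
#' distribution, with add-one smoothing:
#' `p(s) = (1 + #\{decoy >= s\}) / (1 + D)`. The fraction of true nulls
#' is estimated as `pi0 = min(1, #\{p > lambda\} / (m (1 - lambda)))` and
#' q-values follow the Storey step-up:
#' sorted ascending, `q_(i) = min_(j>=i) pi0 m p_(j) / j`, capped at 1.
#'
#' @param target_scores numeric vector of target best-feature scores.
#' @param decoy_scores numeric vector of decoy best-feature scores.
#' @param lambda pi0 tuning constant (default 0.5).
#' @return List with `table` (`data.frame(score, p, q)` in input order),
#'   `pi0`, `lambda`, and `m` (number of targets).
#' @export
estimate_qvalues <- function(target_scores, decoy_scores, lambda = 0.5) {
  if (length(decoy_scores) == 0L)
    stop("decoy scores required for q-value estimation")
  if (length(target_scores) == 0L) stop("no target scores")
  p <- vapply(target_scores, function(s)
    (1 + sum(decoy_scores >= s)) / (1 + length(decoy_scores)), 0)
  q <- storey_qvalues(p, lambda)
  list(table = data.frame(score = target_scores, p = p, q = q$q),
       pi0 = q$pi0, lambda = lambda, m = length(target_scores))
}

#' Storey q-values from a p-value vector
#'
#' @param p numeric p-values in [0, 1].
#' @param lambda pi0 tuning constant.
#' @return List with `q` (same order as `p`) and `pi0`.
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  if (pi0 <= 0) pi0 <- 1 / m # degenerate: all p tiny; stay conservative
  ord <- order(p)
  q_sorted <- pi0 * m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(1, q_sorted)
  q <- numeric(m)
  q[ord] <- q_sorted
  list(q = q, pi0 = pi0)
}

#' Decoy-counting FDR at a score threshold
#'
#' `fft * #\{decoy >= t\} / max(1, #\{target >= t\})`, where `fft` (the
#' fraction of false targets) rescales the decoy count to account for
#' queried targets absent from the sample.
#'
#' @param threshold score threshold.
#' @param target_scores,decoy_scores numeric score vectors.
#' @param fft fraction of false targets in (0, 1].
#' @return Estimated FDR (proportion).
#' @export
decoy_fdr <- function(threshold, target_scores, decoy_scores, fft = 1) {
  if (fft <= 0 || fft > 1) stop("fft must be in (0, 1]")
  fft * sum(decoy_scores >= threshold) /
    max(1L, sum(target_scores >= threshold))
}

#' Grid search over detection parameters
#'
#' Runs detection for every parameter combination on the target and decoy
#' queries, keeps the best feature per query, estimates q-values, and
#' counts targets at `q <= fdr_cutoff`. Selected is the combination
#' maximizing that count among combinations whose decoy-estimated FDR at
#' the corresponding score threshold stays at or below the cutoff; ties
#' break toward fewer detected decoys, then grid order.
#'
#' @param tm a protein-level `sec_traces`.
#' @param targets,decoys `complex_queries` tables.
#' @param corrs,windows,smoothings,rt_heights grid axes (defaults are the
#'   ranges scanned for SEC-SWATH data).
#' @param fdr_cutoff FDR threshold (default 0.05).
#' @param lambda pi0 tuning constant.
#' @param base_params template [detection_params()] supplying the
#'   non-scanned settings (perturbation, collapse method, seed).
#' @return List with `grid` (`data.frame` of parameter sets, target and
#'   decoy counts at the cutoff, estimated FDR, `selected` flag) and
#'   `best_params` (a [detection_params()], or `NULL` when no set
#'   passes).
#' @export
grid_search <- function(tm, targets, decoys,
                        corrs = c(0.7, 0.8, 0.9, 0.95),
                        windows = c(8L, 10L, 12L),
                        smoothings = c(5L, 7L, 9L),
                        rt_heights = c(3, 5),
                        fdr_cutoff = 0.05, lambda = 0.5,
                        base_params = detection_params()) {
  grid <- expand.grid(corr_cutoff = corrs, window_size = windows,
                      smoothing_length = smoothings,
                      rt_height = rt_heights,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0L) stop("empty parameter grid")
  n_det <- integer(nrow(grid)); n_dec <- integer(nrow(grid))
  fdr <- numeric(nrow(grid))
  qset <- rbind(targets, decoys, fill = TRUE)
  for (g in seq_len(nrow(grid))) {
    params <- detection_params(
      corr_cutoff = grid$corr_cutoff[g], window_size = grid$window_size[g],
      smoothing_length = grid$smoothing_length[g],
      rt_height = grid$rt_height[g],
      perturb_quantile = base_params$perturb_quantile,
      collapse_method = base_params$collapse_method,
      seed = base_params$seed)
    feats <- find_features(tm, qset, params)
    if (nrow(feats) == 0L) { fdr[g] <- 0; next }
    best <- best_feature_per_query(feats)
    best$score <- coelution_score(best)
    tsc <- query_scores(targets$query_id, best)
    dsc <- query_scores(decoys$query_id, best)
    sq <- estimate_qvalues(tsc, dsc, lambda)
    pass <- sq$table$q <= fdr_cutoff
    n_det[g] <- sum(pass)
    if (any(pass)) {
      thr <- min(sq$table$score[pass])
      n_dec[g] <- sum(dsc >= thr)
      fdr[g] <- decoy_fdr(thr, tsc, dsc)
    }
  }
  grid$n_detected <- n_det
  grid$n_decoy <- n_dec
  grid$est_fdr <- fdr
  grid$selected <- FALSE
  ok <- which(grid$est_fdr <= fdr_cutoff & grid$n_detected > 0L)
  best_params <- NULL
  if (length(ok)) {
    ord <- ok[order(-grid$n_detected[ok], grid$n_decoy[ok], ok)]
    sel <- ord[1L]
    grid$selected[sel] <- TRUE
    best_params <- detection_params(
      corr_cutoff = grid$corr_cutoff[sel],
      window_size = grid$window_size[sel],
      smoothing_length = grid$smoothing_length[sel],
      rt_height = grid$rt_height[sel],
      perturb_quantile = base_params$perturb_quantile,
      collapse_method = base_params$collapse_method,
      seed = base_params$seed)
  } else {
    warning("no parameter set achieves the FDR cutoff")
  }
  list(grid = grid, best_params = best_params)
}
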