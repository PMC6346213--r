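#' Detection parameters for co-elution feature finding
#'
#' Defaults follow the settings that a grid search selects on
#' high-quality SEC-SWATH data: correlation cutoff 0.95 over a sliding
#' window of 8 fractions, 9-fraction smoothing, apex clustering height of
#' 3 fractions, and 5% zero-perturbation.
#'
#' @param corr_cutoff minimal pairwise Pearson correlation within a window
#'   for two analytes to be linked (0 < corr_cutoff <= 1).
#' @param window_size sliding-window width in fractions (>= 2).
#' @param smoothing_length moving-average length in fractions (odd).
#' @param rt_height apex clustering height in fractions: window-local
#'   groups whose apexes fall within this distance are merged.
#' @param perturb_quantile zeros are replaced by uniform draws on
#'   `[0, q]` where q is this quantile of the non-zero intensities;
#'   prevents spurious perfect correlations between all-zero stretches.
#' @param collapse_method `"apex_network"` merges all correlation-connected
#'   groups within an apex cluster; `"apex_only"` merges only groups
#'   sharing the identical apex.
#' @param min_monomer_distance_factor features must elute at an apparent
#'   MW at least this multiple of the largest detected monomer.
#' @param seed seed for the zero-perturbation draws.
#' @return A `detection_params` list.
#' @export
detection_params <- function(corr_cutoff = 0.95, window_size = 8L,
                             smoothing_length = 9L, rt_height = 3,
                             perturb_quantile = 0.05,
                             collapse_method = c("apex_network", "apex_only"),
                             min_monomer_distance_factor = 2,
                             seed = 1L) {
  collapse_method <- match.arg(collapse_method)
  if (corr_cutoff <= 0 || corr_cutoff > 1) stop("corr_cutoff in (0, 1]")
  if (window_size < 2L) stop("window_size must be >= 2")
  if (smoothing_length < 1L || smoothing_length %% 2L == 0L)
    stop("smoothing_length must be odd and >= 1")
  if (rt_height < 0) stop("rt_height must be >= 0")
  structure(list(corr_cutoff = corr_cutoff,
                 window_size = as.integer(window_size),
                 smoothing_length = as.integer(smoothing_length),
                 rt_height = rt_height,
                 perturb_quantile = perturb_quantile,
                 collapse_method = collapse_method,
                 min_monomer_distance_factor = min_monomer_distance_factor,
                 seed = as.integer(seed)),
            class = "detection_params")
}

#' Replace zero intensities by sub-noise uniform draws
#'
#' Dense trace matrices code missing observations as zeros; identical
#' zero stretches would correlate perfectly and trigger false co-elution
#' links. Each zero cell is therefore replaced by a uniform draw on
#' `[0, q]`, with q the given quantile of all non-zero intensities in the
#' matrix. Non-zero cells are untouched; the operation is reproducible
#' under the seed.
#'
#' @param tm a `sec_traces` object.
#' @param quantile quantile of non-zero intensities defining the noise
#'   ceiling (default 0.05).
#' @param seed integer seed.
#' @return A `sec_traces` with all zeros replaced.
#' @export
perturb_zeros <- function(tm, quantile = 0.05, seed = 1L) {
  stopifnot(inherits(tm, "sec_traces"))
  nz <- tm$intensity[tm$intensity > 0]
  if (length(nz) == 0L) stop("all-zero trace matrix cannot be perturbed")
  q <- stats::quantile(nz, quantile, names = FALSE)
  zero <- tm$intensity == 0
  set.seed(seed)
  tm$intensity[zero] <- runif(sum(zero), 0, q)
  tm
}

#' Smooth traces by a centered moving average
#'
#' At the edges the window shrinks symmetrically so the average stays
#' centered; a constant trace is unchanged and output stays non-negative.
#'
#' @param tm a `sec_traces` object.
#' @param length odd window length in fractions (default 9).
#' @return Smoothed `sec_traces`.
#' @export
smooth_traces <- function(tm, length = 9L) {
  stopifnot(inherits(tm, "sec_traces"))
  if (length %% 2L == 0L) stop("smoothing length must be odd")
  tm$intensity <- t(apply(tm$intensity, 1L, smooth_vec, half = (length - 1L) %/% 2L))
  colnames(tm$intensity) <- as.character(tm$fractions)
  tm
}

smooth_vec <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    mean(x[(i - h):(i + h)])
  }, 0)
}

# Shared preparation for repeated detection on one matrix: perturb the
# zeros once (seeded) and smooth once; correlations are computed on the
# perturbed raw traces, apexes and boundaries on the smoothed ones.
prepare_detection <- function(tm, params) {
  pert <- perturb_zeros(tm, params$perturb_quantile, params$seed)
  sm <- smooth_traces(pert, params$smoothing_length)
  list(raw = tm$intensity, pert = pert$intensity, smooth = sm$intensity,
       fractions = tm$fractions, ids = rownames(tm$intensity))
}

# Window-local co-elution groups for one analyte subset: for every
# window position, analytes with any pre-perturbation signal in the
# window are pairwise correlated on the perturbed traces; pairs at or
# above the cutoff are linked and connected components of size >= 2
# become groups. Returns list(window, members, apex, edges).
window_groups <- function(prep, members, params) {
  F <- length(prep$fractions)
  ws <- params$window_size
  if (ws > F) stop("window_size exceeds the number of fractions")
  idx <- match(members, prep$ids)
  raw <- prep$raw[idx, , drop = FALSE]
  pert <- prep$pert[idx, , drop = FALSE]
  sm <- prep$smooth[idx, , drop = FALSE]
  out <- list()
  for (w in seq_len(F - ws + 1L)) {
    cols <- w:(w + ws - 1L)
    active <- which(rowSums(raw[, cols, drop = FALSE] > 0) > 0)
    if (length(active) < 2L) next
    cc <- suppressWarnings(cor(t(pert[active, cols, drop = FALSE])))
    cc[!is.finite(cc)] <- 0
    adj <- cc >= params$corr_cutoff
    diag(adj) <- FALSE
    comp <- graph_components(adj)
    for (grp in comp) {
      if (length(grp) < 2L) next
      g_rows <- active[grp]
      s_win <- colSums(sm[g_rows, cols, drop = FALSE])
      # argmax within the window, then hill-climbed on the full-axis
      # group sum to the nearest local maximum: windows covering only a
      # peak flank would otherwise report the window edge as apex
      s_full <- colSums(sm[g_rows, , drop = FALSE])
      a <- cols[which.max(s_win)]
      while (a < F && s_full[a + 1L] > s_full[a]) a <- a + 1L
      while (a > 1L && s_full[a - 1L] > s_full[a]) a <- a - 1L
      apex <- prep$fractions[a]
      pairs <- which(adj[grp, grp, drop = FALSE], arr.ind = TRUE)
      pairs <- pairs[pairs[, 1L] < pairs[, 2L], , drop = FALSE]
      edges <- cbind(members[g_rows[pairs[, 1L]]],
                     members[g_rows[pairs[, 2L]]])
      out[[length(out) + 1L]] <- list(window = w,
                                      members = members[g_rows],
                                      apex = apex, edges = edges)
    }
  }
  out
}

# connected components of a logical adjacency matrix (row indices)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  split(seq_len(n), comp)
}

# peak boundaries: nearest local minima of the smoothed group sum around
# the apex, with a floor at 5% of apex height and a minimum width of 2.
peak_boundaries <- function(s, apex_pos) {
  n <- length(s)
  floor_h <- 0.05 * s[apex_pos]
  l <- apex_pos
  while (l > 1L && s[l - 1L] < s[l] && s[l - 1L] > floor_h) l <- l - 1L
  if (l > 1L && s[l - 1L] <= floor_h) l <- l - 1L
  r <- apex_pos
  while (r < n && s[r + 1L] < s[r] && s[r + 1L] > floor_h) r <- r + 1L
  if (r < n && s[r + 1L] <= floor_h) r <- r + 1L
  if (r - l < 1L) { # enforce minimum width 2 fractions
    if (r < n) r <- r + 1L else if (l > 1L) l <- l - 1L
  }
  c(l, r)
}

mean_pairwise_corr <- function(mat) {
  if (nrow(mat) < 2L) return(NA_real_)
  cc <- suppressWarnings(cor(t(mat)))
  cc[!is.finite(cc)] <- 0
  mean(cc[upper.tri(cc)])
}

empty_features <- function() {
  data.table(query_id = character(), subunits = list(),
             n_subunits = integer(), n_query = integer(),
             completeness = numeric(), apex = integer(),
             left_pp = integer(), right_pp = integer(),
             peak_corr = numeric(), total_area = numeric(),
             areas = list(), apparent_mw = numeric(),
             is_decoy = logical())
}

#' Detect co-elution features for complex queries
#'
#' The core sliding-window detector. For each query, the subunit traces
#' present in the matrix are (1) zero-perturbed and smoothed; (2) scanned
#' with a window of `window_size` fractions, computing pairwise Pearson
#' correlations of the perturbed raw traces within each window and taking
#' connected components of the `corr >= corr_cutoff` link graph (size >=
#' 2) as window-local groups; (3) each group receives an apex, the argmax
#' of its summed smoothed trace within the window; (4) groups are
#' clustered on apex by complete linkage cut at `rt_height` and merged
#' within clusters according to `collapse_method`; (5) peak boundaries
#' are the nearest local minima of the merged group's summed smoothed
#' trace around the consensus apex; (6) mean within-boundary correlation,
#' completeness (detected / queried subunits observed in the matrix),
#' per-subunit raw areas and, when a calibration is given, the apparent
#' MW at the apex are reported.
#'
#' @param tm a `sec_traces` (protein level for complex queries, peptide
#'   level for protein-centric use).
#' @param queries a `complex_queries` table (or a single query row).
#' @param params a [detection_params()].
#' @param calibration optional [fit_calibration()] model for apparent MW.
#' @return `data.table` of features sorted by completeness then peak
#'   correlation (descending): `query_id, subunits, n_subunits, n_query,
#'   completeness, apex, left_pp, right_pp, peak_corr, total_area, areas,
#'   apparent_mw, is_decoy`.
#' @export
find_features <- function(tm, queries, params = detection_params(),
                          calibration = NULL) {
  stopifnot(inherits(tm, "sec_traces"))
  prep <- prepare_detection(tm, params)
  res <- lapply(seq_len(nrow(queries)), function(i)
    find_features_one(prep, queries$query_id[i], queries$subunits[[i]],
                      isTRUE(queries$is_decoy[i]), params, calibration))
  out <- rbindlist(c(list(empty_features()), res))
  completeness <- peak_corr <- NULL
  setorder(out, -completeness, -peak_corr)
  out[]
}

find_features_one <- function(prep, query_id, subunits, is_decoy, params,
                              calibration) {
  present <- intersect(subunits, prep$ids)
  if (length(present) < 2L) return(NULL)
  groups <- window_groups(prep, present, params)
  if (length(groups) == 0L) return(NULL)
  apexes <- vapply(groups, `[[`, 0, "apex")
  cl <- if (length(groups) == 1L) 1L else
    cutree(hclust(stats::dist(apexes), method = "complete"),
           h = params$rt_height)
  feats <- list()
  for (k in unique(cl)) {
    gidx <- which(cl == k)
    merged <- merge_cluster_groups(groups[gidx], params$collapse_method)
    for (m in merged) {
      members <- m$members
      s <- colSums(prep$smooth[match(members, prep$ids), , drop = FALSE])
      rng <- range(m$apexes)
      span <- which(prep$fractions >= rng[1L] & prep$fractions <= rng[2L])
      apex_pos <- span[which.max(s[span])]
      bounds <- peak_boundaries(s, apex_pos)
      cols <- bounds[1L]:bounds[2L]
      ridx <- match(members, prep$ids)
      pc <- mean_pairwise_corr(prep$pert[ridx, cols, drop = FALSE])
      areas <- rowSums(prep$raw[ridx, cols, drop = FALSE])
      feats[[length(feats) + 1L]] <- data.table(
        query_id = query_id, subunits = list(sort(members)),
        n_subunits = length(members), n_query = length(present),
        completeness = length(members) / length(present),
        apex = prep$fractions[apex_pos],
        left_pp = prep$fractions[bounds[1L]],
        right_pp = prep$fractions[bounds[2L]],
        peak_corr = pc, total_area = sum(areas),
        areas = list(setNames(unname(areas), members)),
        apparent_mw = if (is.null(calibration)) NA_real_ else
          fraction_to_mw(calibration, prep$fractions[apex_pos]),
        is_decoy = is_decoy)
    }
  }
  rbindlist(feats)
}

# merge window-local groups inside one apex cluster
merge_cluster_groups <- function(groups, collapse_method) {
  if (collapse_method == "apex_only") {
    by_apex <- split(groups, vapply(groups, `[[`, 0, "apex"))
    lapply(by_apex, function(gs) list(
      members = sort(unique(unlist(lapply(gs, `[[`, "members")))),
      apexes = vapply(gs, `[[`, 0, "apex")))
  } else {
    # apex_network: groups whose members are connected in the union
    # correlation graph (shared member or cross edge) are merged
    n <- length(groups)
    adj <- diag(TRUE, n)
    edges <- do.call(rbind, lapply(groups, `[[`, "edges"))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      mi <- groups[[i]]$members; mj <- groups[[j]]$members
      linked <- length(intersect(mi, mj)) > 0L ||
        any((edges[, 1L] %in% mi & edges[, 2L] %in% mj) |
              (edges[, 1L] %in% mj & edges[, 2L] %in% mi))
      adj[i, j] <- adj[j, i] <- linked
    }
    comp <- graph_components(adj)
    lapply(comp, function(ix) list(
      members = sort(unique(unlist(lapply(groups[ix], `[[`, "members")))),
      apexes = vapply(groups[ix], `[[`, 0, "apex")))
  }
}

#' Enumerate window-local co-elution groups
#'
#' Exposes step (2)-(3) of [find_features()] — the thresholded
#' window-correlation groups before apex clustering — mainly for
#' validation against exhaustive enumeration.
#'
#' @inheritParams find_features
#' @param subunits character vector of analyte ids to scan.
#' @return List of `list(window, members, apex, edges)`.
#' @export
window_coelution_groups <- function(tm, subunits,
                                    params = detection_params()) {
  prep <- prepare_detection(tm, params)
  present <- intersect(subunits, prep$ids)
  if (length(present) < 2L) return(list())
  window_groups(prep, present, params)
}

#' Filter features by apparent molecular weight and quality
#'
#' Retains features whose apparent MW at the apex is at least
#' `min_monomer_distance_factor` times the largest monomer mass among the
#' detected subunits — the two-fold (by default) rule separating
#' assembled signals from monomer elution. Optional completeness,
#' correlation, and subunit-count thresholds are applied only when given.
#'
#' @param features feature table from [find_features()].
#' @param monomer_mw named numeric vector, monomer mass (kDa) per protein.
#' @param min_monomer_distance_factor MW multiple (default 2); 0 disables.
#' @param min_completeness,min_peak_corr,min_subunits optional cutoffs.
#' @return Filtered feature table.
#' @export
filter_features <- function(features, monomer_mw,
                            min_monomer_distance_factor = 2,
                            min_completeness = NULL, min_peak_corr = NULL,
                            min_subunits = NULL) {
  keep <- rep(TRUE, nrow(features))
  if (min_monomer_distance_factor > 0 && nrow(features)) {
    if (any(!is.finite(features$apparent_mw)))
      stop("apparent_mw missing; run detection with a calibration model")
    maxmono <- vapply(features$subunits, function(s) {
      mw <- monomer_mw[s]
      if (any(is.na(mw)))
        stop("missing monomer mass for: ",
             paste(s[is.na(mw)], collapse = ", "))
      max(mw)
    }, 0)
    keep <- keep & features$apparent_mw >= min_monomer_distance_factor * maxmono
  }
  if (!is.null(min_completeness))
    keep <- keep & features$completeness >= min_completeness
  if (!is.null(min_peak_corr)) keep <- keep & features$peak_corr >= min_peak_corr
  if (!is.null(min_subunits)) keep <- keep & features$n_subunits >= min_subunits
  features[keep]
}

#' Best (most complete) feature per query
#'
#' Only the best co-elution feature per query enters scoring and FDR
#' estimation. Ranking: completeness, then peak correlation, then total
#' area (all descending); ties beyond that break on apex (ascending) for
#' determinism.
#'
#' @param features feature table from [find_features()].
#' @return One row per `query_id`.
#' @export
best_feature_per_query <- function(features) {
  if (nrow(features) == 0L) return(features)
  features <- copy(features) # leave the caller's table untouched
  completeness <- peak_corr <- total_area <- apex <- query_id <- NULL
  setorder(features, -completeness, -peak_corr, -total_area, apex)
  features[, head(.SD, 1L), by = "query_id"]
}

#' Best-feature scores for a set of queries, zero where none detected
#'
#' Queries without any detected feature are null trials and enter the
#' target-decoy competition with score 0 rather than being dropped.
#'
#' @param query_ids character vector of query ids.
#' @param best best-feature table carrying a `score` column.
#' @return Named numeric score vector, one entry per query id.
#' @export
query_scores <- function(query_ids, best) {
  s <- setNames(rep(0, length(query_ids)), query_ids)
  hit <- best$query_id %in% query_ids
  s[best$query_id[hit]] <- best$score[hit]
  s
}

#' Protein-centric detection of elution features with q-values
#'
#' Runs the co-elution detector per protein, querying its own peptides,
#' against a random decoy model: for every real protein with k peptides a
#' decoy "protein" is assembled from k peptides sampled uniformly without
#' replacement from other proteins. Best features are scored, q-values
#' estimated from the target-decoy competition, and target features at
#' `q <= qvalue_cutoff` returned with apparent MW and the
#' apparent-to-monomer mass ratio.
#'
#' @param tm_peptide a filtered peptide-level `sec_traces` with
#'   annotations attached.
#' @param params a [detection_params()].
#' @param calibration a [fit_calibration()] model (optional; required for
#'   `mw_ratio`).
#' @param qvalue_cutoff maximal q-value (default 0.1, i.e. 10% FDR).
#' @param lambda Storey pi0 tuning constant.
#' @param seed seed for the decoy peptide resampling.
#' @return `data.table` of protein features (`protein_id`, apex,
#'   boundaries, peak_corr, n_peptides, score, p, q, `apparent_mw`,
#'   `monomer_mw`, `mw_ratio`).
#' @export
find_protein_features <- function(tm_peptide, params = detection_params(),
                                  calibration = NULL, qvalue_cutoff = 0.1,
                                  lambda = 0.5, seed = 1L) {
  stopifnot(inherits(tm_peptide, "sec_traces"), tm_peptide$level == "peptide")
  ids <- analyte_ids(tm_peptide)
  groups <- split(ids, tm_peptide$parent_ids)
  sizes <- lengths(groups)
  skipped <- names(groups)[sizes < 2L]
  if (length(skipped))
    message(length(skipped), " protein(s) with < 2 peptides skipped")
  groups <- groups[sizes >= 2L]
  if (length(groups) == 0L) stop("no protein with >= 2 peptides")
  set.seed(seed)
  # decoy "proteins": size-matched peptide sets drawn from other
  # proteins, one peptide per donor protein so a decoy can never inherit
  # a genuinely co-eluting sibling pair
  all_prots <- unique(tm_peptide$parent_ids)
  decoy_groups <- lapply(names(groups), function(p) {
    donors <- setdiff(all_prots, p)
    k <- min(length(groups[[p]]), length(donors))
    picked <- sample(donors, k)
    vapply(picked, function(dp) {
      peps <- ids[tm_peptide$parent_ids == dp]
      if (length(peps) == 1L) peps else sample(peps, 1L)
    }, "")
  })
  names(decoy_groups) <- paste0("DECOY_", names(groups))
  qtab <- new_query_table(
    c(names(groups), names(decoy_groups)),
    c(names(groups), names(decoy_groups)),
    c(unname(groups), unname(decoy_groups)),
    c(rep(FALSE, length(groups)), rep(TRUE, length(decoy_groups))),
    rep("protein_centric", length(groups) + length(decoy_groups)))
  feats <- find_features(tm_peptide, qtab, params, calibration)
  if (nrow(feats) == 0L) return(feats)
  best <- best_feature_per_query(feats)
  best$score <- coelution_score(best)
  # queries without any detected feature compete with score 0
  tsc <- query_scores(names(groups), best)
  dsc <- query_scores(names(decoy_groups), best)
  sq <- estimate_qvalues(tsc, dsc, lambda = lambda)
  tgt <- best[!best$is_decoy]
  qi <- match(tgt$query_id, names(groups))
  tgt$p <- sq$table$p[qi]
  tgt$q <- sq$table$q[qi]
  # all features of proteins passing the cutoff, each annotated
  q <- NULL
  tgt <- tgt[q <= qvalue_cutoff]
  out <- feats[!feats$is_decoy & feats$query_id %in% tgt$query_id]
  out <- merge(out, tgt[, c("query_id", "score", "p", "q")],
               by = "query_id", all.x = TRUE)
  setnames(out, "query_id", "protein_id")
  if (!is.null(tm_peptide$annotations)) {
    ann <- tm_peptide$annotations
    pid_of <- tm_peptide$parent_ids[match(ann$analyte_id, ids)]
    mono <- tapply(ann$protein_mw_kda, pid_of, function(v) v[1L])
    out$monomer_mw <- as.numeric(mono[out$protein_id])
    out$mw_ratio <- out$apparent_mw / out$monomer_mw
  }
  out[]
}
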