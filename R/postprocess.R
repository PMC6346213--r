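#' Secondary features: candidate complex variants
#'
#' For queries whose best feature passes the q-value cutoff, all
#' additional (non-best) features with at least `min_peak_corr` peak
#' correlation are returned flagged `secondary`. These are candidate
#' complex variants — assembly intermediates or sub-complexes eluting
#' apart from the main signal — and carry no FDR of their own.
#'
#' @param all_features full feature table from [find_features()].
#' @param best_q_table `data.frame(query_id, q)` for the best feature per
#'   query (from [estimate_qvalues()] applied to best features).
#' @param q_cutoff maximal best-feature q-value (default 0.05).
#' @param min_peak_corr minimal peak correlation of a secondary feature
#'   (default 0.5).
#' @return Feature table of secondary features with `secondary = TRUE`.
#' @export
secondary_variant_features <- function(all_features, best_q_table,
                                       q_cutoff = 0.05,
                                       min_peak_corr = 0.5) {
  pass <- best_q_table$query_id[best_q_table$q <= q_cutoff]
  feats <- all_features[all_features$query_id %in% pass]
  if (nrow(feats) == 0L) {
    feats$secondary <- logical(0)
    return(feats)
  }
  best <- best_feature_per_query(copy(feats))
  best_key <- paste(best$query_id, best$apex)
  sec <- feats[!paste(feats$query_id, feats$apex) %in% best_key]
  sec <- sec[sec$peak_corr >= min_peak_corr]
  sec$secondary <- rep(TRUE, nrow(sec))
  sec
}

# composition/elution distance used for collapsing: additive
# (1 - Jaccard) + |delta apex| / rt_height, gated to Inf when apexes are
# farther than rt_height apart or the compositions are disjoint.
feature_distance <- function(subunits, apex, rt_height) {
  n <- length(subunits)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    da <- abs(apex[i] - apex[j])
    if (da > rt_height) next
    inter <- length(intersect(subunits[[i]], subunits[[j]]))
    if (inter == 0L) next
    jac <- inter / length(union(subunits[[i]], subunits[[j]]))
    d[i, j] <- d[j, i] <- (1 - jac) + da / rt_height
  }
  d
}

#' Collapse redundant features into unique co-elution signals
#'
#' Features detected from overlapping queries (possibly across several
#' query sources) describing the same physical signal are merged.
#' Pairwise distance is `(1 - Jaccard(subunits)) + |delta apex| /
#' rt_height` when the apexes lie within `rt_height` fractions and the
#' compositions overlap, `Inf` otherwise; single-linkage clusters cut at
#' `distance_cutoff` become one signal each, with the subunit union and
#' the area-weighted mean apex (rounded to the nearest fraction).
#' Fully disjoint compositions never merge. The operation is idempotent.
#'
#' @param features feature table with `subunits` (list), `apex`,
#'   `total_area`, and optionally `query_id` / `source` columns; decoy
#'   rows (if any) are removed first.
#' @param rt_height maximal apex distance in fractions (default 3).
#' @param distance_cutoff single-linkage cut height (default 1.25).
#' @return `data.table` of collapsed signals: `signal_id`, `subunits`,
#'   `n_subunits`, `apex`, `total_area`, `n_members`, `member_queries`.
#' @export
collapse_features <- function(features, rt_height = 3,
                              distance_cutoff = 1.25) {
  if ("is_decoy" %in% names(features))
    features <- features[!features$is_decoy]
  n <- nrow(features)
  if (n == 0L)
    return(data.table(signal_id = character(), subunits = list(),
                      n_subunits = integer(), apex = integer(),
                      total_area = numeric(), n_members = integer(),
                      member_queries = list()))
  qid <- if ("query_id" %in% names(features)) features$query_id
         else if ("member_queries" %in% names(features))
           vapply(features$member_queries, paste, "", collapse = ";")
         else as.character(seq_len(n))
  if (n == 1L) {
    cl <- 1L
  } else {
    d <- feature_distance(features$subunits, features$apex, rt_height)
    d[!is.finite(d)] <- 1e6 # beyond any reachable cut height
    cl <- cutree(hclust(as.dist(d), method = "single"),
                 h = distance_cutoff)
  }
  out <- lapply(sort(unique(cl)), function(k) {
    ix <- which(cl == k)
    w <- features$total_area[ix]
    if (all(w == 0)) w <- rep(1, length(ix))
    data.table(
      subunits = list(sort(unique(unlist(features$subunits[ix])))),
      apex = as.integer(round(sum(features$apex[ix] * w) / sum(w))),
      total_area = sum(features$total_area[ix]),
      n_members = length(ix),
      member_queries = list(sort(unique(unlist(strsplit(qid[ix], ";"))))))
  })
  out <- rbindlist(out)
  out$n_subunits <- lengths(out$subunits)
  out$signal_id <- sprintf("signal_%03d", seq_len(nrow(out)))
  setcolorder(out, c("signal_id", "subunits", "n_subunits", "apex",
                     "total_area", "n_members", "member_queries"))
  out[]
}

#' Small-integer subunit stoichiometry from feature areas
#'
#' Within-boundary subunit areas are normalized by the smallest; integer
#' scalings k = 1..`max_scale` of the normalized vector are scanned and
#' the k minimizing the total rounding error is chosen. The rounded
#' integers (reduced by their greatest common divisor) and the raw ratios
#' are both reported.
#'
#' @param feature one feature row (with an `areas` list column) or a
#'   named numeric vector of areas.
#' @param max_scale largest integer scaling scanned (default 10).
#' @return List with `stoichiometry` (named integers), `ratios` (named
#'   raw ratios), and `scale` (the chosen k).
#' @export
estimate_stoichiometry <- function(feature, max_scale = 10L) {
  areas <- if (is.numeric(feature)) feature else feature$areas[[1L]]
  if (any(areas <= 0) || min(areas) == 0)
    stop("all subunit areas must be positive")
  r <- areas / min(areas)
  err <- vapply(seq_len(max_scale), function(k)
    sum(abs(round(k * r) - k * r)), 0)
  k <- which.min(err)
  ints <- as.integer(round(k * r))
  g <- Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b), ints)
  list(stoichiometry = setNames(ints %/% g, names(areas)),
       ratios = setNames(r, names(areas)), scale = k)
}

#' Attribute protein signal to assembled vs monomeric state
#'
#' Each detected protein elution peak is classified by the ratio of the
#' calibrated apparent MW at its apex to the protein's monomer mass:
#' assembled when the ratio is at least `factor` (default 2, the two-fold
#' rule). Peak areas (protein-trace intensity within the peak
#' boundaries) are pooled into assembled and monomeric mass; intensity
#' outside any detected peak is reported as unassigned rather than
#' folded into either pool.
#'
#' @param protein_features feature table with `protein_id`, `apex`,
#'   `left_pp`, `right_pp` (e.g. from [find_protein_features()]).
#' @param tm_protein protein-level `sec_traces` with monomer masses
#'   annotated.
#' @param calibration a [fit_calibration()] model.
#' @param factor assembled threshold on the apparent/monomer MW ratio.
#' @return List with `peaks` (per-peak table: `protein_id`, `apex`,
#'   `mw_ratio`, `area`, `assembled`), `proteins` (per-protein state:
#'   assembled / monomer_only / both / no_peak), `assembled_mass_fraction`
#'   and `monomeric_mass_fraction` (of peak-assigned mass),
#'   `assembled_protein_fraction` (of proteins with peaks),
#'   `unassigned_intensity` and `peakless_intensity`.
#' @export
assembly_state_report <- function(protein_features, tm_protein,
                                  calibration, factor = 2) {
  stopifnot(inherits(tm_protein, "sec_traces"))
  if (missing(calibration) || is.null(calibration))
    stop("a calibration model is required for assembly-state attribution")
  if (is.null(tm_protein$annotations))
    stop("tm_protein must carry monomer mass annotations")
  mono <- setNames(tm_protein$annotations$protein_mw_kda,
                   tm_protein$annotations$analyte_id)
  pf <- as.data.table(protein_features)
  if (!"protein_id" %in% names(pf) && "query_id" %in% names(pf))
    setnames(pf, "query_id", "protein_id")
  peaks <- pf[, c("protein_id", "apex", "left_pp", "right_pp")]
  peaks$monomer_mw <- as.numeric(mono[peaks$protein_id])
  if (any(is.na(peaks$monomer_mw)))
    stop("missing monomer mass for: ", paste(
      unique(peaks$protein_id[is.na(peaks$monomer_mw)]), collapse = ", "))
  peaks$mw_ratio <- fraction_to_mw(calibration, peaks$apex) / peaks$monomer_mw
  peaks$assembled <- peaks$mw_ratio >= factor
  fr <- tm_protein$fractions
  peaks$area <- vapply(seq_len(nrow(peaks)), function(i) {
    cols <- which(fr >= peaks$left_pp[i] & fr <= peaks$right_pp[i])
    sum(tm_protein$intensity[peaks$protein_id[i], cols])
  }, 0)
  state <- tapply(peaks$assembled, peaks$protein_id, function(a) {
    if (all(a)) "assembled" else if (!any(a)) "monomer_only" else "both"
  })
  all_prot <- analyte_ids(tm_protein)
  proteins <- data.frame(protein_id = all_prot,
                         state = ifelse(all_prot %in% names(state),
                                        state[all_prot], "no_peak"),
                         stringsAsFactors = FALSE)
  assembled_mass <- sum(peaks$area[peaks$assembled])
  monomeric_mass <- sum(peaks$area[!peaks$assembled])
  with_peaks <- unique(peaks$protein_id)
  assembled_prots <- unique(peaks$protein_id[peaks$assembled])
  peakless <- setdiff(all_prot, with_peaks)
  # within-boundary mass per protein, to separate unassigned intensity
  assigned <- sum(peaks$area)
  total_with_peaks <- sum(tm_protein$intensity[with_peaks, , drop = FALSE])
  list(peaks = peaks[], proteins = proteins,
       assembled_mass_fraction =
         assembled_mass / (assembled_mass + monomeric_mass),
       monomeric_mass_fraction =
         monomeric_mass / (assembled_mass + monomeric_mass),
       assembled_protein_fraction =
         length(assembled_prots) / length(with_peaks),
       unassigned_intensity = max(0, total_with_peaks - assigned),
       peakless_intensity =
         sum(tm_protein$intensity[peakless, , drop = FALSE]))
}

#' Two-component Gaussian deconvolution of an elution peak
#'
#' Least-squares fit of a sum of Gaussians (amplitude, mean, sd each) to
#' a trace segment, resolving e.g. a peak-plus-shoulder into two
#' underlying signals. Initialization takes the first component from the
#' global apex and each further component from the largest positive
#' residual. The mixing fraction of component i is
#' `A_i sd_i / sum_j A_j sd_j` (proportional to its integrated area).
#'
#' @param segment non-negative numeric vector, the trace values.
#' @param fractions fraction coordinates of `segment` (default
#'   `seq_along(segment)`).
#' @param n_components number of Gaussians (default 2).
#' @param init optional initialization: `data.frame(A, mu, sd)` with one
#'   row per component.
#' @return List with `components` (`data.frame(A, mu, sd,
#'   mixing_fraction)`, ordered by mean), `fitted`, and `rss`.
#' @export
gaussian_deconvolve <- function(segment, fractions = seq_along(segment),
                                n_components = 2L, init = NULL) {
  y <- as.numeric(segment)
  x <- as.numeric(fractions)
  if (length(y) < 3L * n_components)
    stop("segment too short: need >= 3 points per component")
  if (any(y < 0)) stop("segment must be non-negative")
  if (is.null(init)) {
    init <- data.frame(A = numeric(), mu = numeric(), sd = numeric())
    resid_y <- y
    for (k in seq_len(n_components)) {
      i0 <- which.max(resid_y)
      A0 <- max(resid_y[i0], max(y) * 0.05)
      mu0 <- x[i0]
      sd0 <- max(1, diff(range(x)) / (4 * n_components))
      init <- rbind(init, data.frame(A = A0, mu = mu0, sd = sd0))
      resid_y <- pmax(0, resid_y - A0 * exp(-(x - mu0)^2 / (2 * sd0^2)))
    }
  }
  par0 <- as.numeric(t(as.matrix(init[, c("A", "mu", "sd")])))
  model_fun <- function(par) {
    m <- matrix(par, ncol = 3L, byrow = TRUE)
    Reduce(`+`, lapply(seq_len(nrow(m)), function(i)
      m[i, 1L] * exp(-(x - m[i, 2L])^2 / (2 * m[i, 3L]^2))))
  }
  fit <- try(minpack.lm::nls.lm(
    par = par0,
    fn = function(par) y - model_fun(abs_par(par)),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("Gaussian deconvolution failed: ", attr(fit, "condition")$message)
  if (fit$info == 0L)
    stop("Gaussian deconvolution did not converge; residual norm ",
         signif(sqrt(fit$deviance), 4))
  par <- abs_par(fit$par)
  comps <- as.data.frame(matrix(par, ncol = 3L, byrow = TRUE))
  names(comps) <- c("A", "mu", "sd")
  comps <- comps[order(comps$mu), , drop = FALSE]
  rownames(comps) <- NULL
  mass <- comps$A * comps$sd
  comps$mixing_fraction <- mass / sum(mass)
  list(components = comps, fitted = model_fun(par), rss = fit$deviance)
}

# amplitudes and sds are sign-free in the Gaussian model; fold the
# optimizer's parameters back to the positive branch
abs_par <- function(par) {
  m <- matrix(par, ncol = 3L, byrow = TRUE)
  m[, 1L] <- abs(m[, 1L]); m[, 3L] <- pmax(abs(m[, 3L]), 1e-6)
  as.numeric(t(m))
}

#' Deconvolve a peak across a complex's subunits
#'
#' Applies [gaussian_deconvolve()] to each subunit's trace over the same
#' fraction range and summarizes the minor-component mixing fraction as
#' mean and sd across subunits.
#'
#' @param tm a `sec_traces`.
#' @param subunits analyte ids to deconvolve.
#' @param range integer fraction range `c(from, to)`.
#' @param n_components number of Gaussians (default 2).
#' @return List with `per_subunit` (`data.frame(analyte_id,
#'   fraction_comp2)`), `mean_fraction`, `sd_fraction`.
#' @export
deconvolve_subunits <- function(tm, subunits, range, n_components = 2L) {
  stopifnot(inherits(tm, "sec_traces"))
  cols <- which(tm$fractions >= range[1L] & tm$fractions <= range[2L])
  fr2 <- vapply(subunits, function(id) {
    fit <- gaussian_deconvolve(tm$intensity[id, cols],
                               tm$fractions[cols], n_components)
    fit$components$mixing_fraction[n_components]
  }, 0)
  list(per_subunit = data.frame(analyte_id = subunits,
                                fraction_comp2 = unname(fr2)),
       mean_fraction = mean(fr2), sd_fraction = sd(fr2))
}
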