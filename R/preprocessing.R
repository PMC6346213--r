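#' Statistical configuration for decoy-based filtering
#'
#' @param fdr_cutoff target protein-level FDR for the sibling-correlation
#'   filter (proportion in (0,1]).
#' @param fft fraction of false targets: the estimated proportion of
#'   queried target proteins absent from the sample, used to scale
#'   decoy-counting FDR estimates. Supplied by the user from an upstream
#'   estimate (for the HEK293 SEC-SWATH study this was 0.5257861); the
#'   conservative default is 1.
#' @param lambda tuning constant of the Storey pi0 estimate.
#' @return A `stat_config` list.
#' @export
stat_config <- function(fdr_cutoff = 0.01, fft = 1, lambda = 0.5) {
  for (v in c(fdr_cutoff, fft, lambda))
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop("stat_config values must lie in (0, 1]")
  structure(list(fdr_cutoff = fdr_cutoff, fft = fft, lambda = lambda),
            class = "stat_config")
}

#' Zero out short identification stretches
#'
#' SEC elution peaks span several fractions; isolated detections in fewer
#' than `min_len` consecutive fractions are most likely false transfers
#' and are removed. Within each trace, every maximal run of consecutive
#' non-zero fractions shorter than `min_len` is set to zero; analytes left
#' all-zero are dropped. The operation is idempotent.
#'
#' @param tm a peptide-level `sec_traces`.
#' @param min_len minimum retained stretch length in fractions (default 3).
#' @return Filtered `sec_traces`.
#' @export
filter_consecutive_stretches <- function(tm, min_len = 3L) {
  stopifnot(inherits(tm, "sec_traces"))
  if (min_len < 1L) stop("min_len must be >= 1")
  if (min_len > 1L) {
    mat <- tm$intensity
    for (i in seq_len(nrow(mat))) {
      r <- rle(mat[i, ] > 0)
      kill <- r$values & r$lengths < min_len
      if (any(kill)) {
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (j in which(kill)) mat[i, starts[j]:ends[j]] <- 0
      }
    }
    tm$intensity <- mat
  }
  keep <- rowSums(tm$intensity) > 0
  if (!all(keep)) tm <- subset_traces(tm, analyte_ids(tm)[keep])
  tm
}

#' Average sibling peptide correlation
#'
#' For each peptide, the mean Pearson correlation of its full trace with
#' the traces of its sibling peptides (other peptides of the same parent
#' protein). A zero-variance trace contributes correlation 0 rather than
#' NaN to the mean. Peptides without siblings get `NA` (they cannot be
#' scored by this criterion).
#'
#' @param tm a peptide-level `sec_traces`.
#' @return Numeric vector of spc values, named by peptide id.
#' @export
sibling_peptide_correlation <- function(tm) {
  stopifnot(inherits(tm, "sec_traces"), tm$level == "peptide")
  ids <- analyte_ids(tm)
  spc <- setNames(rep(NA_real_, length(ids)), ids)
  groups <- split(seq_along(ids), tm$parent_ids)
  for (idx in groups) {
    if (length(idx) < 2L) next
    sub <- t(tm$intensity[idx, , drop = FALSE])
    cc <- suppressWarnings(cor(sub))   # NA where a trace has zero variance
    cc[!is.finite(cc)] <- 0
    diag(cc) <- NA
    spc[idx] <- rowMeans(t(cc), na.rm = TRUE)
  }
  spc
}

#' Filter peptides by sibling correlation at a target protein FDR
#'
#' Scans candidate spc thresholds (the observed spc values) and, for each
#' threshold t, counts target and decoy proteins retaining at least one
#' peptide with spc >= t. The estimated protein-level FDR at t is
#' `fft * D(t) / T(t)`. Raw decoy/target ratios are made monotone by a
#' cumulative minimum from high to low threshold so that "the smallest
#' threshold achieving FDR <= cutoff" is well defined. Peptides below the
#' chosen threshold and all decoy peptides are removed from the returned
#' matrix; peptides without a sibling (spc undefined) pass through the
#' filter but never count toward a protein's passing status.
#'
#' @param tm a peptide-level `sec_traces` containing decoy peptides.
#' @param cfg a [stat_config()]; uses `fdr_cutoff` and `fft`.
#' @return List with `traces` (filtered, decoy-free), `threshold` (chosen
#'   spc cutoff), and `fdr_table` (threshold, target/decoy counts, raw and
#'   monotone FDR).
#' @export
filter_by_sibling_correlation <- function(tm, cfg = stat_config()) {
  stopifnot(inherits(tm, "sec_traces"), tm$level == "peptide")
  if (!any(tm$is_decoy))
    stop("no decoy peptides present; decoy-based protein FDR control ",
         "requires importing with keep_decoys = TRUE")
  spc <- sibling_peptide_correlation(tm)
  scored <- !is.na(spc)
  thresholds <- sort(unique(spc[scored]))
  prot <- tm$parent_ids
  dec <- tm$is_decoy
  n_t <- integer(length(thresholds)); n_d <- integer(length(thresholds))
  for (k in seq_along(thresholds)) {
    pass <- scored & spc >= thresholds[k]
    n_t[k] <- length(unique(prot[pass & !dec]))
    n_d[k] <- length(unique(prot[pass & dec]))
  }
  raw_fdr <- cfg$fft * n_d / pmax(1L, n_t)
  # enforce monotone non-increasing FDR toward higher thresholds
  mono_fdr <- rev(cummin(rev(raw_fdr)))
  ok <- which(mono_fdr <= cfg$fdr_cutoff)
  tab <- data.frame(threshold = thresholds, n_target = n_t, n_decoy = n_d,
                    fdr_raw = raw_fdr, fdr = mono_fdr)
  if (length(ok) == 0L)
    stop(sprintf(
      "no spc threshold achieves FDR <= %g (best achievable: %.4g)",
      cfg$fdr_cutoff, min(mono_fdr)))
  thr <- thresholds[min(ok)]
  keep <- !tm$is_decoy & (!scored | spc >= thr)
  out <- subset_traces(tm, analyte_ids(tm)[keep])
  list(traces = out, threshold = thr, fdr_table = tab)
}

#' Infer protein traces by top-N peptide summation
#'
#' Per protein, proteotypic peptides are ranked by their total intensity
#' across all fractions (ties broken by peptide id for order
#' independence), and the protein trace is the fraction-wise sum of the
#' top `top_n` peptides. The peptide selection is recorded so that a
#' replicate run can be quantified from the same peptides.
#'
#' @param tm a filtered peptide-level `sec_traces`.
#' @param top_n number of peptides summed per protein (default 2).
#' @param keep_less keep proteins with fewer than `top_n` peptides (summing
#'   what is there)? Default `FALSE`: such proteins are dropped.
#' @param rm_decoys drop decoy peptides before quantification (default
#'   `TRUE`).
#' @param peptide_selection optional `data.frame(protein_id, peptide_id)`
#'   from a previous run; when given, exactly these peptides are summed
#'   (proteins whose recorded peptides are absent are dropped).
#' @return A protein-level `sec_traces`; the selection used is stored in
#'   the `peptides_used` attribute.
#' @export
infer_protein_traces <- function(tm, top_n = 2L, keep_less = FALSE,
                                 rm_decoys = TRUE,
                                 peptide_selection = NULL) {
  stopifnot(inherits(tm, "sec_traces"), tm$level == "peptide")
  if (top_n < 1L) stop("top_n must be >= 1")
  if (rm_decoys && any(tm$is_decoy))
    tm <- subset_traces(tm, analyte_ids(tm)[!tm$is_decoy])
  totals <- rowSums(tm$intensity)
  ids <- analyte_ids(tm)
  if (is.null(peptide_selection)) {
    ord <- order(tm$parent_ids, -totals, ids)
    dt <- data.table(protein_id = tm$parent_ids[ord], peptide_id = ids[ord])
    rank_in_prot <- NULL
    dt[, rank_in_prot := seq_len(.N), by = "protein_id"]
    n_pep <- dt[, list(n = .N), by = "protein_id"]
    sel <- dt[dt$rank_in_prot <= top_n]
    if (!keep_less) {
      full <- n_pep$protein_id[n_pep$n >= top_n]
      sel <- sel[sel$protein_id %in% full]
    }
  } else {
    sel <- as.data.table(as.data.frame(peptide_selection))
    sel <- sel[sel$peptide_id %in% ids]
    cnt <- sel[, list(n = .N), by = "protein_id"]
    orig <- as.data.table(as.data.frame(peptide_selection))[
      , list(n0 = .N), by = "protein_id"]
    ok <- merge(cnt, orig, by = "protein_id")
    sel <- sel[sel$protein_id %in% ok$protein_id[ok$n == ok$n0]]
  }
  if (nrow(sel) == 0L) stop("no proteins quantifiable with these settings")
  prots <- sort(unique(sel$protein_id))
  mat <- matrix(0, length(prots), ncol(tm$intensity),
                dimnames = list(prots, colnames(tm$intensity)))
  pi_idx <- match(sel$protein_id, prots)
  pe_idx <- match(sel$peptide_id, ids)
  for (k in seq_len(nrow(sel)))
    mat[pi_idx[k], ] <- mat[pi_idx[k], ] + tm$intensity[pe_idx[k], ]
  ann <- NULL
  if (!is.null(tm$annotations)) {
    # peptide annotations describe the parent protein: take any peptide's row
    first_pep <- ids[match(prots, tm$parent_ids)]
    a <- tm$annotations[match(first_pep, tm$annotations$analyte_id), ]
    ann <- data.frame(analyte_id = prots,
                      protein_mw_kda = a$protein_mw_kda,
                      gene_name = a$gene_name, stringsAsFactors = FALSE)
  }
  out <- sec_traces(mat, level = "protein", parent_ids = prots,
                    fractions = tm$fractions, annotations = ann,
                    fraction_mw = tm$fraction_mw)
  attr(out, "peptides_used") <- as.data.frame(
    sel[, c("protein_id", "peptide_id")])
  out
}
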