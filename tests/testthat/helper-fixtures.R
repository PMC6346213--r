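# in-code fixtures shared across test files

# tiny trace matrix from a plain numeric matrix
toy_traces <- function(mat, level = "peptide", parents = NULL,
                       decoy = NULL) {
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("a", seq_len(nrow(mat)))
  if (is.null(parents))
    parents <- if (level == "protein") rownames(mat)
               else rep("prot1", nrow(mat))
  if (is.null(decoy)) decoy <- rep(FALSE, nrow(mat))
  sec_traces(mat, level = level, parent_ids = parents, is_decoy = decoy)
}

# gaussian elution trace on an n-fraction axis
gauss_trace <- function(n, apex, sd = 2, height = 100) {
  height * exp(-(seq_len(n) - apex)^2 / (2 * sd^2))
}

# a strictly positive random matrix (no zeros: perturbation is identity)
positive_traces <- function(n_analytes, n_fractions, seed,
                            level = "peptide") {
  set.seed(seed)
  mat <- matrix(runif(n_analytes * n_fractions, 0.1, 10),
                n_analytes, n_fractions,
                dimnames = list(paste0("a", seq_len(n_analytes)), NULL))
  toy_traces(mat, level = level)
}

# one small simulated dataset run through the preprocessing stages,
# computed once per session
small_pipeline_input <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sim <- simulate_dataset(simulation_params(n_complexes = 15), seed = 42)
    tm <- import_long_table(sim$long_table, sim$fraction_map)
    tm <- filter_consecutive_stretches(tm, 3)
    sib <- filter_by_sibling_correlation(tm, stat_config())
    tm2 <- suppressWarnings(annotate_traces(sib$traces, sim$annotations))
    cal <- fit_calibration(sim$standards)
    tmp <- infer_protein_traces(annotate_fraction_mw(tm2, cal))
    cache <<- list(sim = sim, peptide = tm2, protein = tmp, cal = cal)
    cache
  }
})

# one full simulate -> detect -> score run for a given seed; used by the
# error-control and sensitivity checks
run_detection_cycle <- function(seed, n_complexes = 50, n_null = 50) {
  sim <- simulate_dataset(simulation_params(n_complexes = n_complexes),
                          seed = seed)
  tm <- import_long_table(sim$long_table, sim$fraction_map)
  tm <- filter_consecutive_stretches(tm, 3)
  sib <- filter_by_sibling_correlation(tm, stat_config())
  tm2 <- suppressWarnings(annotate_traces(sib$traces, sim$annotations))
  cal <- fit_calibration(sim$standards)
  tmp <- infer_protein_traces(annotate_fraction_mw(tm2, cal))
  tgt <- queries_from_truth(sim$truth)
  nulls <- simulate_null_queries(sim$truth, n_null, seed = seed + 1000L)
  all_t <- rbind(tgt, nulls, fill = TRUE)
  dec <- generate_decoys(all_t, sim$network, 2, seed = seed + 2000L)
  feats <- find_features(tmp, rbind(all_t, dec, fill = TRUE),
                         detection_params(), cal)
  mono <- stats::setNames(tmp$annotations$protein_mw_kda,
                          tmp$annotations$analyte_id)
  known <- !vapply(feats$subunits, function(s) any(is.na(mono[s])), TRUE)
  feats <- filter_features(feats[known], mono, 2)
  best <- best_feature_per_query(feats)
  best$score <- coelution_score(best)
  tsc <- query_scores(all_t$query_id, best)
  dsc <- query_scores(dec$query_id, best)
  sq <- estimate_qvalues(tsc, dsc)
  tab <- data.frame(query_id = all_t$query_id, q = sq$table$q)
  reported <- tab$query_id[tab$q <= 0.05]
  observable <- rownames(tmp$intensity)
  rec <- 0L; tot <- 0L
  for (cx in sim$truth$complexes) {
    if (sum(cx$subunits %in% observable) < 3L) next
    tot <- tot + 1L
    if (cx$complex_id %in% reported) {
      ap <- best$apex[best$query_id == cx$complex_id][1L]
      if (abs(ap - cx$apex) <= 2) rec <- rec + 1L
    }
  }
  list(n_reported = length(reported),
       n_false = sum(grepl("^NULL_", reported)),
       recall_num = rec, recall_den = tot,
       best = best, sim = sim)
}

# error-control/sensitivity runs are shared between two acceptance
# checks; memoise by seed
detection_cycles <- local({
  cache <- list()
  function(seeds) {
    for (s in as.character(seeds))
      if (is.null(cache[[s]]))
        cache[[s]] <<- run_detection_cycle(as.integer(s))
    cache[as.character(seeds)]
  }
})
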