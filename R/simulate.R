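#' Simulation parameters for synthetic co-fractionation data
#'
#' Defines the generative model of a ground-truthed SEC co-fractionation
#' experiment: protein complexes elute as Gaussian peaks at the fraction
#' corresponding to their summed subunit mass under the log-linear size
#' calibration; each protein is observed through several peptides whose
#' intensities scale the protein profile by a peptide-specific
#' ionization efficiency ("flyability") and multiplicative log-normal
#' noise, with intensities below a detection threshold dropping out.
#'
#' @param n_fractions SEC fractions (default 81).
#' @param n_complexes number of true complexes (default 50).
#' @param size_range complex size range, drawn uniformly (default 2..8).
#' @param mw_meanlog,mw_sdlog log-normal monomer mass, kDa (median 60).
#' @param calib_slope,calib_intercept generating log-linear calibration,
#'   ln(kDa) per fraction and ln(kDa); the defaults span roughly 5 MDa at
#'   fraction 1 to 10 kDa at fraction 81.
#' @param peak_sd elution peak sd in fractions (default 1.5).
#' @param peptides_mean Poisson mean peptides per protein (min 1).
#' @param flyability_sdlog log-normal sd of the peptide flyability factor.
#' @param abundance_meanlog,abundance_sdlog log-normal complex abundance
#'   (apex intensity of the protein profile).
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal intensity noise (default 0.15).
#' @param dropout_threshold intensities below this are set to zero
#'   (default 1000; 0 disables dropout).
#' @param monomer_extra_rate fraction of complex subunits that also show
#'   a monomer elution peak.
#' @param monomer_abundance_factor monomer peak height relative to the
#'   complex abundance.
#' @param null_rate fraction of all proteins that are monomer-only
#'   ("null" proteins outside any complex).
#' @param shared_subunit_rate probability that a complex donates one
#'   subunit to a second complex (moonlighting).
#' @param subcomplex_rate probability that a complex additionally elutes
#'   a smaller sub-complex of its subunits at the sub-complex mass.
#' @param stoich2_rate probability that a subunit is present in two
#'   copies instead of one.
#' @param decoy_protein_rate decoy proteins (uncorrelated noise peptides,
#'   flagged as upstream decoys) emitted relative to the target protein
#'   count; required by the decoy-based protein FDR filter.
#' @param extra_edge_rate random extra network edges relative to the
#'   number of true co-complex edges.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_fractions = 81L, n_complexes = 50L,
                              size_range = c(2L, 8L),
                              mw_meanlog = log(60), mw_sdlog = 0.4,
                              calib_slope = -0.0778,
                              calib_intercept = 8.6,
                              peak_sd = 1.5, peptides_mean = 6,
                              flyability_sdlog = 0.8,
                              abundance_meanlog = log(1e6),
                              abundance_sdlog = 0.8,
                              noise_cv = 0.15, dropout_threshold = 1000,
                              monomer_extra_rate = 0.5,
                              monomer_abundance_factor = 0.5,
                              null_rate = 0.3,
                              shared_subunit_rate = 0.1,
                              subcomplex_rate = 0.1,
                              stoich2_rate = 0.2,
                              decoy_protein_rate = 0.2,
                              extra_edge_rate = 0.2) {
  if (n_fractions < 10L) stop("n_fractions must be >= 10")
  rates <- c(monomer_extra_rate, null_rate, shared_subunit_rate,
             subcomplex_rate, stoich2_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(as.list(environment()), class = "simulation_params")
}

gauss_peak <- function(fr, apex, sd, height) {
  height * exp(-(fr - apex)^2 / (2 * sd^2))
}

#' Simulate a ground-truthed co-fractionation dataset
#'
#' Generates complexes, monomer peaks, peptide-level noisy traces with
#' dropout, an interaction network containing all true co-complex edges
#' plus random extras, noiseless calibration standards, and the matching
#' protein annotation and fraction-map tables — everything the pipeline
#' reads, byte-reproducible under the seed.
#'
#' @param params a [simulation_params()].
#' @param seed integer seed.
#' @return List with `long_table` (import-format rows), `truth`
#'   (complexes with subunits, stoichiometry, true apex, abundance;
#'   per-protein monomer peaks; membership map), `network` (`igraph`),
#'   `standards`, `annotations`, `fraction_map`, and `calibration` (the
#'   generating model).
#' @export
simulate_dataset <- function(params = simulation_params(), seed = 1L) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(seed)
  p <- params
  fr <- seq_len(p$n_fractions)
  gen_cal <- structure(list(slope = p$calib_slope,
                            intercept = p$calib_intercept,
                            n_standards = 0L, rmse = 0),
                       class = "calibration_model")

  # --- complexes and their proteins -------------------------------------
  sizes <- sample(p$size_range[1L]:p$size_range[2L], p$n_complexes,
                  replace = TRUE)
  n_complex_prot <- sum(sizes)
  n_null <- round(p$null_rate / (1 - p$null_rate) * n_complex_prot)
  all_prot <- sprintf("P%04d", seq_len(n_complex_prot + n_null))
  prot_mw <- setNames(rlnorm(length(all_prot), p$mw_meanlog, p$mw_sdlog),
                      all_prot)
  cplx_members <- split(all_prot[seq_len(n_complex_prot)],
                        rep(seq_len(p$n_complexes), sizes))
  # moonlighting: a complex donates one subunit to another complex
  for (i in seq_len(p$n_complexes)) {
    if (p$n_complexes > 1L && runif(1) < p$shared_subunit_rate) {
      j <- sample(setdiff(seq_len(p$n_complexes), i), 1L)
      donor <- sample(cplx_members[[i]], 1L)
      cplx_members[[j]] <- sort(unique(c(cplx_members[[j]], donor)))
    }
  }
  complexes <- vector("list", p$n_complexes)
  for (i in seq_len(p$n_complexes)) {
    members <- cplx_members[[i]]
    stoich <- setNames(1L + (runif(length(members)) < p$stoich2_rate),
                       members)
    mw <- sum(stoich * prot_mw[members])
    apex0 <- mw_to_fraction(gen_cal, mw)
    apex <- apex0 + runif(1, -0.5, 0.5)
    clipped <- FALSE
    if (apex < 2 || apex > p$n_fractions - 1) {
      apex <- min(max(apex, 2), p$n_fractions - 1)
      clipped <- TRUE
    }
    if (clipped)
      warning("complex ", i, " apex clipped to the fraction range")
    complexes[[i]] <- list(
      complex_id = sprintf("C%03d", i), subunits = members,
      stoichiometry = stoich, mw_kda = mw, apex = apex,
      abundance = rlnorm(1, p$abundance_meanlog, p$abundance_sdlog),
      subcomplex = NULL)
    if (length(members) >= 3L && runif(1) < p$subcomplex_rate) {
      sub <- sort(sample(members, sample(2:(length(members) - 1L), 1L)))
      sub_mw <- sum(stoich[sub] * prot_mw[sub])
      complexes[[i]]$subcomplex <- list(
        subunits = sub,
        apex = mw_to_fraction(gen_cal, sub_mw),
        abundance = complexes[[i]]$abundance * 0.5)
    }
  }

  # --- per-protein elution profiles -------------------------------------
  profile <- matrix(0, length(all_prot), p$n_fractions,
                    dimnames = list(all_prot, fr))
  for (cx in complexes) {
    for (m in cx$subunits)
      profile[m, ] <- profile[m, ] +
        gauss_peak(fr, cx$apex, p$peak_sd,
                   cx$abundance * cx$stoichiometry[m])
    if (!is.null(cx$subcomplex))
      for (m in cx$subcomplex$subunits)
        profile[m, ] <- profile[m, ] +
          gauss_peak(fr, cx$subcomplex$apex, p$peak_sd,
                     cx$subcomplex$abundance)
  }
  in_complex <- all_prot %in% unlist(lapply(complexes, `[[`, "subunits"))
  monomer_peaks <- list()
  for (pr in all_prot) {
    is_member <- in_complex[match(pr, all_prot)]
    add_mono <- if (is_member) runif(1) < p$monomer_extra_rate else TRUE
    if (add_mono) {
      m_apex <- mw_to_fraction(gen_cal, prot_mw[pr])
      m_apex <- min(max(m_apex, 2), p$n_fractions - 1)
      m_ab <- if (is_member)
        p$monomer_abundance_factor *
          rlnorm(1, p$abundance_meanlog, p$abundance_sdlog)
      else rlnorm(1, p$abundance_meanlog, p$abundance_sdlog)
      profile[pr, ] <- profile[pr, ] + gauss_peak(fr, m_apex, p$peak_sd, m_ab)
      monomer_peaks[[pr]] <- m_apex
    }
  }

  # --- peptide observation layer ----------------------------------------
  sdlog_noise <- sqrt(log(1 + p$noise_cv^2))
  rows <- list()
  for (pr in all_prot) {
    n_pep <- max(1L, rpois(1L, p$peptides_mean))
    fly <- rlnorm(n_pep, 0, p$flyability_sdlog)
    for (k in seq_len(n_pep)) {
      noise <- if (p$noise_cv > 0) rlnorm(p$n_fractions, 0, sdlog_noise)
               else rep(1, p$n_fractions)
      val <- profile[pr, ] * fly[k] * noise
      val[val < p$dropout_threshold] <- 0
      nz <- which(val > 0)
      if (length(nz) == 0L) next
      rows[[length(rows) + 1L]] <- data.table(
        peptide_id = sprintf("%s_pep%02d", pr, k), protein_id = pr,
        fraction = nz, intensity = val[nz], decoy = FALSE)
    }
  }
  # decoy proteins: peptides are mutually uncorrelated noise peaks
  n_decoy <- round(p$decoy_protein_rate * length(all_prot))
  for (dn in seq_len(n_decoy)) {
    pr <- sprintf("DECOY_P%04d", dn)
    n_pep <- max(1L, rpois(1L, p$peptides_mean))
    for (k in seq_len(n_pep)) {
      apex <- runif(1, 2, p$n_fractions - 1)
      ab <- rlnorm(1, p$abundance_meanlog, p$abundance_sdlog)
      val <- gauss_peak(fr, apex, p$peak_sd, ab) *
        rlnorm(p$n_fractions, 0, max(sdlog_noise, 0.1))
      val[val < p$dropout_threshold] <- 0
      nz <- which(val > 0)
      if (length(nz) == 0L) next
      rows[[length(rows) + 1L]] <- data.table(
        peptide_id = sprintf("%s_pep%02d", pr, k), protein_id = pr,
        fraction = nz, intensity = val[nz], decoy = TRUE)
    }
  }
  long <- rbindlist(rows)
  long$run_id <- sprintf("run_%03d", long$fraction)
  fraction_map <- data.frame(run_id = sprintf("run_%03d", fr),
                             fraction_number = fr)
  long <- long[, c("peptide_id", "protein_id", "run_id", "intensity",
                   "decoy")]

  # --- network: true co-complex edges plus random extras ----------------
  true_edges <- unique(rbindlist(lapply(complexes, function(cx) {
    pr <- t(utils::combn(sort(cx$subunits), 2L))
    data.table(protein_a = pr[, 1L], protein_b = pr[, 2L])
  })))
  n_extra <- round(p$extra_edge_rate * nrow(true_edges))
  extra <- data.table(protein_a = sample(all_prot, n_extra, replace = TRUE),
                      protein_b = sample(all_prot, n_extra, replace = TRUE))
  extra <- extra[extra$protein_a != extra$protein_b]
  network <- build_network(rbind(true_edges, extra))

  # --- standards, annotations -------------------------------------------
  std_mw <- c(5000, 2000, 1000, 500, 250, 120, 60, 25, 12)
  standards <- data.frame(std_weights_kda = std_mw,
                          std_elu_fractions = mw_to_fraction(gen_cal, std_mw))
  annotations <- data.frame(protein_id = all_prot,
                            protein_mw_kda = unname(prot_mw),
                            gene_name = all_prot,
                            stringsAsFactors = FALSE)
  membership <- lapply(setNames(all_prot, all_prot), function(pr)
    which(vapply(complexes, function(cx) pr %in% cx$subunits, TRUE)))
  truth <- list(complexes = complexes, monomer_peaks = monomer_peaks,
                membership = membership, protein_mw = prot_mw,
                in_complex = setNames(in_complex, all_prot))
  list(long_table = long[], truth = truth, network = network,
       standards = standards, annotations = annotations,
       fraction_map = fraction_map, calibration = gen_cal)
}

#' Guaranteed-false complex queries from the simulation truth
#'
#' Samples protein sets in which no pair shares membership in any true
#' complex — queries that are false by construction, for measuring the
#' empirical false discovery proportion of the pipeline. Sizes are drawn
#' from the true complex size distribution (size-matched null).
#'
#' @param truth the `truth` element of [simulate_dataset()].
#' @param n number of null queries.
#' @param seed integer seed.
#' @param max_tries sampling attempts per query member.
#' @return A `complex_queries` table with `source = "null"`.
#' @export
simulate_null_queries <- function(truth, n, seed = 1L, max_tries = 200L) {
  set.seed(seed)
  prots <- names(truth$membership)
  sizes_pool <- vapply(truth$complexes, function(cx)
    length(cx$subunits), 0L)
  subs <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(sizes_pool, 1L)
    members <- sample(prots, 1L)
    tries <- 0L
    while (length(members) < k && tries < max_tries) {
      tries <- tries + 1L
      cand <- sample(setdiff(prots, members), 1L)
      shares <- any(vapply(members, function(m)
        length(intersect(truth$membership[[m]],
                         truth$membership[[cand]])) > 0L, TRUE))
      if (!shares) members <- c(members, cand)
    }
    subs[[i]] <- sort(members)
  }
  new_query_table(sprintf("NULL_%03d", seq_len(n)),
                  sprintf("NULL_%03d", seq_len(n)),
                  subs, rep(FALSE, n), rep("null", n))
}

#' True complexes as a query table
#'
#' @param truth the `truth` element of [simulate_dataset()].
#' @return A `complex_queries` table of the simulated complexes.
#' @export
queries_from_truth <- function(truth) {
  ids <- vapply(truth$complexes, `[[`, "", "complex_id")
  subs <- lapply(truth$complexes, function(cx) sort(cx$subunits))
  new_query_table(ids, ids, subs, rep(FALSE, length(ids)),
                  rep("truth", length(ids)))
}
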