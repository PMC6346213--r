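#' Pipeline configuration
#'
#' Bundles inputs, parameters, stage toggles, and the master seed for
#' [run_pipeline()]. Inputs can be supplied in memory (as the list
#' returned by [simulate_dataset()]) or as TSV paths.
#'
#' @param data optional in-memory dataset: a list with `long_table`,
#'   `fraction_map`, `annotations`, `standards`, and either `network` or
#'   a query table.
#' @param paths optional named list of TSV paths: `long_table`,
#'   `fraction_map`, `annotations`, `standards`, and `complex_table` or
#'   `edge_list`.
#' @param queries optional `complex_queries` table of targets (overrides
#'   query generation from tables/networks).
#' @param out_dir output directory for stage TSVs and the manifest
#'   (`NULL`: nothing written).
#' @param params a [detection_params()].
#' @param stats a [stat_config()] (sibling-filter FDR, FFT, lambda).
#' @param min_stretch_length consecutive-identification filter length.
#' @param top_n peptides summed per protein.
#' @param decoy_min_distance network distance constraint for decoys.
#' @param qvalue_cutoff complex-level q-value cutoff (default 0.05).
#' @param monomer_factor apparent/monomer MW multiple for the feature
#'   filter (0 disables).
#' @param do_sibling_filter,do_variants,do_collapse,do_protein_features
#'   stage toggles.
#' @param seed master seed; stage sub-seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data = NULL, paths = NULL, queries = NULL,
                            out_dir = NULL,
                            params = detection_params(),
                            stats = stat_config(),
                            min_stretch_length = 3L, top_n = 2L,
                            decoy_min_distance = 2L,
                            qvalue_cutoff = 0.05, monomer_factor = 2,
                            do_sibling_filter = TRUE,
                            do_variants = TRUE, do_collapse = TRUE,
                            do_protein_features = TRUE, seed = 1L) {
  if (is.null(data) && is.null(paths))
    stop("either data or paths must be given")
  structure(as.list(environment()), class = "pipeline_config")
}

# stage-specific sub-seed: stable hash of the stage name folded into the
# master seed, kept within 32-bit integer range
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

flatten_features <- function(f) {
  out <- as.data.frame(f[, setdiff(names(f), c("subunits", "areas",
                                               "member_queries")),
                         with = FALSE])
  if ("subunits" %in% names(f))
    out$subunits <- vapply(f$subunits, paste, "", collapse = ";")
  if ("areas" %in% names(f))
    out$areas <- vapply(f$areas, function(a)
      paste(signif(a, 8), collapse = ";"), "")
  if ("member_queries" %in% names(f))
    out$member_queries <- vapply(f$member_queries, paste, "",
                                 collapse = ";")
  out
}

#' Run the full complex-centric analysis pipeline
#'
#' Executes import, SEC-informed filtering, protein quantification,
#' molecular-weight calibration, query and decoy generation, co-elution
#' feature detection, target-decoy scoring, variant extraction, feature
#' collapsing, and protein-centric assembly-state accounting. Every
#' intermediate table is written to `out_dir` (when set) along with a
#' manifest of row counts, parameters, seed, and file checksums.
#'
#' @param config a [pipeline_config()].
#' @return List with the stage outputs: `traces_peptide`,
#'   `traces_protein`, `calibration`, `targets`, `decoys`, `features`,
#'   `scored` (best features with p/q), `pi0`, `variants`, `collapsed`,
#'   `protein_features`, `assembly`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  manifest <- list()
  note <- function(stage, rows) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, rows = rows, stringsAsFactors = FALSE)
  }
  dat <- cfg$data
  if (is.null(dat)) {
    p <- cfg$paths
    dat <- list(
      long_table = read.table(p$long_table, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE),
      fraction_map = read.table(p$fraction_map, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE),
      annotations = read.table(p$annotations, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE),
      standards = read.table(p$standards, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE))
    if (!is.null(p$edge_list))
      dat$network <- build_network(
        read.table(p$edge_list, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE))
    if (!is.null(p$complex_table))
      dat$complex_table <- read.table(p$complex_table, sep = "\t",
                                      header = TRUE,
                                      stringsAsFactors = FALSE)
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  tm <- run_stage("import",
                  import_long_table(dat$long_table, dat$fraction_map,
                                    keep_decoys = TRUE))
  note("import", nrow(tm$intensity))
  tm <- run_stage("stretch_filter",
                  filter_consecutive_stretches(tm, cfg$min_stretch_length))
  note("stretch_filter", nrow(tm$intensity))
  if (cfg$do_sibling_filter) {
    sib <- run_stage("sibling_filter",
                     filter_by_sibling_correlation(tm, cfg$stats))
    tm <- sib$traces
  } else {
    sib <- NULL
    tm <- subset_traces(tm, analyte_ids(tm)[!tm$is_decoy])
  }
  note("sibling_filter", nrow(tm$intensity))
  tm <- run_stage("annotate",
                  suppressWarnings(annotate_traces(tm, dat$annotations)))
  cal <- run_stage("calibrate", fit_calibration(dat$standards))
  tm <- annotate_fraction_mw(tm, cal)
  tmp <- run_stage("quantify",
                   infer_protein_traces(tm, top_n = cfg$top_n))
  note("quantify", nrow(tmp$intensity))

  targets <- cfg$queries
  if (is.null(targets)) {
    if (!is.null(dat$complex_table))
      targets <- run_stage("queries",
                           queries_from_complex_table(dat$complex_table))
    else if (!is.null(dat$network))
      targets <- run_stage("queries", queries_from_network(dat$network))
    else stop("no queries, complex table, or network supplied")
  }
  # intersect queries with quantified proteins (targets and decoys alike)
  note("queries", nrow(targets))
  net <- if (!is.null(dat$network)) dat$network
         else network_from_queries(targets)
  decoys <- run_stage("decoys",
                      generate_decoys(targets, net, cfg$decoy_min_distance,
                                      seed = stage_seed(cfg$seed, "decoys")))
  note("decoys", nrow(decoys))

  qset <- rbind(targets, decoys, fill = TRUE)
  feats <- run_stage("detect", find_features(tmp, qset, cfg$params, cal))
  note("detect", nrow(feats))
  if (cfg$monomer_factor > 0 && nrow(feats) > 0L) {
    mono <- setNames(tmp$annotations$protein_mw_kda,
                     tmp$annotations$analyte_id)
    known <- !vapply(feats$subunits, function(s) any(is.na(mono[s])), TRUE)
    feats <- filter_features(feats[known], mono,
                             min_monomer_distance_factor = cfg$monomer_factor)
    note("mw_filter", nrow(feats))
  }

  scored <- NULL; pi0 <- NA_real_; variants <- NULL; collapsed <- NULL
  if (nrow(feats) > 0L) {
    best <- best_feature_per_query(feats)
    best$score <- coelution_score(best)
    # every query competes; featureless queries score 0
    tsc_all <- query_scores(targets$query_id, best)
    dsc_all <- query_scores(decoys$query_id, best)
    sq <- estimate_qvalues(tsc_all, dsc_all, cfg$stats$lambda)
    tsc <- best[!best$is_decoy]
    qi <- match(tsc$query_id, targets$query_id)
    tsc$p <- sq$table$p[qi]; tsc$q <- sq$table$q[qi]
    pi0 <- sq$pi0
    scored <- tsc
    note("scored", nrow(scored))
    if (cfg$do_variants) {
      variants <- secondary_variant_features(
        feats[!feats$is_decoy],
        data.frame(query_id = tsc$query_id, q = tsc$q),
        q_cutoff = cfg$qvalue_cutoff)
      note("variants", nrow(variants))
    }
    if (cfg$do_collapse) {
      q <- NULL
      conf <- tsc[q <= cfg$qvalue_cutoff]
      collapsed <- collapse_features(conf, rt_height = cfg$params$rt_height)
      note("collapse", nrow(collapsed))
    }
  }

  protein_features <- NULL; assembly <- NULL
  if (cfg$do_protein_features) {
    protein_features <- run_stage("protein_features",
      find_protein_features(tm, cfg$params, cal,
                            seed = stage_seed(cfg$seed, "protein_decoys")))
    note("protein_features", nrow(protein_features))
    if (nrow(protein_features) > 0L)
      assembly <- run_stage("assembly",
        assembly_state_report(protein_features, tmp, cal))
  }

  manifest <- do.call(rbind, manifest)
  manifest$seed <- cfg$seed
  out <- list(traces_peptide = tm, traces_protein = tmp, calibration = cal,
              sibling_filter = sib, targets = targets, decoys = decoys,
              features = feats, scored = scored, pi0 = pi0,
              variants = variants, collapsed = collapsed,
              protein_features = protein_features, assembly = assembly,
              manifest = manifest)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg)
  out
}

write_pipeline_outputs <- function(out, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) return(NULL)
    path <- file.path(cfg$out_dir, paste0(name, ".tsv"))
    df <- if (inherits(x, "data.frame")) flatten_features(as.data.table(x))
          else x
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- c(
    wr(out$features, "features"), wr(out$scored, "scored"),
    wr(out$variants, "variants"), wr(out$collapsed, "collapsed"),
    wr(out$protein_features, "protein_features"))
  write_traces(out$traces_peptide,
               file.path(cfg$out_dir, "traces_peptide.tsv"))
  write_traces(out$traces_protein,
               file.path(cfg$out_dir, "traces_protein.tsv"))
  files <- c(files, file.path(cfg$out_dir, "traces_peptide.tsv"),
             file.path(cfg$out_dir, "traces_protein.tsv"))
  man <- out$manifest
  sums <- tools::md5sum(files)
  man_path <- file.path(cfg$out_dir, "manifest.tsv")
  write.table(man, man_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(file = basename(names(sums)), md5 = unname(sums)),
              file.path(cfg$out_dir, "checksums.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(files)
}
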