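mk_feat <- function(qid, subs, apex, area = 100, corr = 0.9) {
  data.table::data.table(
    query_id = qid, subunits = list(sort(subs)),
    n_subunits = length(subs), completeness = 1, apex = as.integer(apex),
    left_pp = as.integer(apex - 2), right_pp = as.integer(apex + 2),
    peak_corr = corr, total_area = area,
    areas = list(stats::setNames(rep(area / length(subs), length(subs)),
                                 sort(subs))),
    apparent_mw = NA_real_, is_decoy = FALSE)
}

test_that("secondary features require a confident best feature and corr >= 0.5", {
  feats <- rbind(mk_feat("q1", c("A", "B", "C"), 30, corr = 0.99),
                 mk_feat("q1", c("A", "B"), 45, corr = 0.6),
                 mk_feat("q1", c("A", "C"), 50, corr = 0.4),
                 mk_feat("q2", c("X", "Y"), 20, corr = 0.95))
  feats$completeness <- c(1, 0.6, 0.6, 1)
  qtab <- data.frame(query_id = c("q1", "q2"), q = c(0.01, 0.2))
  sec <- secondary_variant_features(feats, qtab)
  expect_equal(nrow(sec), 1L)       # corr 0.4 dropped; q2 not confident
  expect_equal(sec$apex, 45L)
  expect_true(all(sec$secondary))
})

test_that("collapsing merges same-composition signals within the apex gate", {
  # identical composition XYZ found from two parent queries at one apex
  feats <- rbind(mk_feat("WXYZ", c("X", "Y", "Z"), 35),
                 mk_feat("VXYZ", c("X", "Y", "Z"), 35))
  col <- collapse_features(feats)
  expect_equal(nrow(col), 1L)
  expect_identical(col$subunits[[1]], c("X", "Y", "Z"))
  expect_equal(col$apex, 35L)
  expect_identical(col$member_queries[[1]], c("VXYZ", "WXYZ"))
  # same composition far apart in elution: distinct signals
  far <- rbind(mk_feat("q1", c("X", "Y"), 10), mk_feat("q2", c("X", "Y"), 20))
  expect_equal(nrow(collapse_features(far)), 2L)
  # disjoint compositions never merge, even at the same apex
  dis <- rbind(mk_feat("q1", c("A", "B"), 30), mk_feat("q2", c("X", "Y"), 30))
  expect_equal(nrow(collapse_features(dis)), 2L)
})

test_that("collapsing is idempotent and never increases signal count", {
  # features are partial views of six disjoint complexes whose elution
  # peaks are chromatographically separated, as overlapping queries of
  # distinct assemblies produce them
  set.seed(12)
  base <- split(LETTERS[1:24], rep(1:6, each = 4))
  apex0 <- c(10, 18, 26, 34, 42, 50)
  feats <- do.call(rbind, lapply(1:25, function(i) {
    b <- sample(6, 1)
    mk_feat(paste0("q", i),
            sample(base[[b]], sample(3:4, 1)),
            apex0[b] + sample(-1:1, 1), area = runif(1, 10, 100))
  }))
  col1 <- collapse_features(feats)
  expect_lte(nrow(col1), nrow(feats))
  col2 <- collapse_features(col1)
  expect_equal(nrow(col2), nrow(col1))
  expect_identical(col2$subunits, col1$subunits)
  expect_equal(col2$apex, col1$apex)
})

test_that("stoichiometry scan finds minimal-rounding-error integer ratios", {
  expect_equal(unname(estimate_stoichiometry(
    c(a = 100, b = 98, c = 205))$stoichiometry), c(1, 1, 2))
  expect_equal(unname(estimate_stoichiometry(
    c(a = 50, b = 100, c = 150))$stoichiometry), c(1, 2, 3))
  expect_equal(unname(estimate_stoichiometry(
    c(a = 70, b = 70, c = 70))$stoichiometry), c(1, 1, 1))
  expect_equal(unname(estimate_stoichiometry(
    c(a = 100, b = 150))$stoichiometry), c(2, 3))
  expect_error(estimate_stoichiometry(c(a = 0, b = 10)), "positive")
})

test_that("assembly report applies the two-fold rule and conserves mass", {
  n <- 81
  cal <- fit_calibration(data.frame(std_weights_kda = c(3000, 15),
                                    std_elu_fractions = c(5, 75)))
  mat <- rbind(P1 = gauss_trace(n, 30, 2, 1000),  # assembled for 50 kDa
               P2 = gauss_trace(n, 30, 2, 700) + gauss_trace(n, 55, 2, 300),
               P3 = gauss_trace(n, 60, 2, 500))   # near its monomer size
  tm <- toy_traces(mat, level = "protein", parents = rownames(mat))
  tm$annotations <- data.frame(analyte_id = rownames(mat),
                               protein_mw_kda = c(50, 50, 40),
                               gene_name = rownames(mat))
  pf <- data.frame(protein_id = c("P1", "P2", "P2", "P3"),
                   apex = c(30L, 30L, 55L, 60L),
                   left_pp = c(26L, 26L, 51L, 56L),
                   right_pp = c(34L, 34L, 59L, 64L))
  rep_ <- assembly_state_report(pf, tm, cal, factor = 2)
  expect_true(all(rep_$peaks$assembled[rep_$peaks$apex == 30]))
  expect_false(any(rep_$peaks$assembled[rep_$peaks$apex >= 55]))
  st <- setNames(rep_$proteins$state, rep_$proteins$protein_id)
  expect_equal(unname(st[c("P1", "P2", "P3")]),
               c("assembled", "both", "monomer_only"))
  expect_equal(rep_$assembled_mass_fraction +
                 rep_$monomeric_mass_fraction, 1)
  expect_equal(rep_$assembled_protein_fraction, 2 / 3)
  # worked ratio: apparent 150 kDa over monomer 50 kDa -> assembled
  expect_true(150 / 50 >= 2)
  expect_error(assembly_state_report(pf, tm, NULL), "calibration")
})

test_that("two-gaussian deconvolution recovers a 3:1 mixture", {
  x <- 20:44
  fr2 <- numeric(20); mu_err <- matrix(0, 20, 2)
  for (s in 1:20) {
    set.seed(s)
    y <- pmax(3 * exp(-(x - 30)^2 / 8) + exp(-(x - 34)^2 / 8) +
                rnorm(length(x), 0, 0.02), 0)
    fit <- gaussian_deconvolve(y, x)
    fr2[s] <- fit$components$mixing_fraction[2]
    mu_err[s, ] <- abs(fit$components$mu - c(30, 34))
  }
  expect_lt(abs(mean(fr2) - 0.25), 0.05)
  expect_true(all(mu_err <= 0.5))
  # a single clean gaussian: one component takes ~all of the mass
  clean <- gaussian_deconvolve(5 * exp(-(x - 30)^2 / 8), x)
  expect_gte(max(clean$components$mixing_fraction), 0.99)
  expect_error(gaussian_deconvolve(c(1, 2, 1), n_components = 2),
               "too short")
})

test_that("subunit-wise deconvolution summarizes the mixing fraction", {
  n <- 81
  mk <- function(sc) sc * (3 * exp(-((1:n) - 30)^2 / 8) +
                             exp(-((1:n) - 34)^2 / 8))
  tm <- toy_traces(rbind(A = mk(1), B = mk(0.5), C = mk(2)),
                   level = "protein", parents = c("A", "B", "C"))
  dv <- deconvolve_subunits(tm, c("A", "B", "C"), c(20, 44))
  expect_lt(abs(dv$mean_fraction - 0.25), 0.03)
  expect_lt(dv$sd_fraction, 0.02)
})
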