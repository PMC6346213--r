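test_that("zero perturbation fills zeros below the noise quantile, reproducibly", {
  mat <- rbind(a = c(0, 5, 10, 0), b = c(2, 0, 8, 4))
  tm <- toy_traces(mat)
  q <- quantile(c(5, 10, 2, 8, 4), 0.05, names = FALSE)
  p1 <- perturb_zeros(tm, seed = 3)
  p2 <- perturb_zeros(tm, seed = 3)
  expect_identical(p1$intensity, p2$intensity)
  zeros <- mat == 0
  expect_true(all(p1$intensity[zeros] >= 0 & p1$intensity[zeros] <= q))
  expect_identical(p1$intensity[!zeros], mat[!zeros])
  # no zeros -> identity
  tm2 <- toy_traces(mat + 1)
  expect_identical(perturb_zeros(tm2, seed = 1)$intensity, tm2$intensity)
  expect_error(perturb_zeros(toy_traces(matrix(0, 2, 3))), "all-zero")
})

test_that("moving-average smoothing matches a direct convolution oracle", {
  const <- toy_traces(matrix(7, 1, 10))
  expect_equal(unname(smooth_traces(const, 9)$intensity[1, ]), rep(7, 10))
  imp <- toy_traces(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 1))
  expect_equal(unname(smooth_traces(imp, 3)$intensity[1, 4:6]),
               rep(1 / 3, 3))
  set.seed(8)
  x <- runif(25)
  sm <- smooth_traces(toy_traces(matrix(x, 1)), 5)$intensity[1, ]
  oracle <- sapply(1:25, function(i) {
    h <- min(2, i - 1, 25 - i)
    mean(x[(i - h):(i + h)])
  })
  expect_equal(unname(sm), oracle)
})

test_that("co-eluting gaussians yield one complete feature at the right apex", {
  n <- 60
  set.seed(2)
  mat <- rbind(s1 = gauss_trace(n, 20), s2 = gauss_trace(n, 20) * 0.7,
               s3 = gauss_trace(n, 20) * 1.3)
  mat[mat < 1e-3] <- 0
  tm <- toy_traces(mat, level = "protein", parents = rownames(mat))
  q <- queries_from_truth(list(complexes = list(
    list(complex_id = "q1", subunits = c("s1", "s2", "s3")))))
  f <- find_features(tm, q, detection_params(seed = 2))
  expect_equal(nrow(f), 1L)
  expect_equal(f$apex, 20L)
  expect_equal(f$completeness, 1)
  expect_gt(f$peak_corr, 0.99)
  expect_true(f$left_pp <= f$apex && f$apex <= f$right_pp)
})

test_that("a non-co-eluting subunit lowers completeness proportionally", {
  n <- 60
  set.seed(4)
  mat <- rbind(s1 = gauss_trace(n, 30), s2 = gauss_trace(n, 30) * 0.8,
               s3 = gauss_trace(n, 30) * 1.2,
               s4 = runif(n, 0.5, 1.5))
  tm <- toy_traces(mat, level = "protein", parents = rownames(mat))
  q <- queries_from_truth(list(complexes = list(
    list(complex_id = "q1", subunits = c("s1", "s2", "s3", "s4")))))
  f <- best_feature_per_query(find_features(tm, q, detection_params(seed = 4)))
  expect_equal(f$completeness, 0.75)
  expect_identical(f$subunits[[1]], c("s1", "s2", "s3"))
})

test_that("independent random traces rarely produce features at corr 0.95", {
  n_hit <- 0L
  for (s in 1:100) {
    set.seed(s)
    mat <- matrix(runif(5 * 30, 0.1, 10), 5, 30,
                  dimnames = list(paste0("r", 1:5), NULL))
    tm <- toy_traces(mat, level = "protein", parents = rownames(mat))
    q <- queries_from_truth(list(complexes = list(
      list(complex_id = "q", subunits = rownames(mat)))))
    f <- find_features(tm, q, detection_params(window_size = 8, seed = s))
    if (nrow(f) > 0L) n_hit <- n_hit + 1L
  }
  expect_lte(n_hit, 5L)
})

test_that("detection is invariant to subunit order, absent subunits, and scaling", {
  inp <- small_pipeline_input()
  tgt <- queries_from_truth(inp$sim$truth)[1:5]
  f1 <- find_features(inp$protein, tgt, detection_params())
  # permute subunit order and add unobserved subunits
  tgt2 <- data.table::copy(tgt)
  tgt2$subunits <- lapply(tgt2$subunits, function(s)
    c(rev(s), "UNOBSERVED_PROTEIN"))
  f2 <- find_features(inp$protein, tgt2, detection_params())
  expect_equal(f1$apex, f2$apex)
  expect_identical(f1$subunits, f2$subunits)
  expect_equal(f1$completeness, f2$completeness)
  # positive scaling leaves features unchanged (Pearson invariance)
  tm_scaled <- inp$protein
  tm_scaled$intensity <- tm_scaled$intensity * 3.7
  f3 <- find_features(tm_scaled, tgt, detection_params())
  expect_equal(f1$apex, f3$apex)
  expect_equal(f1$peak_corr, f3$peak_corr, tolerance = 1e-12)
  # reported apexes always lie within their boundaries and the axis
  expect_true(all(f1$left_pp <= f1$apex & f1$apex <= f1$right_pp))
  expect_true(all(f1$left_pp >= 1 & f1$right_pp <= 81))
})

test_that("the MW filter keeps only features above the monomer-distance factor", {
  f <- data.table::data.table(
    query_id = c("a", "b"), subunits = list(c("P1", "P2"), c("P1", "P2")),
    n_subunits = 2L, completeness = 1, apex = c(20L, 40L),
    left_pp = c(18L, 38L), right_pp = c(22L, 42L), peak_corr = 0.99,
    total_area = 100, areas = list(c(P1 = 50, P2 = 50)),
    apparent_mw = c(250, 100), is_decoy = FALSE)
  mono <- c(P1 = 50, P2 = 60)
  out <- filter_features(f, mono, 2)
  expect_equal(out$query_id, "a")   # 250 >= 2*60; 100 < 120 removed
  expect_equal(nrow(filter_features(f, mono, 0)), 2L)
  expect_error(filter_features(f, c(P1 = 50), 2), "P2")
})

test_that("best feature ranking prefers completeness, then correlation", {
  f <- data.table::data.table(
    query_id = "q", subunits = list("x", "x", "x"),
    n_subunits = 2L, completeness = c(1, 0.6, 1),
    apex = c(10L, 20L, 30L), left_pp = 1L, right_pp = 40L,
    peak_corr = c(0.8, 0.99, 0.9), total_area = c(5, 5, 5),
    areas = list(1), apparent_mw = NA_real_, is_decoy = FALSE)
  best <- best_feature_per_query(f)
  expect_equal(best$apex, 30L) # completeness 1 beats 0.6; 0.9 beats 0.8
  single <- best_feature_per_query(f[2])
  expect_equal(single$apex, 20L)
})

test_that("protein-centric detection separates distinct elution peaks", {
  n <- 81
  set.seed(6)
  mk <- function(apex, fly) pmax(
    gauss_trace(n, apex, 2, 1000 * fly) * rlnorm(n, 0, 0.1), 0)
  mat <- rbind(
    # protein A elutes twice: fractions 20 and 45
    A_p1 = mk(20, 1) + mk(45, 1), A_p2 = mk(20, 0.8) + mk(45, 0.8),
    A_p3 = mk(20, 1.2) + mk(45, 1.1),
    # protein B elutes once
    B_p1 = mk(60, 1), B_p2 = mk(60, 0.9),
    # fillers for the decoy pool
    C_p1 = mk(33, 1), C_p2 = mk(33, 1.1),
    D_p1 = mk(52, 1), D_p2 = mk(52, 0.7))
  mat[mat < 1] <- 0
  tm <- toy_traces(mat, parents = sub("_p[0-9]$", "", rownames(mat)))
  cal <- fit_calibration(data.frame(std_weights_kda = c(3000, 15),
                                    std_elu_fractions = c(5, 75)))
  tm <- annotate_fraction_mw(tm, cal)
  pf <- find_protein_features(tm, detection_params(seed = 6), cal,
                              qvalue_cutoff = 0.5, seed = 6)
  apexes_A <- sort(pf$apex[pf$protein_id == "A"])
  expect_equal(length(apexes_A), 2L)
  expect_true(abs(apexes_A[1] - 20) <= 1 && abs(apexes_A[2] - 45) <= 1)
})

test_that("label-shuffled peptides yield no confident protein features", {
  n_nonempty <- 0L
  for (s in 1:5) {
    set.seed(s)
    mat <- matrix(runif(12 * 40, 0.5, 5), 12, 40,
                  dimnames = list(paste0("pep", 1:12), NULL))
    tm <- toy_traces(mat, parents = rep(paste0("P", 1:4), each = 3))
    pf <- find_protein_features(tm, detection_params(seed = s),
                                qvalue_cutoff = 0.1, seed = s)
    if (nrow(pf) > 0L) n_nonempty <- n_nonempty + 1L
  }
  expect_lte(n_nonempty, 1L)
})

test_that("the apparent-to-monomer mass ratio is plain arithmetic", {
  inp <- small_pipeline_input()
  pf <- find_protein_features(inp$peptide, detection_params(), inp$cal,
                              qvalue_cutoff = 0.2, seed = 1)
  expect_true(all(abs(pf$mw_ratio - pf$apparent_mw / pf$monomer_mw) < 1e-12))
})
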