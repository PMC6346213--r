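test_that("complex-table queries expand variants, merge duplicates, drop homomers", {
  tab <- data.frame(
    complex_id = c("c1", "c1", "c1", "c2", "c2", "c2", "c3", "c3",
                   "c4", "c4"),
    complex_name = c(rep("alpha", 3), rep("beta", 3), rep("gamma", 2),
                     rep("homo", 2)),
    protein_id = c("A", "B|Bp", "C", "A", "B", "C", "A", "C", "X", "X"),
    stringsAsFactors = FALSE)
  q <- suppressMessages(queries_from_complex_table(tab))
  # c1 expands to {A,B,C} and {A,Bp,C}; c2 == variant 1 of c1 (merged);
  # c3 = {A,C}; c4 homo-oligomer dropped
  expect_equal(nrow(q), 3L)
  sets <- lapply(q$subunits, sort)
  has_set <- function(s) any(vapply(sets, identical, TRUE, s))
  expect_true(has_set(c("A", "B", "C")))
  expect_true(has_set(c("A", "Bp", "C")))
  expect_true(has_set(c("A", "C")))
  merged <- q$name[vapply(sets, identical, TRUE, c("A", "B", "C"))]
  expect_match(merged, "alpha.*beta|beta.*alpha")
  expect_false(any(grepl("homo", q$name)))
})

test_that("shortest path lengths equal a matrix-power reachability oracle", {
  g <- build_network(data.frame(protein_a = c("A", "B"),
                                protein_b = c("B", "C")))
  d <- shortest_path_lengths(g)
  expect_equal(d["A", "C"], 2)
  g2 <- build_network(data.frame(protein_a = c("A", "C"),
                                 protein_b = c("B", "D")))
  expect_equal(shortest_path_lengths(g2)["A", "C"], Inf)
  # random graph vs brute-force boolean matrix powers
  set.seed(21)
  n <- 30
  adj <- matrix(runif(n * n) < 0.08, n, n)
  adj <- adj | t(adj); diag(adj) <- FALSE
  nodes <- sprintf("n%02d", 1:n)
  dimnames(adj) <- list(nodes, nodes)
  ed <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g3 <- build_network(data.frame(protein_a = nodes[ed[, 1]],
                                 protein_b = nodes[ed[, 2]]))
  oracle <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(oracle) <- 0
  reach <- diag(TRUE, n)
  cur <- adj
  for (k in 1:n) {
    newly <- cur & !reach & is.infinite(oracle)
    oracle[newly] <- k
    reach <- reach | cur
    cur <- (cur %*% adj) > 0
  }
  d3 <- shortest_path_lengths(g3)
  present <- rownames(d3)
  expect_equal(d3[present, present], oracle[present, present])
})

test_that("network queries keep maximal neighborhoods only", {
  star <- build_network(data.frame(protein_a = c("A", "B"),
                                   protein_b = c("C", "C")))
  q <- queries_from_network(star)
  expect_equal(nrow(q), 1L)
  expect_equal(q$subunits[[1]], c("A", "B", "C"))
  # clique of 4 -> one query of size 4
  cl <- build_network(data.frame(
    protein_a = c("w", "w", "w", "x", "x", "y"),
    protein_b = c("x", "y", "z", "y", "z", "z")))
  qc <- queries_from_network(cl)
  expect_equal(nrow(qc), 1L)
  expect_equal(lengths(qc$subunits), 4L)
  # edgeless network: no queries
  lone <- igraph::make_empty_graph(3, directed = FALSE)
  lone <- igraph::set_vertex_attr(lone, "name", value = c("a", "b", "c"))
  expect_equal(nrow(queries_from_network(lone)), 0L)
})

test_that("network query output is independent of node iteration order", {
  set.seed(5)
  ed <- data.frame(protein_a = sample(letters[1:12], 20, replace = TRUE),
                   protein_b = sample(letters[1:12], 20, replace = TRUE))
  ed <- ed[ed$protein_a != ed$protein_b, ]
  q1 <- queries_from_network(build_network(ed))
  q2 <- queries_from_network(build_network(ed[rev(seq_len(nrow(ed))), ]))
  key <- function(q) sort(vapply(q$subunits, paste, "", collapse = ";"))
  expect_identical(key(q1), key(q2))
})

test_that("decoys are size-matched, distance-constrained, and reproducible", {
  # path graph A-B-C-D-E
  path_g <- build_network(data.frame(protein_a = c("A", "B", "C", "D"),
                                     protein_b = c("B", "C", "D", "E")))
  d <- shortest_path_lengths(path_g)
  expect_false(d["A", "C"] > 2)  # {A,C} inadmissible at min_distance 2
  expect_true(d["A", "D"] > 2)   # {A,D} admissible
  tgt <- queries_from_truth(list(complexes = list(
    list(complex_id = "t1", subunits = c("A", "B")))))
  dec1 <- suppressWarnings(generate_decoys(tgt, path_g, 2, seed = 9))
  dec2 <- suppressWarnings(generate_decoys(tgt, path_g, 2, seed = 9))
  expect_identical(dec1$subunits, dec2$subunits)
  expect_true(all(dec1$is_decoy))
  # larger run: every non-relaxed decoy respects the constraint, and the
  # fraction of decoy pairs that are direct network edges is ~0
  set.seed(31)
  nodes <- sprintf("p%03d", 1:500)
  ed <- data.frame(protein_a = sample(nodes, 700, replace = TRUE),
                   protein_b = sample(nodes, 700, replace = TRUE))
  g <- build_network(ed[ed$protein_a != ed$protein_b, ])
  sizes <- sample(2:6, 200, replace = TRUE)
  tgt2 <- queries_from_truth(list(complexes = lapply(seq_along(sizes),
    function(i) list(complex_id = paste0("t", i),
                     subunits = sample(igraph::V(g)$name, sizes[i])))))
  dec <- generate_decoys(tgt2, g, 2, seed = 13)
  expect_equal(nrow(dec), nrow(tgt2))
  expect_identical(sort(lengths(dec$subunits)), sort(lengths(tgt2$subunits)))
  dmat <- shortest_path_lengths(g)
  n_edge_pairs <- 0L; n_pairs <- 0L
  for (i in which(!dec$relaxed)) {
    s <- dec$subunits[[i]]
    pd <- dmat[s, s]
    expect_true(all(pd[upper.tri(pd)] > 2))
    n_pairs <- n_pairs + sum(upper.tri(pd))
    n_edge_pairs <- n_edge_pairs + sum(pd[upper.tri(pd)] == 1)
  }
  expect_equal(n_edge_pairs / n_pairs, 0)
})
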