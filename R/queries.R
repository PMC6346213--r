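#' Build a protein interaction network from an edge list
#'
#' @param edges `data.frame` with columns `protein_a`, `protein_b` and
#'   optionally `score` (e.g. a database combined score). Self-loops and
#'   duplicate (undirected) edges are removed.
#' @param min_score optional minimal score; edges below it are dropped.
#' @return An undirected `igraph` graph.
#' @export
build_network <- function(edges, min_score = NULL) {
  edges <- as.data.frame(edges)
  if (!all(c("protein_a", "protein_b") %in% names(edges)))
    stop("edges need columns protein_a, protein_b")
  if (!is.null(min_score)) {
    if (!"score" %in% names(edges))
      stop("min_score given but edges carry no score column")
    edges <- edges[edges$score >= min_score, , drop = FALSE]
  }
  edges <- edges[edges$protein_a != edges$protein_b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b")], directed = FALSE)
  igraph::simplify(g)
}

#' Build a binary network from a set of complex queries
#'
#' Connects every within-complex protein pair; used to compute the
#' connectivity constraint for decoy generation when targets come from a
#' complex table rather than an interaction database.
#'
#' @param queries a query table from [queries_from_complex_table()] or
#'   [queries_from_network()].
#' @return An undirected `igraph` graph.
#' @export
network_from_queries <- function(queries) {
  pairs <- lapply(queries$subunits, function(s) {
    if (length(s) < 2L) return(NULL)
    t(utils::combn(sort(s), 2L))
  })
  pairs <- do.call(rbind, pairs)
  build_network(data.frame(protein_a = pairs[, 1L], protein_b = pairs[, 2L],
                           stringsAsFactors = FALSE))
}

#' All-pairs shortest path lengths (hop counts)
#'
#' Breadth-first hop counts between all node pairs; disconnected pairs are
#' `Inf`.
#'
#' @param network an `igraph` graph.
#' @return Numeric matrix of hop counts with node names on both margins.
#' @export
shortest_path_lengths <- function(network) {
  if (igraph::vcount(network) == 0L) stop("empty network")
  igraph::distances(network, algorithm = "unweighted")
}

new_query_table <- function(query_id, name, subunits, is_decoy, source) {
  dt <- data.table(query_id = query_id, name = name,
                   subunits = subunits, is_decoy = is_decoy,
                   source = source)
  setattr(dt, "class", c("complex_queries", class(dt)))
  dt
}

#' @export
print.complex_queries <- function(x, ...) {
  cat(sprintf("<complex_queries> %d queries (%d decoys), sizes %d-%d\n",
              nrow(x), sum(x$is_decoy),
              min(lengths(x$subunits)), max(lengths(x$subunits))))
  invisible(x)
}

#' Complex queries from a complex annotation table
#'
#' Expands alternative-subunit cells (pipe- or semicolon-delimited, e.g.
#' paralog pairs) by Cartesian product into complex variants suffixed
#' `-1`, `-2`, ...; removes complexes collapsing to a single distinct
#' protein (homo-oligomers); merges entries with identical subunit sets,
#' concatenating their names.
#'
#' @param table `data.frame` with columns `complex_id`, `complex_name`,
#'   `protein_id` (one row per subunit slot; a cell may list alternatives).
#' @param alt_sep characters separating alternative subunits in one cell.
#' @return A `complex_queries` table with columns `query_id`, `name`,
#'   `subunits` (list of character vectors), `is_decoy`, `source`.
#' @export
queries_from_complex_table <- function(table, alt_sep = c("|", ";")) {
  table <- as.data.frame(table)
  need <- c("complex_id", "complex_name", "protein_id")
  if (!all(need %in% names(table)))
    stop("complex table needs columns: ", paste(need, collapse = ", "))
  sep_re <- paste0("[", paste(gsub("([][\\^|-])", "\\\\\\1", alt_sep),
                              collapse = ""), "]")
  ids <- character(); names_ <- character(); subs <- list()
  n_dropped <- 0L
  for (cid in unique(table$complex_id)) {
    rows <- table[table$complex_id == cid, , drop = FALSE]
    cname <- rows$complex_name[1L]
    alts <- strsplit(rows$protein_id, sep_re)
    variants <- Reduce(function(acc, a) {
      unlist(lapply(acc, function(v) lapply(a, function(x) c(v, x))),
             recursive = FALSE)
    }, alts, accumulate = FALSE, init = list(character()))
    variants <- lapply(variants, function(v) sort(unique(v)))
    variants <- unique(variants)
    variants <- Filter(function(v) length(v) >= 2L, variants)
    if (length(variants) == 0L) {
      n_dropped <- n_dropped + 1L
      next
    }
    suffix <- if (length(variants) > 1L)
      paste0("-", seq_along(variants)) else ""
    ids <- c(ids, paste0(cid, suffix))
    names_ <- c(names_, paste0(cname, suffix))
    subs <- c(subs, variants)
  }
  if (n_dropped > 0L)
    message(n_dropped,
            " complex(es) dropped (fewer than 2 distinct subunits)")
  if (length(subs) == 0L)
    return(new_query_table(character(), character(), list(),
                           logical(), character()))
  # merge duplicate subunit sets, concatenating names
  key <- vapply(subs, paste, "", collapse = ";")
  first <- !duplicated(key)
  merged_name <- vapply(key[first], function(k)
    paste(unique(names_[key == k]), collapse = "/"), "")
  new_query_table(ids[first], unname(merged_name), subs[first],
                  rep(FALSE, sum(first)), rep("complex_table", sum(first)))
}

#' Complex queries from an interaction network
#'
#' One candidate query per node: the node plus all nodes within
#' `max_distance` hops. With `redundancy_cutoff = 0` any candidate whose
#' subunit set is contained in (or equal to) another candidate's is
#' removed; among identical sets the candidate seeded by the
#' lexicographically smallest node is kept, making the output independent
#' of node iteration order.
#'
#' @param network an `igraph` graph.
#' @param max_distance hop radius around each seed node (default 1).
#' @param redundancy_cutoff containment tolerance; only 0 (remove exact
#'   subsets/duplicates) is currently implemented.
#' @return A `complex_queries` table.
#' @export
queries_from_network <- function(network, max_distance = 1L,
                                 redundancy_cutoff = 0) {
  if (redundancy_cutoff != 0)
    stop("only redundancy_cutoff = 0 is implemented")
  if (igraph::vcount(network) == 0L)
    return(new_query_table(character(), character(), list(),
                           logical(), character()))
  d <- shortest_path_lengths(network)
  nodes <- sort(rownames(d))
  d <- d[nodes, nodes, drop = FALSE]
  cands <- lapply(nodes, function(v) sort(names(which(d[v, ] <= max_distance))))
  sizes <- lengths(cands)
  keep <- rep(TRUE, length(cands))
  key <- vapply(cands, paste, "", collapse = ";")
  # drop singletons (edgeless nodes) and duplicate sets (keep smallest seed)
  keep[sizes < 2L] <- FALSE
  keep[duplicated(key)] <- FALSE
  for (i in which(keep)) {
    for (j in which(sizes > sizes[i])) {
      if (all(cands[[i]] %in% cands[[j]])) { keep[i] <- FALSE; break }
    }
  }
  idx <- which(keep)
  new_query_table(paste0("net_", nodes[idx]), nodes[idx], cands[idx],
                  rep(FALSE, length(idx)), rep("network", length(idx)))
}

#' Generate network-aware decoy complex queries
#'
#' For every target query, one size-matched decoy is assembled by drawing
#' proteins uniformly without replacement from the network's nodes under
#' the constraint that all pairwise path lengths within the decoy exceed
#' `min_distance` hops. Each member is redrawn up to `n_tries` times
#' before the whole decoy is restarted; after `max_restarts` restarts the
#' constraint is relaxed (a plain random size-matched set is emitted,
#' flagged `relaxed`) so that the 1:1 target:decoy matching is never
#' broken.
#'
#' @param targets a `complex_queries` table of targets.
#' @param network an `igraph` graph defining the sampling universe and the
#'   distance constraint.
#' @param min_distance decoy members must be more than this many hops
#'   apart (2 for curated complex/AP-MS networks, 1 for dense
#'   functional-association networks).
#' @param n_tries redraw attempts per member before restarting the decoy.
#' @param seed integer seed; identical seeds give identical decoy sets.
#' @param max_restarts whole-decoy restarts before relaxing the
#'   constraint.
#' @return A `complex_queries` table of decoys (query ids prefixed
#'   `DECOY_`), with a logical `relaxed` column.
#' @export
generate_decoys <- function(targets, network, min_distance = 2L,
                            n_tries = 3L, seed = 1L, max_restarts = 50L) {
  stopifnot(nrow(targets) >= 1L)
  d <- shortest_path_lengths(network)
  nodes <- rownames(d)
  set.seed(seed)
  ids <- character(nrow(targets)); subs <- vector("list", nrow(targets))
  relaxed <- logical(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    k <- length(targets$subunits[[i]])
    res <- NULL
    for (restart in seq_len(max_restarts)) {
      members <- sample(nodes, 1L)
      ok <- TRUE
      while (length(members) < k) {
        placed <- FALSE
        for (try in seq_len(n_tries)) {
          cand <- sample(setdiff(nodes, members), 1L)
          if (all(d[cand, members] > min_distance)) {
            members <- c(members, cand); placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) { res <- members; break }
    }
    if (is.null(res)) {
      res <- sample(nodes, k)
      relaxed[i] <- TRUE
    }
    ids[i] <- paste0("DECOY_", targets$query_id[i])
    subs[[i]] <- sort(res)
  }
  if (any(relaxed))
    warning(sum(relaxed),
            " decoy(s) emitted with relaxed distance constraint")
  out <- new_query_table(ids, ids, subs, rep(TRUE, nrow(targets)),
                         rep("decoy", nrow(targets)))
  out$relaxed <- relaxed
  out
}
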