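# Chaining significant pairs into a directed trajectory graph, Markov
# clustering of the event graph, per-cluster demographics and DOT export.

#' Build the trajectory graph from significant pairs
#'
#' Keeps pairs carried by at least `min_patients` patients and assembles the
#' directed graph whose nodes are event labels and whose edges carry the
#' patient count, the percentage of the cohort and the resampling-mean RR.
#'
#' @param pairs data frame from [pair_statistics()], already
#'   significance-filtered and direction-selected.
#' @param min_patients minimum `n_patients` per edge.
#' @param cohort_size total cohort size used for edge percentages.
#' @param window optional [time_range()] annotation.
#' @return list of class `ptra_graph`: `nodes`, `edges` (with a `patients`
#'   list-column when present in `pairs`), `min_patients`, `cohort_size`,
#'   `window`.
#' @export
build_graph <- function(pairs, min_patients, cohort_size, window = NULL) {
  keep <- !is.na(pairs$n_patients) & pairs$n_patients >= min_patients
  edges <- pairs[keep, , drop = FALSE]
  cols <- c("event_a", "event_b", "n_patients", "rr_mean")
  stopifnot(all(cols %in% names(edges)))
  edges$pct <- 100 * edges$n_patients / cohort_size
  rownames(edges) <- NULL
  structure(list(
    nodes = sort(unique(c(edges$event_a, edges$event_b))),
    edges = edges,
    min_patients = as.integer(min_patients),
    cohort_size = as.integer(cohort_size),
    window = window
  ), class = "ptra_graph")
}

#' @export
print.ptra_graph <- function(x, ...) {
  cat(sprintf("<ptra_graph> %d nodes, %d edges (min %d patients/edge)\n",
              length(x$nodes), nrow(x$edges), x$min_patients))
  invisible(x)
}

#' Markov clustering parameters
#'
#' @param expansion matrix-power of the expansion step (integer >= 2).
#' @param inflation entrywise power of the inflation step (> 1); larger
#'   values give finer clusters. 2.0 is the customary default.
#' @param max_iter iteration cap before a non-convergence error.
#' @param convergence_tol maximum absolute change between successive iterates
#'   that counts as converged.
#' @param edge_weight edge weighting of the flow matrix: patient counts
#'   (default), RR, or unit weights.
#' @param prune entries below this are zeroed after each inflation (numeric
#'   hygiene only).
#' @return list of class `ptra_mcl_params`.
#' @export
mcl_params <- function(expansion = 2L, inflation = 2.0, max_iter = 100L,
                       convergence_tol = 1e-8,
                       edge_weight = c("n_patients", "rr", "unit"),
                       prune = 1e-10) {
  stopifnot(expansion >= 2L, inflation > 1, max_iter >= 1L,
            convergence_tol > 0)
  structure(list(
    expansion = as.integer(expansion), inflation = inflation,
    max_iter = as.integer(max_iter), convergence_tol = convergence_tol,
    edge_weight = match.arg(edge_weight), prune = prune
  ), class = "ptra_mcl_params")
}

mcl_adjacency <- function(graph, params) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges)) {
    w <- switch(params$edge_weight,
                n_patients = graph$edges$n_patients,
                rr = graph$edges$rr_mean,
                unit = rep(1, nrow(graph$edges)))
    ia <- match(graph$edges$event_a, graph$nodes)
    ib <- match(graph$edges$event_b, graph$nodes)
    for (e in seq_along(ia)) {
      # symmetrize by max: flow ignores edge direction
      A[ia[e], ib[e]] <- max(A[ia[e], ib[e]], w[e])
      A[ib[e], ia[e]] <- max(A[ib[e], ia[e]], w[e])
    }
  }
  # self-loops at the maximum incident weight: a unit loop next to heavy
  # edges makes the expansion favor the diagonal and shatters connected
  # pairs into singletons under inflation
  diag(A) <- pmax(apply(A, 1, max), 1)
  A
}

col_normalize <- function(M) sweep(M, 2, colSums(M), "/")

#' Markov clustering of the trajectory graph
#'
#' Standard MCL on the symmetrized weighted adjacency with self-loops:
#' column-normalize, then alternate expansion (matrix power) and inflation
#' (entrywise power followed by renormalization) until the iterate is stable.
#' Clusters are the connected components of the limit matrix's nonzero
#' structure, so every node lands in exactly one cluster and clusters never
#' span disconnected components.
#'
#' @param graph a `ptra_graph` (nonempty).
#' @param params an [mcl_params()].
#' @return list of class `ptra_clusters`: `membership` (named integer vector
#'   over nodes), `clusters` (list of node-label vectors, largest first),
#'   `n_iter`.
#' @export
mcl_cluster <- function(graph, params = mcl_params()) {
  if (!length(graph$nodes)) {
    stop("mcl_cluster(): empty graph", call. = FALSE)
  }
  M <- col_normalize(mcl_adjacency(graph, params))
  for (it in seq_len(params$max_iter)) {
    prev <- M
    for (i in seq_len(params$expansion - 1L)) M <- M %*% prev  # expansion
    M <- M^params$inflation
    M[M < params$prune] <- 0
    M <- col_normalize(M)
    if (max(abs(M - prev)) < params$convergence_tol) {
      return(read_clusters(M, graph$nodes, it))
    }
  }
  stop(sprintf(
    "mcl_cluster(): no convergence after %d iterations (last delta %.3g)",
    params$max_iter, max(abs(M - prev))), call. = FALSE)
}

# connected components of the limit matrix's nonzero structure (union-find)
read_clusters <- function(M, nodes, n_iter) {
  n <- length(nodes)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nz <- which(M > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    a <- find(nz[r, 1L]); b <- find(nz[r, 2L])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  membership <- match(roots, unique(roots))
  sizes <- tabulate(membership)
  relabel <- order(order(-sizes))  # largest cluster first
  membership <- relabel[membership]
  names(membership) <- nodes
  clusters <- split(nodes, membership)
  structure(list(membership = membership,
                 clusters = clusters[order(as.integer(names(clusters)))],
                 n_iter = n_iter),
            class = "ptra_clusters")
}

#' @export
print.ptra_clusters <- function(x, ...) {
  cat(sprintf("<ptra_clusters> %d clusters over %d nodes (%d MCL iterations)\n",
              length(x$clusters), length(x$membership), x$n_iter))
  invisible(x)
}

#' Finite-population Z-test for a gender proportion
#'
#' Treats the full cohort as a finite population of size `population_size`
#' from which the `n` cluster patients were sampled:
#' `z = (n_female/n - ref) / sqrt(ref (1 - ref) / n * (N - n)/(N - 1))`
#' with a two-sided normal tail. When the sample is the whole population the
#' variance vanishes; the test then returns 1 when the proportions agree and 0
#' otherwise, with a warning.
#'
#' @param n_female number of female patients in the sample.
#' @param n sample size.
#' @param ref_proportion reference female proportion in (0, 1).
#' @param population_size the finite population size `N >= n`.
#' @return Two-sided p-value.
#' @export
test_gender_proportion <- function(n_female, n, ref_proportion,
                                   population_size) {
  stopifnot(n_female >= 0, n_female <= n, n <= population_size,
            ref_proportion > 0, ref_proportion < 1)
  phat <- n_female / n
  if (n == population_size) {
    warning("sample equals the population; variance is zero", call. = FALSE)
    return(if (isTRUE(all.equal(phat, ref_proportion))) 1 else 0)
  }
  fpc <- (population_size - n) / (population_size - 1)
  se <- sqrt(ref_proportion * (1 - ref_proportion) / n * fpc)
  2 * pnorm(-abs((phat - ref_proportion) / se))
}

#' Per-cluster demographics
#'
#' A patient belongs to a cluster when they contribute to the exposed-with-
#' outcome count of at least one intra-cluster edge. Age is taken at the
#' patient's first event among the cluster's labels; gender proportions are
#' compared to the cohort with the finite-population Z-test.
#'
#' @param clusters a `ptra_clusters` from [mcl_cluster()].
#' @param graph the `ptra_graph` that was clustered (its edges must carry the
#'   `patients` list-column).
#' @param cohort the `ptra_cohort`.
#' @param events the `ptra_events` used to build the pairs.
#' @param ref_proportion reference female proportion; defaults to the cohort's.
#' @return data frame, one row per cluster: `cluster_id`, `n_events`,
#'   `events`, `n_patients`, `pct_of_cohort`, `mean_age`, `sd_age`,
#'   `n_female`, `pct_female`, `z_p_value`.
#' @export
cluster_statistics <- function(clusters, graph, cohort, events,
                               ref_proportion = NULL) {
  stopifnot(!is.null(graph$edges$patients))
  N <- cohort_size(cohort)
  if (is.null(ref_proportion)) {
    ref_proportion <- mean(cohort$patients$sex == "F")
  }
  sex <- setNames(cohort$patients$sex, cohort$patients$patient_id)
  birth <- setNames(cohort$patients$birth_date, cohort$patients$patient_id)
  rows <- lapply(seq_along(clusters$clusters), function(ci) {
    labs <- clusters$clusters[[ci]]
    in_cl <- graph$edges$event_a %in% labs & graph$edges$event_b %in% labs
    pats <- unique(unlist(graph$edges$patients[in_cl]))
    n <- length(pats)
    if (!n) {
      return(data.frame(
        cluster_id = ci, n_events = length(labs),
        events = paste(labs, collapse = "; "), n_patients = 0L,
        pct_of_cohort = 0, mean_age = NA_real_, sd_age = NA_real_,
        n_female = NA_integer_, pct_female = NA_real_,
        z_p_value = NA_real_, stringsAsFactors = FALSE))
    }
    ev <- events[events$patient_id %in% pats & events$label %in% labs, ,
                 drop = FALSE]
    first <- tapply(as.integer(ev$date), ev$patient_id, min)
    ages <- age_at(birth[names(first)],
                   as.Date(as.integer(first), origin = "1970-01-01"))
    n_f <- sum(sex[pats] == "F")
    data.frame(
      cluster_id = ci, n_events = length(labs),
      events = paste(labs, collapse = "; "), n_patients = n,
      pct_of_cohort = 100 * n / N, mean_age = mean(ages),
      sd_age = if (length(ages) > 1) sd(ages) else NA_real_,
      n_female = n_f, pct_female = 100 * n_f / n,
      z_p_value = test_gender_proportion(n_f, n, ref_proportion, N),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Export the clustered trajectory graph as Graphviz DOT
#'
#' Emits one DOT subgraph per cluster with at least three events; edges carry
#' the label `"n (pct%)\\nRR r"` and edges with `rr_mean < display_min_rr` are
#' omitted. Clusters of exactly two events are not drawn; their single pair is
#' returned as a side table. Singleton clusters are skipped entirely.
#'
#' @param graph a `ptra_graph`.
#' @param clusters a `ptra_clusters` (optional; `NULL` draws one subgraph).
#' @param display_min_rr minimum RR for a drawn edge (1.05 and 1.25 are the
#'   customary display cutoffs at the two coarser windows).
#' @param path output file path.
#' @return Invisibly, `path`; the two-event side table is attached as
#'   `attr(, "pair_table")`.
#' @export
export_graph <- function(graph, clusters = NULL, display_min_rr = 0,
                         path) {
  edges <- graph$edges
  shown <- !is.na(edges$rr_mean) & edges$rr_mean >= display_min_rr
  lines <- c("digraph trajectories {",
             "  rankdir=LR;",
             "  node [shape=box, style=rounded];")
  edge_line <- function(e) {
    sprintf("    %s -> %s [label=\"%d (%.1f%%)\\nRR %.2f\"];",
            dot_quote(e$event_a), dot_quote(e$event_b), e$n_patients,
            e$pct, e$rr_mean)
  }
  pair_table <- NULL
  if (is.null(clusters)) {
    for (i in which(shown)) lines <- c(lines, edge_line(edges[i, ]))
  } else {
    for (ci in seq_along(clusters$clusters)) {
      labs <- clusters$clusters[[ci]]
      in_cl <- which(edges$event_a %in% labs & edges$event_b %in% labs &
                       shown)
      if (length(labs) < 2L) next
      if (length(labs) == 2L) {
        pair_table <- rbind(pair_table,
                            edges[in_cl, setdiff(names(edges), "patients"),
                                  drop = FALSE])
        next
      }
      lines <- c(lines,
                 sprintf("  subgraph cluster_%d {", ci),
                 sprintf("    label=\"cluster %d\";", ci),
                 vapply(labs, function(l) paste0("    ", dot_quote(l), ";"),
                        ""),
                 vapply(in_cl, function(i) edge_line(edges[i, ]), ""),
                 "  }")
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  out <- invisible(path)
  attr(out, "pair_table") <- pair_table
  out
}
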