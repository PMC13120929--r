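mk_pairs <- function(a, b, n, rr, patients = NULL) {
  df <- data.frame(event_a = a, event_b = b, n_patients = n, rr_mean = rr,
                   stringsAsFactors = FALSE)
  df$patients <- if (is.null(patients)) {
    lapply(n, function(k) sprintf("P%03d", seq_len(k)))
  } else patients
  df
}

test_that("graph building enforces the minimum patient count", {
  pairs <- mk_pairs(c("a", "b", "a"), c("b", "c", "c"), c(12, 9, 15),
                    c(1.5, 2.0, 1.2))
  g <- build_graph(pairs, min_patients = 10, cohort_size = 100)
  expect_setequal(g$nodes, c("a", "b", "c"))
  expect_equal(nrow(g$edges), 2L)  # the n = 9 edge is gone
  expect_equal(g$edges$pct, c(12, 15))
  g_empty <- build_graph(mk_pairs("a", "b", 9, 2), 10, 100)
  expect_equal(length(g_empty$nodes), 0L)
})

test_that("disconnected components can never merge under MCL", {
  tri <- mk_pairs(c("a", "b", "c", "x", "y", "z"),
                  c("b", "c", "a", "y", "z", "x"),
                  rep(20, 6), rep(2, 6))
  g <- build_graph(tri, 1, 100)
  cl <- mcl_cluster(g)
  expect_equal(length(cl$clusters), 2L)
  expect_setequal(cl$clusters[[which(vapply(cl$clusters, function(x)
    "a" %in% x, TRUE))]], c("a", "b", "c"))
  # a connected pair stays one cluster; a lone node is a singleton cluster
  g2 <- build_graph(mk_pairs("u", "v", 20, 2), 1, 100)
  expect_equal(length(mcl_cluster(g2)$clusters), 1L)
  g1 <- structure(list(nodes = "solo",
                       edges = mk_pairs("a", "b", 1, 1)[0, ],
                       min_patients = 1L, cohort_size = 100L,
                       window = NULL), class = "ptra_graph")
  expect_equal(length(mcl_cluster(g1)$clusters), 1L)
})

test_that("MCL splits a barbell at the bridge like the reference implementation", {
  # two 4-cliques joined by one weak bridge
  cliq <- function(nodes) {
    cmb <- t(combn(nodes, 2))
    mk_pairs(cmb[, 1], cmb[, 2], rep(10, nrow(cmb)), rep(2, nrow(cmb)))
  }
  pairs <- rbind(cliq(c("a1", "a2", "a3", "a4")),
                 cliq(c("b1", "b2", "b3", "b4")),
                 mk_pairs("a4", "b1", 1, 1.1))
  g <- build_graph(pairs, 1, 100)
  cl <- mcl_cluster(g, mcl_params(inflation = 2.0))
  expect_equal(length(cl$clusters), 2L)
  split_a <- sort(cl$clusters[[which(vapply(cl$clusters, function(x)
    "a1" %in% x, TRUE))]])
  expect_equal(split_a, c("a1", "a2", "a3", "a4"))
  # independent dense reference MCL on the same adjacency
  nodes <- g$nodes
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(g$edges))) {
    w <- g$edges$n_patients[i]
    A[g$edges$event_a[i], g$edges$event_b[i]] <- w
    A[g$edges$event_b[i], g$edges$event_a[i]] <- w
  }
  diag(A) <- pmax(apply(A, 1, max), 1)  # same loop convention as the package
  ref <- oracle_mcl(A, inflation = 2)
  ref_sets <- lapply(ref, function(ix) sort(nodes[ix]))
  got_sets <- lapply(cl$clusters, sort)
  expect_setequal(lapply(got_sets, paste, collapse = "|"),
                  lapply(ref_sets, paste, collapse = "|"))
})

test_that("finite-population Z-test matches its closed form and limits", {
  # exact agreement with the reference proportion gives p = 1
  expect_equal(test_gender_proportion(70, 100, 0.7, 1000), 1)
  # sample = population: degenerate variance
  expect_warning(p <- test_gender_proportion(60, 100, 0.7, 100), "population")
  expect_equal(p, 0)
  # N -> infinity converges to the classical one-sample proportion Z-test
  z_inf <- 2 * pnorm(-abs((0.6 - 0.7) / sqrt(0.7 * 0.3 / 100)))
  expect_equal(test_gender_proportion(60, 100, 0.7, 10^7), z_inf,
               tolerance = 1e-4)
})

test_that("cluster demographics equal a direct recomputation", {
  coh <- tiny_synth(n = 40, seed = 31)
  ev <- extract_events(coh)
  ids <- coh$patients$patient_id
  # edge membership: patients who genuinely carry both endpoint events
  with_both <- function(a, b) {
    intersect(unique(ev$patient_id[ev$label == a]),
              unique(ev$patient_id[ev$label == b]))
  }
  labs <- rbind(c("Relapse", "MRI BR"), c("MRI BR", "+EDSS"),
                c("+EDSS", "Relapse"))
  members <- lapply(1:3, function(i) with_both(labs[i, 1], labs[i, 2]))
  pairs <- mk_pairs(labs[, 1], labs[, 2], lengths(members),
                    c(1.5, 1.4, 1.3), patients = members)
  g <- build_graph(pairs, 1, cohort_size(coh))
  cl <- mcl_cluster(g)
  st <- cluster_statistics(cl, g, coh, ev)
  expect_equal(nrow(st), length(cl$clusters))
  big <- st[st$n_events == 3, ]
  pats <- unique(unlist(members))
  expect_equal(big$n_patients, length(pats))
  # brute-force age at first in-cluster event
  ages <- sapply(pats, function(p) {
    e <- ev[ev$patient_id == p & ev$label %in% g$nodes, ]
    birth <- coh$patients$birth_date[coh$patients$patient_id == p]
    as.numeric(min(e$date) - birth) / 365.25
  })
  expect_equal(big$mean_age, mean(ages), tolerance = 1e-10)
  expect_equal(big$sd_age, sd(ages), tolerance = 1e-10)
  n_f <- sum(coh$patients$sex[match(pats, ids)] == "F")
  expect_equal(big$n_female, n_f)
  expect_equal(big$z_p_value,
               test_gender_proportion(n_f, length(pats),
                                      mean(coh$patients$sex == "F"),
                                      cohort_size(coh)))
  # an all-female cluster reports 100% female
  fem <- ids[coh$patients$sex == "F"]
  fem_members <- intersect(with_both("Relapse", "MRI BR"), fem)[1:2]
  pairs_f <- mk_pairs("Relapse", "MRI BR", 2, 2,
                      patients = list(fem_members))
  g_f <- build_graph(pairs_f, 1, cohort_size(coh))
  st_f <- cluster_statistics(mcl_cluster(g_f), g_f, coh, ev)
  expect_equal(st_f$pct_female, 100)
})

test_that("DOT export draws >=3-event clusters and applies the RR cutoff", {
  pairs <- rbind(
    mk_pairs(c("a", "b", "c"), c("b", "c", "a"), c(20, 18, 15),
             c(1.50, 1.20, 1.30)),
    mk_pairs("x", "y", 12, 1.40))
  g <- build_graph(pairs, 10, 100)
  cl <- mcl_cluster(g)
  path <- withr::local_tempfile(fileext = ".dot")
  out <- export_graph(g, cl, display_min_rr = 1.25, path = path)
  txt <- readLines(path)
  expect_true(any(grepl("subgraph cluster_", txt)))
  expect_true(any(grepl("\"a\" -> \"b\"", txt)))
  expect_false(any(grepl("\"b\" -> \"c\"", txt)))  # rr 1.20 < 1.25 dropped
  # the 2-event cluster goes to the side table, not the drawing
  expect_false(any(grepl("\"x\"", txt)))
  side <- attr(out, "pair_table")
  expect_equal(side$event_a, "x")
  # edge multiset round-trips through the DOT text
  edges <- regmatches(txt, regexpr('"[^"]+" -> "[^"]+"', txt))
  drawn <- g$edges[g$edges$rr_mean >= 1.25 &
                     g$edges$event_a %in% c("a", "b", "c"), ]
  expect_setequal(edges, sprintf('"%s" -> "%s"', drawn$event_a,
                                 drawn$event_b))
  # empty graph still yields a valid DOT digraph
  g0 <- build_graph(mk_pairs("a", "b", 1, 2), 10, 100)
  path0 <- withr::local_tempfile(fileext = ".dot")
  export_graph(g0, NULL, path = path0)
  txt0 <- readLines(path0)
  expect_equal(txt0[1], "digraph trajectories {")
  expect_equal(txt0[length(txt0)], "}")
})

test_that("min-patients and display-RR edge filters commute", {
  set.seed(2)
  pairs <- mk_pairs(sample(letters[1:6], 20, TRUE),
                    sample(LETTERS[1:6], 20, TRUE),
                    sample(5:30, 20, TRUE), runif(20, 0.8, 2.5))
  by_n_then_rr <- subset(build_graph(pairs, 12, 100)$edges,
                         rr_mean >= 1.25)
  g_rr_first <- build_graph(pairs[pairs$rr_mean >= 1.25, ], 12, 100)
  expect_setequal(paste(by_n_then_rr$event_a, by_n_then_rr$event_b),
                  paste(g_rr_first$edges$event_a, g_rr_first$edges$event_b))
})
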