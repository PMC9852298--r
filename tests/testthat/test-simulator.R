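test_that("the bundled karate-club fixture is the canonical graph", {
  kc <- karate_club()
  tg <- bipval:::as_truth_graph(kc)
  expect_equal(length(tg$nodes), 34)
  expect_equal(nrow(tg$edges), 78)
  g <- igraph::graph_from_data_frame(kc, directed = FALSE)
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_simple(g))
  # cross-check against the igraph built-in
  ref <- igraph::make_graph("Zachary")
  expect_true(igraph::isomorphic(g, ref))
})

test_that("attribute sampling respects ranges and concentration limits", {
  set.seed(1)
  at <- sample_influence_attributes(karate_club(), ni_range = c(1, 1),
                                    ci_range = c(0.2, 0.4))
  expect_true(all(at$connect_prob == 1))
  expect_true(all(at$mimic_prob >= 0.2 & at$mimic_prob <= 0.4))
  prefs <- as.matrix(at[paste0("pref_a", 1:3)])
  expect_equal(rowSums(prefs), rep(1, 34), tolerance = 1e-12)

  # maximal concentration forces one-hot vectors, s = 1 forces equality
  onehot <- sample_influence_attributes(karate_club(),
                                        concentration_range = c(0, 0))
  P <- as.matrix(onehot[paste0("pref_a", 1:3)])
  expect_true(all(apply(P, 1, max) == 1))
  flat <- sample_influence_attributes(karate_club(),
                                      concentration_range = c(1, 1))
  expect_true(all(abs(as.matrix(flat[paste0("pref_a", 1:3)]) - 1 / 3) < 1e-12))

  # uniform moment check on a large node set
  chain <- data.frame(from = sprintf("v%05d", 1:9999),
                      to = sprintf("v%05d", 2:10000))
  set.seed(7)
  big <- sample_influence_attributes(chain)
  se <- sqrt(1 / 12 / nrow(big))
  expect_lt(abs(mean(big$connect_prob) - 0.5), 3 * se)
})

test_that("cascades respect graph structure and connection probabilities", {
  # edgeless graph: the seed is the only connected agent
  iso <- igraph::make_empty_graph(4, directed = FALSE)
  at <- sample_influence_attributes(iso)
  set.seed(3)
  for (r in 1:10) {
    ev <- simulate_event_cascade(iso, at)
    expect_equal(nrow(ev), 1)
  }

  # forced full cascade on a connected graph
  at1 <- sample_influence_attributes(karate_club(), ni_range = c(1, 1))
  set.seed(4)
  ev <- simulate_event_cascade(karate_club(), at1)
  expect_equal(nrow(ev), 34)

  # agents outside the seed's component never connect
  two_comp <- data.frame(from = c("a", "c"), to = c("b", "d"))
  atc <- sample_influence_attributes(two_comp, ni_range = c(1, 1))
  set.seed(5)
  for (r in 1:10) {
    ev <- simulate_event_cascade(two_comp, atc)
    expect_true(all(ev$agent %in% c("a", "b")) || all(ev$agent %in% c("c", "d")))
  }
})

test_that("with no mimicry, link types follow each agent's own preferences", {
  pair <- data.frame(from = "u", to = "v")
  at <- tibble::tibble(agent = c("u", "v"), connect_prob = 1, mimic_prob = 0,
                       pref_a1 = c(0.7, 0.2), pref_a2 = c(0.2, 0.5),
                       pref_a3 = c(0.1, 0.3))
  net <- simulate_bipartite(pair, n_events = 1000, attrs = at, seed = 8)
  counts <- bipval:::type_counts(net$B, 3)
  for (a in 1:2) {
    p <- unlist(at[a, paste0("pref_a", 1:3)])
    n <- sum(counts[a, ])
    for (k in 1:3) {
      se <- sqrt(p[k] * (1 - p[k]) / n)
      expect_lt(abs(counts[a, k] / n - p[k]), 3 * se + 1e-9)
    }
  }
})

test_that("bipartite simulation is deterministic and structurally sound", {
  expect_error(simulate_bipartite(karate_club(), n_events = 0), "n_events")
  expect_error(simulate_bipartite(karate_club(), n_types = 1), "n_types")
  n1 <- simulate_bipartite(karate_club(), n_events = 50, seed = 123)
  n2 <- simulate_bipartite(karate_club(), n_events = 50, seed = 123)
  expect_identical(n1$B, n2$B)
  expect_identical(incidence(n1), incidence(n2))

  n3 <- simulate_bipartite(karate_club(), n_events = 100, seed = 9)
  expect_equal(length(n3$events), 100)
  expect_true(all(colSums(n3$B > 0) >= 1))           # every event has its seed
  expect_true(all(n3$B %in% 0:3))
  expect_equal(n3$types$types, c("a1", "a2", "a3"))

  # per-neighbor exposure raises connectivity on the same attribute draw
  set.seed(11)
  at <- sample_influence_attributes(karate_club(), ni_range = c(0.3, 0.5))
  d_once <- mean(simulate_bipartite(karate_club(), 50, attrs = at,
                                    seed = 13, exposure = "once")$B > 0)
  d_per <- mean(simulate_bipartite(karate_club(), 50, attrs = at,
                                   seed = 13, exposure = "per_neighbor")$B > 0)
  expect_gt(d_per, d_once)
})

test_that("adjacent agents co-use link types more than non-adjacent ones", {
  kc <- karate_club()
  adj_key <- paste(pmin(kc$from, kc$to), pmax(kc$from, kc$to))
  same_adj <- 0; n_adj <- 0; same_non <- 0; n_non <- 0
  for (seed in 1:8) {
    net <- simulate_bipartite(kc, n_events = 60, seed = 100 + seed)
    st <- pair_statistics(net)
    is_adj <- paste(st$agent_i, st$agent_j) %in% adj_key
    same_adj <- same_adj + sum(st$same_type[is_adj])
    n_adj <- n_adj + sum(is_adj)
    same_non <- same_non + sum(st$same_type[!is_adj])
    n_non <- n_non + sum(!is_adj)
    # pair-statistic bounds on simulator output
    expect_true(all(st$co_events >= pmax(st$degree_i + st$degree_j -
                                           st$n_events, 0)))
    expect_true(all(st$same_type <= st$co_events))
    expect_true(all(st$co_events <= pmin(st$degree_i, st$degree_j)))
  }
  expect_gt(same_adj / n_adj, same_non / n_non)
})
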