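test_that("incidence loading validates records and preserves order", {
  lt <- link_type_set(c("x", "y"))
  rec <- data.frame(agent_id = c("b", "a", "b"),
                    event_id = c("e2", "e1", "e1"),
                    link_type = c("x", "y", "x"))
  net <- typed_bipartite(rec, lt)
  expect_equal(net$agents, c("b", "a"))       # first appearance
  expect_equal(net$events, c("e2", "e1"))
  expect_equal(nrow(incidence(net)), 3)

  # identical duplicate collapses with a warning
  expect_warning(net2 <- typed_bipartite(rec[c(1, 1, 2), ], lt),
                 "duplicate")
  expect_equal(sum(net2$B > 0), 2)

  # conflicting duplicate and unknown types are hard errors
  bad <- rbind(rec, data.frame(agent_id = "b", event_id = "e2", link_type = "y"))
  expect_error(typed_bipartite(bad, lt), "conflicting.*'b'.*'e2'")
  expect_error(typed_bipartite(data.frame(agent_id = "a", event_id = "e1",
                                          link_type = "zzz"), lt),
               "unknown link type")

  # an event universe is mandatory; declared empty events are allowed
  expect_error(typed_bipartite(rec[0, ], lt), "non-empty")
  empty <- typed_bipartite(rec[0, ], lt, agents = "a", events = c("e1", "e2"))
  expect_equal(dim(empty$B), c(1, 2))
  expect_equal(sum(empty$B), 0)
})

test_that("link type sets enforce their invariants", {
  expect_error(link_type_set(character()), "non-empty")
  expect_error(link_type_set(c("a", "a")), "duplicates")
  expect_error(link_type_set(c("a", "b"), neutral = "c"), "not registered")
  expect_error(link_type_set(c("a", "b"), opposing = list(c("a", "a"))),
               "distinct")
  expect_error(link_type_set(c("a", "b", "c"), neutral = "b",
                             opposing = list(c("b", "c"))),
               "both neutral and opposing")
})

test_that("the bundled worked-example network matches its contingency table", {
  net <- table1_network()
  expect_equal(length(net$agents), 2)
  expect_equal(length(net$events), 100)
  expect_equal(sum(net$B > 0), 70)

  prof <- agent_profiles(net)
  expect_equal(prof$degree, c(40L, 30L))
  expect_equal(unlist(prof[prof$agent_id == "i", c("pref_a1", "pref_a2", "pref_a3")],
                      use.names = FALSE), c(0.1, 0.5, 0.4))
  expect_equal(unlist(prof[prof$agent_id == "j", c("pref_a1", "pref_a2", "pref_a3")],
                      use.names = FALSE), c(0.1, 7 / 30, 20 / 30))

  pop <- population_preferences(net)
  expect_equal(pop$preference, c(7, 27, 36) / 70)

  # the in-code rebuild agrees with the shipped fixture
  code <- table1_from_code()
  expect_equal(unname(table(net$B)), unname(table(code$B)))
  expect_equal(pair_statistics(net)[-(1:2)], pair_statistics(code)[-(1:2)])
})

test_that("agent profiles handle degenerate degrees", {
  lt <- link_type_set(c("a1", "a2"))
  net <- typed_bipartite(
    data.frame(agent_id = "u", event_id = c("e1", "e2"), link_type = "a1"),
    lt, agents = c("u", "zero"), events = c("e1", "e2"))
  prof <- agent_profiles(net)
  expect_equal(prof$pref_a1[prof$agent_id == "u"], 1)   # full concentration
  expect_false(prof$defined[prof$agent_id == "zero"])
  expect_true(is.na(prof$pref_a1[prof$agent_id == "zero"]))
  expect_error(population_preferences(
    typed_bipartite(data.frame(agent_id = character(), event_id = character(),
                               link_type = character()),
                    lt, agents = "u", events = "e1")),
    "no incidences")
})

test_that("pair statistics reproduce the worked example and match brute force", {
  stats <- pair_statistics(table1_network())
  expect_equal(stats$co_events, 21L)
  expect_equal(stats$same_type, 2L)
  expect_equal(stats$opposing_type, 17L)
  expect_equal(c(stats$overlap_a1, stats$overlap_a2, stats$overlap_a3),
               c(2L, 0L, 0L))
  expect_equal(stats$p_same, 118 / 300)
  expect_equal(stats$p_opposing, 32 / 75)

  for (seed in 1:5) {
    net <- random_net(seed)
    stats <- pair_statistics(net)
    for (r in sample(nrow(stats), 5)) {
      bf <- bf_pair_stats(net, stats$agent_i[r], stats$agent_j[r])
      expect_equal(stats$co_events[r], bf$co)
      expect_equal(stats$same_type[r], bf$same)
      expect_equal(stats$opposing_type[r], bf$opp)
      expect_equal(unlist(stats[r, paste0("overlap_", net$types$types)],
                          use.names = FALSE), as.integer(bf$per))
      # bounds: max(Ni+Nj-N, 0) <= co; 0 <= same <= co <= min(Ni, Nj)
      expect_gte(bf$co, max(bf$di + bf$dj - stats$n_events[r], 0))
      expect_lte(bf$same, bf$co)
      expect_lte(bf$co, min(bf$di, bf$dj))
    }
    # symmetry in (i, j) for every field
    sw <- pair_statistics(net, pairs = data.frame(agent_i = stats$agent_j,
                                                  agent_j = stats$agent_i))
    expect_identical(stats$co_events, sw$co_events)
    expect_identical(stats$same_type, sw$same_type)
    expect_identical(stats$opposing_type, sw$opposing_type)
    expect_identical(stats$p_same, sw$p_same)
    expect_identical(stats$p_opposing, sw$p_opposing)
    # preferences sum to one for positive-degree agents
    prof <- agent_profiles(net)
    sums <- rowSums(as.matrix(prof[paste0("pref_", net$types$types)]))
    expect_true(all(abs(sums[prof$defined] - 1) < 1e-12))
    # p_same + p_opposing <= 1 when opposing pairs are disjoint from neutral
    expect_true(all(stats$p_same + stats$p_opposing <= 1 + 1e-12))
  }

  # identical and disjoint agents
  lt <- link_type_set(c("a1", "a2"))
  twin <- typed_bipartite(
    data.frame(agent_id = rep(c("u", "v"), each = 3),
               event_id = rep(c("e1", "e2", "e3"), 2),
               link_type = rep(c("a1", "a2", "a1"), 2)),
    lt, events = sprintf("e%d", 1:5))
  st <- pair_statistics(twin)
  expect_equal(st$co_events, 3L)
  expect_equal(st$same_type, 3L)
  disj <- typed_bipartite(
    data.frame(agent_id = c("u", "v"), event_id = c("e1", "e2"),
               link_type = "a1"),
    lt, events = c("e1", "e2"))
  expect_equal(pair_statistics(disj)$co_events, 0L)
  expect_equal(pair_statistics(disj)$same_type, 0L)
})

test_that("Herfindahl-Hirschman concentration evaluates overlap vectors", {
  expect_equal(herfindahl_hirschman(c(2, 0, 0)), 1)
  expect_equal(herfindahl_hirschman(c(1, 1, 1)), 1 / 3)
  expect_equal(herfindahl_hirschman(c(3, 1, 0)), 10 / 16)
  expect_warning(hh0 <- herfindahl_hirschman(c(0, 0, 0)), "undefined")
  expect_true(is.na(hh0))
  withhh <- herfindahl_hirschman(pair_statistics(table1_network()))
  expect_equal(withhh$hh, 1)
})

test_that("trading states discretize net-scaled volume with a closed neutral band", {
  tr <- data.frame(agent_id = "i", event_id = c("d1", "d2", "d3", "d4"),
                   bought = c(10, 5, 0, 5.5), sold = c(0, 5, 10, 4.5))
  st <- trading_states(tr, theta = 0.1)
  expect_equal(st$link_type, c("b", "bs", "s", "bs"))  # v = 1, 0, -1, 0.1
  expect_error(trading_states(data.frame(agent_id = "i", event_id = "d",
                                         bought = 0, sold = 0)),
               "zero total volume")
  expect_error(trading_states(tr, theta = 1.2), "theta")
})

test_that("degree filters act once on one partition only", {
  net <- random_net(11)
  expect_equal(filter_agents_by_degree(net, 0)$agents, net$agents)
  expect_equal(filter_events_by_degree(net, 0)$events, net$events)

  lt <- link_type_set("a1")
  att <- c(2, 2, 3, 4, 4)
  rec <- do.call(rbind, lapply(seq_along(att), function(e)
    data.frame(agent_id = sprintf("u%d", seq_len(att[e])),
               event_id = sprintf("e%d", e), link_type = "a1")))
  net5 <- typed_bipartite(rec, lt)
  expect_equal(length(filter_events_by_degree(net5, 3)$events), 3)
  # agents untouched by the event filter, even if their degree drops
  expect_equal(filter_events_by_degree(net5, 3)$agents, net5$agents)
  flt <- filter_agents_by_degree(net5, 10)
  expect_equal(length(flt$agents), 0)
  expect_equal(flt$events, net5$events)
})

test_that("incidence TSV plus JSON config round-trips the data model", {
  net <- random_net(3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  cfg <- withr::local_tempfile(fileext = ".json")
  write_incidence(net, tsv, config_path = cfg)
  back <- read_incidence(tsv, config = cfg)
  expect_identical(back$agents, net$agents)
  expect_identical(back$events, net$events)
  expect_identical(back$B, net$B)
  expect_identical(back$types$types, net$types$types)
  expect_identical(back$types$opposing, net$types$opposing)
})
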