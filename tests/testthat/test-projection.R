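test_that("pair validation reproduces the worked example under both nulls", {
  net <- table1_network()
  expect_equal(validate_pairs(net, "positive")$p_value, 0.9667,
               tolerance = 5e-4)
  expect_equal(validate_pairs(net, "negative")$p_value, 1.70e-7,
               tolerance = 5e-3)
  ref <- validate_pairs(net, model = "reference", aggregation = "none")
  expect_equal(ref$p_a1, 3.58e-3, tolerance = 5e-3)
  expect_equal(ref$p_a2, 1)  # no overlap in a2/a3: tails are 1
  expect_equal(ref$p_a3, 1)
  expect_equal(validate_pairs(net, model = "reference", aggregation = "min")$p_value,
               3.58e-3, tolerance = 5e-3)
  expect_equal(validate_pairs(net, model = "reference", aggregation = "max")$p_value, 1)
})

test_that("validation is symmetric and zero overlap is never significant", {
  net <- random_net(21)
  a <- validate_pair(net, "ag01", "ag05")
  b <- validate_pair(net, "ag05", "ag01")
  expect_identical(a$p_value, b$p_value)
  lt <- link_type_set(c("a1", "a2"))
  disjoint <- typed_bipartite(
    data.frame(agent_id = c("u", "v"), event_id = c("e1", "e2"),
               link_type = "a1"),
    lt, events = c("e1", "e2", "e3"))
  expect_equal(validate_pairs(disjoint, "positive")$p_value, 1)
})

test_that("zero-overlap p-values are invariant to event relabeling", {
  net <- random_net(31)
  perm <- sample(seq_along(net$events))
  shuffled <- net
  shuffled$events <- net$events[perm]
  shuffled$B <- net$B[, perm]
  expect_identical(validate_pairs(net, "positive")$p_value,
                   validate_pairs(shuffled, "positive")$p_value)
})

test_that("projection thresholds pairs per sign family", {
  net <- table1_network()
  sn <- project(net, alpha = 0.01, correction = "bonferroni")
  expect_s3_class(sn, "signed_network")
  expect_equal(nrow(sn$edges), 1)
  expect_equal(sn$edges$sign, "negative")
  expect_equal(sn$edges$p_value, 1.70e-7, tolerance = 5e-3)
  expect_equal(unname(sn$n_tests), c(1L, 1L))

  # vanishing threshold removes everything
  none <- project(net, alpha = 1e-15, correction = "none")
  expect_equal(nrow(none$edges), 0)

  # four-agent toy agrees with pair-by-pair manual thresholding
  net4 <- random_net(77, n_agents = 4, n_events = 40)
  for (corr in c("none", "bonferroni")) {
    sn4 <- project(net4, alpha = 0.05, correction = corr, modes = "positive")
    pv <- validate_pairs(net4, "positive")
    thr <- if (corr == "none") 0.05 else 0.05 / nrow(pv)
    manual <- pv[!is.na(pv$p_value) & pv$p_value < thr, c("agent_i", "agent_j")]
    expect_equal(sn4$edges[c("agent_i", "agent_j")], manual,
                 ignore_attr = TRUE)
  }
})

test_that("edge sets are monotone in alpha", {
  net <- simulate_bipartite(karate_club(), n_events = 60, seed = 5)
  alphas <- c(1e-6, 1e-4, 1e-2, 0.1)
  keys <- lapply(alphas, function(a) {
    e <- tidy(project(net, alpha = a, modes = "positive"))
    paste(e$agent_i, e$agent_j)
  })
  for (i in seq_len(length(alphas) - 1)) {
    expect_true(all(keys[[i]] %in% keys[[i + 1]]))
  }
})

test_that("triad census classifies by the sign-product rule", {
  # complete 4-node graph with fixed signs: brute-force comparison
  nodes <- c("a", "b", "c", "d")
  cmb <- utils::combn(nodes, 2)
  edges <- tibble::tibble(
    agent_i = cmb[1, ], agent_j = cmb[2, ],
    sign = c("positive", "negative", "negative", "positive", "negative",
             "positive"),
    p_value = 1e-5, co_events = 1L, same_type = 1L, opposing_type = 0L)
  cen <- triad_census_signed(make_signed(edges, nodes))
  bf <- bf_triads(edges, nodes)
  expect_equal(cen$ppp, bf[["ppp"]])
  expect_equal(cen$pmm, bf[["pmm"]])
  expect_equal(cen$ppm, bf[["ppm"]])
  expect_equal(cen$mmm, bf[["mmm"]])
  expect_equal(cen$triangles, 4)
  expect_equal(cen$stable, cen$ppp + cen$pmm)

  for (seed in 1:8) {
    sn <- random_signed(seed)
    cen <- triad_census_signed(sn)
    bf <- bf_triads(sn$edges, sn$nodes)
    expect_equal(unlist(cen[c("ppp", "pmm", "ppm", "mmm")], use.names = FALSE),
                 unname(bf))
    expect_equal(cen$stable + cen$unstable, cen$triangles)
  }

  # a doubly-signed pair is resolved to its smaller p-value
  dbl <- tibble::tibble(
    agent_i = c("a", "a", "b", "a"), agent_j = c("b", "b", "c", "c"),
    sign = c("positive", "negative", "positive", "positive"),
    p_value = c(1e-8, 1e-3, 1e-4, 1e-4),
    co_events = 1L, same_type = 1L, opposing_type = 0L)
  cen <- triad_census_signed(make_signed(dbl, c("a", "b", "c")))
  expect_equal(cen$ppp, 1)
  expect_equal(cen$triangles, 1)
})

test_that("rolling windows recompute profiles inside each window", {
  net <- random_net(55, n_agents = 5, n_events = 30)
  full <- rolling_window_projection(net, window_size = 30)
  expect_equal(unique(full$window), 1)
  expect_equal(full$p_value, validate_pairs(net, "positive")$p_value)

  # 300 events, window 120, step 30 -> 7 windows
  lt <- link_type_set("a1")
  rec <- data.frame(agent_id = rep(c("u", "v"), each = 300),
                    event_id = rep(sprintf("e%03d", 1:300), 2),
                    link_type = "a1")
  net300 <- typed_bipartite(rec, lt)
  rw <- rolling_window_projection(net300, window_size = 120, step = 30)
  expect_equal(max(rw$window), 7)
  expect_equal(rw$start_event[rw$window == 7][1], "e181")
  expect_error(rolling_window_projection(net300, window_size = 301), "window_size")
})

test_that("jaccard similarity compares signed edge sets", {
  ed <- function(pairs, sign = "positive") tibble::tibble(
    agent_i = substr(pairs, 1, 1), agent_j = substr(pairs, 2, 2),
    sign = sign, p_value = 1e-6, co_events = 1L, same_type = 1L,
    opposing_type = 0L)
  nodes <- letters[1:5]
  A <- make_signed(ed(c("ab", "bc", "cd")), nodes)
  B <- make_signed(ed(c("ab", "cd", "de")), nodes)
  expect_equal(jaccard_links(A, B)$jaccard, 0.5)
  expect_equal(jaccard_links(A, A)$jaccard, 1)
  expect_equal(jaccard_links(A, B)$n_only_a, 1)
  C <- make_signed(ed(c("ab"), sign = "negative"), nodes)
  expect_equal(jaccard_links(A, C)$jaccard, 0)  # same pair, different sign
  E <- make_signed(ed(character(0)), nodes)
  expect_warning(j <- jaccard_links(E, E), "empty")
  expect_equal(j$jaccard, 1)
})

test_that("tidiers and output files expose the edge list", {
  net <- table1_network()
  sn <- project(net, alpha = 0.01)
  expect_named(glance(sn),
               c("n_nodes", "n_positive", "n_negative", "alpha", "correction",
                 "n_tests", "model", "preference_mode"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signed_edges(sn, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 1)
  expect_equal(back$sign, "negative")
  g <- as_igraph(sn)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$sign, -1L)
})
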