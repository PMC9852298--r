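# Shared fixtures and independent brute-force oracles.

# The worked two-agent example, rebuilt in code from its contingency table
# (rows: agent j's link type / absent; columns: agent i's).
table1_contingency <- function() {
  matrix(c(2, 1, 0, 0,
           1, 0, 3, 3,
           0, 14, 0, 6,
           1, 5, 13, 51),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("a1", "a2", "a3", "-"), c("a1", "a2", "a3", "-")))
}

table1_records <- function() {
  X <- table1_contingency()
  ev <- sprintf("e%03d", seq_len(sum(X)))
  itype <- character(0); jtype <- character(0)
  for (jr in rownames(X)) {
    for (ic in colnames(X)) {
      n <- X[jr, ic]
      itype <- c(itype, rep(ic, n)); jtype <- c(jtype, rep(jr, n))
    }
  }
  rec <- rbind(
    data.frame(agent_id = "i", event_id = ev, link_type = itype),
    data.frame(agent_id = "j", event_id = ev, link_type = jtype))
  rec[rec$link_type != "-", ]
}

table1_types <- function() {
  link_type_set(c("a1", "a2", "a3"), neutral = "a1",
                opposing = list(c("a2", "a3")))
}

table1_from_code <- function() {
  typed_bipartite(table1_records(), table1_types(),
                  agents = c("i", "j"), events = sprintf("e%03d", 1:100))
}

# random typed bipartite network for property tests
random_net <- function(seed, n_agents = 8, n_events = 30, n_types = 3,
                       density = 0.5) {
  set.seed(seed)
  lt <- link_type_set(paste0("a", seq_len(n_types)), neutral = "a1",
                      opposing = list(c("a2", "a3")))
  on <- matrix(runif(n_agents * n_events) < density, n_agents, n_events)
  rec <- data.frame(
    agent_id = rep(sprintf("ag%02d", seq_len(n_agents)), n_events)[as.vector(on)],
    event_id = rep(sprintf("ev%02d", seq_len(n_events)),
                   each = n_agents)[as.vector(on)],
    link_type = sample(lt$types, sum(on), replace = TRUE))
  typed_bipartite(rec, lt, agents = sprintf("ag%02d", seq_len(n_agents)),
                  events = sprintf("ev%02d", seq_len(n_events)))
}

# direct per-event-loop pair statistics, independent of the matrix algebra
bf_pair_stats <- function(net, i, j) {
  Bi <- net$B[i, ]; Bj <- net$B[j, ]
  types <- net$types$types
  co <- sum(Bi > 0 & Bj > 0)
  same <- sum(Bi > 0 & Bi == Bj)
  per <- vapply(seq_along(types), function(k) sum(Bi == k & Bj == k), 0)
  opp <- 0
  for (pr in net$types$opposing) {
    kp <- match(pr[1], types); km <- match(pr[2], types)
    opp <- opp + sum(Bi == kp & Bj == km) + sum(Bi == km & Bj == kp)
  }
  list(co = co, same = same, per = per, opp = opp,
       di = sum(Bi > 0), dj = sum(Bj > 0))
}

# brute-force mixture tail: enumerate every pair of event subsets the two
# agents could choose and sum exact binomial match probabilities
bf_mixture_tail <- function(k, N, Ni, Nj, p) {
  if (k <= 0) return(1)
  Si <- utils::combn(N, Ni)
  Sj <- utils::combn(N, Nj)
  Ii <- matrix(0L, N, ncol(Si)); Ii[cbind(as.vector(Si), rep(seq_len(ncol(Si)), each = Ni))] <- 1L
  Ij <- matrix(0L, N, ncol(Sj)); Ij[cbind(as.vector(Sj), rep(seq_len(ncol(Sj)), each = Nj))] <- 1L
  X <- crossprod(Ii, Ij)  # overlap for every subset pair
  tail_given_x <- function(x) {
    if (x < k) return(0)
    y <- k:x
    sum(choose(x, y) * p^y * (1 - p)^(x - y))
  }
  xs <- sort(unique(as.vector(X)))
  tails <- vapply(xs, tail_given_x, 0)
  freq <- tabulate(match(as.vector(X), xs), length(xs))
  sum(freq * tails) / length(X)
}

# brute-force signed triangle census over all vertex triples
bf_triads <- function(edges, nodes) {
  sgn <- setNames(ifelse(edges$sign == "positive", 1L, -1L),
                  paste(pmin(edges$agent_i, edges$agent_j),
                        pmax(edges$agent_i, edges$agent_j)))
  out <- c(ppp = 0L, pmm = 0L, ppm = 0L, mmm = 0L)
  if (length(nodes) < 3) return(out)
  trip <- utils::combn(nodes, 3)
  for (t in seq_len(ncol(trip))) {
    v <- trip[, t]
    ks <- c(paste(min(v[1], v[2]), max(v[1], v[2])),
            paste(min(v[1], v[3]), max(v[1], v[3])),
            paste(min(v[2], v[3]), max(v[2], v[3])))
    if (!all(ks %in% names(sgn))) next
    nn <- sum(sgn[ks] < 0)
    out[c("ppp", "ppm", "pmm", "mmm")[nn + 1]] <-
      out[c("ppp", "ppm", "pmm", "mmm")[nn + 1]] + 1L
  }
  out
}

# wrap an edge tibble as a signed_network for census/jaccard tests
make_signed <- function(edges, nodes) {
  structure(list(nodes = nodes, edges = edges, alpha = 0.01,
                 correction = "none", n_tests = c(positive = 0L),
                 thresholds = c(positive = 0.01), model = "mixture",
                 aggregation = NA_character_, preference_mode = "per_agent",
                 family = "per_sign"),
            class = "signed_network")
}

random_signed <- function(seed, n_nodes = 6, p_edge = 0.7) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  cmb <- utils::combn(nodes, 2)
  keep <- runif(ncol(cmb)) < p_edge
  edges <- tibble::tibble(
    agent_i = cmb[1, keep], agent_j = cmb[2, keep],
    sign = sample(c("positive", "negative"), sum(keep), replace = TRUE),
    p_value = runif(sum(keep), 0, 0.001),
    co_events = 1L, same_type = 1L, opposing_type = 0L)
  make_signed(edges, nodes)
}
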