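# Normalize a ground-truth graph to node names + adjacency list.
# Accepts a two-column edge data frame or an igraph object.
as_truth_graph <- function(graph) {
  if (inherits(graph, "igraph")) {
    el <- igraph::as_edgelist(graph)
    nodes <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
    graph <- data.frame(from = as.character(el[, 1]), to = as.character(el[, 2]))
  } else {
    graph <- as.data.frame(graph)
    if (ncol(graph) < 2) stop("edge list needs two columns")
    names(graph)[1:2] <- c("from", "to")
    graph$from <- as.character(graph$from)
    graph$to <- as.character(graph$to)
    nodes <- unique(c(graph$from, graph$to))
  }
  if (any(graph$from == graph$to)) stop("self-loops are not allowed")
  key <- paste(pmin(graph$from, graph$to), pmax(graph$from, graph$to))
  if (anyDuplicated(key)) {
    graph <- graph[!duplicated(key), ]
  }
  n <- length(nodes)
  fi <- match(graph$from, nodes)
  ti <- match(graph$to, nodes)
  adj <- vector("list", n)
  for (v in seq_len(n)) {
    adj[[v]] <- sort(c(ti[fi == v], fi[ti == v]))
  }
  list(nodes = nodes, edges = tibble::tibble(from = graph$from, to = graph$to),
       adj = adj)
}

#' Sample per-agent attributes of the influence model
#'
#' Each agent of the ground-truth graph receives three fixed attributes for a
#' bipartite-network realization: a probability `connect_prob` of joining an
#' event when exposed to it, a probability `mimic_prob` of copying a
#' neighbor's link type rather than drawing from its own preferences, and a
#' link-type preference vector. The two probabilities are uniform on the
#' given ranges. Preferences are drawn in two stages: a per-agent
#' concentration level `s ~ Uniform(concentration_range)` is mapped to a
#' symmetric Dirichlet parameter `s / (1 - s)`, so realizations span the full
#' range from complete concentration on one link type (`s = 0`, a one-hot
#' vector) to exactly equal preference for all types (`s = 1`).
#'
#' @param graph Ground-truth graph (edge data frame or igraph).
#' @param n_types Number of link types.
#' @param ni_range,ci_range Ranges (length-2 in `[0, 1]`) for the connect and
#'   mimic probabilities.
#' @param concentration_range Range for the preference concentration level.
#' @param link_types Names of the link types (default `a1, a2, ...`).
#' @return A tibble with `agent`, `connect_prob`, `mimic_prob` and one
#'   `pref_<type>` column per type.
#' @export
sample_influence_attributes <- function(graph, n_types = 3,
                                        ni_range = c(0, 1),
                                        ci_range = c(0, 1),
                                        concentration_range = c(0, 1),
                                        link_types = paste0("a", seq_len(n_types))) {
  tg <- as_truth_graph(graph)
  n <- length(tg$nodes)
  check_range <- function(r, nm) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] > 1) {
      stop("`", nm, "` must be an increasing range within [0, 1]")
    }
  }
  check_range(ni_range, "ni_range")
  check_range(ci_range, "ci_range")
  check_range(concentration_range, "concentration_range")

  ni <- runif(n, ni_range[1], ni_range[2])
  ci <- runif(n, ci_range[1], ci_range[2])
  s <- runif(n, concentration_range[1], concentration_range[2])
  prefs <- t(vapply(s, function(si) rdirichlet_sym(n_types, si / (1 - si)),
                    numeric(n_types)))
  colnames(prefs) <- paste0("pref_", link_types)
  tibble::tibble(agent = tg$nodes, connect_prob = ni, mimic_prob = ci,
                 !!!tibble::as_tibble(prefs))
}

# symmetric Dirichlet draw; alpha = 0 degenerates to a one-hot vector,
# alpha = Inf to the exactly uniform vector
rdirichlet_sym <- function(n_types, alpha) {
  if (!is.finite(alpha)) return(rep(1 / n_types, n_types))
  if (alpha <= 0) {
    out <- numeric(n_types)
    out[sample.int(n_types, 1)] <- 1
    return(out)
  }
  g <- rgamma(n_types, shape = alpha)
  if (sum(g) == 0) {  # extreme concentration underflow: treat as one-hot
    out <- numeric(n_types)
    out[sample.int(n_types, 1)] <- 1
    return(out)
  }
  g / sum(g)
}

# one influence-model event on prepared structures;
# returns integer vector over nodes: 0 = not connected, k = link-type index.
# exposure = "per_neighbor": standard independent-cascade semantics, every
# newly connected neighbor gives an undecided agent one independent
# connection attempt; "once": each agent decides a single time per event.
cascade_once <- function(adj, ni, ci, pref_mat, exposure = "once") {
  n <- length(adj)
  type <- integer(n)
  decided <- logical(n)
  seed <- sample.int(n, 1)
  decided[seed] <- TRUE
  type[seed] <- sample.int(ncol(pref_mat), 1, prob = pref_mat[seed, ])
  queue <- seed
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (type[w] > 0 || (exposure == "once" && decided[w])) next
      decided[w] <- TRUE
      if (runif(1) <= ni[w]) {
        if (runif(1) <= ci[w]) {
          donors <- adj[[w]][type[adj[[w]]] > 0]
          donor <- if (length(donors) == 1) donors else
            donors[sample.int(length(donors), 1)]
          type[w] <- type[donor]
        } else {
          type[w] <- sample.int(ncol(pref_mat), 1, prob = pref_mat[w, ])
        }
        queue <- c(queue, w)
      }
    }
  }
  type
}

#' Simulate one influence-model event cascade
#'
#' A single event node is added and participation spreads over the
#' ground-truth graph in breadth-first order: a uniformly chosen seed agent
#' always connects (with a link type drawn from its own preferences); then
#' every not-yet-decided graph neighbor of a connected agent decides, once
#' per event, to connect with its probability `connect_prob`. An agent that
#' connects copies the link type of a uniformly chosen already-connected
#' graph neighbor with probability `mimic_prob`, and otherwise draws from its
#' own preference vector. The cascade stops when the frontier is empty, so
#' agents outside the seed's component never connect.
#'
#' @inheritParams sample_influence_attributes
#' @param attrs Attribute tibble from [sample_influence_attributes()].
#' @param exposure `"once"` (default: each agent decides a single time per
#'   event, on first exposure) or `"per_neighbor"` (classical
#'   independent-cascade semantics: every newly connected graph neighbor
#'   gives a still-unconnected agent one more independent connection
#'   attempt, raising effective connectivity).
#' @return A tibble with one row per connected agent: `agent`, `link_type`.
#' @export
simulate_event_cascade <- function(graph, attrs,
                                   exposure = c("once", "per_neighbor")) {
  exposure <- match.arg(exposure)
  tg <- as_truth_graph(graph)
  pa <- prepare_attrs(tg, attrs)
  type <- cascade_once(tg$adj, pa$ni, pa$ci, pa$pref, exposure)
  on <- which(type > 0)
  tibble::tibble(agent = tg$nodes[on], link_type = pa$types[type[on]])
}

prepare_attrs <- function(tg, attrs) {
  attrs <- as.data.frame(attrs)
  if (!all(tg$nodes %in% attrs$agent)) {
    stop("`attrs` must contain every graph node")
  }
  attrs <- attrs[match(tg$nodes, attrs$agent), ]
  pref_cols <- grep("^pref_", names(attrs), value = TRUE)
  pref <- as.matrix(attrs[pref_cols])
  list(ni = attrs$connect_prob, ci = attrs$mimic_prob, pref = pref,
       types = sub("^pref_", "", pref_cols))
}

#' Generate a synthetic typed bipartite network with the influence model
#'
#' Runs `n_events` independent event cascades (see
#' [simulate_event_cascade()]) over the ground-truth graph and assembles the
#' results into one typed bipartite network: the graph nodes become the
#' agents, the cascades become events `event_001, event_002, ...`. By
#' construction, agents adjacent in the ground-truth graph co-attend events
#' (and share link types) more often than non-adjacent ones, which is what
#' the downstream validation methods are benchmarked on. Attributes are
#' sampled once per realization unless supplied.
#'
#' @inheritParams sample_influence_attributes
#' @param n_events Number of event cascades (the benchmark setting is 100).
#' @param attrs Optional attribute tibble; sampled fresh when `NULL`.
#' @param seed Optional integer seed; a fixed seed makes the realization
#'   (attributes and cascades, in that order) fully reproducible.
#' @return A [typed_bipartite()] network.
#' @examples
#' net <- simulate_bipartite(karate_club(), n_events = 20, seed = 1)
#' net
#' @export
simulate_bipartite <- function(graph, n_events = 100, n_types = 3,
                               attrs = NULL, seed = NULL,
                               ni_range = c(0, 1), ci_range = c(0, 1),
                               concentration_range = c(0, 1),
                               exposure = c("once", "per_neighbor")) {
  exposure <- match.arg(exposure)
  if (n_events < 1) stop("`n_events` must be >= 1")
  if (n_types < 2) stop("`n_types` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tg <- as_truth_graph(graph)
  if (is.null(attrs)) {
    attrs <- sample_influence_attributes(
      tg$edges, n_types = n_types, ni_range = ni_range, ci_range = ci_range,
      concentration_range = concentration_range)
  }
  pa <- prepare_attrs(tg, attrs)
  ev_names <- sprintf("event_%03d", seq_len(n_events))
  B <- matrix(0L, nrow = length(tg$nodes), ncol = n_events,
              dimnames = list(tg$nodes, ev_names))
  for (t in seq_len(n_events)) {
    B[, t] <- cascade_once(tg$adj, pa$ni, pa$ci, pa$pref, exposure)
  }
  structure(
    list(agents = tg$nodes, events = ev_names,
         types = link_type_set(pa$types), B = B),
    class = "typed_bipartite"
  )
}
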