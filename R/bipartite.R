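#' Build a typed bipartite network from incidence records
#'
#' Constructs the central data object of the package: a bipartite network
#' `G = (U, V, E)` between agents and events, where each edge carries one of a
#' declared set of link types. The incidence is stored as an agent-by-event
#' matrix whose entries index the link type used (0 meaning no connection);
#' at most one link may exist per (agent, event) pair.
#'
#' @param records A data frame with columns `agent_id`, `event_id`,
#'   `link_type`, one row per agent-event connection.
#' @param link_types A [link_type_set()] declaring the admissible types.
#' @param agents,events Optional character vectors declaring (and ordering)
#'   the full agent/event universes. When omitted they are taken from the
#'   records in first-appearance order. Events nobody attended can only be
#'   represented by declaring them here; the event set must be non-empty.
#'
#' @return An object of class `typed_bipartite` with elements `agents`,
#'   `events`, `types` and the integer incidence matrix `B`.
#' @examples
#' lt <- link_type_set(c("a1", "a2"))
#' net <- typed_bipartite(
#'   data.frame(agent_id = c("i", "j", "j"),
#'              event_id = c("e1", "e1", "e2"),
#'              link_type = c("a1", "a1", "a2")),
#'   lt
#' )
#' net
#' @export
typed_bipartite <- function(records, link_types, agents = NULL, events = NULL) {
  stopifnot(inherits(link_types, "link_type_set"))
  records <- as.data.frame(records)
  need <- c("agent_id", "event_id", "link_type")
  if (!all(need %in% names(records))) {
    stop("`records` must have columns agent_id, event_id, link_type")
  }
  records <- records[need]
  records[] <- lapply(records, as.character)

  unknown <- setdiff(unique(records$link_type), link_types$types)
  if (length(unknown) > 0) {
    stop("unknown link type(s): ", paste(unknown, collapse = ", "))
  }

  # duplicates: identical rows collapse with a warning, conflicting types are
  # a hard error naming the offending (agent, event) pair
  key <- paste(records$agent_id, records$event_id, sep = "\r")
  if (anyDuplicated(key)) {
    n_distinct_typed <- length(unique(paste(key, records$link_type, sep = "\r")))
    conflicts <- unique(key[duplicated(key)])
    conflict_types <- vapply(
      conflicts,
      function(k) length(unique(records$link_type[key == k])), 1L
    )
    if (any(conflict_types > 1)) {
      bad <- strsplit(conflicts[which(conflict_types > 1)[1]], "\r")[[1]]
      stop(sprintf("conflicting link types for agent '%s', event '%s'",
                   bad[1], bad[2]))
    }
    warning(sprintf("%d duplicate record(s) collapsed",
                    nrow(records) - n_distinct_typed))
    records <- records[!duplicated(key), ]
  }

  agents <- as.character(agents %||% unique(records$agent_id))
  events <- as.character(events %||% unique(records$event_id))
  if (anyDuplicated(agents)) stop("duplicate agent identifiers declared")
  if (anyDuplicated(events)) stop("duplicate event identifiers declared")
  if (length(events) == 0) {
    stop("the event set must be non-empty (declare `events` explicitly ",
         "when there are no records)")
  }
  if (!all(records$agent_id %in% agents)) {
    stop("records reference undeclared agent(s): ",
         paste(head(setdiff(records$agent_id, agents), 5), collapse = ", "))
  }
  if (!all(records$event_id %in% events)) {
    stop("records reference undeclared event(s): ",
         paste(head(setdiff(records$event_id, events), 5), collapse = ", "))
  }

  B <- matrix(0L, nrow = length(agents), ncol = length(events),
              dimnames = list(agents, events))
  if (nrow(records) > 0) {
    B[cbind(match(records$agent_id, agents), match(records$event_id, events))] <-
      match(records$link_type, link_types$types)
  }
  structure(
    list(agents = agents, events = events, types = link_types, B = B),
    class = "typed_bipartite"
  )
}

#' @export
print.typed_bipartite <- function(x, ...) {
  cat(sprintf("<typed_bipartite> %d agents x %d events, %d links, %d link types\n",
              length(x$agents), length(x$events), sum(x$B > 0),
              length(x$types$types)))
  invisible(x)
}

#' Incidence records of a typed bipartite network
#'
#' @param net A [typed_bipartite()] network.
#' @return A tibble with one row per connection: `agent_id`, `event_id`,
#'   `link_type`, ordered by agent then event (declaration order).
#' @export
incidence <- function(net) {
  stopifnot(inherits(net, "typed_bipartite"))
  idx <- which(net$B > 0, arr.ind = TRUE)
  out <- tibble::tibble(
    agent_id = net$agents[idx[, 1]],
    event_id = net$events[idx[, 2]],
    link_type = net$types$types[net$B[idx]]
  )
  dplyr::arrange(out, match(.data$agent_id, net$agents),
                 match(.data$event_id, net$events))
}

#' Per-agent activity and link-type preference profiles
#'
#' For each agent `i` the profile holds the degree `N_i` (number of events the
#' agent connects to) and the empirical link-type preference vector
#' `p_i(a_k) = #\{events where i used a_k\} / N_i`. Preferences are undefined
#' (`NA`, with `defined = FALSE`) for agents of degree zero.
#'
#' @param net A [typed_bipartite()] network.
#' @param agents Optional subset of agent identifiers.
#' @return A tibble with columns `agent_id`, `degree`, `defined` and one
#'   `pref_<type>` column per link type.
#' @examples
#' net <- table1_network()
#' agent_profiles(net)
#' @export
agent_profiles <- function(net, agents = NULL) {
  stopifnot(inherits(net, "typed_bipartite"))
  agents <- agents %||% net$agents
  if (!all(agents %in% net$agents)) {
    stop("unknown agent(s): ", paste(setdiff(agents, net$agents), collapse = ", "))
  }
  B <- net$B[match(agents, net$agents), , drop = FALSE]
  counts <- type_counts(B, length(net$types$types))
  degree <- rowSums(counts)
  prefs <- counts / ifelse(degree > 0, degree, NA_real_)
  colnames(prefs) <- paste0("pref_", net$types$types)
  tibble::tibble(
    agent_id = agents,
    degree = as.integer(degree),
    defined = degree > 0,
    !!!tibble::as_tibble(prefs)
  )
}

# agents x types matrix of per-type link counts
type_counts <- function(B, n_types) {
  vapply(seq_len(n_types), function(k) rowSums(B == k),
         numeric(nrow(B)))
}

#' Population-level link-type preferences
#'
#' Pools the incidences of all agents into a single preference vector
#' `p(a_k) = sum_i #\{events where i used a_k\} / sum_i N_i`, the alternative
#' to per-agent preference estimation.
#'
#' @param net A [typed_bipartite()] network with at least one connection.
#' @return A tibble with columns `link_type` and `preference` (summing to 1).
#' @export
population_preferences <- function(net) {
  stopifnot(inherits(net, "typed_bipartite"))
  total <- sum(net$B > 0)
  if (total == 0) stop("network has no incidences")
  counts <- vapply(seq_along(net$types$types),
                   function(k) sum(net$B == k), numeric(1))
  tibble::tibble(link_type = net$types$types, preference = counts / total)
}

#' Keep only agents (or events) of sufficient degree
#'
#' Single-pass activity filters: `filter_agents_by_degree()` drops agents
#' connected to fewer than `min_degree` events (as in keeping only investors
#' active on at least ten trading days); `filter_events_by_degree()` drops
#' events attended by fewer than `min_degree` agents (as in keeping only votes
#' with a quorum). The other partition is left untouched and the filter is not
#' iterated.
#'
#' @param net A [typed_bipartite()] network.
#' @param min_degree Minimum degree (inclusive) to be retained.
#' @return A new `typed_bipartite` network.
#' @export
filter_agents_by_degree <- function(net, min_degree) {
  stopifnot(inherits(net, "typed_bipartite"), min_degree >= 0)
  keep <- rowSums(net$B > 0) >= min_degree
  out <- net
  out$agents <- net$agents[keep]
  out$B <- net$B[keep, , drop = FALSE]
  out
}

#' @rdname filter_agents_by_degree
#' @export
filter_events_by_degree <- function(net, min_degree) {
  stopifnot(inherits(net, "typed_bipartite"), min_degree >= 0)
  keep <- colSums(net$B > 0) >= min_degree
  out <- net
  out$events <- net$events[keep]
  out$B <- net$B[, keep, drop = FALSE]
  out
}

#' Discretize signed trading volumes into trading-state link types
#'
#' Converts per-agent, per-event bought/sold volume pairs into one of three
#' trading states via the net-scaled volume
#' `v = (bought - sold) / (bought + sold)`: `"b"` (primarily buying) when
#' `v > theta`, `"s"` (primarily selling) when `v < -theta`, and the neutral
#' day-trading state `"bs"` when `-theta <= v <= theta` (boundary values map
#' to the neutral state so the assignment is total).
#'
#' @param trades A data frame with columns `agent_id`, `event_id`, `bought`,
#'   `sold` (non-negative volumes; each row must have `bought + sold > 0`).
#' @param theta Threshold in (0, 1); the conventional choice is 0.1.
#' @return A tibble of incidence records (`agent_id`, `event_id`, `link_type`)
#'   ready for [typed_bipartite()] with
#'   `link_type_set(c("b","s","bs"), neutral = "bs", opposing = list(c("b","s")))`.
#' @examples
#' trading_states(data.frame(agent_id = "i", event_id = "d1",
#'                           bought = 10, sold = 0))
#' @export
trading_states <- function(trades, theta = 0.1) {
  trades <- as.data.frame(trades)
  need <- c("agent_id", "event_id", "bought", "sold")
  if (!all(need %in% names(trades))) {
    stop("`trades` must have columns agent_id, event_id, bought, sold")
  }
  if (theta <= 0 || theta >= 1) stop("`theta` must lie in (0, 1)")
  if (any(trades$bought < 0 | trades$sold < 0)) {
    stop("volumes must be non-negative")
  }
  tot <- trades$bought + trades$sold
  if (any(tot == 0)) {
    stop(sum(tot == 0), " record(s) with zero total volume produce no link")
  }
  v <- (trades$bought - trades$sold) / tot
  tibble::tibble(
    agent_id = as.character(trades$agent_id),
    event_id = as.character(trades$event_id),
    link_type = dplyr::case_when(v > theta ~ "b", v < -theta ~ "s",
                                 TRUE ~ "bs")
  )
}

#' Read and write incidence tables
#'
#' The tabular interchange format is a headered TSV with columns `agent_id`,
#' `event_id`, `link_type`, one row per connection. Because unattended events
#' cannot appear in such a table, `read_incidence()` accepts either an
#' explicit `events` vector or a JSON link-config (see [read_link_config()])
#' carrying the full universes; `write_incidence()` can emit that config
#' alongside the table so the round trip is lossless.
#'
#' @param path Path of the TSV file.
#' @param link_types A [link_type_set()], or `NULL` when `config` is given.
#' @param config Optional path of a JSON link-config declaring types (and
#'   possibly agent/event universes).
#' @param agents,events Optional explicit universes (override the config).
#' @return `read_incidence()` returns a [typed_bipartite()] network.
#' @export
read_incidence <- function(path, link_types = NULL, config = NULL,
                           agents = NULL, events = NULL) {
  if (!is.null(config)) {
    cfg <- read_link_config(config)
    link_types <- link_types %||% cfg$link_types
    agents <- agents %||% cfg$agents
    events <- events %||% cfg$events
  }
  if (is.null(link_types)) stop("supply `link_types` or a `config` path")
  rec <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  typed_bipartite(rec, link_types, agents = agents, events = events)
}

#' @param net A [typed_bipartite()] network to write.
#' @param config_path Optional path; when given, [write_link_config()] is
#'   called so types and universes are preserved.
#' @rdname read_incidence
#' @export
write_incidence <- function(net, path, config_path = NULL) {
  stopifnot(inherits(net, "typed_bipartite"))
  readr::write_tsv(incidence(net), path, progress = FALSE)
  if (!is.null(config_path)) write_link_config(net, config_path)
  invisible(path)
}

#' Bundled fixtures: Zachary karate club and the two-agent example network
#'
#' `karate_club()` returns the classical 34-node, 78-edge karate club social
#' network as an edge tibble; it is the ground-truth graph used throughout the
#' reconstruction benchmarks. `table1_network()` returns the worked two-agent
#' example: agents `i` and `j` connected to 100 events via three link types
#' (`a1` neutral, `a2`/`a3` opposing), with degrees 40 and 30, 21 shared
#' events, 2 same-type and 17 opposing-type overlaps.
#'
#' @return `karate_club()`: a tibble with columns `from`, `to` (node labels
#'   `"1" ... "34"`). `table1_network()`: a [typed_bipartite()] network.
#' @examples
#' nrow(karate_club())
#' table1_network()
#' @export
karate_club <- function() {
  path <- system.file("extdata", "zachary_karate.tsv", package = "bipval",
                      mustWork = TRUE)
  el <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  tibble::as_tibble(el)
}

#' @rdname karate_club
#' @export
table1_network <- function() {
  read_incidence(
    system.file("extdata", "table1_incidence.tsv", package = "bipval",
                mustWork = TRUE),
    config = system.file("extdata", "table1_types.json", package = "bipval",
                         mustWork = TRUE)
  )
}
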