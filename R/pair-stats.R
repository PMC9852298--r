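# Matrix-level sufficient statistics for all agent pairs.
# Returns agent x agent matrices: co_events N_ij, same_type Ntilde_ij,
# opposing_type Nd_ij (NULL when no opposing pairs are declared), the
# per-type overlaps, and the chance probabilities p_ij / q_ij under the
# requested preference mode.
pair_stat_core <- function(net, preference_mode = c("per_agent", "population")) {
  preference_mode <- match.arg(preference_mode)
  B <- net$B
  n_types <- length(net$types$types)
  M <- B > 0
  storage.mode(M) <- "double"
  co <- tcrossprod(M)

  overlaps <- lapply(seq_len(n_types), function(k) {
    Mk <- B == k
    storage.mode(Mk) <- "double"
    tcrossprod(Mk)
  })
  same <- Reduce(`+`, overlaps)

  opp <- NULL
  if (length(net$types$opposing) > 0) {
    opp <- matrix(0, nrow(B), nrow(B))
    for (pr in net$types$opposing) {
      kp <- match(pr[1], net$types$types)
      km <- match(pr[2], net$types$types)
      Mp <- B == kp; Mm <- B == km
      storage.mode(Mp) <- "double"; storage.mode(Mm) <- "double"
      opp <- opp + tcrossprod(Mp, Mm) + tcrossprod(Mm, Mp)
    }
  }

  counts <- type_counts(B, n_types)
  degree <- rowSums(counts)
  P <- counts / ifelse(degree > 0, degree, NA_real_)
  if (preference_mode == "population") {
    total <- sum(counts)
    if (total == 0) {
      P[] <- NA_real_
    } else {
      pop <- colSums(counts) / total
      P <- matrix(pop, nrow = nrow(B), ncol = n_types, byrow = TRUE)
      P[degree == 0, ] <- NA_real_
    }
  }
  p_same <- tcrossprod(P)
  q_opp <- NULL
  if (length(net$types$opposing) > 0) {
    q_opp <- matrix(0, nrow(B), nrow(B))
    for (pr in net$types$opposing) {
      kp <- match(pr[1], net$types$types)
      km <- match(pr[2], net$types$types)
      q_opp <- q_opp + tcrossprod(P[, kp], P[, km]) + tcrossprod(P[, km], P[, kp])
    }
  }

  list(
    agents = net$agents, n_events = length(net$events),
    degree = setNames(as.integer(degree), net$agents),
    co_events = co, same_type = same, opposing_type = opp,
    per_type = overlaps, p_same = p_same, q_opp = q_opp,
    prefs = P, type_counts = counts, types = net$types$types
  )
}

# all unordered pairs in lexicographic identifier order
lexico_pairs <- function(agents) {
  ord <- sort_ids(agents)
  if (length(ord) < 2) {
    return(tibble::tibble(agent_i = character(), agent_j = character()))
  }
  cmb <- utils::combn(ord, 2)
  tibble::tibble(agent_i = cmb[1, ], agent_j = cmb[2, ])
}

#' Pairwise sufficient statistics of a typed bipartite network
#'
#' For each unordered pair of agents `(i, j)` computes every quantity the null
#' models consume: the co-attendance count `N_ij`, the same-type overlap
#' `Ntilde_ij` (events where both agents are connected *via the same type*;
#' events where both are absent never count), the opposing-type overlap
#' `Nd_ij` over declared opposing pairs, the per-type overlaps `N_ij(a_k)`,
#' and the chance probabilities `p_same = sum_k p_i(a_k) p_j(a_k)` and
#' `q_opposing = sum_(a+,a-) p_i(a+) p_j(a-) + p_i(a-) p_j(a+)`.
#'
#' Pairs involving a degree-zero agent are returned with zero counts and `NA`
#' probabilities. All statistics are symmetric in `(i, j)`; pairs are listed
#' with `agent_i < agent_j` in lexicographic order.
#'
#' @param net A [typed_bipartite()] network.
#' @param pairs Optional data frame with columns `agent_i`, `agent_j`
#'   selecting specific pairs; defaults to all unordered pairs.
#' @param preference_mode `"per_agent"` (default) estimates a preference
#'   vector per agent; `"population"` pools all agents into one vector.
#' @return A tibble with one row per pair: identifiers, `n_events`,
#'   `degree_i`, `degree_j`, `co_events`, `same_type`, `opposing_type`,
#'   one `overlap_<type>` column per link type, `p_same` and `p_opposing`
#'   (`NA` when no opposing pairs are declared).
#' @examples
#' pair_statistics(table1_network())
#' @export
pair_statistics <- function(net, pairs = NULL,
                            preference_mode = c("per_agent", "population")) {
  stopifnot(inherits(net, "typed_bipartite"))
  core <- pair_stat_core(net, preference_mode)
  pairs <- if (is.null(pairs)) {
    lexico_pairs(net$agents)
  } else {
    tibble::tibble(agent_i = as.character(pairs$agent_i),
                   agent_j = as.character(pairs$agent_j))
  }
  if (any(pairs$agent_i == pairs$agent_j)) stop("pairs must have agent_i != agent_j")
  bad <- setdiff(c(pairs$agent_i, pairs$agent_j), net$agents)
  if (length(bad) > 0) stop("unknown agent(s): ", paste(bad, collapse = ", "))

  ii <- match(pairs$agent_i, net$agents)
  jj <- match(pairs$agent_j, net$agents)
  idx <- cbind(ii, jj)
  out <- tibble::tibble(
    agent_i = pairs$agent_i,
    agent_j = pairs$agent_j,
    n_events = core$n_events,
    degree_i = core$degree[ii],
    degree_j = core$degree[jj],
    co_events = as.integer(core$co_events[idx]),
    same_type = as.integer(core$same_type[idx]),
    opposing_type = if (is.null(core$opposing_type)) NA_integer_ else
      as.integer(core$opposing_type[idx])
  )
  for (k in seq_along(core$types)) {
    out[[paste0("overlap_", core$types[k])]] <- as.integer(core$per_type[[k]][idx])
  }
  out$p_same <- core$p_same[idx]
  out$p_opposing <- if (is.null(core$q_opp)) NA_real_ else core$q_opp[idx]
  out
}

#' Herfindahl-Hirschman concentration of link-type overlap
#'
#' Measures how concentrated the same-type overlap of a pair is across link
#' types: `HH = sum_k N_ij(a_k)^2 / Ntilde_ij^2`, ranging from `1/n` (overlap
#' split equally over all `n` types) to 1 (all overlap in a single type).
#' Undefined (`NA`) when the pair has no same-type overlap.
#'
#' @param x Either a numeric vector of per-type overlap counts, or a data
#'   frame with `overlap_<type>` columns as produced by [pair_statistics()]
#'   (a `hh` column is appended).
#' @return A single number in `[1/n, 1]`, or the input tibble with an added
#'   `hh` column.
#' @examples
#' herfindahl_hirschman(c(2, 0, 0))  # 1
#' herfindahl_hirschman(c(1, 1, 1))  # 1/3
#' @export
herfindahl_hirschman <- function(x) {
  if (is.data.frame(x)) {
    cols <- grep("^overlap_", names(x), value = TRUE)
    if (length(cols) == 0) stop("no overlap_<type> columns found")
    O <- as.matrix(x[cols])
    tot <- rowSums(O)
    x$hh <- ifelse(tot > 0, rowSums(O^2) / tot^2, NA_real_)
    return(x)
  }
  x <- as.numeric(x)
  if (any(x < 0)) stop("overlap counts must be non-negative")
  tot <- sum(x)
  if (tot == 0) {
    warning("zero same-type overlap: concentration undefined")
    return(NA_real_)
  }
  sum(x^2) / tot^2
}
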