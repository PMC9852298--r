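# p-values for a set of pairs given precomputed sufficient statistics.
# Returns a numeric vector aligned with (ii, jj) index vectors.
pair_pvalues <- function(core, ii, jj, mode, model, aggregation = "min") {
  N <- core$n_events
  di <- core$degree[ii]
  dj <- core$degree[jj]
  idx <- cbind(ii, jj)
  if (model == "mixture") {
    if (mode == "positive") {
      k <- core$same_type[idx]
      p <- core$p_same[idx]
    } else {
      if (is.null(core$opposing_type)) {
        stop("negative validation requires declared opposing link-type pairs")
      }
      k <- core$opposing_type[idx]
      p <- core$q_opp[idx]
    }
    out <- rep(NA_real_, length(ii))
    ok <- di > 0 & dj > 0 & !is.na(p)
    out[ok] <- mapply(hb_mix_scalar, k[ok], N, di[ok], dj[ok], p[ok])
    return(out)
  }
  # reference null: per-type hypergeometric upper tails on per-type degrees
  if (mode != "positive") {
    stop("the reference null validates same-type overlap only (mode = \"positive\")")
  }
  per_type <- vapply(seq_along(core$types), function(k) {
    ok_k <- core$per_type[[k]][idx]
    mk <- core$type_counts[ii, k]
    nk <- core$type_counts[jj, k]
    phyper(ok_k - 1, mk, N - mk, nk, lower.tail = FALSE)
  }, numeric(length(ii)))
  per_type <- matrix(per_type, nrow = length(ii))
  undefined <- di == 0 | dj == 0
  agg <- switch(aggregation,
    min  = apply(per_type, 1, min),
    mean = rowMeans(per_type),
    max  = apply(per_type, 1, max),
    none = per_type,
    stop("unknown aggregation: ", aggregation)
  )
  if (aggregation == "none") {
    agg[undefined, ] <- NA_real_
    colnames(agg) <- paste0("p_", core$types)
  } else {
    agg[undefined] <- NA_real_
  }
  agg
}

#' Statistically validate agent pairs of a typed bipartite network
#'
#' Assigns each unordered agent pair a p-value for the null hypothesis that
#' its link-type overlap arose by chance. Under the default mixture model the
#' observed same-type overlap `Ntilde_ij` (mode `"positive"`) or
#' opposing-type overlap `Nd_ij` (mode `"negative"`) is referred to the
#' hypergeometric-binomial mixture null ([hb_mixture_survival()]) with
#' success probability `p_ij` resp. `q_ij`. Under the `"reference"` model,
#' each link type is tested separately with a hypergeometric upper tail on
#' per-type degrees, and the per-type p-values are aggregated with `min`
#' (the sharpest reference), `mean`, `max`, or returned unaggregated
#' (`"none"`).
#'
#' Pairs involving a degree-zero agent cannot be tested and receive `NA`.
#'
#' @inheritParams pair_statistics
#' @param mode `"positive"` (same-type overlap) or `"negative"`
#'   (opposing-type overlap; mixture model only, requires declared opposing
#'   pairs).
#' @param model `"mixture"` or `"reference"`.
#' @param aggregation Aggregation of per-type reference p-values.
#' @return The [pair_statistics()] tibble with an appended `p_value` column
#'   (or `p_<type>` columns for `aggregation = "none"`).
#' @examples
#' net <- table1_network()
#' validate_pairs(net, mode = "positive")$p_value    # 0.967
#' validate_pairs(net, mode = "negative")$p_value    # 1.70e-7
#' @export
validate_pairs <- function(net, mode = c("positive", "negative"),
                           model = c("mixture", "reference"),
                           aggregation = c("min", "mean", "max", "none"),
                           pairs = NULL,
                           preference_mode = c("per_agent", "population")) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  aggregation <- match.arg(aggregation)
  preference_mode <- match.arg(preference_mode)
  stats <- pair_statistics(net, pairs = pairs, preference_mode = preference_mode)
  core <- pair_stat_core(net, preference_mode)
  ii <- match(stats$agent_i, net$agents)
  jj <- match(stats$agent_j, net$agents)
  p <- pair_pvalues(core, ii, jj, mode, model, aggregation)
  if (is.matrix(p)) {
    stats <- dplyr::bind_cols(stats, tibble::as_tibble(p))
  } else {
    stats$p_value <- p
  }
  n_skip <- if (is.matrix(p)) sum(is.na(p[, 1])) else sum(is.na(p))
  if (n_skip > 0) {
    message(n_skip, " pair(s) skipped: degree-zero agent, preferences undefined")
  }
  stats
}

#' @param i,j Agent identifiers of a single pair.
#' @rdname validate_pairs
#' @export
validate_pair <- function(net, i, j, mode = c("positive", "negative"),
                          model = c("mixture", "reference"),
                          aggregation = c("min", "mean", "max", "none"),
                          preference_mode = c("per_agent", "population")) {
  if (i == j) stop("`i` and `j` must differ")
  validate_pairs(net, mode = mode, model = model, aggregation = aggregation,
                 pairs = tibble::tibble(agent_i = min(i, j), agent_j = max(i, j)),
                 preference_mode = preference_mode)
}

#' Project a typed bipartite network onto a validated signed network
#'
#' Tests every unordered pair of positive-degree agents in the requested sign
#' modes, applies multiple-test correction, and links the pairs whose
#' p-values fall below the (corrected) significance threshold. Positive links
#' come from significant same-type overlap, negative links from significant
#' opposing-type overlap. With Bonferroni correction the threshold is
#' `alpha / m`; by default the positive and negative tests form two
#' independent correction families, each with `m` equal to the number of
#' tested pairs (`family = "joint"` pools them into a single family with
#' `m = ` total number of tests).
#'
#' @inheritParams validate_pairs
#' @param alpha Significance level in (0, 1).
#' @param correction `"bonferroni"` or `"none"`.
#' @param modes Character vector of sign modes to test (reference model:
#'   `"positive"` only).
#' @param family Bonferroni family layout, `"per_sign"` or `"joint"`.
#' @return A `signed_network` object: eligible agents as `nodes`, an edge
#'   tibble with raw p-values, and the validation settings. Use [tidy()] for
#'   the edges, [glance()] for a one-row summary, `autoplot()` to draw it.
#' @examples
#' project(table1_network(), alpha = 0.01)
#' @export
project <- function(net, alpha = 0.01, correction = c("bonferroni", "none"),
                    modes = c("positive", "negative"),
                    model = c("mixture", "reference"),
                    aggregation = c("min", "mean", "max"),
                    preference_mode = c("per_agent", "population"),
                    family = c("per_sign", "joint")) {
  stopifnot(inherits(net, "typed_bipartite"))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  correction <- match.arg(correction)
  model <- match.arg(model)
  aggregation <- match.arg(aggregation)
  preference_mode <- match.arg(preference_mode)
  family <- match.arg(family)
  modes <- match.arg(modes, c("positive", "negative"), several.ok = TRUE)
  if (model == "reference") modes <- "positive"

  core <- pair_stat_core(net, preference_mode)
  eligible <- names(core$degree)[core$degree > 0]
  n_zero <- length(net$agents) - length(eligible)
  if (n_zero > 0) {
    message(n_zero, " degree-zero agent(s) excluded from validation")
  }
  pairs <- lexico_pairs(eligible)
  if (nrow(pairs) == 0) {
    warning("no eligible agent pairs: empty network")
  }
  ii <- match(pairs$agent_i, net$agents)
  jj <- match(pairs$agent_j, net$agents)
  idx <- cbind(ii, jj)

  m_per_mode <- setNames(rep(nrow(pairs), length(modes)), modes)
  m_eff <- if (family == "joint") sum(m_per_mode) else m_per_mode
  thresholds <- switch(correction,
    none = setNames(rep(alpha, length(modes)), modes),
    bonferroni = alpha / pmax(m_eff, 1)
  )
  if (family == "joint") thresholds <- setNames(rep(thresholds[1], length(modes)), modes)

  edges <- purrr::map_dfr(modes, function(md) {
    p <- pair_pvalues(core, ii, jj, md, model, aggregation)
    keep <- !is.na(p) & p < thresholds[[md]]
    tibble::tibble(
      agent_i = pairs$agent_i[keep],
      agent_j = pairs$agent_j[keep],
      sign = if (md == "positive") "positive" else "negative",
      p_value = p[keep],
      co_events = as.integer(core$co_events[idx][keep]),
      same_type = as.integer(core$same_type[idx][keep]),
      opposing_type = if (is.null(core$opposing_type)) NA_integer_ else
        as.integer(core$opposing_type[idx][keep])
    )
  })
  edges <- dplyr::arrange(edges, .data$agent_i, .data$agent_j, .data$sign)

  structure(
    list(
      nodes = sort_ids(eligible),
      edges = edges,
      alpha = alpha,
      correction = correction,
      n_tests = m_per_mode,
      thresholds = thresholds,
      model = model,
      aggregation = if (model == "reference") aggregation else NA_character_,
      preference_mode = preference_mode,
      family = family
    ),
    class = "signed_network"
  )
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf(
    "<signed_network> %d nodes, %d positive / %d negative links (model %s, alpha %g, %s)\n",
    length(x$nodes), sum(x$edges$sign == "positive"),
    sum(x$edges$sign == "negative"), x$model, x$alpha, x$correction))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for validated signed networks
#'
#' `tidy()` returns the edge list (one row per validated link with its sign
#' and raw p-value); `glance()` returns a one-row summary of the network and
#' of the validation settings.
#'
#' @param x A `signed_network` from [project()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy signed_network
#' @export
tidy.signed_network <- function(x, ...) x$edges

#' @rdname tidy.signed_network
#' @method glance signed_network
#' @export
glance.signed_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_positive = sum(x$edges$sign == "positive"),
    n_negative = sum(x$edges$sign == "negative"),
    alpha = x$alpha,
    correction = x$correction,
    n_tests = sum(x$n_tests),
    model = x$model,
    preference_mode = x$preference_mode
  )
}

#' Write a signed edge list as TSV
#'
#' @param snet A `signed_network`.
#' @param path Output path.
#' @export
write_signed_edges <- function(snet, path) {
  stopifnot(inherits(snet, "signed_network"))
  readr::write_tsv(tidy(snet), path, progress = FALSE)
  invisible(path)
}

# resolve multi-sign pairs and build an undirected igraph with a sign attribute
resolve_signed_graph <- function(snet, multi_edge = c("min_p", "exclude")) {
  multi_edge <- match.arg(multi_edge)
  e <- snet$edges
  if (nrow(e) > 0) {
    e <- e |>
      dplyr::group_by(.data$agent_i, .data$agent_j) |>
      (\(g) if (multi_edge == "min_p") {
        dplyr::slice_min(g, .data$p_value, n = 1, with_ties = FALSE)
      } else {
        dplyr::filter(g, dplyr::n() == 1)
      })() |>
      dplyr::ungroup()
  }
  g <- igraph::graph_from_data_frame(
    e[c("agent_i", "agent_j")], directed = FALSE,
    vertices = data.frame(name = snet$nodes)
  )
  igraph::E(g)$sign <- ifelse(e$sign == "positive", 1L, -1L)
  igraph::E(g)$p_value <- e$p_value
  g
}

#' Convert a signed network to an igraph object
#'
#' Edges carry `sign` (+1/-1) and `p_value` attributes; when a pair is linked
#' both positively and negatively, the edge with the smaller p-value is kept
#' (or the pair is dropped with `multi_edge = "exclude"`).
#'
#' @inheritParams write_signed_edges
#' @param multi_edge Resolution rule for pairs carrying both signs.
#' @return An undirected [igraph::graph].
#' @export
as_igraph <- function(snet, multi_edge = c("min_p", "exclude")) {
  stopifnot(inherits(snet, "signed_network"))
  resolve_signed_graph(snet, multi_edge)
}

#' Census of signed triangles under structural balance
#'
#' Enumerates the closed triangles of a signed network and classifies each by
#' its multiset of edge signs: `(+,+,+)` and `(+,-,-)` are *stable* (the
#' product of signs is positive), `(+,+,-)` and `(-,-,-)` are *unstable*.
#' Pairs linked by both a positive and a negative edge are resolved per
#' `multi_edge` before the census.
#'
#' @inheritParams as_igraph
#' @return A one-row tibble with counts `ppp`, `pmm`, `ppm`, `mmm`,
#'   `stable`, `unstable` and `triangles`.
#' @export
triad_census_signed <- function(snet, multi_edge = c("min_p", "exclude")) {
  g <- resolve_signed_graph(snet, multi_edge)
  tri <- matrix(as.integer(igraph::triangles(g)), nrow = 3)
  counts <- c(ppp = 0L, pmm = 0L, ppm = 0L, mmm = 0L)
  if (ncol(tri) > 0) {
    sgn <- igraph::E(g)$sign
    eid <- function(a, b) igraph::get_edge_ids(g, rbind(a, b))
    s1 <- sgn[eid(tri[1, ], tri[2, ])]
    s2 <- sgn[eid(tri[1, ], tri[3, ])]
    s3 <- sgn[eid(tri[2, ], tri[3, ])]
    n_neg <- (s1 < 0) + (s2 < 0) + (s3 < 0)
    counts <- c(
      ppp = sum(n_neg == 0L), pmm = sum(n_neg == 2L),
      ppm = sum(n_neg == 1L), mmm = sum(n_neg == 3L)
    )
  }
  tibble::tibble(
    ppp = counts[["ppp"]], pmm = counts[["pmm"]],
    ppm = counts[["ppm"]], mmm = counts[["mmm"]],
    stable = counts[["ppp"]] + counts[["pmm"]],
    unstable = counts[["ppm"]] + counts[["mmm"]],
    triangles = sum(counts)
  )
}

#' Rolling-window projection p-values
#'
#' Slides a window of `window_size` consecutive events (in declared event
#' order) across the network in steps of `step` events, re-estimates degrees
#' and preferences within each window, and records the validation p-value of
#' each requested pair, window by window. This is the machinery used to track
#' slowly changing agent similarities, e.g. voting-bloc membership over a
#' parliamentary term.
#'
#' @inheritParams validate_pairs
#' @param window_size Number of events per window (`<= ` number of events).
#' @param step Displacement between consecutive window starts.
#' @return A tibble with `window`, `start_event`, `end_event`, `agent_i`,
#'   `agent_j`, `p_value`.
#' @export
rolling_window_projection <- function(net, window_size, step = window_size,
                                      pairs = NULL,
                                      mode = c("positive", "negative"),
                                      model = c("mixture", "reference"),
                                      aggregation = c("min", "mean", "max"),
                                      preference_mode = c("per_agent", "population")) {
  stopifnot(inherits(net, "typed_bipartite"))
  N <- length(net$events)
  if (window_size < 1 || window_size > N) {
    stop("`window_size` must lie in [1, number of events]")
  }
  if (step < 1) stop("`step` must be >= 1")
  mode <- match.arg(mode)
  model <- match.arg(model)
  aggregation <- match.arg(aggregation)
  preference_mode <- match.arg(preference_mode)
  starts <- seq(1L, N - window_size + 1L, by = step)
  purrr::map_dfr(seq_along(starts), function(w) {
    sel <- starts[w]:(starts[w] + window_size - 1L)
    sub <- net
    sub$events <- net$events[sel]
    sub$B <- net$B[, sel, drop = FALSE]
    res <- validate_pairs(sub, mode = mode, model = model,
                          aggregation = aggregation, pairs = pairs,
                          preference_mode = preference_mode)
    tibble::tibble(
      window = w,
      start_event = net$events[starts[w]],
      end_event = net$events[starts[w] + window_size - 1L],
      agent_i = res$agent_i, agent_j = res$agent_j, p_value = res$p_value
    )
  })
}

#' Jaccard similarity of two validated networks
#'
#' Compares the signed edge sets of two networks over unordered agent pairs:
#' `|A intersect B| / |A union B|`, together with the counts of links unique
#' to each network. Two empty networks are defined as identical (similarity
#' 1, with a warning).
#'
#' @param a,b `signed_network` objects.
#' @return A one-row tibble: `jaccard`, `n_common`, `n_only_a`, `n_only_b`.
#' @export
jaccard_links <- function(a, b) {
  stopifnot(inherits(a, "signed_network"), inherits(b, "signed_network"))
  key <- function(s) paste(s$edges$agent_i, s$edges$agent_j, s$edges$sign)
  ka <- unique(key(a)); kb <- unique(key(b))
  union_n <- length(union(ka, kb))
  if (union_n == 0) {
    warning("both networks are empty; similarity defined as 1")
    return(tibble::tibble(jaccard = 1, n_common = 0L,
                          n_only_a = 0L, n_only_b = 0L))
  }
  tibble::tibble(
    jaccard = length(intersect(ka, kb)) / union_n,
    n_common = length(intersect(ka, kb)),
    n_only_a = length(setdiff(ka, kb)),
    n_only_b = length(setdiff(kb, ka))
  )
}

#' Plot a validated signed network
#'
#' Draws the network with a force-directed layout computed from the positive
#' links only (mirroring how validated political networks are usually
#' displayed), positive links solid and negative links dashed.
#'
#' @param object A `signed_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signed_network
#' @export
autoplot.signed_network <- function(object, ...) {
  g <- resolve_signed_graph(object)
  gpos <- igraph::subgraph_from_edges(
    g, igraph::E(g)[igraph::E(g)$sign > 0], delete.vertices = FALSE)
  set.seed(1L)  # layout only
  xy <- igraph::layout_with_fr(gpos)
  nodes <- tibble::tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  e <- tidy(object)
  e <- dplyr::left_join(e, nodes, by = c(agent_i = "name"))
  e <- dplyr::left_join(e, nodes, by = c(agent_j = "name"),
                        suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$sign,
                   linetype = .data$sign),
      linewidth = 0.3, alpha = 0.6) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 2) +
    ggplot2::scale_colour_manual(
      values = c(positive = "#2a9d34", negative = "#d62728")) +
    ggplot2::scale_linetype_manual(
      values = c(positive = "solid", negative = "dashed")) +
    ggplot2::theme_void()
}
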