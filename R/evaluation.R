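pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "\r")

#' Score a reconstructed edge set against a ground-truth graph
#'
#' Builds the confusion table of predicted versus true links over all
#' `choose(n, 2)` unordered node pairs of the ground-truth graph and reports
#' accuracy, precision, recall and F1. An empty prediction has precision
#' (and F1) defined as 0, flagged via `empty_prediction`, so ensemble
#' averages over strict thresholds remain defined.
#'
#' @param predicted A `signed_network` (its positive links are used) or a
#'   data frame with columns `agent_i`, `agent_j`.
#' @param truth Ground-truth graph (edge data frame or igraph).
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `f1`, `accuracy`, `empty_prediction`.
#' @examples
#' truth <- karate_club()
#' reconstruction_scores(truth, truth)  # perfect scores
#' @export
reconstruction_scores <- function(predicted, truth) {
  tg <- as_truth_graph(truth)
  if (inherits(predicted, "signed_network")) {
    predicted <- predicted$edges[predicted$edges$sign == "positive", ]
  }
  predicted <- as.data.frame(predicted)
  if (nrow(predicted) > 0 && ncol(predicted) >= 2) {
    names(predicted)[1:2] <- c("agent_i", "agent_j")
    bad <- setdiff(unique(c(predicted$agent_i, predicted$agent_j)), tg$nodes)
    if (length(bad) > 0) {
      stop("predicted edges reference unknown node(s): ",
           paste(head(bad, 5), collapse = ", "))
    }
  }
  n <- length(tg$nodes)
  total <- choose(n, 2)
  truth_keys <- pair_key(tg$edges$from, tg$edges$to)
  pred_keys <- if (nrow(predicted) > 0) {
    unique(pair_key(as.character(predicted$agent_i),
                    as.character(predicted$agent_j)))
  } else character()
  tp <- length(intersect(pred_keys, truth_keys))
  fp <- length(setdiff(pred_keys, truth_keys))
  fn <- length(setdiff(truth_keys, pred_keys))
  tn <- total - tp - fp - fn
  empty <- length(pred_keys) == 0
  precision <- if (empty) 0 else tp / (tp + fp)
  recall <- if (length(truth_keys) == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = precision, recall = recall, f1 = f1,
    accuracy = (tp + tn) / total,
    empty_prediction = empty
  )
}

#' Rank-based AUC of validation p-values against a ground-truth graph
#'
#' Measures how well per-pair p-values separate true links from non-links:
#' the Mann-Whitney AUC of the score `1 - p` against the edge/non-edge
#' labels, with tied scores mid-ranked. Truth pairs without a supplied
#' p-value are scored as `p = 1` (never co-connected, hence never
#' significant).
#'
#' @param pvalues Data frame with columns `agent_i`, `agent_j`, `p_value`.
#' @param truth Ground-truth graph (edge data frame or igraph).
#' @return The AUC in `[0, 1]`, or `NA` (with a warning) when the labels are
#'   degenerate (all pairs are edges, or none).
#' @export
auc_from_pvalues <- function(pvalues, truth) {
  tg <- as_truth_graph(truth)
  n <- length(tg$nodes)
  pairs <- lexico_pairs(tg$nodes)
  key <- pair_key(pairs$agent_i, pairs$agent_j)
  p <- rep(1, nrow(pairs))
  if (nrow(pvalues) > 0) {
    m <- match(pair_key(as.character(pvalues$agent_i),
                        as.character(pvalues$agent_j)), key)
    if (anyNA(m)) stop("p-values reference pairs outside the truth node set")
    p[m] <- ifelse(is.na(pvalues$p_value), 1, pvalues$p_value)
  }
  labels <- key %in% pair_key(tg$edges$from, tg$edges$to)
  auc_rank(1 - p, labels)
}

# Mann-Whitney AUC with midranks
auc_rank <- function(score, label) {
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) {
    warning("degenerate labels: AUC undefined")
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# fast per-simulation validation used by ensemble_experiment:
# returns p-value vectors for all eligible pairs under every model
validate_models <- function(net, aggregations = c("min", "mean", "max")) {
  core <- pair_stat_core(net, "per_agent")
  eligible <- which(core$degree > 0)
  cmb <- utils::combn(eligible, 2)
  ii <- cmb[1, ]; jj <- cmb[2, ]
  idx <- cbind(ii, jj)
  out <- list(
    agent_i = core$agents[ii], agent_j = core$agents[jj],
    mixture = pair_pvalues(core, ii, jj, "positive", "mixture")
  )
  if (length(aggregations) > 0) {
    per_type <- vapply(seq_along(core$types), function(k) {
      ok_k <- core$per_type[[k]][idx]
      mk <- core$type_counts[ii, k]
      nk <- core$type_counts[jj, k]
      phyper(ok_k - 1, mk, core$n_events - mk, nk, lower.tail = FALSE)
    }, numeric(length(ii)))
    per_type <- matrix(per_type, nrow = length(ii))
    for (a in aggregations) {
      out[[paste0("reference_", a)]] <- switch(a,
        min = apply(per_type, 1, min),
        mean = rowMeans(per_type),
        max = apply(per_type, 1, max))
    }
  }
  out
}

#' Benchmark validation models on an ensemble of simulated networks
#'
#' The reconstruction experiment: simulate `n_sims` typed bipartite networks
#' from a ground-truth graph with the influence model, validate every agent
#' pair of each network with the mixture null and with the per-type
#' hypergeometric reference null (min/mean/max aggregation), and score the
#' results against the ground truth. Reports per-model mean AUCs, mean
#' precision/recall/F1/accuracy per significance level `alpha` (Bonferroni
#' applied per projection), and paired comparisons of the mixture model
#' against a reference aggregation (run-by-run mean differences, paired
#' t-tests, and the fraction of runs where the mixture does at least as
#' well).
#'
#' @inheritParams simulate_bipartite
#' @param n_sims Number of simulated networks (>= 2).
#' @param alpha_grid Significance levels for the threshold sweep.
#' @param correction Multiple-test correction applied at each alpha.
#' @param reference Aggregation of the reference model used in the paired
#'   comparisons; `"min"` is the sharpest reference and the default
#'   benchmark.
#' @param seed Integer master seed; the whole experiment is reproducible
#'   bit-for-bit under a fixed seed.
#' @return An `ensemble_summary` object: a list with per-run tibbles
#'   (`auc_runs`, `metric_runs`), aggregated tibbles (`auc`, `metrics`,
#'   `auc_comparison`, `comparison`) and the configuration. `tidy()` returns
#'   the aggregated threshold metrics, `glance()` the AUC summary.
#' @examples
#' \donttest{
#' ens <- ensemble_experiment(karate_club(), n_sims = 10, seed = 1)
#' glance(ens)
#' }
#' @export
ensemble_experiment <- function(graph, n_sims, n_events = 100, n_types = 3,
                                alpha_grid = 10^(-(10:1)),
                                correction = c("bonferroni", "none"),
                                reference = c("min", "mean", "max"),
                                ni_range = c(0, 1), ci_range = c(0, 1),
                                concentration_range = c(0, 1),
                                exposure = c("once", "per_neighbor"),
                                seed = NULL) {
  exposure <- match.arg(exposure)
  if (n_sims < 2) stop("`n_sims` must be >= 2")
  correction <- match.arg(correction)
  reference <- match.arg(reference)
  if (!is.null(seed)) set.seed(seed)
  tg <- as_truth_graph(graph)
  alpha_grid <- sort(alpha_grid)
  models <- c("mixture", "reference_min", "reference_mean", "reference_max")

  auc_runs <- vector("list", n_sims)
  metric_runs <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    net <- simulate_bipartite(tg$edges, n_events = n_events, n_types = n_types,
                              ni_range = ni_range, ci_range = ci_range,
                              concentration_range = concentration_range,
                              exposure = exposure)
    val <- validate_models(net)
    m <- length(val$mixture)  # tested pairs, Bonferroni family size
    thr <- if (correction == "bonferroni") alpha_grid / m else alpha_grid
    pv_tbl <- function(p) tibble::tibble(agent_i = val$agent_i,
                                         agent_j = val$agent_j, p_value = p)
    auc_runs[[s]] <- tibble::tibble(
      sim = s, model = models,
      auc = vapply(models, function(mod) {
        suppressWarnings(auc_from_pvalues(pv_tbl(val[[mod]]), tg$edges))
      }, numeric(1))
    )
    metric_runs[[s]] <- purrr::map_dfr(models, function(mod) {
      p <- val[[mod]]
      purrr::map_dfr(seq_along(alpha_grid), function(a) {
        keep <- !is.na(p) & p < thr[a]
        sc <- reconstruction_scores(
          tibble::tibble(agent_i = val$agent_i[keep],
                         agent_j = val$agent_j[keep]), tg$edges)
        dplyr::bind_cols(tibble::tibble(sim = s, model = mod,
                                        alpha = alpha_grid[a]), sc)
      })
    })
  }
  auc_runs <- dplyr::bind_rows(auc_runs)
  metric_runs <- dplyr::bind_rows(metric_runs)

  auc <- auc_runs |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_auc = mean(.data$auc), sd_auc = stats::sd(.data$auc),
                     .groups = "drop")
  metrics <- metric_runs |>
    dplyr::group_by(.data$model, .data$alpha) |>
    dplyr::summarise(dplyr::across(c("precision", "recall", "f1", "accuracy"),
                                   mean),
                     n_empty = sum(.data$empty_prediction), .groups = "drop")

  ref_mod <- paste0("reference_", reference)
  paired_p <- function(x, y) {
    if (stats::sd(x - y) == 0) return(1)
    t.test(x, y, paired = TRUE)$p.value
  }
  mix_auc <- auc_runs$auc[auc_runs$model == "mixture"]
  ref_auc <- auc_runs$auc[auc_runs$model == ref_mod]
  auc_comparison <- tibble::tibble(
    reference = ref_mod,
    mean_diff = mean(mix_auc - ref_auc),
    p_ttest = paired_p(mix_auc, ref_auc),
    frac_ge = mean(mix_auc >= ref_auc)
  )
  wide <- function(metric) {
    mr <- metric_runs[metric_runs$model %in% c("mixture", ref_mod), ]
    tidyr::pivot_wider(mr[c("sim", "model", "alpha", metric)],
                       names_from = "model",
                       values_from = dplyr::all_of(metric))
  }
  comparison <- purrr::map_dfr(
    c("precision", "recall", "f1", "accuracy"),
    function(metric) {
      w <- wide(metric)
      w |>
        dplyr::group_by(.data$alpha) |>
        dplyr::summarise(
          metric = metric,
          mean_mixture = mean(.data$mixture),
          mean_reference = mean(.data[[ref_mod]]),
          mean_diff = mean(.data$mixture - .data[[ref_mod]]),
          p_ttest = paired_p(.data$mixture, .data[[ref_mod]]),
          frac_ge = mean(.data$mixture >= .data[[ref_mod]]),
          .groups = "drop")
    })

  structure(
    list(auc_runs = auc_runs, metric_runs = metric_runs, auc = auc,
         metrics = metrics, auc_comparison = auc_comparison,
         comparison = comparison,
         config = list(n_sims = n_sims, n_events = n_events,
                       n_types = n_types, alpha_grid = alpha_grid,
                       correction = correction, reference = reference,
                       ni_range = ni_range, ci_range = ci_range,
                       concentration_range = concentration_range,
                       exposure = exposure, seed = seed)),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %d simulations, %d events, %d link types\n",
              x$config$n_sims, x$config$n_events, x$config$n_types))
  cat("mean AUC by model:\n")
  print(as.data.frame(x$auc), row.names = FALSE)
  invisible(x)
}

#' Tidiers for ensemble benchmark summaries
#'
#' `tidy()` returns the mean reconstruction metrics per model and
#' significance level; `glance()` returns the per-model AUC summary joined
#' with the paired mixture-vs-reference AUC comparison.
#'
#' @param x An `ensemble_summary` from [ensemble_experiment()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ensemble_summary
#' @export
tidy.ensemble_summary <- function(x, ...) x$metrics

#' @rdname tidy.ensemble_summary
#' @method glance ensemble_summary
#' @export
glance.ensemble_summary <- function(x, ...) {
  dplyr::bind_cols(
    tidyr::pivot_wider(x$auc[c("model", "mean_auc")],
                       names_from = "model", values_from = "mean_auc",
                       names_prefix = "auc_"),
    x$auc_comparison[c("mean_diff", "p_ttest", "frac_ge")]
  )
}

#' Plot an ensemble benchmark summary
#'
#' Mean precision, recall, F1 and accuracy against the significance level,
#' one line per validation model.
#'
#' @param object An `ensemble_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ensemble_summary
#' @export
autoplot.ensemble_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              c("precision", "recall", "f1", "accuracy"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$alpha, .data$value,
                                     colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = expression(alpha), y = "ensemble mean") +
    ggplot2::theme_minimal()
}
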