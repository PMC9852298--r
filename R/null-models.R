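check_null_params <- function(n_events, degree_i, degree_j, prob = 0.5) {
  if (any(n_events < 1)) stop("`n_events` must be >= 1")
  if (any(degree_i < 0 | degree_i > n_events) ||
      any(degree_j < 0 | degree_j > n_events)) {
    stop("degrees must lie in [0, n_events]")
  }
  if (any(prob < 0 | prob > 1)) stop("`prob` must lie in [0, 1]")
  invisible(TRUE)
}

#' Hypergeometric null for co-attendance counts
#'
#' Under the reference null model, agent `i` connects to `degree_i` of the
#' `n_events` events uniformly at random and independently of agent `j`, so
#' the number of shared events `X` is hypergeometric.
#' `hypergeom_pmf()` is its probability mass function (zero outside the
#' support `[max(degree_i + degree_j - n_events, 0), min(degree_i, degree_j)]`);
#' `hypergeom_survival()` evaluates the upper tail `P(X >= k)` (or the lower
#' tail `P(X <= k)`), the quantity used for per-type link validation.
#'
#' @param x,k Overlap count(s) at which to evaluate.
#' @param n_events Total number of events `N`.
#' @param degree_i,degree_j Agent degrees `N_i`, `N_j`.
#' @param log Return the log pmf?
#' @param tail `"upper"` for `P(X >= k)`, `"lower"` for `P(X <= k)`.
#' @return Probabilities (vectorized over `x`/`k`).
#' @examples
#' hypergeom_survival(2, 100, 3, 4)            # 3.58e-3
#' hypergeom_survival(2, 100, 30, 40, tail = "lower")  # 2.91e-6
#' @export
hypergeom_pmf <- function(x, n_events, degree_i, degree_j, log = FALSE) {
  check_null_params(n_events, degree_i, degree_j)
  dhyper(x, degree_i, n_events - degree_i, degree_j, log = log)
}

#' @rdname hypergeom_pmf
#' @export
hypergeom_survival <- function(k, n_events, degree_i, degree_j,
                               tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  check_null_params(n_events, degree_i, degree_j)
  if (tail == "upper") {
    phyper(k - 1, degree_i, n_events - degree_i, degree_j, lower.tail = FALSE)
  } else {
    phyper(k, degree_i, n_events - degree_i, degree_j)
  }
}

#' Binomial upper tail
#'
#' `P(Y >= k)` for `Y ~ Binomial(size, prob)`, evaluated through the
#' regularized incomplete beta function ([stats::pbinom()]), which keeps tiny
#' tails accurate.
#'
#' @param k Success count(s).
#' @param size Number of trials.
#' @param prob Success probability.
#' @return `P(Y >= k)`, vectorized.
#' @examples
#' binom_survival(2, 3, 0.5)  # 0.5
#' @export
binom_survival <- function(k, size, prob) {
  if (any(size < 0)) stop("`size` must be >= 0")
  if (any(prob < 0 | prob > 1)) stop("`prob` must lie in [0, 1]")
  ifelse(k <= 0, 1, pbinom(k - 1, size, prob, lower.tail = FALSE))
}

# scalar log-space kernel: sum_{X=k}^{min(Ni,Nj)} H(X) * P(Bin(X,p) >= k)
hb_mix_scalar <- function(k, n_events, degree_i, degree_j, prob) {
  hi <- min(degree_i, degree_j)
  if (k <= 0) return(1)
  if (k > hi) return(0)
  X <- k:hi
  lt <- dhyper(X, degree_i, n_events - degree_i, degree_j, log = TRUE) +
    pbinom(k - 1, X, prob, lower.tail = FALSE, log.p = TRUE)
  lt <- lt[is.finite(lt)]
  if (length(lt) == 0) return(0)
  m <- max(lt)
  min(exp(m) * sum(exp(lt - m)), 1)
}

#' Hypergeometric-binomial mixture survival function
#'
#' The null distribution for the number of events where two agents are
#' connected *via the same link type*. Under the null, the number of shared
#' events `X` is hypergeometric (given `N`, `N_i`, `N_j`), and conditional on
#' `X` the number of same-type matches is binomial with per-event match
#' probability `prob` (`p_ij` for positive tests, `q_ij` with opposing-type
#' counts for negative tests). The tail probability is
#' \deqn{P(Y \ge k) = \sum_{X=k}^{\min(N_i,N_j)} H(X \mid N, N_i, N_j)\,
#'   B(Y \ge k \mid X, p),}
#' accumulated in log space so that values down to below 1e-12 remain
#' accurate. With a single link type (`prob = 1`) it reduces to the
#' hypergeometric upper tail.
#'
#' @inheritParams hypergeom_pmf
#' @param k Observed same-type (or opposing-type) overlap count(s).
#' @param prob Per-event probability that the two agents use the same
#'   (or opposing) link type.
#' @return `P(Y >= k)` in `[0, 1]`, vectorized over `k` (and parameters,
#'   recycled). `k` larger than `min(degree_i, degree_j)` yields 0 with a
#'   warning: such an overlap is impossible under the null.
#' @examples
#' hb_mixture_survival(2, 100, 40, 30, 118 / 300)    # 0.967
#' hb_mixture_survival(17, 100, 40, 30, 32 / 75)     # 1.70e-7
#' @export
hb_mixture_survival <- function(k, n_events, degree_i, degree_j, prob) {
  check_null_params(n_events, degree_i, degree_j, prob)
  args <- vctrs_recycle(k, n_events, degree_i, degree_j, prob)
  if (any(args[[1]] > pmin(args[[3]], args[[4]]))) {
    warning("k exceeds min(degree_i, degree_j): impossible overlap, ",
            "returning 0")
  }
  mapply(hb_mix_scalar, args[[1]], args[[2]], args[[3]], args[[4]], args[[5]])
}

vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, n)
}

#' Monte-Carlo estimate of the mixture null tail
#'
#' Independent validation oracle for [hb_mixture_survival()]: simulates the
#' null directly (agent `i` picks `degree_i` events uniformly without
#' replacement, agent `j` picks `degree_j`, and every jointly attended event
#' is a same-type match with probability `prob`) and reports the fraction of
#' replicates with at least `k` matches.
#'
#' @inheritParams hb_mixture_survival
#' @param reps Number of simulated null replicates.
#' @param seed Optional integer seed for reproducibility.
#' @return A one-row tibble with `estimate`, `se` (binomial standard error)
#'   and `reps`.
#' @export
mc_mixture_survival <- function(k, n_events, degree_i, degree_j, prob,
                                reps = 10000, seed = NULL) {
  stopifnot(length(k) == 1, reps >= 1)
  check_null_params(n_events, degree_i, degree_j, prob)
  if (!is.null(seed)) set.seed(seed)
  hits <- vapply(seq_len(reps), function(r) {
    joint <- sum(sample.int(n_events, degree_i) %in%
                   sample.int(n_events, degree_j))
    rbinom(1L, joint, prob) >= k
  }, logical(1))
  est <- mean(hits)
  tibble::tibble(estimate = est, se = sqrt(est * (1 - est) / reps),
                 reps = as.integer(reps))
}
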