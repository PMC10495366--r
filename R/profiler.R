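## coerce counts input (named vector, list, or one-row data.frame possibly
## with a 'sample' column) to a named numeric vector of the four outlets
.as_counts <- function(counts) {
  if (is.data.frame(counts)) {
    if (nrow(counts) != 1L) {
      stop("counts: expected a single sample (one row)", call. = FALSE)
    }
    counts <- as.list(counts)
  }
  if (is.list(counts)) counts <- unlist(counts[setdiff(names(counts), "sample")])
  need <- c("negative", "low", "medium", "high")
  if (!all(need %in% names(counts))) {
    stop(sprintf("counts: missing outlet(s): %s",
                 paste(setdiff(need, names(counts)), collapse = ", ")),
         call. = FALSE)
  }
  x <- as.numeric(counts[need])
  names(x) <- need
  if (anyNA(x) || any(x < 0)) {
    stop("counts: outlet counts must be non-negative numbers", call. = FALSE)
  }
  if (sum(x) == 0) stop("counts: all outlets are zero", call. = FALSE)
  x
}

#' Deflection efficiency
#'
#' Fraction of input particles diverted into the low/medium/high outlets:
#' D = (L + M + H) / (negative + L + M + H). Counts may be integer tallies or
#' real-valued concentrations (particles/mL); the statistic is scale
#' invariant.
#'
#' @param counts Named vector / list / one-row data.frame with entries
#'   `negative`, `low`, `medium`, `high`.
#' @return D in `[0, 1]`.
#' @export
deflection_efficiency <- function(counts) {
  x <- .as_counts(counts)
  unname((x["low"] + x["medium"] + x["high"]) / sum(x))
}

#' Outlet expression profile
#'
#' Deflection efficiency plus the deflected-fraction triplet
#' f_i = count_i / (L + M + H). Fractions are `NA` when nothing deflected
#' (D = 0), with D still reported.
#'
#' @inheritParams deflection_efficiency
#' @return List with `D`, `f_L`, `f_M`, `f_H`.
#' @export
exo_profile <- function(counts) {
  x <- .as_counts(counts)
  defl <- x["low"] + x["medium"] + x["high"]
  if (defl == 0) {
    return(list(D = 0, f_L = NA_real_, f_M = NA_real_, f_H = NA_real_))
  }
  list(D = unname(defl / sum(x)),
       f_L = unname(x["low"] / defl),
       f_M = unname(x["medium"] / defl),
       f_H = unname(x["high"] / defl))
}

#' Weighted expression score of a sorted sample
#'
#' score = 100 * D * (w_L f_L + w_M f_M + w_H f_H). With the default weights
#' (1, 2, 3) the score is 0 for a fully negative sample and at most 300 for
#' complete deflection into the high outlet. The weighting is this package's
#' stated definition of the expression index: it incorporates both the
#' deflection efficiency and the outlet profile, is strictly increasing in D
#' and under shifts of deflected mass toward higher outlets, and its weights
#' are configurable.
#'
#' @inheritParams deflection_efficiency
#' @param weights Positive weights `(w_L, w_M, w_H)`; default `c(1, 2, 3)`.
#' @return Dimensionless score.
#' @export
nanoepic_score <- function(counts, weights = c(1, 2, 3)) {
  if (length(weights) != 3L || any(weights < 0) || anyNA(weights)) {
    stop("nanoepic_score: weights must be three non-negative numbers", call. = FALSE)
  }
  x <- .as_counts(counts)
  defl <- x["low"] + x["medium"] + x["high"]
  if (defl == 0) return(0)
  D <- defl / sum(x)
  f <- x[c("low", "medium", "high")] / defl
  unname(100 * D * sum(weights * f))
}

#' Score fold-change across treatment
#'
#' Ratio of the expression score after treatment over the score before; a
#' fold change of 1 signifies no change, and responders to checkpoint
#' therapy show fold change < 1.
#'
#' @param before Score before treatment, > 0.
#' @param after Score after treatment, >= 0.
#' @return after / before.
#' @export
score_fold_change <- function(before, after) {
  if (any(before <= 0)) {
    stop("score_fold_change: undefined ratio (before must be > 0)", call. = FALSE)
  }
  if (any(after < 0)) stop("score_fold_change: after must be >= 0", call. = FALSE)
  after / before
}

#' Exponential-plateau model parameters
#'
#' The saturating growth model y(x) = Y_max - (Y_max - Y_0) exp(-k x):
#' `y_max` is the asymptotic outcome (e.g. tumor volume, mm^3), `y0` the
#' model value at score 0 (may be negative -- the curve can cross zero within
#' the observed range), `k` the rate constant per score unit.
#'
#' @param y_max Asymptote (mm^3).
#' @param y0 Value at x = 0 (mm^3); must be < `y_max`.
#' @param k Rate constant (> 0, per score unit).
#' @param rss Optional residual sum of squares from a fit.
#' @return Object of class `plateau_params`.
#' @export
plateau_params <- function(y_max, y0, k, rss = NA_real_) {
  if (!is.finite(k) || k <= 0) stop("plateau_params: k must be > 0", call. = FALSE)
  if (!is.finite(y_max) || !is.finite(y0) || y_max <= y0) {
    stop("plateau_params: require y_max > y0", call. = FALSE)
  }
  structure(list(y_max = y_max, y0 = y0, k = k, rss = rss),
            class = "plateau_params")
}

#' @export
print.plateau_params <- function(x, ...) {
  cat(sprintf("<plateau_params> y = %.4g - (%.4g - %.4g) exp(-%.6g x)%s\n",
              x$y_max, x$y_max, x$y0, x$k,
              if (is.na(x$rss)) "" else sprintf("  [RSS = %.4g]", x$rss)))
  invisible(x)
}

#' Evaluate the exponential-plateau model
#'
#' @param params A [plateau_params()].
#' @param x Scores (>= 0). Vectorised.
#' @return Model outcome values.
#' @export
plateau_eval <- function(params, x) {
  if (any(x < 0)) stop("plateau_eval: x must be >= 0", call. = FALSE)
  params$y_max - (params$y_max - params$y0) * exp(-params$k * x)
}

#' Fit the exponential-plateau model by nonlinear least squares
#'
#' Multi-start Levenberg-Marquardt: rate-constant starts span four decades
#' around 1/range(x), asymptote and intercept starts come from the data
#' envelope; the best converged fit (lowest RSS) is returned. Noise-free data
#' generated from the model are recovered to near machine precision.
#'
#' @param x Scores (>= 4 distinct values).
#' @param y Outcomes, same length.
#' @return A [plateau_params()] with the fit RSS attached.
#' @export
plateau_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L) {
    stop("plateau_fit: need >= 4 (x, y) points", call. = FALSE)
  }
  if (length(unique(x)) < 4L) {
    stop("plateau_fit: need >= 4 distinct x values", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("plateau_fit: degenerate fit, flat response (k unidentifiable)", call. = FALSE)
  }
  xr <- diff(range(x))
  k_starts <- c(0.1, 0.5, 1, 2, 5, 20) / xr
  spread <- diff(range(y))
  y_end <- y[which.max(x)]
  y_begin <- y[which.min(x)]
  starts <- expand.grid(
    k = k_starts,
    y_max = unique(c(y_end, max(y) + 0.1 * spread)),
    y0 = unique(c(y_begin, min(y) - 0.1 * spread))
  )
  best <- NULL
  diagnostics <- character(0)
  for (i in seq_len(nrow(starts))) {
    st <- as.list(starts[i, ])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ y_max - (y_max - y0) * exp(-k * x),
        start = st,
        data = data.frame(x = x, y = y),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(coef = cf, rss = rss)
    }
  }
  if (is.null(best) || best$coef[["k"]] <= 0 ||
      best$coef[["y_max"]] <= best$coef[["y0"]]) {
    stop(sprintf("plateau_fit: no admissible converged fit (%s)",
                 paste(unique(diagnostics), collapse = "; ")), call. = FALSE)
  }
  plateau_params(best$coef[["y_max"]], best$coef[["y0"]], best$coef[["k"]],
                 rss = best$rss)
}

#' Generate a synthetic outcome cohort from the plateau model
#'
#' Subjects receive scores uniform over `score_range`; outcomes are the
#' plateau curve plus Gaussian noise (clipped at zero by default, since
#' measured volumes cannot be negative); response categories are assigned by
#' outcome terciles (smallest volumes = complete responders).
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param params A [plateau_params()].
#' @param score_range Length-2 numeric, scores drawn uniformly in between.
#' @param noise_sd Gaussian noise standard deviation (same units as the
#'   outcome).
#' @param seed RNG seed.
#' @param clip_at_zero Clip outcomes at 0 (default TRUE). Disable for
#'   parameter-recovery experiments where unbiased noise is wanted.
#' @return Data.frame: `subject`, `score`, `volume`, `response`.
#' @export
synth_cohort <- function(n_subjects, params, score_range = c(0, 400),
                         noise_sd = 0, seed = NULL, clip_at_zero = TRUE) {
  if (n_subjects < 4) stop("synth_cohort: n_subjects must be >= 4", call. = FALSE)
  if (length(score_range) != 2L || score_range[1] < 0 ||
      score_range[2] <= score_range[1]) {
    stop("synth_cohort: invalid score_range", call. = FALSE)
  }
  with_seed(seed, {
    score <- stats::runif(n_subjects, score_range[1], score_range[2])
    vol <- plateau_eval(params, score) + stats::rnorm(n_subjects, 0, noise_sd)
    if (clip_at_zero) vol <- pmax(vol, 0)
    br <- stats::quantile(vol, c(1 / 3, 2 / 3), names = FALSE)
    response <- cut(vol, breaks = c(-Inf, br, Inf),
                    labels = c("complete_responder", "partial_responder",
                               "non_responder"))
    data.frame(subject = seq_len(n_subjects), score = score, volume = vol,
               response = as.character(response), stringsAsFactors = FALSE)
  })
}
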