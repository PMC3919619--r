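# Normalization, smoothing and significance-of-change gating.

#' Z-score normalize an expression matrix
#'
#' Centres and scales every experiment column to mean 0 and standard
#' deviation 1 (population denominator), preserving gene and experiment
#' labels. Zero-variance columns are set to all zeros with a warning rather
#' than erroring, since degenerate replicates can arise in simulated
#' deletions.
#'
#' @param x a genes x experiments numeric matrix or an `egrin_expression`.
#' @return object of the same type, normalized.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 4, 4), 3, 2)
#' colMeans(zscore_normalize(m))
zscore_normalize <- function(x) {
  if (inherits(x, "egrin_expression")) {
    x$values <- zscore_normalize(x$values)
    return(x)
  }
  if (!is.matrix(x) || nrow(x) == 0L || ncol(x) == 0L)
    egr_stop("expression matrix is empty", "egrinet_contract_error")
  mu <- colMeans(x)
  sdp <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  zero <- sdp <= 0 | !is.finite(sdp)
  if (any(zero)) {
    warning(sprintf("%d zero-variance column(s) set to zero", sum(zero)))
    sdp[zero] <- 1
  }
  out <- sweep(sweep(x, 2L, mu), 2L, sdp, "/")
  out[, zero] <- 0
  out
}

#' Loess-smooth a time series
#'
#' Local linear smoothing with tricube weights, used to prepare expression
#' profiles for plotting and reporting (never for inference). Duplicated
#' time points (replicate arrays) are accepted.
#'
#' @param time,value numeric vectors of equal length (>= 4 points).
#' @param span smoothing span in (0, 1].
#' @return smoothed values at the input time points.
#' @export
loess_smooth <- function(time, value, span = 0.5) {
  if (length(time) != length(value) || length(time) < 4L)
    egr_stop("loess smoothing needs >= 4 (time, value) pairs",
             "egrinet_smooth_error")
  if (!is.finite(span) || span <= 0 || span > 1)
    egr_stop("span must be in (0, 1]", "egrinet_smooth_error")
  ## duplicated time points make the local design near-singular; the
  ## degree-1 fit is still well defined, so silence the numeric grumbling
  suppressWarnings({
    fit <- stats::loess(value ~ time, span = span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    as.numeric(predict(fit, newdata = data.frame(time = time)))
  })
}

#' Fit a significance-of-change model
#'
#' Models the null distribution of log ratios per experiment so that
#' individual measurements can be assigned a probability of representing no
#' change. Three modes:
#' \describe{
#'   \item{normal-fit}{fit a normal to each experiment's log ratios with
#'     robust location and scale (median and MAD), so the minority of
#'     genuinely responding genes does not inflate the null scale;
#'     two-tailed p-values (the default).}
#'   \item{chi-squared-fit}{fit a scale per experiment so that the squared
#'     standardized ratio follows a chi-squared distribution with `df`
#'     degrees of freedom; upper-tail p-values.}
#'   \item{provided-lambda}{values passed to [change_significance()] are
#'     treated as precomputed lambda statistics and referred directly to a
#'     chi-squared distribution with `df` degrees of freedom.}
#' }
#'
#' @param x genes x experiments matrix or `egrin_expression` to fit on.
#'   Ignored in `provided-lambda` mode.
#' @param mode one of `"normal-fit"`, `"chi-squared-fit"`,
#'   `"provided-lambda"`.
#' @param df chi-squared degrees of freedom (modes other than normal-fit).
#' @return an object of class `egrin_sig_model`.
#' @export
fit_change_model <- function(x = NULL,
                             mode = c("normal-fit", "chi-squared-fit",
                                      "provided-lambda"),
                             df = 1) {
  mode <- match.arg(mode)
  if (mode != "normal-fit" && (!is.finite(df) || df <= 0))
    egr_stop("df must be positive", "egrinet_config_error")
  model <- list(mode = mode, df = df, location = NULL, scale = NULL,
                fitted = FALSE)
  class(model) <- "egrin_sig_model"
  if (mode == "provided-lambda") {
    model$fitted <- TRUE
    return(model)
  }
  if (inherits(x, "egrin_expression")) x <- x$values
  if (!is.matrix(x) || nrow(x) < 30L)
    egr_stop("significance model must be fitted on >= 30 observations",
             "egrinet_config_error")
  model$location <- apply(x, 2L, stats::median)
  r2 <- sweep(x, 2L, model$location)^2
  if (mode == "normal-fit") {
    model$scale <- apply(x, 2L, stats::mad)
  } else {
    ## robust scale: median of (x - loc)^2 / s^2 matches the chi-squared
    ## median for df degrees of freedom
    model$scale <- sqrt(apply(r2, 2L, stats::median) /
                          stats::qchisq(0.5, df))
  }
  model$scale[model$scale <= 0] <- 1
  model$fitted <- TRUE
  model
}

#' Per-experiment significance of change for one gene
#'
#' @param profile named numeric vector of per-experiment log ratios (names
#'   must match the experiments the model was fitted on, unless the model
#'   has no per-experiment parameters).
#' @param model a fitted `egrin_sig_model`.
#' @param alpha significance level applied after Benjamini-Hochberg
#'   adjustment across the profile's experiments.
#' @return list with `p` (per-experiment p-values), `p_adjusted`, and
#'   `significant` (single logical: does the gene change significantly?).
#' @export
change_significance <- function(profile, model, alpha = 0.05) {
  if (!inherits(model, "egrin_sig_model") || !isTRUE(model$fitted))
    egr_stop("significance model is not fitted", "egrinet_state_error")
  p <- significance_p(rbind(profile), model)[1L, ]
  adj <- p.adjust(p, "BH")
  list(p = p, p_adjusted = adj, significant = any(adj <= alpha))
}

#' Vectorized p-value computation for a genes x experiments matrix
#' @noRd
significance_p <- function(values, model) {
  if (model$mode == "provided-lambda") {
    return(pchisq(values, df = model$df, lower.tail = FALSE))
  }
  if (!is.null(names(model$location)) && !is.null(colnames(values))) {
    idx <- match(colnames(values), names(model$location))
    if (anyNA(idx))
      egr_stop("profile has experiments the model was not fitted on",
               "egrinet_lookup_error")
  } else {
    idx <- seq_len(ncol(values))
  }
  z <- sweep(sweep(values, 2L, model$location[idx]), 2L, model$scale[idx], "/")
  if (model$mode == "normal-fit") {
    2 * pnorm(-abs(z))
  } else {
    pchisq(z^2, df = model$df, lower.tail = FALSE)
  }
}

#' Restrict an analysis to significantly changing genes
#'
#' Computes significance-of-change p-values for every (gene, experiment)
#' entry, applies Benjamini-Hochberg control across the whole matrix, and
#' keeps genes with at least one adjusted p-value at or below `alpha`.
#'
#' @param exprs `egrin_expression` (typically the condition-specific
#'   experiments) or a genes x experiments matrix.
#' @param regulators candidate regulator ids.
#' @param model fitted `egrin_sig_model` (fitted on the same experiments).
#' @param alpha FDR level.
#' @return list with `targets` (changing genes), `regulators` (changing
#'   candidate regulators) and `flags` (named logical over all genes).
#' @export
filter_to_changing <- function(exprs, regulators, model, alpha = 0.05) {
  values <- if (inherits(exprs, "egrin_expression")) exprs$values else exprs
  if (!inherits(model, "egrin_sig_model") || !isTRUE(model$fitted))
    egr_stop("significance model is not fitted", "egrinet_state_error")
  p <- significance_p(values, model)
  adj <- matrix(p.adjust(p, "BH"), nrow(p), ncol(p),
                dimnames = dimnames(values))
  flags <- apply(adj <= alpha, 1L, any)
  changing <- rownames(values)[flags]
  if (length(changing) == 0L)
    egr_stop("no genes change significantly at this level",
             "egrinet_empty_error")
  list(targets = changing,
       regulators = intersect(regulators, changing),
       flags = flags)
}
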