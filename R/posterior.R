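# Posterior reporting: parameter tables (mean, SD, 95% credible interval,
# odds ratios for fixed effects), DIC, autocorrelations, smooth-effect
# curves, and per-zone effect tables.

#' Summarise retained draws
#'
#' Per scalar parameter: posterior mean, SD, and the 2.5/97.5% quantiles
#' (linear interpolation of order statistics, the type-7 default) as the 95%
#' credible interval.  Fixed-effect rows additionally carry the odds-ratio
#' transform `exp(mean)` with CI `(exp(q2.5), exp(q97.5))`.
#'
#' @param fit a `bstar_fit` from [run_chain()].
#' @return data.frame with columns `parameter, block, mean, sd, q2.5, q97.5,
#'   or, or_low, or_high` (OR columns `NA` outside the fixed block).
#' @export
summarize_posterior <- function(fit) {
  draws <- fit$draws
  if (is.null(dim(draws)) || nrow(draws) < 2) stop("need at least 2 retained draws")
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE,
              type = 7)
  out <- data.frame(
    parameter = colnames(draws),
    block = fit$param_info$block[match(colnames(draws), fit$param_info$parameter)],
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    q2.5 = qs[1, ], q97.5 = qs[2, ],
    row.names = NULL, stringsAsFactors = FALSE)
  isfix <- out$block == "fixed" & out$parameter != "(Intercept)"
  out$or <- ifelse(isfix, exp(out$mean), NA_real_)
  out$or_low <- ifelse(isfix, exp(out$q2.5), NA_real_)
  out$or_high <- ifelse(isfix, exp(out$q97.5), NA_real_)
  out
}

#' @export
summary.bstar_fit <- function(object, ...) summarize_posterior(object)

#' Deviance information criterion
#'
#' `DIC = Dbar + p_d` with `Dbar` the posterior mean deviance and
#' `p_d = Dbar - D(eta_bar)`, where the plug-in deviance is evaluated at the
#' posterior mean of the per-observation linear predictor (invariant to the
#' identifiability constraints applied per block).  Lower is better.
#'
#' @param fit a `bstar_fit`.
#' @return list with `dic`, `p_d`, `dbar`, `dhat`.
#' @export
compute_dic <- function(fit) {
  if (any(!is.finite(fit$deviance)))
    stop("non-finite deviance at draw ", which(!is.finite(fit$deviance))[1])
  dbar <- mean(fit$deviance)
  eta <- fit$eta_mean
  loglik <- sum(fit$y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
  dhat <- -2 * loglik
  p_d <- dbar - dhat
  list(dic = dbar + p_d, p_d = p_d, dbar = dbar, dhat = dhat)
}

#' Sample autocorrelation of a chain
#'
#' @param chain numeric vector of retained draws for one parameter.
#' @param max_lag largest lag, must be below `length(chain)`.
#' @return list with `acf` (lags 0..max_lag, lag-0 value 1) and `degenerate`
#'   (`TRUE` for a zero-variance chain, in which case `acf` is `NA`).
#' @export
autocorrelation <- function(chain, max_lag = 20) {
  stopifnot(length(chain) > max_lag)
  if (var(chain) == 0)
    return(list(acf = rep(NA_real_, max_lag + 1), degenerate = TRUE))
  a <- acf(chain, lag.max = max_lag, plot = FALSE, demean = TRUE)
  list(acf = as.numeric(a$acf), degenerate = FALSE)
}

#' Posterior curve of a nonlinear effect
#'
#' Pointwise posterior mean and 95% band of a smooth term at its knots — the
#' fitted nonlinear effect of the covariate on the log-odds scale.
#'
#' @param fit a `bstar_fit`.
#' @param covariate name of a smooth term in the fit.
#' @return data.frame with columns `knot, mean, q2.5, q97.5`.
#' @export
effect_curve <- function(fit, covariate) {
  if (!covariate %in% names(fit$knots))
    stop("no smooth term for covariate '", covariate, "' in this fit")
  cols <- fit$param_info$parameter[fit$param_info$block == paste0("smooth:", covariate)]
  d <- fit$draws[, cols, drop = FALSE]
  qs <- apply(d, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(knot = fit$knots[[covariate]], mean = colMeans(d),
             q2.5 = qs[1, ], q97.5 = qs[2, ], row.names = NULL)
}

#' Per-zone posterior effect table
#'
#' Posterior means of the structured and unstructured effects plus the
#' summary of their per-draw total, keyed by zone id for joining to any
#' mapping tool.  Structured means sum to ~0 within each graph component.
#'
#' @param fit a `bstar_fit` with spatial terms.
#' @return data.frame with columns `zone, str_mean, uns_mean, total,
#'   q2.5, q97.5`.
#' @export
zone_effect_table <- function(fit) {
  if (!length(fit$zones)) stop("fit has no spatial terms")
  s <- fit$draws[, fit$param_info$block == "spatial_str", drop = FALSE]
  u <- fit$draws[, fit$param_info$block == "spatial_uns", drop = FALSE]
  tot <- s + u
  qs <- apply(tot, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(zone = fit$zones, str_mean = colMeans(s), uns_mean = colMeans(u),
             total = colMeans(tot), q2.5 = qs[1, ], q97.5 = qs[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Persist retained draws as CSV with a side-car provenance file
#'
#' One row per retained draw, one column per scalar parameter plus a
#' `deviance` column; the side-car text file records the seed, iteration
#' plan, blocks and constraint conventions.
#'
#' @param fit a `bstar_fit`.
#' @param path CSV path; the side-car is written at `paste0(path, ".info")`.
#' @return `fit`, invisibly.
#' @export
write_draws <- function(fit, path) {
  m <- cbind(as.data.frame(fit$draws, check.names = FALSE),
             deviance = fit$deviance)
  write.csv(m, path, row.names = FALSE)
  info <- c(
    paste0("bstar version: ", as.character(packageVersion("bstar"))),
    paste0("seed: ", fit$config$seed),
    paste0("iterations: ", fit$config$iterations,
           " burn_in: ", fit$config$burn_in, " thin: ", fit$config$thin),
    paste0("blocks: ", paste(unique(fit$param_info$block), collapse = ", ")),
    "constraints: smooths recentred to mean zero (constant folded into intercept);",
    "structured spatial effect sum-to-zero per graph component")
  writeLines(info, paste0(path, ".info"))
  invisible(fit)
}

#' Read a draws CSV written by [write_draws()]
#' @param path CSV path.
#' @return list with `draws` (matrix) and `deviance` (vector).
#' @export
read_draws <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  dev <- d$deviance
  m <- as.matrix(d[, setdiff(names(d), "deviance"), drop = FALSE])
  list(draws = m, deviance = dev)
}
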