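# Ground truth for synthetic-data experiments: the full set of parameters of
# the geo-additive predictor, so that recovery tests can compare posterior
# estimates against known values.

# default nonlinear effects (log-odds scale), chosen to mimic the shapes
# reported for the Ethiopia food-insecurity analysis: risk lowest below age
# 40 then increasing; steady decline with schooling; flat then declining
# beyond asset index 4; rising with dependency ratio up to 3 then flat;
# mildly declining with family size
default_smooths <- function() {
  list(
    age         = function(x) 0.0006 * (x - 40)^2 * (x > 40) - 0.1,
    schooling   = function(x) -0.08 * x + 0.4,
    asset       = function(x) -0.25 * pmax(0, x - 4),
    dep_ratio   = function(x) 0.25 * pmin(x, 3) - 0.2,
    family_size = function(x) -0.05 * x
  )
}

# default fixed-effect log-odds contrasts (reference levels: male,
# never-married, rural, shock = yes, credit = no, wave w1), on the scale of
# the adjusted odds ratios reported for the motivating survey analysis
default_fixed <- function() {
  list(
    sex       = c(female = log(1.60)),
    marital   = c(married = log(0.41), divorced = -0.35, widowed = -0.25),
    residence = c(small_town = log(0.78), large_town = log(0.76)),
    shock     = c(no = log(0.23)),
    credit    = c(yes = log(0.58)),
    wave      = c(w2 = -0.10, w3 = log(0.64), w4 = log(0.42))
  )
}

#' Ground truth for the synthetic data generator
#'
#' Bundles an intercept, fixed-effect contrasts, nonlinear effect functions,
#' and the two zone-level fields: a structured effect drawn from the ICAR
#' prior on `graph` (sum-to-zero per component) and an unstructured i.i.d.
#' Gaussian effect.  Defaults give an overall outcome prevalence near 27%
#' under the default covariate marginals.
#'
#' @param graph a [zone_graph()].
#' @param seed integer master seed for the two zone fields.
#' @param intercept log-odds intercept.
#' @param fixed named list of named numeric vectors of log-odds contrasts
#'   (names are non-reference levels).
#' @param smooths named list of vectorised functions on the log-odds scale.
#' @param tau2_str,tau2_uns variances of the structured / unstructured field.
#'   Note `tau2_str` scales the ICAR *increments*; the realized field's
#'   marginal variance is `tau2_str` times the mean diagonal of the
#'   Laplacian pseudo-inverse (about 0.58 on a 6 x 6 lattice).  The defaults
#'   give a structured field whose range is roughly twice the unstructured
#'   one, matching the reported dominance of the structured effect.
#' @return an object of class `ground_truth`.
#' @export
default_truth <- function(graph, seed = 1, intercept = 1.27,
                          fixed = default_fixed(),
                          smooths = default_smooths(),
                          tau2_str = 1.0, tau2_uns = 0.1) {
  zstr <- if (tau2_str > 0) sample_icar_field(graph, tau2_str, split_seed(seed, "truth_str"))
          else structure(numeric(length(graph$zones)), names = graph$zones)
  zuns <- with_stream(seed, "truth_uns",
                      rnorm(length(graph$zones), 0, sqrt(max(tau2_uns, 0))))
  names(zuns) <- graph$zones
  stopifnot(all(is.finite(unlist(fixed))), is.finite(intercept))
  structure(
    list(intercept = intercept, fixed = fixed, smooths = smooths,
         zone_structured = zstr, zone_unstructured = zuns,
         zones = graph$zones),
    class = "ground_truth")
}

#' Ground truth with every effect zero
#'
#' Convenience for calibration checks: `eta = intercept` for all households.
#'
#' @param graph a [zone_graph()].
#' @param intercept log-odds intercept (default 0, prevalence 1/2).
#' @return a `ground_truth` object.
#' @export
null_truth <- function(graph, intercept = 0) {
  zero_fun <- function(x) rep(0, length(x))
  z <- structure(numeric(length(graph$zones)), names = graph$zones)
  structure(
    list(intercept = intercept,
         fixed = lapply(default_fixed(), function(v) v * 0),
         smooths = lapply(default_smooths(), function(f) zero_fun),
         zone_structured = z, zone_unstructured = z, zones = graph$zones),
    class = "ground_truth")
}

# linear predictor of the generating model for a household table
eval_truth_eta <- function(truth, data) {
  eta <- rep(truth$intercept, nrow(data))
  for (v in names(truth$fixed)) {
    coefs <- truth$fixed[[v]]
    hit <- match(data[[v]], names(coefs))
    eta <- eta + ifelse(is.na(hit), 0, coefs[hit])
  }
  for (v in names(truth$smooths)) eta <- eta + truth$smooths[[v]](data[[v]])
  eta + truth$zone_structured[data$zone] + truth$zone_unstructured[data$zone]
}

# serialisation grid for the smooth functions (covariate ranges of the
# default generator)
truth_grid <- function() {
  list(age = seq(18, 95, length.out = 41),
       schooling = seq(0, 18, length.out = 41),
       asset = seq(0, 8, length.out = 41),
       dep_ratio = seq(0, 6, length.out = 41),
       family_size = seq(1, 16, length.out = 41))
}

#' Write / read ground truth as a flat key-value text file
#'
#' Fixed effects, intercept, zone fields and variance-free smooth-function
#' values on a fixed grid (read back as interpolating functions) — enough to
#' drive parameter-recovery tests.
#'
#' @param truth a `ground_truth` object.
#' @param path file path.
#' @return `write_truth` returns `truth` invisibly; `read_truth` a
#'   `ground_truth` object whose smooths interpolate the stored grid.
#' @export
write_truth <- function(truth, path) {
  lines <- c(sprintf("intercept\t%.17g", truth$intercept))
  for (v in names(truth$fixed)) {
    cf <- truth$fixed[[v]]
    lines <- c(lines, sprintf("fixed.%s.%s\t%.17g", v, names(cf), cf))
  }
  grid <- truth_grid()
  for (v in names(truth$smooths)) {
    g <- grid[[v]]
    lines <- c(lines, sprintf("smooth.%s.%.17g\t%.17g", v, g,
                              truth$smooths[[v]](g)))
  }
  lines <- c(lines,
             sprintf("zone_str.%s\t%.17g", names(truth$zone_structured),
                     truth$zone_structured),
             sprintf("zone_uns.%s\t%.17g", names(truth$zone_unstructured),
                     truth$zone_unstructured))
  writeLines(lines, path)
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  kv <- utils::read.delim(path, header = FALSE,
                          col.names = c("key", "value"),
                          colClasses = c("character", "numeric"))
  pick <- function(prefix) kv[startsWith(kv$key, prefix), , drop = FALSE]
  intercept <- kv$value[kv$key == "intercept"]
  fx <- pick("fixed.")
  fixed <- list()
  if (nrow(fx)) {
    parts <- strsplit(sub("^fixed\\.", "", fx$key), ".", fixed = TRUE)
    vars <- vapply(parts, `[`, "", 1)
    lvls <- vapply(parts, function(p) paste(p[-1], collapse = "."), "")
    for (v in unique(vars)) {
      sel <- vars == v
      fixed[[v]] <- structure(fx$value[sel], names = lvls[sel])
    }
  }
  sm <- pick("smooth.")
  smooths <- list()
  if (nrow(sm)) {
    parts <- strsplit(sub("^smooth\\.", "", sm$key), ".", fixed = TRUE)
    vars <- vapply(parts, `[`, "", 1)
    xs <- as.numeric(vapply(parts, function(p) paste(p[-1], collapse = "."), ""))
    for (v in unique(vars)) {
      sel <- vars == v
      smooths[[v]] <- stats::approxfun(xs[sel], sm$value[sel], rule = 2)
    }
  }
  zs <- pick("zone_str.")
  zu <- pick("zone_uns.")
  zstr <- structure(zs$value, names = sub("^zone_str\\.", "", zs$key))
  zuns <- structure(zu$value, names = sub("^zone_uns\\.", "", zu$key))
  structure(
    list(intercept = intercept, fixed = fixed, smooths = smooths,
         zone_structured = zstr, zone_unstructured = zuns,
         zones = names(zstr)),
    class = "ground_truth")
}
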