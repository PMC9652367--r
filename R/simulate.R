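# Synthetic household-survey generator.  Covariate marginals default to the
# published distribution of the Ethiopia Socioeconomic Survey analysis sample
# (5262 households, 72 zones, 4 waves); the outcome is Bernoulli with
# logit-linear predictor evaluated from a ground_truth object.

default_marginals <- function() {
  list(
    sex       = c(male = 0.696, female = 0.304),
    marital   = c(never = 0.080, married = 0.682, divorced = 0.096,
                  widowed = 0.142),
    residence = c(rural = 0.632, small_town = 0.168, large_town = 0.200),
    shock     = c(yes = 0.362, no = 0.638),
    credit    = c(yes = 0.252, no = 0.748),
    wave      = c(w1 = 0.25, w2 = 0.25, w3 = 0.25, w4 = 0.25),
    age       = list(mean = 42, sd = 15, lower = 18, upper = 95),
    family_size = list(rate = 3.4),               # 1 + Poisson(rate)
    schooling = list(mean = 7.0, sd = 4.4, lower = 0, upper = 18),
    asset     = list(mean = 3.0, sd = 1.4, lower = 0, upper = 8),
    dep_ratio = list(shape = 0.956, scale = 0.920) # mean .88, sd .90
  )
}

# truncated normal by rejection (vectorised refill)
rtnorm <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Generate a synthetic household table
#'
#' Draws covariates from configurable marginals, assigns zones uniformly,
#' evaluates the geo-additive linear predictor from `truth` and draws the
#' binary outcome `y ~ Bernoulli(plogis(eta))`.  All randomness flows from
#' `seed` through per-draw-type sub-streams ([split_seed()]), so tables are
#' byte-identical across calls with the same arguments.
#'
#' @param graph a [zone_graph()]; `truth` must be defined on its zones.
#' @param truth a `ground_truth` object (see [default_truth()]).
#' @param n number of households (default 5262, the motivating survey size).
#' @param seed integer master seed.
#' @param marginals covariate marginals; see `bstar:::default_marginals()`.
#' @return data.frame with columns `y, sex, marital, residence, shock,
#'   credit, wave, age, family_size, schooling, asset, dep_ratio, zone`.
#' @export
#' @examples
#' g <- make_zone_lattice(3, 3)
#' d <- generate_households(g, default_truth(g, seed = 1), n = 100, seed = 1)
#' table(d$y)
generate_households <- function(graph, truth = default_truth(graph),
                                n = 5262, seed = 1,
                                marginals = default_marginals()) {
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (!all(names(truth$zone_structured) %in% graph$zones) ||
      length(truth$zone_structured) != length(graph$zones))
    stop("truth is not defined on the graph's zones")
  m <- marginals
  cat_draw <- function(key) {
    p <- m[[key]]
    with_stream(seed, key, sample(names(p), n, replace = TRUE, prob = p))
  }
  d <- data.frame(
    sex = cat_draw("sex"), marital = cat_draw("marital"),
    residence = cat_draw("residence"), shock = cat_draw("shock"),
    credit = cat_draw("credit"), wave = cat_draw("wave"),
    stringsAsFactors = FALSE)
  d$age <- with_stream(seed, "age", {
    a <- m$age
    round(rtnorm(n, a$mean, a$sd, a$lower, a$upper))
  })
  d$family_size <- with_stream(seed, "family_size",
                               1 + rpois(n, m$family_size$rate))
  d$schooling <- with_stream(seed, "schooling", {
    a <- m$schooling
    round(rtnorm(n, a$mean, a$sd, a$lower, a$upper), 2)
  })
  d$asset <- with_stream(seed, "asset", {
    a <- m$asset
    round(rtnorm(n, a$mean, a$sd, a$lower, a$upper), 2)
  })
  d$dep_ratio <- with_stream(seed, "dep_ratio", {
    a <- m$dep_ratio
    round(rgamma(n, shape = a$shape, scale = a$scale), 2)
  })
  d$zone <- with_stream(seed, "zone",
                        sample(graph$zones, n, replace = TRUE))
  eta <- eval_truth_eta(truth, d)
  d$y <- with_stream(seed, "outcome", rbinom(n, 1, plogis(eta)))
  d[, c("y", "sex", "marital", "residence", "shock", "credit", "wave",
        "age", "family_size", "schooling", "asset", "dep_ratio", "zone")]
}

household_columns <- c("y", "sex", "marital", "residence", "shock", "credit",
                       "wave", "age", "family_size", "schooling", "asset",
                       "dep_ratio", "zone")

#' Write / read a household table as CSV
#'
#' Header row with exactly the 13 documented columns; `zone` is kept as a
#' character key so it joins back to the graph roster.
#'
#' @param data household data.frame.
#' @param path file path.
#' @return `write_households` returns `data` invisibly; `read_households`
#'   the data.frame.
#' @export
write_households <- function(data, path) {
  missing <- setdiff(household_columns, names(data))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  write.csv(data[, household_columns], path, row.names = FALSE, quote = FALSE)
  invisible(data)
}

#' @rdname write_households
#' @export
read_households <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(household_columns, names(d))
  if (length(missing))
    stop("household CSV is missing columns: ", paste(missing, collapse = ", "))
  d$zone <- as.character(d$zone)
  d
}
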