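test_that("simulate subcommand writes the documented files deterministically", {
  out <- withr::local_tempdir()
  args <- c("simulate", "--out", out, "--n", "100", "--seed", "7",
            "--rows", "2", "--cols", "3")
  bstar_cli(args)
  csv <- file.path(out, "households.csv")
  d <- read.csv(csv, colClasses = c(zone = "character"))
  expect_equal(nrow(d), 100)
  expect_identical(names(d),
                   c("y", "sex", "marital", "residence", "shock", "credit",
                     "wave", "age", "family_size", "schooling", "asset",
                     "dep_ratio", "zone"))
  expect_true(file.exists(file.path(out, "manifest.txt")))
  h1 <- tools::md5sum(csv)
  bstar_cli(args)
  expect_identical(unname(tools::md5sum(csv)), unname(h1))

  # round-trip through the package's own readers
  g <- read_zone_graph(file.path(out, "zones_edges.tsv"),
                       file.path(out, "zones_roster.txt"))
  expect_length(g$zones, 6)
  expect_s3_class(read_truth(file.path(out, "truth.tsv")), "ground_truth")
  expect_identical(read_households(csv)$zone, d$zone)
})

test_that("describe subcommand emits one row per categorical level", {
  out <- withr::local_tempdir()
  bstar_cli(c("simulate", "--out", out, "--n", "400", "--seed", "3",
              "--rows", "2", "--cols", "2"))
  bstar_cli(c("describe", "--data", file.path(out, "households.csv"),
              "--out", out))
  desc <- read.csv(file.path(out, "describe.csv"))
  d <- read_households(file.path(out, "households.csv"))
  for (v in c("sex", "marital", "residence", "shock", "credit", "wave")) {
    expect_equal(sum(desc$variable == v), length(unique(d[[v]])))
  }
  ct <- contingency(d, "sex")
  expect_equal(desc$pct_yes[desc$variable == "sex"],
               unname(prevalence_rows(ct)))
})

test_that("fit subcommand runs the pipeline end to end with GLM comparison", {
  out <- withr::local_tempdir()
  bstar_cli(c("simulate", "--out", out, "--n", "500", "--seed", "5",
              "--rows", "2", "--cols", "3"))
  suppressMessages(bstar_cli(c(
    "fit", "--data", file.path(out, "households.csv"),
    "--edges", file.path(out, "zones_edges.tsv"),
    "--roster", file.path(out, "zones_roster.txt"),
    "--iterations", "2200", "--burn-in", "200", "--thin", "2",
    "--seed", "5", "--compare-glm", "--out", out)))
  for (f in c("draws.csv", "summary.csv", "zone_effects.csv", "fit.log",
              paste0("curve_", c("age", "schooling", "asset", "dep_ratio",
                                 "family_size"), ".csv"))) {
    expect_true(file.exists(file.path(out, f)), info = f)
  }
  summ <- read.csv(file.path(out, "summary.csv"))
  expect_equal(sum(summ$block == "dic"), 2) # both models' DIC present
  zt <- read.csv(file.path(out, "zone_effects.csv"),
                 colClasses = c(zone = "character"))
  expect_equal(nrow(zt), 6)
  log_lines <- readLines(file.path(out, "fit.log"))
  expect_true(any(grepl("seed=5", log_lines)))
  expect_true(any(grepl("structured range", log_lines)))
  back <- read_draws(file.path(out, "draws.csv"))
  expect_equal(nrow(back$draws), 1000)

  bstar_cli(c("summarize", "--draws", file.path(out, "draws.csv"),
              "--out", out))
  expect_true(file.exists(file.path(out, "summary.csv")))
})

test_that("fit subcommand fails with a schema error naming the column", {
  out <- withr::local_tempdir()
  bstar_cli(c("simulate", "--out", out, "--n", "60", "--seed", "2",
              "--rows", "2", "--cols", "2"))
  d <- read.csv(file.path(out, "households.csv"))
  d$zone <- NULL
  write.csv(d, file.path(out, "broken.csv"), row.names = FALSE)
  expect_error(bstar_cli(c("fit", "--data", file.path(out, "broken.csv"),
                           "--edges", file.path(out, "zones_edges.tsv"),
                           "--roster", file.path(out, "zones_roster.txt"),
                           "--out", out)),
               "zone")
})

test_that("config files provide defaults that flags override", {
  out <- withr::local_tempdir()
  cfgf <- file.path(out, "run.cfg")
  writeLines(c("# comment", "n=50", "seed=4", "rows=2", "cols=2"), cfgf)
  bstar_cli(c("simulate", "--config", cfgf, "--out", out, "--n", "75"))
  d <- read.csv(file.path(out, "households.csv"))
  expect_equal(nrow(d), 75) # flag wins
  cfg <- bstar:::read_run_config(cfgf)
  expect_equal(cfg$seed, "4")
  writeLines("nonsense", cfgf)
  expect_error(bstar:::read_run_config(cfgf), "malformed")
})

test_that("the shipped launcher script runs under Rscript", {
  script <- system.file("cli", "bstar.R", package = "bstar")
  expect_true(nzchar(script))
  out <- withr::local_tempdir()
  res <- system2(file.path(R.home("bin"), "Rscript"),
                 c(script, "simulate", "--out", shQuote(out), "--n", "30",
                   "--seed", "1", "--rows", "2", "--cols", "2"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "households.csv")))
})
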