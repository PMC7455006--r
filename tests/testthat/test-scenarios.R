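test_that("scenario builders scale density-preservingly and are seed-deterministic", {
  p <- sim_params()
  set.seed(51)
  b1 <- build_scenario(scenario_spec(1, scale = 0.01), p)
  expect_equal(nrow(b1$population), 1000L)
  expect_equal(b1$params$sizeX, 100)
  expect_equal(nrow(b1$population) / (b1$params$sizeX * b1$params$sizeY),
               p$initR / (p$sizeX * p$sizeY))
  expect_true(all(replication_rate(b1$population$sequence) == 200))
  set.seed(51)
  b1b <- build_scenario(scenario_spec(1, scale = 0.01), p)
  expect_identical(b1$population, b1b$population)
  expect_error(scenario_spec(5), "unknown")
})

test_that("random pools carry accidental replicases at the binomial tail rate", {
  set.seed(52)
  b2 <- build_scenario(scenario_spec(2, scale = 0.05), sim_params())
  n <- nrow(b2$population)
  expect_equal(n, 5000L)
  frac <- b2$info$n_accidental_replicases / n
  # P(Binomial(20, 1/4) >= 7): probability a random 20-mer has a working motif
  p_tail <- stats::pbinom(6, 20, 0.25, lower.tail = FALSE)
  se <- sqrt(p_tail * (1 - p_tail) / n)
  expect_lt(abs(frac - p_tail), 3 * se)
})

test_that("the hydrolysis scenario makes every agent decay faster than the base rate", {
  set.seed(53)
  b3 <- build_scenario(scenario_spec(3, scale = 0.005), sim_params())
  expect_equal(sum(unclass(b3$params$hydrolysis) > 0), 8L)
  b <- decay_rate(b3$population$sequence, b3$params$d,
                  b3$params$hydrolysis)
  expect_true(all(b > b3$params$d))
})

test_that("population statistics classify by efficiency and handle empty classes", {
  pop <- data.frame(a = c(0.9, 0.8, 0, 0, 0), l = c(0.5, 0.3, 0.2, 0.1, 0.3),
                    state = c("enzyme", "free", "template", "free", "free"))
  s <- record_stats(pop, step = 5)
  expect_equal(s$n_replicases, 2L)
  expect_equal(s$n_parasites, 3L)
  expect_equal(s$n_complexes, 1L)
  expect_equal(s$mean_a_replicases, 0.85)
  expect_equal(s$mean_l_parasites, 0.2)
  empty <- record_stats(data.frame(a = numeric(0), l = numeric(0)))
  expect_equal(empty$n_total, 0L)
  expect_true(is.na(empty$mean_a_replicases))
  # the R-side statistics agree with the core's trajectory row
  res <- small_run(seed = 54, max_steps = 40)
  last <- res$stats[nrow(res$stats), ]
  redo <- record_stats(res$population, step = last$step)
  expect_equal(redo$n_replicases, last$n_replicases)
  expect_equal(redo$mean_a_replicases, last$mean_a_replicases)
  expect_equal(redo$mean_l_replicases, last$mean_l_replicases)
  expect_equal(redo$mean_l_parasites, last$mean_l_parasites)
})

test_that("survivor export samples agents binomially into FASTA", {
  pop <- data.frame(sequence = random_sequence(50, 400),
                    l = runif(400), a = 0, b = 0.01)
  f <- withr::local_tempfile(fileext = ".fasta")
  set.seed(55)
  n_all <- export_survivors(pop, 1, f)
  expect_equal(n_all, 400L)
  expect_length(read_fasta_sequences(f), 400L)
  expect_equal(export_survivors(pop, 0, f), 0L)
  counts <- vapply(1:10, function(i) {
    set.seed(100 + i)
    export_survivors(pop, 0.1, f)
  }, integer(1))
  se <- sqrt(400 * 0.1 * 0.9)
  expect_lt(abs(mean(counts) - 40), 3 * se / sqrt(10))
  # headers carry class and parameters
  set.seed(55)
  export_survivors(pop[1:5, ], 1, f)
  nm <- names(read_fasta_sequences(f))
  expect_true(all(grepl("parasite\\|l=", nm)))
})

test_that("a single-value sweep reduces to one run per replicate", {
  spec <- scenario_spec(4, scale = 0.002, sweep_var = "d",
                        sweep_values = 0.01, replicates = 2)
  tab <- sweep_parameter(spec, sim_params(max_steps = 30), seed = 56)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$value, c(0.01, 0.01))
  expect_false(any(tab$extinct))
  expect_true(all(tab$population > 0))
})

test_that("YAML configuration round-trips, rejecting unknown keys", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("d: 0.02", "D: 8", "K: inf", "neigh: 5",
               "hydrolysis:", "  UA: 0.000953"), f)
  p <- read_params_yaml(f)
  expect_equal(p$d, 0.02)
  expect_equal(p$D, 8)
  expect_true(is.infinite(p$K))
  expect_equal(p$neigh, 5L)
  expect_equal(unname(unclass(p$hydrolysis)["UA"]), 0.000953)
  writeLines("bogus: 1", f)
  expect_error(read_params_yaml(f), "unknown parameter")
})

test_that("run manifests record the resolved configuration", {
  f <- withr::local_tempfile(fileext = ".json")
  write_run_manifest(sim_params(), seed = 99, f, extra = list(note = "x"))
  m <- jsonlite::read_json(f)
  expect_equal(m$seed, 99)
  expect_equal(m$K, "inf")
  expect_equal(m$motif, MOTIF)
  expect_equal(m$note, "x")
})

test_that("higher base decay restores replicase-parasite coexistence", {
  # at d = 0.6 parasites clear in ~1/(d dt) = 17 steps unless copied, so
  # replicase-rich regions purge their mutational load and both classes
  # persist; at the reference d = 0.01 the parasite wake lingers for ~1000
  # steps and accumulates (see the methods vignette)
  set.seed(71)
  built <- build_scenario(scenario_spec(4, scale = 0.01, sweep_values = 0.6),
                          sim_params(max_steps = 3000, d = 0.6))
  res <- run_simulation(built$params, built$population)
  last <- res$stats[nrow(res$stats), ]
  expect_false(res$extinct)
  expect_gt(last$n_replicases, 0)
  expect_gt(last$n_parasites, 0)
})
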