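#' Scenario specification
#'
#' The four study scenarios:
#' 1. a pool of ideal replicases only (parasites arise by mutation);
#' 2. a pool of completely random sequences (replicases arise by accident of
#'    composition);
#' 3. as scenario 1 but with the measured dinucleotide hydrolysis rates
#'    installed, so decay is sequence-dependent;
#' 4. as scenario 1 at a smaller scale, swept over the base decay rate `d`
#'    or the diffusion constant `D` to map the survival boundary.
#'
#' `scale` shrinks the reference system (100,000 agents on a 1000 x 1000
#' area) while preserving its initial density: the initial count is
#' multiplied by `scale` and each area side by `sqrt(scale)`. The dynamics
#' are density-driven (radius interactions and crowding), so a
#' density-preserving reduction keeps the qualitative regime.
#'
#' @param scenario Scenario id in 1..4.
#' @param scale Population/area scale factor (1 = reference scale).
#' @param init Optional explicit initial agent count (overrides scaling).
#' @param sweep_var For scenario 4: `"d"` or `"D"`.
#' @param sweep_values For scenario 4: numeric vector of values (>= 1).
#' @param replicates For scenario 4: seeds per sweep value.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario, scale = 0.09, init = NULL,
                          sweep_var = NULL, sweep_values = NULL,
                          replicates = 3) {
  if (!scenario %in% 1:4) stop("unknown scenario id: ", scenario)
  stopifnot(scale > 0, is.null(init) || init >= 0)
  if (scenario == 4) {
    if (is.null(sweep_var)) sweep_var <- "d"
    if (!sweep_var %in% c("d", "D"))
      stop("sweep variable must be \"d\" or \"D\"")
    if (is.null(sweep_values))
      sweep_values <- if (sweep_var == "d") c(0.001, 0.01, 0.6, 0.7)
                      else c(0, 4, 40, 400)
    if (!length(sweep_values)) stop("sweep needs at least one value")
  }
  structure(list(scenario = as.integer(scenario), scale = scale,
                 init = if (!is.null(init)) as.integer(init),
                 sweep_var = sweep_var, sweep_values = sweep_values,
                 replicates = as.integer(replicates)),
            class = "scenario_spec")
}

#' Build a scenario's parameters and initial population
#'
#' Applies the scenario's overrides to `params` (area scaling; the measured
#' hydrolysis table for scenario 3) and constructs the initial population:
#' ideal replicases at uniform random positions (scenarios 1, 3, 4) or
#' fully random sequences (scenario 2), some of which carry a working
#' replicase motif by chance.
#'
#' @param spec A [scenario_spec()].
#' @param params Base [sim_params()].
#' @return List with elements `params` (scaled), `population` (data frame
#'   `sequence, x, y`), and `info` (realized counts, including
#'   `n_accidental_replicases` for scenario 2).
#' @export
build_scenario <- function(spec, params = sim_params()) {
  stopifnot(inherits(spec, "scenario_spec"))
  reference_init <- 100000L
  params$sizeX <- params$sizeX * sqrt(spec$scale)
  params$sizeY <- params$sizeY * sqrt(spec$scale)
  n <- if (!is.null(spec$init)) spec$init
       else as.integer(round(reference_init * spec$scale))
  if (spec$scenario == 3) params$hydrolysis <- kierzek_rates()
  seqs <- if (spec$scenario == 2) {
    params$initP <- n
    random_sequence(params$seq_length, n)
  } else {
    params$initR <- n
    build_ideal_replicase(params$motif, params$seq_length, n)
  }
  pop <- data.frame(sequence = seqs,
                    x = stats::runif(n, 0, params$sizeX),
                    y = stats::runif(n, 0, params$sizeY),
                    stringsAsFactors = FALSE)
  n_repl <- sum(replication_rate(seqs, params$motif) > 0)
  list(params = params, population = pop,
       info = list(n = n, n_replicases = n_repl,
                   n_accidental_replicases =
                     if (spec$scenario == 2) n_repl))
}

#' Per-step population statistics
#'
#' Classifies agents as replicases (`a > 0`) or parasites (`a = 0`) and
#' computes class counts and class means of `a` and `l`. Means of an empty
#' class are `NA`.
#'
#' @param population Data frame with at least columns `a`, `l`, and
#'   optionally `state`.
#' @param step Step number to record.
#' @return One-row data frame matching the per-step trajectory schema.
#' @export
record_stats <- function(population, step = 0L) {
  repl <- population$a > 0
  n_complex <- if ("state" %in% names(population))
    sum(population$state == "enzyme") else 0L
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  data.frame(step = as.integer(step),
             n_total = nrow(population),
             n_replicases = sum(repl),
             n_parasites = sum(!repl),
             n_complexes = as.integer(n_complex),
             mean_a_replicases = mean_or_na(population$a[repl]),
             mean_l_replicases = mean_or_na(population$l[repl]),
             mean_l_parasites = mean_or_na(population$l[!repl]))
}

#' Export surviving sequences to FASTA
#'
#' Each surviving agent is included independently with probability
#' `sel_prob`. Headers carry the agent index, class, and its `(l, a, b)`
#' parameters.
#'
#' @param population Final population data frame (from [run_simulation()]).
#' @param sel_prob Inclusion probability in `[0, 1]`.
#' @param file Output FASTA path.
#' @return Invisibly, the number of records written.
#' @export
export_survivors <- function(population, sel_prob, file) {
  stopifnot(sel_prob >= 0, sel_prob <= 1)
  keep <- stats::runif(nrow(population)) < sel_prob
  sel <- population[keep, , drop = FALSE]
  seqs <- sel$sequence
  names(seqs) <- sprintf("agent_%d|%s|l=%.4f;a=%.6f;b=%.6f",
                         which(keep),
                         ifelse(sel$a > 0, "replicase", "parasite"),
                         sel$l, sel$a, sel$b)
  if (length(seqs) == 0) {
    # valid empty FASTA
    cat("", file = file)
  } else {
    write_fasta_sequences(seqs, file)
  }
  invisible(sum(keep))
}

#' Run a parameter sweep (scenario 4)
#'
#' One run per sweep value and replicate seed; reports the end state of
#' each run. Extinct runs have population 0 and `NA` means.
#'
#' @param spec A [scenario_spec()] with scenario 4 sweep settings.
#' @param params Base [sim_params()] (its `max_steps` bounds each run).
#' @param seed Base seed; replicate r of value v uses
#'   `seed + (index(v) - 1) * replicates + (r - 1)`.
#' @return Data frame with one row per run: `value`, `replicate`, `seed`,
#'   `steps_run`, `population`, `n_replicases`, `n_parasites`,
#'   `mean_a_replicases`, `mean_l_replicases`, `mean_l_parasites`,
#'   `extinct`.
#' @export
sweep_parameter <- function(spec, params = sim_params(), seed = 1) {
  stopifnot(inherits(spec, "scenario_spec"), spec$scenario == 4)
  rows <- list()
  for (iv in seq_along(spec$sweep_values)) {
    v <- spec$sweep_values[iv]
    for (r in seq_len(spec$replicates)) {
      run_seed <- seed + (iv - 1) * spec$replicates + (r - 1)
      p <- params
      if (spec$sweep_var == "d") p$d <- v else p$D <- v
      set.seed(run_seed)
      built <- build_scenario(spec, p)
      res <- run_simulation(built$params, built$population)
      last <- res$stats[nrow(res$stats), ]
      rows[[length(rows) + 1]] <- data.frame(
        value = v, replicate = r, seed = run_seed,
        steps_run = res$steps_run, population = last$n_total,
        n_replicases = last$n_replicases, n_parasites = last$n_parasites,
        mean_a_replicases = last$mean_a_replicases,
        mean_l_replicases = last$mean_l_replicases,
        mean_l_parasites = last$mean_l_parasites,
        extinct = res$extinct)
    }
  }
  do.call(rbind, rows)
}

#' Write a run manifest
#'
#' Records the fully resolved configuration and seed of a run as JSON, for
#' reproducibility audits.
#'
#' @param params The [sim_params()] used.
#' @param seed The RNG seed used.
#' @param file Output JSON path.
#' @param extra Optional named list of additional fields.
#' @export
write_run_manifest <- function(params, seed, file, extra = list()) {
  cfg <- params[c("int_radius", "sizeX", "sizeY", "seq_length", "d",
                  "seq_mut", "dt", "D", "K", "selProb", "initR", "initP",
                  "neigh", "max_steps")]
  cfg$K <- if (is.infinite(cfg$K)) "inf" else cfg$K
  cfg$hydrolysis <- as.list(unclass(params$hydrolysis))
  cfg$motif <- params$motif$bases
  cfg$match_threshold <- params$motif$match_threshold
  cfg$rate_per_match <- params$motif$rate_per_match
  cfg$min_loop <- params$folding$min_loop
  cfg$allow_wobble <- params$folding$allow_wobble
  out <- c(list(seed = seed), cfg, extra)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
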