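#' Sample a reaction waiting time in simulation steps
#'
#' Draws an exponential waiting time `t = -log(X) / k` with
#' `X ~ Uniform(0, 1]` and converts it to a step count
#' `floor(t / dt) + 1` (always at least 1). An infinite rate yields 1 step;
#' a zero rate means the reaction never fires and is an error for the
#' caller to avoid.
#'
#' @param k Reaction rate (> 0, possibly `Inf`).
#' @param dt Step length (> 0).
#' @param n Number of draws.
#' @param u Optional uniform draws in `(0, 1]` to use instead of fresh ones
#'   (deterministic evaluation of the mapping).
#' @return Integer-valued numeric vector of step counts (>= 1).
#' @export
sample_action_steps <- function(k, dt, n = 1, u = NULL) {
  stopifnot(dt > 0)
  if (k <= 0) stop("rate k must be positive; k = 0 means no reaction")
  if (is.infinite(k)) return(rep(1, if (is.null(u)) n else length(u)))
  if (is.null(u)) u <- stats::runif(n)
  stopifnot(all(u > 0), all(u <= 1))
  floor((-log(u) / k) / dt) + 1
}

#' Complex formation probability
#'
#' Probability that a meeting between an enzyme candidate (efficiency `a_E`,
#' folded fraction `l_E`) and a template (folded fraction `l_T`) forms a
#' complex: the enzyme must be folded to be catalytically active and the
#' template unfolded to be copyable, giving `a_E * l_E * (1 - l_T)`.
#'
#' @param a_E Enzyme replicase efficiency in `[0, 1]`.
#' @param l_E Enzyme folded fraction in `[0, 1]`.
#' @param l_T Template folded fraction in `[0, 1]`.
#' @return Numeric probability vector.
#' @export
complex_formation_probability <- function(a_E, l_E, l_T) {
  stopifnot(all(a_E >= 0 & a_E <= 1), all(l_E >= 0 & l_E <= 1),
            all(l_T >= 0 & l_T <= 1))
  a_E * l_E * (1 - l_T)
}

#' Create an agent from a sequence
#'
#' Derives the agent's three behavioural parameters from its sequence:
#' folded fraction `l` (secondary structure prediction), replicase
#' efficiency `a` (motif match and Poisson kinetics), decay rate `b` (base
#' rate plus phosphodiester hydrolysis), and samples its remaining lifetime
#' in steps.
#'
#' @param seq Character scalar RNA sequence of length `params$seq_length`.
#' @param x,y Position.
#' @param params A [sim_params()].
#' @return One-row data frame with columns `sequence, x, y, l, a, b,
#'   lifetime_steps, state`.
#' @export
make_agent <- function(seq, x, y, params = sim_params()) {
  seq <- toupper(seq)
  if (nchar(seq) != params$seq_length)
    stop("sequence length ", nchar(seq), " differs from seq_length ",
         params$seq_length)
  l <- folded_fraction(predict_structure(seq, params$folding))
  a <- replicase_efficiency(replication_rate(seq, params$motif), params$dt)
  b <- decay_rate(seq, params$d, params$hydrolysis)
  lifetime <- if (b > 0) sample_action_steps(b, params$dt) else Inf
  data.frame(sequence = seq, x = x %% params$sizeX, y = y %% params$sizeY,
             l = l, a = a, b = b, lifetime_steps = lifetime,
             state = "free", stringsAsFactors = FALSE)
}

#' Run the replicase-parasite simulation
#'
#' Executes `params$max_steps` steps of the two-phase loop. Phase one
#' (decay/diffusion), over agents in fresh random order: a complexed enzyme
#' decrements its complex's replication countdown and, at zero, copies the
#' template with mutation (offspring appears at the template's position,
#' its parameters derived from its own sequence) and dissociates the
#' complex; a free agent decrements its lifetime and is removed at zero,
#' otherwise diffuses. Phase two (interactions), over free agents in fresh
#' random order: an agent with more than `neigh` neighbours within
#' `int_radius` is removed (crowding); otherwise it scans its neighbours in
#' random order and forms a complex (itself as enzyme) with probability
#' `a * l * (1 - l_T)`, stopping at the first success. Complexed agents
#' neither diffuse, nor age, nor decay. The run stops early if the
#' population reaches zero. With a fixed seed the trajectory is
#' bit-identical across runs.
#'
#' @param params A [sim_params()].
#' @param population Initial population: data frame with columns `sequence`,
#'   `x`, `y` (e.g. from [build_scenario()]), or NULL for an empty start.
#' @param seed Integer RNG seed; if NULL the current RNG state is used.
#' @return A list of class `sim_result`:
#'   * `stats` — per-step data frame (`step`, `n_total`, `n_replicases`,
#'     `n_parasites`, `n_complexes`, `mean_a_replicases`,
#'     `mean_l_replicases`, `mean_l_parasites`, `births`, `decays`,
#'     `removals`), beginning with a step-0 row for the initial state;
#'   * `population` — final population data frame (`sequence, x, y, l, a,
#'     b, state`);
#'   * `steps_run`, `extinct`.
#' @export
run_simulation <- function(params = sim_params(), population = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(population))
    population <- data.frame(sequence = character(0), x = numeric(0),
                             y = numeric(0))
  stopifnot(all(c("sequence", "x", "y") %in% names(population)))
  seqs <- toupper(population$sequence)
  if (length(seqs)) {
    check_rna(seqs)
    if (any(nchar(seqs) != params$seq_length))
      stop("all sequences must have length seq_length = ",
           params$seq_length)
  }
  if (is.function(params$folding$backend))
    stop("run_simulation uses the builtin folding backend; ",
         "external backends are supported in predict_structure()")
  res <- sim_run_cpp(
    seqs, as.numeric(population$x %% params$sizeX),
    as.numeric(population$y %% params$sizeY),
    list(sizeX = params$sizeX, sizeY = params$sizeY,
         int_radius = params$int_radius, dt = params$dt, D = params$D,
         d = params$d, seq_mut = params$seq_mut, neigh = params$neigh,
         K = params$K, min_loop = params$folding$min_loop,
         allow_wobble = params$folding$allow_wobble,
         motif = encode_rna(params$motif$bases),
         match_threshold = params$motif$match_threshold,
         rate_per_match = params$motif$rate_per_match,
         hyd = matrix(unclass(params$hydrolysis), 4, 4,
                      dimnames = NULL),
         max_steps = params$max_steps,
         seq_length = params$seq_length))
  stats <- as.data.frame(res$stats)
  pop <- as.data.frame(res$population)
  structure(list(stats = stats, population = pop,
                 steps_run = res$steps_run,
                 extinct = nrow(pop) == 0),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  last <- x$stats[nrow(x$stats), ]
  cat("replicase-parasite simulation: ", x$steps_run, " steps, ",
      if (x$extinct) "extinct" else "alive", "\n", sep = "")
  cat(sprintf("  final: %d agents (%d replicases, %d parasites, %d complexes)\n",
              last$n_total, last$n_replicases, last$n_parasites,
              last$n_complexes))
  if (last$n_replicases > 0)
    cat(sprintf("  mean a (replicases) %.4f, mean l (replicases) %.3f\n",
                last$mean_a_replicases, last$mean_l_replicases))
  if (last$n_parasites > 0)
    cat(sprintf("  mean l (parasites) %.3f\n", last$mean_l_parasites))
  invisible(x)
}
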