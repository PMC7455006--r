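#' Global simulation parameters
#'
#' Constructs the set of global constants governing a run. Defaults are the
#' reference parameterization of the model: a 1000 x 1000 toroidal area,
#' 50-nt sequences, base decay rate 0.01, per-nucleotide substitution
#' probability 0.01, step length dt = 0.1, diffusion constant D = 4,
#' instantaneous replication (K = Inf, one step per complex), interaction
#' radius 3, and a crowding cap of 4 neighbours.
#'
#' @param int_radius Interaction radius of a single agent.
#' @param sizeX,sizeY Simulation area dimensions (toroidal).
#' @param seq_length Sequence length, constant for all agents.
#' @param d Base decay rate.
#' @param seq_mut Per-nucleotide substitution probability at replication.
#' @param dt Step length (time units per simulation step).
#' @param D Diffusion constant.
#' @param K Replication rate of a formed complex; `Inf` means the complex
#'   replicates on the next step.
#' @param selProb Probability that a surviving agent is included in the
#'   survivor FASTA export.
#' @param initR,initP Default initial counts of ideal replicases and of
#'   random-sequence agents (scenario builders may override).
#' @param neigh Maximum number of neighbours before crowding removal.
#' @param hydrolysis A [hydrolysis_table()].
#' @param folding A [folding_options()].
#' @param motif A [replicase_motif()].
#' @param max_steps Number of simulation steps.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(int_radius = 3, sizeX = 1000, sizeY = 1000,
                       seq_length = 50, d = 0.01, seq_mut = 0.01,
                       dt = 0.1, D = 4, K = Inf, selProb = 0.01,
                       initR = 100000, initP = 0, neigh = 4,
                       hydrolysis = hydrolysis_table(),
                       folding = folding_options(),
                       motif = replicase_motif(),
                       max_steps = 10000) {
  stopifnot(int_radius > 0, sizeX > 0, sizeY > 0, seq_length > 0,
            d >= 0, seq_mut >= 0, seq_mut <= 1, dt > 0, D >= 0, K > 0,
            selProb >= 0, selProb <= 1, initR >= 0, initP >= 0, neigh >= 0,
            max_steps >= 0)
  stopifnot(inherits(hydrolysis, "hydrolysis_table"),
            inherits(folding, "folding_options"),
            inherits(motif, "replicase_motif"))
  structure(list(int_radius = int_radius, sizeX = sizeX, sizeY = sizeY,
                 seq_length = as.integer(seq_length), d = d,
                 seq_mut = seq_mut, dt = dt, D = D, K = K,
                 selProb = selProb, initR = as.integer(initR),
                 initP = as.integer(initP), neigh = as.integer(neigh),
                 hydrolysis = hydrolysis, folding = folding, motif = motif,
                 max_steps = as.integer(max_steps)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("simulation parameters:\n")
  cat(sprintf("  area %g x %g (torus), int_radius %g, neigh cap %d\n",
              x$sizeX, x$sizeY, x$int_radius, x$neigh))
  cat(sprintf("  seq_length %d, seq_mut %g, motif %s (>=%d matches)\n",
              x$seq_length, x$seq_mut, x$motif$bases,
              x$motif$match_threshold))
  cat(sprintf("  dt %g, D %g, K %s, d %g, max_steps %d\n",
              x$dt, x$D, format(x$K), x$d, x$max_steps))
  cat(sprintf("  hydrolysis: %d nonzero bonds\n",
              sum(unclass(x$hydrolysis) > 0)))
  invisible(x)
}

#' Read simulation parameters from a YAML file
#'
#' Keys are named exactly as the global parameter table
#' (`int_radius`, `sizeX`, `sizeY`, `seq_length`, `d`, `seq_mut`, `dt`,
#' `D`, `K`, `selProb`, `initR`, `initP`, `neigh`, `max_steps`), plus an
#' optional `hydrolysis` mapping of dinucleotide to rate. `K: inf` (any
#' case) is read as infinity. Unknown keys are an error.
#'
#' @param file Path to a YAML file.
#' @param base A `sim_params` object supplying values absent from the file.
#' @return A [sim_params()] object.
#' @export
read_params_yaml <- function(file, base = sim_params()) {
  y <- yaml::read_yaml(file)
  known <- c("int_radius", "sizeX", "sizeY", "seq_length", "d", "seq_mut",
             "dt", "D", "K", "selProb", "initR", "initP", "neigh",
             "max_steps", "hydrolysis")
  extra <- setdiff(names(y), known)
  if (length(extra)) stop("unknown parameter keys: ",
                          paste(extra, collapse = ", "))
  args <- base[setdiff(known, "hydrolysis")]
  for (k in setdiff(names(y), "hydrolysis")) {
    v <- y[[k]]
    if (k == "K" && is.character(v) && tolower(v) %in% c("inf", "infinity"))
      v <- Inf
    args[[k]] <- v
  }
  if (!is.null(y$hydrolysis))
    args$hydrolysis <- hydrolysis_table(unlist(y$hydrolysis))
  else
    args$hydrolysis <- base$hydrolysis
  args$folding <- base$folding
  args$motif <- base$motif
  do.call(sim_params, args)
}
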