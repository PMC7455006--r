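# Shared fixtures and independent oracles used across test files.

MOTIF <- "UCAUUGAAAAAAAAAGACAA"
MOTIF_RC <- "UUGUCUUUUUUUUUCAAUGA"

# brute-force O(n^2) toroidal neighbour scan (oracle for the grid index)
brute_neighbors <- function(x, y, sizeX, sizeY, radius) {
  n <- length(x)
  lapply(seq_len(n), function(i) {
    d <- torus_distance(x[i], y[i], x, y, sizeX, sizeY)
    sort(setdiff(which(d < radius), i))
  })
}

# maximum pair count over the exhaustive enumeration (oracle for the DP)
enum_max_pairs <- function(seq, opts = folding_options()) {
  max(vapply(enumerate_structures(seq, opts),
             function(s) nrow(s$pairs), integer(1)))
}

# a 50-nt sequence whose first 20 nt match the motif in exactly k positions:
# mismatched positions are shifted to the next base in the alphabet
seq_with_matches <- function(k, tail = strrep("G", 30)) {
  ch <- strsplit(MOTIF, "", fixed = TRUE)[[1]]
  flip <- seq_len(20 - k)
  alphabet <- c("A", "C", "G", "U")
  ch[flip] <- alphabet[(match(ch[flip], alphabet) %% 4) + 1]
  paste0(paste(ch, collapse = ""), tail)
}

# small scenario-1 style run shared by reaction-engine tests
small_run <- function(seed = 42, scale = 0.005, max_steps = 300, ...) {
  set.seed(seed)
  spec <- scenario_spec(1, scale = scale)
  b <- build_scenario(spec, sim_params(max_steps = max_steps, ...))
  run_simulation(b$params, b$population)
}
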