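RNA_ALPHABET <- c("A", "C", "G", "U")

#' The catalytic replicase motif
#'
#' The 20-nt 5' motif that marks a sequence as a candidate RNA replicase,
#' together with the scoring rule that turns an ungapped match count into a
#' replication rate \eqn{k_R}: `k_R = rate_per_match * matches` when
#' `matches >= match_threshold`, otherwise 0 (the agent is a parasite).
#' The default motif is the 5' segment of the engineered polymerase ribozyme
#' tC19Z.
#'
#' @param bases Motif sequence (character scalar over A/C/G/U).
#' @param match_threshold Minimum number of position-wise matches for a
#'   nonzero rate.
#' @param rate_per_match Rate contributed by each matching position.
#' @return An object of class `replicase_motif`.
#' @export
#' @examples
#' replicase_motif()
replicase_motif <- function(bases = "UCAUUGAAAAAAAAAGACAA",
                            match_threshold = 7,
                            rate_per_match = 10) {
  bases <- toupper(bases)
  check_rna(bases)
  stopifnot(match_threshold >= 0, match_threshold <= nchar(bases),
            rate_per_match >= 0)
  structure(list(bases = bases,
                 match_threshold = as.integer(match_threshold),
                 rate_per_match = rate_per_match),
            class = "replicase_motif")
}

#' @export
print.replicase_motif <- function(x, ...) {
  cat("replicase motif: ", x$bases, "\n",
      "  k_R = ", x$rate_per_match, " * matches, zero below ",
      x$match_threshold, " matches\n", sep = "")
  invisible(x)
}

check_rna <- function(seq) {
  bad <- grepl("[^ACGU]", seq)
  if (any(bad))
    stop("sequence contains symbols outside {A,C,G,U}: ",
         paste(seq[bad][seq_len_min(bad)], collapse = ", "))
  invisible(seq)
}

seq_len_min <- function(x) seq_len(min(3L, sum(x)))

#' Generate random RNA sequences
#'
#' Each position is drawn i.i.d. uniformly from {A, C, G, U}.
#'
#' @param length Sequence length in nucleotides (> 0).
#' @param n Number of sequences to draw.
#' @return Character vector of `n` sequences.
#' @export
random_sequence <- function(length, n = 1) {
  if (length <= 0) stop("sequence length must be positive")
  vapply(seq_len(n), function(i) {
    paste(sample(RNA_ALPHABET, length, replace = TRUE), collapse = "")
  }, character(1))
}

#' Reverse complement of an RNA sequence
#'
#' Watson-Crick complement (A-U, C-G) read 3' to 5'.
#'
#' @param seq Character vector of RNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("UCAUUGAAAAAAAAAGACAA")
reverse_complement <- function(seq) {
  check_rna(toupper(seq))
  vapply(toupper(seq), function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Mutate a sequence by independent point substitutions
#'
#' Every nucleotide is replaced with probability `seq_mut` by one of the three
#' other nucleotides, chosen uniformly. Insertions and deletions never occur;
#' length is always preserved.
#'
#' @param seq Character scalar RNA sequence.
#' @param seq_mut Per-nucleotide substitution probability in `[0, 1]`.
#' @return Mutated sequence (character scalar).
#' @export
mutate_sequence <- function(seq, seq_mut) {
  stopifnot(seq_mut >= 0, seq_mut <= 1)
  seq <- toupper(seq)
  check_rna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < seq_mut
  if (any(hit)) {
    idx <- match(chars[hit], RNA_ALPHABET)
    # uniform over the 3 alternatives, never the original base
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    chars[hit] <- RNA_ALPHABET[((idx - 1L + shift) %% 4L) + 1L]
  }
  paste(chars, collapse = "")
}

#' Count position-wise motif matches
#'
#' Ungapped, position-wise identity between the first `nchar(motif$bases)`
#' nucleotides of `seq` and the motif. No alignment is performed.
#'
#' @param seq Character vector of RNA sequences, each at least as long as the
#'   motif.
#' @param motif A [replicase_motif()].
#' @return Integer vector of match counts.
#' @export
motif_match_count <- function(seq, motif = replicase_motif()) {
  seq <- toupper(seq)
  check_rna(seq)
  m <- nchar(motif$bases)
  if (any(nchar(seq) < m))
    stop("sequence shorter than the motif (", m, " nt)")
  mot <- strsplit(motif$bases, "", fixed = TRUE)[[1]]
  vapply(seq, function(s) {
    sum(strsplit(substr(s, 1L, m), "", fixed = TRUE)[[1]] == mot)
  }, integer(1), USE.NAMES = FALSE)
}

#' Replication rate from the motif match
#'
#' `k_R = rate_per_match * matches` if `matches >= match_threshold`, else 0.
#' Agents with `k_R = 0` are parasites.
#'
#' @inheritParams motif_match_count
#' @return Numeric vector of rates `k_R`.
#' @export
replication_rate <- function(seq, motif = replicase_motif()) {
  matches <- motif_match_count(seq, motif)
  ifelse(matches >= motif$match_threshold,
         motif$rate_per_match * matches, 0)
}

#' Replicase efficiency from a replication rate
#'
#' Probability that a replication reaction at rate `k_R` fires within one
#' simulation step of length `dt`, under constant-hazard (Poisson) kinetics:
#' `a = 1 - exp(-k_R * dt)`. `a = 0` exactly when `k_R = 0`, which marks a
#' parasite.
#'
#' @param k_R Nonnegative replication rate(s).
#' @param dt Step length (> 0).
#' @return Numeric vector of probabilities in `[0, 1)`.
#' @export
replicase_efficiency <- function(k_R, dt) {
  stopifnot(all(k_R >= 0), dt > 0)
  1 - exp(-k_R * dt)
}

#' Sequence decay rate from phosphodiester hydrolysis
#'
#' The decay rate of an agent is the base spontaneous-decay rate plus the sum
#' of the hydrolysis rates of its `length - 1` internal phosphodiester bonds,
#' looked up per ordered (5' to 3') dinucleotide.
#'
#' @param seq Character vector of RNA sequences.
#' @param base_d Base decay rate (>= 0).
#' @param table A [hydrolysis_table()].
#' @return Numeric vector of decay rates `b >= base_d`.
#' @export
decay_rate <- function(seq, base_d, table = hydrolysis_table()) {
  stopifnot(base_d >= 0)
  seq <- toupper(seq)
  check_rna(seq)
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n < 2) return(base_d)
    din <- substring(s, 1:(n - 1), 2:n)
    base_d + sum(table[din])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Dinucleotide hydrolysis-rate table
#'
#' A complete lookup over the 16 ordered dinucleotides; rates not supplied
#' default to 0. Orientation matters: `UA` (5'-UA-3') is distinct from `AU`.
#'
#' @param rates Named numeric vector of rates, names among the 16 ordered
#'   dinucleotides. Missing entries are 0.
#' @return Named numeric vector of length 16 with class `hydrolysis_table`.
#' @export
#' @examples
#' hydrolysis_table(c(UA = 0.000953))
hydrolysis_table <- function(rates = numeric(0)) {
  dinucs <- as.vector(outer(RNA_ALPHABET, RNA_ALPHABET, paste0))
  out <- stats::setNames(numeric(16), dinucs)
  if (length(rates)) {
    nm <- toupper(names(rates))
    if (is.null(names(rates)) || !all(nm %in% dinucs))
      stop("rates must be named by ordered dinucleotides over {A,C,G,U}")
    if (any(rates < 0)) stop("hydrolysis rates must be nonnegative")
    out[nm] <- as.numeric(rates)
  }
  class(out) <- c("hydrolysis_table", "numeric")
  out
}

#' Measured non-enzymatic hydrolysis rates
#'
#' Dinucleotide phosphodiester hydrolysis rates for spontaneous RNA
#' degradation, from the Kierzek oligoribonucleotide cleavage measurements:
#' pyrimidine-A bonds are the most labile, pyrimidine-C intermediate,
#' pyrimidine-G/U weakly labile, and purine-initiated bonds stable (0).
#'
#' @return A [hydrolysis_table()] with the eight nonzero measured entries.
#' @export
kierzek_rates <- function() {
  hydrolysis_table(c(
    UA = 0.000953, CA = 0.000932,
    UC = 0.000846, CC = 0.000846,
    UG = 0.000100, CG = 0.000100,
    UU = 0.000100, CU = 0.000100
  ))
}

#' Read a hydrolysis table from a text file
#'
#' Two whitespace-separated columns: dinucleotide, rate. Lines starting with
#' `#` are ignored. Dinucleotides absent from the file get rate 0.
#'
#' @param file Path to the table file.
#' @return A [hydrolysis_table()].
#' @export
#' @examples
#' f <- system.file("extdata", "hydrolysis_kierzek.txt",
#'                  package = "rnaworld")
#' read_hydrolysis_table(f)
read_hydrolysis_table <- function(file) {
  tab <- utils::read.table(file, header = FALSE, comment.char = "#",
                           col.names = c("dinucleotide", "rate"),
                           colClasses = c("character", "numeric"))
  hydrolysis_table(stats::setNames(tab$rate, tab$dinucleotide))
}

#' Build an ideal motif-driven replicase sequence
#'
#' Positions 1-20 carry the replicase motif, positions 21-40 its reverse
#' complement (so the two segments form a perfect 18-bp stem under the
#' hairpin-loop constraint), and the final `seq_length - 40` positions are
#' uniform random. Such agents have the maximal replication rate by
#' construction.
#'
#' @param motif A [replicase_motif()] (must be 20 nt for the default layout).
#' @param seq_length Total sequence length; must be 50 with the default motif.
#' @param n Number of sequences to draw.
#' @return Character vector of `n` sequences.
#' @export
build_ideal_replicase <- function(motif = replicase_motif(), seq_length = 50,
                                  n = 1) {
  m <- nchar(motif$bases)
  if (seq_length != 2 * m + 10)
    stop("ideal replicase layout needs seq_length = ", 2 * m + 10,
         " for a ", m, "-nt motif (got ", seq_length, ")")
  stem <- paste0(motif$bases, reverse_complement(motif$bases))
  paste0(stem, random_sequence(seq_length - 2 * m, n))
}

#' Read sequences from a FASTA file
#'
#' @param file Path to an (uncompressed) FASTA file of RNA sequences.
#' @return Named character vector of sequences (T is converted to U).
#' @export
read_fasta_sequences <- function(file) {
  ss <- Biostrings::readBStringSet(file)
  seqs <- chartr("Tt", "Uu", toupper(as.character(ss)))
  check_rna(seqs)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Character vector of RNA sequences; names become FASTA headers.
#' @param file Output path.
#' @export
write_fasta_sequences <- function(seqs, file) {
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq_", seq_along(seqs))
  ss <- Biostrings::RNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}
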