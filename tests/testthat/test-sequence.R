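test_that("random sequences are uniform over the alphabet and reproducible", {
  expect_error(random_sequence(0), "positive")
  set.seed(11)
  seqs <- random_sequence(50, 2000)          # 1e5 bases
  expect_true(all(nchar(seqs) == 50))
  bases <- unlist(strsplit(seqs, "", fixed = TRUE))
  expect_setequal(unique(bases), c("A", "C", "G", "U"))
  freq <- table(bases) / length(bases)
  se <- sqrt(0.25 * 0.75 / length(bases))
  expect_true(all(abs(freq - 0.25) < 3 * se))
  set.seed(99); s1 <- random_sequence(50)
  set.seed(99); s2 <- random_sequence(50)
  expect_identical(s1, s2)
})

test_that("reverse complement matches the motif's printed complement and is an involution", {
  expect_identical(reverse_complement(MOTIF), MOTIF_RC)
  expect_identical(reverse_complement("A"), "U")
  set.seed(3)
  for (s in random_sequence(30, 10))
    expect_identical(reverse_complement(reverse_complement(s)), s)
})

test_that("mutation is substitution-only with binomial per-site rate", {
  s <- random_sequence(50)
  set.seed(5)
  expect_identical(mutate_sequence(s, 0), s)
  m1 <- mutate_sequence(s, 1)
  expect_true(all(strsplit(m1, "")[[1]] != strsplit(s, "")[[1]]))
  expect_equal(nchar(m1), nchar(s))
  # per-site substitution frequency over 1e5 site draws
  set.seed(6)
  n_rep <- 2000
  hits <- vapply(seq_len(n_rep), function(i) {
    m <- mutate_sequence(s, 0.01)
    sum(strsplit(m, "")[[1]] != strsplit(s, "")[[1]])
  }, numeric(1))
  n_sites <- n_rep * 50
  p_hat <- sum(hits) / n_sites
  se <- sqrt(0.01 * 0.99 / n_sites)
  expect_lt(abs(p_hat - 0.01), 3 * se)
  # mean Hamming distance matches Binomial(50, 0.01)
  expect_lt(abs(mean(hits) - 0.5), 3 * sqrt(50 * 0.01 * 0.99 / n_rep))
})

test_that("motif matching is position-wise identity over the first 20 nt", {
  expect_equal(motif_match_count(paste0(MOTIF, strrep("A", 30))), 20L)
  expect_equal(motif_match_count(paste0(MOTIF_RC, strrep("A", 30))), 4L)
  # the motif contains exactly two G (positions 6 and 16)
  expect_equal(motif_match_count(strrep("G", 50)), 2L)
  expect_equal(motif_match_count(strrep("C", 50)), 2L)  # C at 2 and 18
  expect_error(motif_match_count("ACGU"), "shorter")
  for (k in c(0, 6, 7, 13, 20))
    expect_equal(motif_match_count(seq_with_matches(k)), k)
})

test_that("replication rate applies the 7-match threshold and 10x multiplier", {
  expect_equal(replication_rate(seq_with_matches(20)), 200)
  expect_equal(replication_rate(seq_with_matches(7)), 70)
  expect_equal(replication_rate(seq_with_matches(6)), 0)
  expect_equal(replication_rate(seq_with_matches(0)), 0)
})

test_that("replicase efficiency follows constant-hazard kinetics", {
  expect_equal(replicase_efficiency(0, 0.1), 0)
  expect_equal(replicase_efficiency(200, 0.1), 1 - exp(-20))
  expect_equal(replicase_efficiency(70, 0.1), 1 - exp(-7))
  expect_equal(round(replicase_efficiency(70, 0.1), 7), 0.9990881)
  # strictly increasing in k_R, bounded in [0, 1)
  k <- seq(0, 300, by = 10)
  a <- replicase_efficiency(k, 0.1)
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= 0 & a < 1))
  expect_true(all((a == 0) == (k == 0)))
})

test_that("decay rate sums ordered-dinucleotide hydrolysis over the bonds", {
  expect_equal(decay_rate("UUUACG", 0.02), 0.02)   # empty table
  expect_equal(decay_rate("UUUACG", 0.01, kierzek_rates()),
               0.01 + 0.0001 + 0.0001 + 0.000953 + 0 + 0.0001)
  # orientation matters: UA is hot, AU is not
  tab <- kierzek_rates()
  expect_gt(decay_rate("UA", 0, tab), 0)
  expect_equal(decay_rate("AU", 0, tab), 0)
  # order of summation is immaterial and b >= base_d always
  set.seed(8)
  for (s in random_sequence(50, 20)) {
    expect_gte(decay_rate(s, 0.01, tab), 0.01)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    din <- function(q) substring(q, 1:(nchar(q) - 1), 2:nchar(q))
    expect_equal(decay_rate(s, 0, tab), sum(tab[din(s)]))
  }
  expect_error(hydrolysis_table(c(XX = 0.1)), "dinucleotide")
  expect_error(hydrolysis_table(c(UA = -1)), "nonnegative")
})

test_that("ideal replicases are motif + complement + random tail", {
  set.seed(12)
  seqs <- build_ideal_replicase(n = 20)
  expect_true(all(substr(seqs, 1, 20) == MOTIF))
  expect_true(all(substr(seqs, 21, 40) == MOTIF_RC))
  expect_true(all(motif_match_count(seqs) == 20L))
  expect_true(all(replication_rate(seqs) == 200))
  expect_gt(length(unique(substr(seqs, 41, 50))), 1)
  expect_error(build_ideal_replicase(seq_length = 40), "seq_length")
})

test_that("hydrolysis tables round-trip through the two-column text format", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# dinucleotide rate", "UA 0.000953", "CA 0.000932"), f)
  tab <- read_hydrolysis_table(f)
  expect_equal(unname(tab["UA"]), 0.000953)
  expect_equal(unname(tab["CA"]), 0.000932)
  expect_equal(sum(unclass(tab) > 0), 2L)
})

test_that("FASTA round-trips sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(one = "ACGUACGU", two = MOTIF)
  write_fasta_sequences(seqs, f)
  back <- read_fasta_sequences(f)
  expect_equal(unname(back), unname(seqs))
  expect_equal(names(back), names(seqs))
})

test_that("the shipped hydrolysis table matches the measured rates", {
  f <- system.file("extdata", "hydrolysis_kierzek.txt", package = "rnaworld")
  expect_identical(read_hydrolysis_table(f), kierzek_rates())
})
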