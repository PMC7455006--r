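test_that("maximum base-pairing recovers hand-checkable structures", {
  expect_equal(nrow(predict_structure(strrep("A", 50))$pairs), 0L)
  # G-run pairs the C-run: 4 pairs, enclosing the AAAA loop
  st <- predict_structure("GGGGAAAACCCC",
                          folding_options(allow_wobble = FALSE))
  expect_equal(nrow(st$pairs), 4L)
  expect_equal(enum_max_pairs("GGGGAAAACCCC",
                              folding_options(allow_wobble = FALSE)), 4L)
  # the designed 40-nt replicase stem: 18 pairs (i, 41 - i); the two
  # innermost rungs are forbidden by the loop constraint
  prefix <- paste0(MOTIF, MOTIF_RC)
  st40 <- predict_structure(prefix)
  expect_equal(nrow(st40$pairs), 18L)
  expect_equal(st40$pairs[order(st40$pairs[, 1]), , drop = FALSE],
               matrix(c(1:18, 40:23), ncol = 2,
                      dimnames = list(NULL, c("i", "j"))))
})

test_that("DP pair count equals the brute-force enumeration maximum", {
  set.seed(21)
  for (len in c(12, 14)) {
    for (s in random_sequence(len, if (len == 12) 40 else 12)) {
      for (wob in c(TRUE, FALSE)) {
        opts <- folding_options(allow_wobble = wob)
        expect_equal(nrow(predict_structure(s, opts)$pairs),
                     enum_max_pairs(s, opts),
                     info = paste(s, "wobble:", wob))
      }
    }
  }
})

test_that("enumeration handles degenerate inputs and guards its size", {
  expect_length(enumerate_structures("ACGU"), 1L)   # min_loop forbids pairs
  expect_length(enumerate_structures(strrep("A", 12)), 1L)
  expect_equal(nrow(enumerate_structures("ACGU")[[1]]$pairs), 0L)
  expect_error(enumerate_structures(strrep("A", 17)), "16")
})

test_that("allowing wobble pairs never decreases the maximum pair count", {
  set.seed(22)
  for (s in random_sequence(30, 25)) {
    expect_gte(nrow(predict_structure(s, folding_options())$pairs),
               nrow(predict_structure(
                 s, folding_options(allow_wobble = FALSE))$pairs))
  }
})

test_that("folded fraction is the paired-nucleotide share", {
  expect_equal(folded_fraction(rna_structure(matrix(integer(0), ncol = 2),
                                             50)), 0)
  stem50 <- paste0(MOTIF, MOTIF_RC, strrep("A", 10))
  expect_equal(folded_fraction(predict_structure(stem50)), 0.72)
  set.seed(23)
  for (s in random_sequence(40, 15)) {
    st <- predict_structure(s)
    l <- folded_fraction(st)
    expect_true(l >= 0 && l <= 1)
    expect_equal((l * st$length) %% 2, 0)  # paired nucleotides come in twos
  }
})

test_that("prediction is deterministic and structures satisfy invariants", {
  set.seed(24)
  for (s in random_sequence(50, 10)) {
    a <- predict_structure(s)
    b <- predict_structure(s)
    expect_identical(a$pairs, b$pairs)
    if (nrow(a$pairs)) {
      expect_false(anyDuplicated(as.vector(a$pairs)) > 0)
      expect_true(all(a$pairs[, 2] - a$pairs[, 1] - 1 >= 3))
      ch <- strsplit(s, "")[[1]]
      expect_true(all(rnaworld:::allowed_pair(ch[a$pairs[, 1]],
                                              ch[a$pairs[, 2]])))
    }
  }
})

test_that("structure objects reject invariant violations", {
  expect_error(rna_structure(rbind(c(1, 5), c(5, 10)), 10), "more than one")
  expect_error(rna_structure(rbind(c(1, 3)), 10), "loop")
  expect_error(rna_structure(rbind(c(1, 12)), 10), "outside")
  expect_error(rna_structure(rbind(c(1, 6)), 10, seq = "AAAAAAAAAA"),
               "disallowed")
  # crossing pairs (a pseudoknot) are allowed by the data model
  pk <- rna_structure(rbind(c(1, 6), c(4, 10)), 12, seq = "GAAAACAAAUAA")
  expect_equal(nrow(pk$pairs), 2L)
})

test_that("dot-bracket notation round-trips, including pseudoknots", {
  st <- predict_structure("GGGGAAAACCCC")
  db <- structure_to_dotbracket(st)
  expect_equal(db, "((((....))))")
  back <- dotbracket_to_structure(db)
  expect_equal(back$pairs, st$pairs)
  pk <- rna_structure(rbind(c(1, 6), c(4, 10)), 12)
  db2 <- structure_to_dotbracket(pk)
  expect_equal(dotbracket_to_structure(db2)$pairs, pk$pairs)
  expect_error(dotbracket_to_structure("(()"), "unbalanced")
})

test_that("a function backend plugs in and is validated; missing external backends error", {
  stub <- function(seq) rbind(c(1L, 6L))   # fixed single pair
  opts <- folding_options(backend = stub)
  st <- predict_structure("GGGGAAAACCCC", opts)
  expect_equal(nrow(st$pairs), 1L)
  bad <- function(seq) rbind(c(1L, 6L), c(6L, 12L))
  expect_error(predict_structure("GGGGAAAACCCC",
                                 folding_options(backend = bad)),
               "more than one")
  expect_error(folding_options(backend = "some-external-tool"),
               "configuration error")
})

test_that("the RNAfold wrapper yields a valid structure for a designed hairpin", {
  backend <- vienna_backend()
  st <- predict_structure("GGGGGAAAACCCCC", folding_options(backend = backend))
  expect_gte(nrow(st$pairs), 4L)
  expect_true(all(st$pairs[, 2] - st$pairs[, 1] - 1 >= 3))
})
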