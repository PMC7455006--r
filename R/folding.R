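#' Folding options
#'
#' Controls the secondary-structure predictor used to derive the folded
#' fraction `l`. The builtin backend is a maximum base-pairing dynamic
#' program (nested structures only); any R function mapping a sequence to a
#' pair matrix can be plugged in as an external backend (for example a
#' wrapper around a thermodynamic folding tool).
#'
#' @param min_loop Minimum number of unpaired nucleotides in a hairpin loop
#'   (default 3).
#' @param allow_wobble Allow G-U wobble pairs in addition to Watson-Crick
#'   (default TRUE).
#' @param backend `"builtin"`, or a function `function(seq)` returning a
#'   two-column integer matrix of 1-based pair indices.
#' @return An object of class `folding_options`.
#' @export
folding_options <- function(min_loop = 3, allow_wobble = TRUE,
                            backend = "builtin") {
  stopifnot(min_loop >= 0)
  if (!is.function(backend) && !identical(backend, "builtin"))
    stop("folding backend must be \"builtin\" or a function; ",
         "an unavailable external backend is a configuration error")
  structure(list(min_loop = as.integer(min_loop),
                 allow_wobble = isTRUE(allow_wobble),
                 backend = backend),
            class = "folding_options")
}

allowed_pair <- function(b1, b2, allow_wobble = TRUE) {
  wc <- (b1 == "A" & b2 == "U") | (b1 == "U" & b2 == "A") |
        (b1 == "G" & b2 == "C") | (b1 == "C" & b2 == "G")
  if (allow_wobble)
    wc <- wc | (b1 == "G" & b2 == "U") | (b1 == "U" & b2 == "G")
  wc
}

#' Construct a secondary structure object
#'
#' A set of base pairs `(i, j)`, `i < j`, 1-based over a sequence of length
#' `length`. Each nucleotide may participate in at most one pair. Crossing
#' (pseudoknotted) pairs are allowed in the data model — an external
#' predictor may report them — but the builtin predictor only produces
#' nested structures.
#'
#' @param pairs Two-column integer matrix of pair indices (0 rows allowed).
#' @param length Sequence length.
#' @param seq Optional sequence used to check pair chemistry.
#' @param opts [folding_options()] used for chemistry checks when `seq` is
#'   given.
#' @return An object of class `rna_structure`.
#' @export
rna_structure <- function(pairs, length, seq = NULL,
                          opts = folding_options()) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs)) {
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, 2:1]
    if (any(pairs[, 1] < 1) || any(pairs[, 2] > length))
      stop("pair index outside the sequence")
    if (anyDuplicated(as.vector(pairs)))
      stop("a nucleotide participates in more than one pair")
    if (any(pairs[, 2] - pairs[, 1] - 1 < opts$min_loop))
      stop("pair violates the hairpin loop constraint (min_loop = ",
           opts$min_loop, ")")
    if (!is.null(seq)) {
      ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
      ok <- allowed_pair(ch[pairs[, 1]], ch[pairs[, 2]], opts$allow_wobble)
      if (!all(ok)) stop("chemically disallowed base pair in structure")
    }
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  structure(list(pairs = pairs, length = as.integer(length)),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("RNA secondary structure: ", nrow(x$pairs), " pairs on ",
      x$length, " nt (l = ", format(folded_fraction(x), digits = 3), ")\n",
      sep = "")
  cat(" ", structure_to_dotbracket(x), "\n")
  invisible(x)
}

#' Predict a secondary structure
#'
#' With the builtin backend, computes a nested structure maximizing the
#' number of base pairs (Nussinov-style dynamic programming) subject to the
#' hairpin-loop constraint and the active pairing rule, with a deterministic
#' traceback that prefers pairing the leftmost admissible partner. With a
#' function backend, calls it and validates the result against the
#' structure invariants.
#'
#' @param seq Character scalar RNA sequence.
#' @param opts [folding_options()].
#' @return An [rna_structure()].
#' @export
#' @examples
#' predict_structure("GGGGAAAACCCC")
predict_structure <- function(seq, opts = folding_options()) {
  seq <- toupper(seq)
  check_rna(seq)
  if (is.function(opts$backend)) {
    pairs <- opts$backend(seq)
    return(rna_structure(pairs, nchar(seq), seq = NULL, opts = opts))
  }
  pairs <- nussinov_pairs_cpp(encode_rna(seq), opts$min_loop,
                              opts$allow_wobble)
  rna_structure(pairs, nchar(seq))
}

encode_rna <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], RNA_ALPHABET) - 1L
}

#' Folded-state fraction of a structure
#'
#' The fraction of time an RNA molecule is assumed to spend folded, taken as
#' the fraction of its nucleotides that are paired:
#' `l = 2 * n_pairs / length`.
#'
#' @param structure An [rna_structure()].
#' @return Numeric scalar in `[0, 1]`.
#' @export
folded_fraction <- function(structure) {
  stopifnot(inherits(structure, "rna_structure"))
  2 * nrow(structure$pairs) / structure$length
}

#' Exhaustively enumerate nested structures (test oracle)
#'
#' Enumerates every valid nested structure of a short sequence by the
#' standard decomposition (first position unpaired, or paired with each
#' admissible partner). Intended as an independent brute-force oracle for
#' the dynamic program; guarded to sequences of at most 16 nt.
#'
#' @inheritParams predict_structure
#' @return List of [rna_structure()] objects (always includes the empty
#'   structure).
#' @export
enumerate_structures <- function(seq, opts = folding_options()) {
  seq <- toupper(seq)
  check_rna(seq)
  n <- nchar(seq)
  if (n > 16) stop("enumeration oracle is limited to 16 nt")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  h <- opts$min_loop
  region <- function(i, j) {
    if (j - i < h + 1) return(list(matrix(integer(0), ncol = 2)))
    out <- lapply(region(i + 1, j), identity)        # i unpaired
    for (k in (i + h + 1):j) {
      if (allowed_pair(ch[i], ch[k], opts$allow_wobble)) {
        inner <- region(i + 1, k - 1)
        outer_ <- region(k + 1, j)
        for (s1 in inner) for (s2 in outer_)
          out[[length(out) + 1]] <- rbind(c(i, k), s1, s2)
      }
    }
    out
  }
  lapply(region(1, n), function(p) rna_structure(p, n, seq = NULL,
                                                 opts = opts))
}

#' Convert a structure to dot-bracket notation
#'
#' Nested pairs are written as `()`; crossing pairs from pseudoknotted
#' external predictions are assigned to additional bracket layers
#' `[]`, `{}`, `<>`.
#'
#' @param structure An [rna_structure()].
#' @return Character scalar.
#' @export
structure_to_dotbracket <- function(structure) {
  open_ <- c("(", "[", "{", "<")
  close_ <- c(")", "]", "}", ">")
  n <- structure$length
  out <- rep(".", n)
  p <- structure$pairs
  if (nrow(p)) {
    layer <- integer(nrow(p))
    for (r in seq_len(nrow(p))) {
      used <- 0L
      if (r > 1) {
        prev <- seq_len(r - 1)
        crossing <- (p[prev, 1] < p[r, 1] & p[r, 1] < p[prev, 2] &
                       p[prev, 2] < p[r, 2]) |
                    (p[r, 1] < p[prev, 1] & p[prev, 1] < p[r, 2] &
                       p[r, 2] < p[prev, 2])
        while (any(crossing & layer[prev] == used)) used <- used + 1L
      }
      if (used >= length(open_)) stop("structure too deeply pseudoknotted")
      layer[r] <- used
      out[p[r, 1]] <- open_[used + 1L]
      out[p[r, 2]] <- close_[used + 1L]
    }
  }
  paste(out, collapse = "")
}

#' Parse dot-bracket notation into a structure
#'
#' Accepts the bracket layers `()`, `[]`, `{}`, `<>`; crossing layers are
#' read as pseudoknots.
#'
#' @param db Character scalar in dot-bracket notation.
#' @param seq Optional sequence for chemistry validation.
#' @param opts [folding_options()] for validation.
#' @return An [rna_structure()].
#' @export
dotbracket_to_structure <- function(db, seq = NULL,
                                    opts = folding_options()) {
  open_ <- c("(", "[", "{", "<")
  close_ <- c(")", "]", "}", ">")
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  pairs <- matrix(integer(0), ncol = 2)
  for (layer in seq_along(open_)) {
    stack <- integer(0)
    for (i in seq_along(ch)) {
      if (ch[i] == open_[layer]) stack <- c(stack, i)
      else if (ch[i] == close_[layer]) {
        if (!length(stack)) stop("unbalanced dot-bracket string")
        pairs <- rbind(pairs, c(stack[length(stack)], i))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack)) stop("unbalanced dot-bracket string")
  }
  rna_structure(pairs, length(ch), seq = seq, opts = opts)
}

#' ViennaRNA RNAfold external backend
#'
#' Convenience wrapper turning the `RNAfold` command-line tool (if present
#' on the PATH) into a folding backend function for [folding_options()].
#' The minimum-free-energy structure it returns is used verbatim; the
#' builtin predictor is not consulted.
#'
#' @return A backend function suitable for `folding_options(backend = )`.
#' @export
vienna_backend <- function() {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe))
    stop("RNAfold not found on PATH; external folding backend unavailable")
  function(seq) {
    out <- system2(exe, c("--noPS"), input = seq, stdout = TRUE)
    db <- sub("\\s.*$", "", out[2])
    dotbracket_to_structure(db)$pairs
  }
}
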