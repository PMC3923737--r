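#' Folding engines
#'
#' A folding engine is a list with a `fold(sequence)` function returning
#' `list(structure = <dot-bracket>, mfe = <kcal/mol>)` and a `name`. The
#' built-in engine is a deterministic dynamic-programming folder over a
#' simplified nearest-neighbour energy model (per-pair energies for G:C,
#' A:U and G:U, stacking implicit, bulge/internal-loop and hairpin-loop
#' penalties, branching restricted to the exterior loop). Candidate
#' pre-miRNA screening only needs MFE *ranges* and a single-hairpin check,
#' so the engine trades thermodynamic exactness for reproducibility; an
#' external thermodynamic folder (ViennaRNA's `RNAfold`) can be plugged in
#' where available.
#'
#' @param min_loop minimum hairpin loop size in nt.
#' @param max_loop maximum joint unpaired length of a bulge/internal loop.
#' @return an object of class `fold_engine`.
#' @examples
#' eng <- builtin_fold_engine()
#' fold_sequence(eng, "GGGGGAAACCCCC")
#' @export
builtin_fold_engine <- function(min_loop = 3, max_loop = 10) {
  structure(list(
    name = "builtin",
    fold = function(sequence) {
      .fold_mfe_cpp(norm_rna(sequence), min_loop = min_loop,
                    max_loop = max_loop)
    }
  ), class = "fold_engine")
}

#' @rdname builtin_fold_engine
#' @param rnafold path to the `RNAfold` executable.
#' @export
viennarna_fold_engine <- function(rnafold = "RNAfold") {
  structure(list(
    name = "viennarna",
    fold = function(sequence) {
      out <- system2(rnafold, c("--noPS"), input = norm_rna(sequence),
                     stdout = TRUE, stderr = FALSE)
      if (length(out) < 2) stop("RNAfold produced no structure")
      line <- out[length(out)]
      db <- sub("^([.()]+).*$", "\\1", line)
      mfe <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
      list(structure = db, mfe = mfe)
    }
  ), class = "fold_engine")
}

#' Fold a sequence with an engine
#'
#' @param engine a `fold_engine`.
#' @param sequence RNA (or DNA) sequence string.
#' @return `list(structure, mfe)`.
#' @export
fold_sequence <- function(engine, sequence) {
  stopifnot(inherits(engine, "fold_engine"))
  res <- engine$fold(sequence)
  stopifnot(nchar(res$structure) == nchar(sequence))
  res
}

#' Parse paired positions from a dot-bracket string
#'
#' @param db dot-bracket structure.
#' @return integer matrix with columns `i`, `j` (1-based, i < j).
#' @export
db_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  stack <- integer(0)
  out <- matrix(0L, 0, 2, dimnames = list(NULL, c("i", "j")))
  pairs <- list()
  for (k in seq_along(chars)) {
    if (chars[k] == "(") stack <- c(stack, k)
    else if (chars[k] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  if (length(pairs)) out <- do.call(rbind, pairs)
  colnames(out) <- c("i", "j")
  out[order(out[, 1]), , drop = FALSE]
}

#' Terminal (hairpin) loops of a structure
#'
#' A terminal loop is the unpaired stretch enclosed by an innermost pair:
#' a pair `(i, j)` with no other pair nested inside it.
#'
#' @param db dot-bracket structure.
#' @return data.frame with one row per terminal loop: columns `start`,
#'   `end` (1-based span of the unpaired loop) and `closing_i`,
#'   `closing_j` (the innermost pair).
#' @export
db_terminal_loops <- function(db) {
  p <- db_pairs(db)
  if (nrow(p) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      closing_i = integer(0), closing_j = integer(0)))
  inner <- vapply(seq_len(nrow(p)), function(k) {
    i <- p[k, 1]; j <- p[k, 2]
    !any(p[, 1] > i & p[, 2] < j)
  }, logical(1))
  q <- p[inner, , drop = FALSE]
  data.frame(start = q[, 1] + 1L, end = q[, 2] - 1L,
             closing_i = q[, 1], closing_j = q[, 2], row.names = NULL)
}

#' Top-level structural domains
#'
#' The outermost pairs of a structure (pairs not nested inside any other
#' pair) delimit its exterior-loop domains; a window folding into two
#' hairpins has two domains. Used to excise the hairpin hosting the
#' mature-read block from a larger candidate window.
#'
#' @param db dot-bracket structure.
#' @return data.frame with one row per domain: `start`, `end` (the
#'   outermost pair, 1-based).
#' @export
db_domains <- function(db) {
  p <- db_pairs(db)
  if (nrow(p) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  outer <- vapply(seq_len(nrow(p)), function(k) {
    i <- p[k, 1]; j <- p[k, 2]
    !any(p[, 1] < i & p[, 2] > j)
  }, logical(1))
  q <- p[outer, , drop = FALSE]
  data.frame(start = q[, 1], end = q[, 2], row.names = NULL)
}

#' Adjusted MFE and the MFE index
#'
#' `amfe()` is the length-adjusted folding energy, `(mfe / length) * 100`
#' (kcal/mol per 100 nt). `mfei()` divides AMFE by the GC percentage of
#' the sequence; its magnitude is the standard hairpin-ness statistic used
#' to screen candidate pre-miRNAs.
#'
#' @param mfe minimum folding free energy, kcal/mol (negative).
#' @param length sequence length, nt (> 0).
#' @param gc_percent GC content in percent (> 0).
#' @return numeric value.
#' @export
mfei <- function(mfe, length, gc_percent) {
  if (any(length <= 0)) stop("mfei(): length must be > 0")
  if (any(gc_percent == 0)) stop("mfei(): undefined ratio at GC percent 0")
  amfe(mfe, length) / gc_percent
}

#' @rdname mfei
#' @export
amfe <- function(mfe, length) {
  if (any(length <= 0)) stop("amfe(): length must be > 0")
  mfe / length * 100
}
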