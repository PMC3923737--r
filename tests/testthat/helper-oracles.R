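# Independent oracles, written from the defining formulas and kept free of
# the package's implementation paths.

# --- folding: exhaustive enumeration over short sequences ----------------
# Energy model mirrors the engine's published constants; structures are
# enumerated explicitly (all non-crossing pair sets, then filtered to the
# engine's grammar: no multibranch loops, interior loops <= max_loop).

oracle_pair_e <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(-1.92)
  if (key %in% c("AU", "UA")) return(-0.81)
  if (key %in% c("GU", "UG")) return(-0.49)
  Inf
}

oracle_fold_mfe <- function(seq, min_loop = 3, max_loop = 10) {
  n <- nchar(seq)
  b <- strsplit(seq, "")[[1]]
  memo <- new.env(parent = emptyenv())
  # enumerate all non-crossing pair sets over [i, j]
  enum <- function(i, j) {
    if (j - i < min_loop + 1) return(list(list()))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- enum(i + 1, j) # i unpaired
    for (k in (i + min_loop + 1):j) {
      if (is.infinite(oracle_pair_e(b[i], b[k]))) next
      inner <- enum(i + 1, k - 1)
      rest <- if (k < j) enum(k + 1, j) else list(list())
      for (x in inner) for (y in rest)
        out[[length(out) + 1]] <- c(list(c(i, k)), x, y)
    }
    memo[[key]] <- out
    out
  }
  energy <- function(pairs) {
    if (length(pairs) == 0) return(0)
    e <- 0
    for (p in pairs) {
      e <- e + oracle_pair_e(b[p[1]], b[p[2]])
      nested <- Filter(function(q) q[1] > p[1] && q[2] < p[2], pairs)
      if (length(nested) == 0) {
        e <- e + 4.0 + 0.3 * ((p[2] - p[1] - 1) - 3)
      } else {
        # direct child = nested pair not inside another nested pair
        direct <- Filter(function(q) {
          !any(vapply(nested, function(r)
            r[1] < q[1] && r[2] > q[2], logical(1)))
        }, nested)
        if (length(direct) > 1) return(Inf)  # multibranch: outside grammar
        q <- direct[[1]]
        li <- q[1] - p[1] - 1
        lj <- p[2] - q[2] - 1
        if (li + lj > max_loop) return(Inf)
        e <- e + if (li == 0 && lj == 0) 0
                 else if (li == 0 || lj == 0) 1.0 * (li + lj)
                 else 0.8 * (li + lj)
      }
    }
    e
  }
  structs <- enum(1, n)
  min(0, min(vapply(structs, energy, numeric(1))))
}

# --- Audic-Claverie: summation through the NB representation -------------
oracle_ac <- function(x, y, n1, n2) {
  r <- n2 / n1
  upper <- max(y, 50 * (x + y + 10))
  p <- dnbinom(0:upper, size = x + 1, prob = 1 / (1 + r))
  min(1, sum(p[p <= p[y + 1] * (1 + 1e-12)]))
}

# --- conditional NB split test -------------------------------------------
oracle_nb <- function(x, y, phi) {
  s <- x + y
  if (s == 0) return(1)
  p <- if (phi == 0) {
    dbinom(0:s, s, 0.5)
  } else {
    w <- dnbinom(0:s, size = 1 / phi, mu = 1) *
      dnbinom(s:0, size = 1 / phi, mu = 1)
    w / sum(w)
  }
  min(1, sum(p[p <= p[x + 1] * (1 + 1e-12)]))
}

# --- TMM: straight-line transcription of the published formulas ----------
oracle_tmm <- function(counts, lib_sizes = colSums(counts),
                       trim_m = 0.30, trim_a = 0.05) {
  nlib <- ncol(counts)
  uq <- numeric(nlib)
  for (k in 1:nlib) uq[k] <- quantile(counts[, k], 0.75) / lib_sizes[k]
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(nlib)
  for (k in 1:nlib) {
    if (k == ref) { f[k] <- 1; next }
    x <- counts[, k]; y <- counts[, ref]
    use <- x > 0 & y > 0
    x <- x[use]; y <- y[use]
    M <- log2((x / lib_sizes[k]) / (y / lib_sizes[ref]))
    A <- 0.5 * log2((x / lib_sizes[k]) * (y / lib_sizes[ref]))
    w <- (lib_sizes[k] - x) / (lib_sizes[k] * x) +
      (lib_sizes[ref] - y) / (lib_sizes[ref] * y)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    f[k] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f / exp(mean(log(f)))
}
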