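# Independent oracles used by the test suite.

# Brute-force optimal parse of S into unit copies + uncovered bases.
# Enumerates every segmentation recursively and minimises the same
# (combined, distance) objective as the package DP, where
# combined = edits + #copies + #uncovered bases.
oracle_decompose <- function(S, units, mismatch = 1, indel = 1) {
  n <- nchar(S)
  memo <- new.env(parent = emptyenv())
  lev <- function(a, b) utils::adist(a, b,
                                     costs = list(ins = indel, del = indel,
                                                  sub = mismatch))[1, 1]
  best <- function(i) {  # parse S[i..n]; returns c(combined, dist)
    if (i > n) return(c(0, 0))
    key <- as.character(i)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- best(i + 1) + c(1, 0)  # uncovered base
    for (j in i:n) {
      seg <- substr(S, i, j)
      for (u in units) {
        e <- lev(seg, u)
        cand <- best(j + 1) + c(1 + e, e)
        if (cand[1] < res[1] ||
            (cand[1] == res[1] && cand[2] < res[2])) res <- cand
      }
    }
    memo[[key]] <- res
    res
  }
  out <- best(1)
  list(combined = out[1], distance = out[2])
}

# Exhaustive minimum-cost edit script search for the EDDC model:
# single-character substitution/insertion/deletion plus duplication of an
# exact unit occurrence (u -> uu) and contraction of an exact adjacent pair
# (uu -> u).  A* over string space with an admissible Levenshtein bound,
# branch-and-bound capped by the plain Levenshtein distance.
oracle_eddc <- function(s, t, units, mismatch = 1, ins = 1, del = 1,
                        dup = function(m) m / 2, con = function(m) m / 2) {
  # only characters of t or of a unit can usefully be written by an optimal
  # script (any other character never survives nor enables a unit match)
  bases <- intersect(c("A", "C", "G", "T"),
                     unique(strsplit(paste0(t, paste0(units, collapse = "")),
                                     "")[[1]]))
  m <- nchar(units)
  dupc <- vapply(m, dup, numeric(1))
  conc <- vapply(m, con, numeric(1))
  # admissible lower bound: weighted Levenshtein where a gap character can
  # cost as little as the cheapest per-base copy-number event and a
  # substitution as little as a mismatch (every EDDC op costs at least its
  # weighted-Levenshtein displacement, which obeys the triangle inequality)
  gapw <- min(c(ins, del, dupc / m, conc / m))
  subw <- min(mismatch, 2 * gapw)
  SCALE <- 4L  # adist needs integer costs; quarter-unit resolution
  gw <- max(1L, as.integer(round(gapw * SCALE)))
  sw <- max(1L, as.integer(round(subw * SCALE)))
  maxlen <- max(nchar(s), nchar(t)) + max(m) + 2
  h <- function(x) {
    utils::adist(x, t, costs = list(ins = gw, del = gw, sub = sw))[1, 1] / SCALE
  }
  ub <- utils::adist(s, t,
                     costs = list(ins = ins, del = del, sub = mismatch))[1, 1]
  g <- new.env(parent = emptyenv(), hash = TRUE)
  key <- function(y) paste0("k", y)  # "" is not a valid env name
  assign(key(s), 0, envir = g)
  qs <- s
  qf <- h(s)
  while (length(qs)) {
    i <- which.min(qf)
    x <- qs[i]
    fx <- qf[i]
    qs <- qs[-i]; qf <- qf[-i]
    gx <- get(key(x), envir = g)
    if (fx > ub + 1e-9) next
    if (fx - h(x) > gx + 1e-9) next  # stale queue entry
    if (x == t) return(gx)
    nx <- nchar(x)
    ch <- if (nx) strsplit(x, "", fixed = TRUE)[[1]] else character(0)
    push <- function(y, cost) {
      gy <- gx + cost
      old <- if (exists(key(y), envir = g, inherits = FALSE))
        get(key(y), envir = g) else Inf
      if (gy < old - 1e-9 && gy + h(y) <= ub + 1e-9) {
        assign(key(y), gy, envir = g)
        qs <<- c(qs, y); qf <<- c(qf, gy + h(y))
      }
    }
    for (i2 in seq_len(nx)) {
      push(paste0(substr(x, 1, i2 - 1), substr(x, i2 + 1, nx)), del)
      for (b in setdiff(bases, ch[i2])) {
        push(paste0(substr(x, 1, i2 - 1), b, substr(x, i2 + 1, nx)), mismatch)
      }
    }
    if (nx < maxlen) {
      for (i2 in 0:nx) {
        for (b in bases) {
          push(paste0(substr(x, 1, i2), b, substr(x, i2 + 1, nx)), ins)
        }
      }
    }
    for (ui in seq_along(units)) {
      u <- units[ui]; mu <- m[ui]
      if (mu > nx) next
      starts <- seq_len(nx - mu + 1L)
      occ <- starts[substring(x, starts, starts + mu - 1L) == u]
      for (p in occ) {
        if (nx + mu <= maxlen) {
          push(paste0(substr(x, 1, p + mu - 1), u, substr(x, p + mu, nx)),
               dupc[ui])
        }
        if (p + 2 * mu - 1 <= nx &&
            substr(x, p + mu, p + 2 * mu - 1) == u) {
          push(paste0(substr(x, 1, p + mu - 1), substr(x, p + 2 * mu, nx)),
               conc[ui])
        }
      }
    }
  }
  ub  # queue exhausted under the bound: plain edit script is optimal
}

# deterministic random DNA string
rand_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
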