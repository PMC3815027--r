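# Independent brute-force oracles, deliberately naive implementations kept
# separate from the package's code paths.

# Flood-fill connected components by breadth-first search over an explicit
# queue; returns an integer label array.
oracle_flood_fill <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    m <- abs(dz) + abs(dy) + abs(dx)
    if (m == 0) next
    if (connectivity == 6 && m > 1) next
    if (connectivity == 18 && m > 2) next
    offs[[length(offs) + 1]] <- c(dz, dy, dx)
  }
  lab <- array(0L, dim = d)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- list(arrayInd(start, d)[1, ])
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        w <- v + o
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- nxt
          queue[[length(queue) + 1]] <- w
        }
      }
    }
  }
  lab
}

# Exhaustive between-class-variance threshold search, one level at a time.
oracle_otsu <- function(v) {
  v <- as.integer(v)
  n <- length(v)
  best_t <- NA_integer_
  best_s <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / n
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  if (is.na(best_t)) stop("constant input")
  best_t
}

# Chi-squared statistic from first principles.
oracle_chi2 <- function(observed, expected) sum((observed - expected)^2 / expected)

# Contingency-table expected counts + statistic.
oracle_chi2_table <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  oracle_chi2(tab, e)
}

# Pooled-variance two-sample t statistic from the textbook formula.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}
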