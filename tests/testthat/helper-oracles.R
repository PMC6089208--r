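# Independent oracles used by the property tests. These deliberately use
# naive exhaustive strategies, not the package's own algorithms.

# Exhaustive 8CM search: enumerate every 8-subset of cysteine positions,
# keep the valid assignments, return the lexicographically smallest.
oracle8cm <- function(sequence, minGap = 2L, maxGap = 40L) {
  res <- strsplit(sequence, "")[[1]]
  cs <- which(res == "C")
  if (length(cs) < 8L) return(NULL)
  sub <- combn(cs, 8L)
  ok <- sub[4L, ] == sub[3L, ] + 1L & sub[6L, ] == sub[5L, ] + 2L
  for (slot in c(1L, 2L, 4L, 6L, 7L)) {
    gap <- sub[slot + 1L, ] - sub[slot, ] - 1L
    ok <- ok & gap >= minGap & gap <= maxGap
  }
  if (!any(ok)) return(NULL)
  valid <- sub[, ok, drop = FALSE]
  best <- do.call(order, as.data.frame(t(valid)))[1]
  valid[, best]
}

# Brute-force Benjamini-Hochberg step-up straight from the definition.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(vapply(i:m, function(j) m * p[o[j]] / j, numeric(1)), 1)
  }
  q
}

# Position-by-position IUPAC comparison (N in the sequence matches nothing).
oracleIupacScan <- function(sequence, pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  s <- strsplit(sequence, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  w <- length(p)
  hits <- integer(0)
  for (start in seq_len(length(s) - w + 1L)) {
    win <- s[start:(start + w - 1L)]
    if (all(vapply(seq_len(w), function(k) win[k] %in% sets[[p[k]]],
                   logical(1))))
      hits <- c(hits, start)
  }
  hits
}

# Fine-grid root of the net-charge curve (step 0.001 pH).
oraclePi <- function(sequence) {
  grid <- seq(0, 14, by = 0.001)
  q <- peptideCharge(sequence, grid)
  grid[which.min(abs(q))]
}

# Random protein with a bounded number of cysteines at random positions.
randomCysProtein <- function(len = 80L, nCys = sample(6:14, 1L)) {
  res <- sample(setdiff(c("A", "D", "E", "G", "K", "L", "N", "Q", "S",
                          "T", "V"), "C"), len, replace = TRUE)
  pos <- sample(len, min(nCys, len))
  res[pos] <- "C"
  paste(res, collapse = "")
}

# plain random peptide over the 20 canonical residues
randomProtein <- function(len = sample(20:120, 1L)) {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aas, len, replace = TRUE), collapse = "")
}
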