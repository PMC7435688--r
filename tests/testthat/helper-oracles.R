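# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the alignment oracle is a plain-R Gotoh dynamic
# program, the BH oracle is the literal step-up definition, and the
# DerSimonian-Laird oracle follows the moment formulas step by step.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(L) paste(sample(AA_LETTERS, L, TRUE), collapse = "")

# Ends-free (overlap) affine-gap alignment by explicit dynamic programming:
# match +1, mismatch +0.01, gap open 10 / extend 1, leading and trailing
# gaps free.  Traceback recovers the identical-residue count and the
# aligned span of each sequence.
overlap_align_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # x residue aligned to a gap
  Iy <- matrix(NEG, n + 1, m + 1)  # y residue aligned to a gap
  M[1, ] <- 0; M[, 1] <- 0         # free leading gaps
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) 1 else 0.01
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - 11, Ix[i - 1, j] - 1)
      Iy[i, j] <- max(M[i, j - 1] - 11, Iy[i, j - 1] - 1)
    }
  }
  best <- 0; bi <- 1; bj <- 1      # empty alignment scores 0
  for (i in 1:(n + 1)) if (M[i, m + 1] > best + 1e-12) { best <- M[i, m + 1]; bi <- i; bj <- m + 1 }
  for (j in 1:(m + 1)) if (M[n + 1, j] > best + 1e-12) { best <- M[n + 1, j]; bi <- n + 1; bj <- j }
  matches <- 0; xs <- integer(0); ys <- integer(0)
  i <- bi; j <- bj; state <- "M"
  while (i > 1 && j > 1) {
    if (state == "M") {
      s <- if (x[i - 1] == y[j - 1]) 1 else 0.01
      if (x[i - 1] == y[j - 1]) matches <- matches + 1
      xs <- c(xs, i - 1); ys <- c(ys, j - 1)
      target <- M[i, j] - s
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      state <- c("M", "Ix", "Iy")[which(abs(prev - target) < 1e-9)[1]]
      i <- i - 1; j <- j - 1
    } else if (state == "Ix") {
      xs <- c(xs, i - 1)
      state <- if (abs(Ix[i, j] - (M[i - 1, j] - 11)) < 1e-9) "M" else "Ix"
      i <- i - 1
    } else {
      ys <- c(ys, j - 1)
      state <- if (abs(Iy[i, j] - (M[i, j - 1] - 11)) < 1e-9) "M" else "Iy"
      j <- j - 1
    }
  }
  span_x <- if (length(xs)) diff(range(xs)) + 1 else 0
  span_y <- if (length(ys)) diff(range(ys)) + 1 else 0
  list(score = best, matches = matches,
       identity = matches / min(n, m),
       coverage_shorter = (if (n <= m) span_x else span_y) / min(n, m))
}

# Benjamini-Hochberg by the literal step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# DerSimonian-Laird pooled estimate computed step by step
dl_oracle <- function(theta, se, alpha = 0.05) {
  k <- length(theta)
  w <- 1 / se^2
  fe <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  pooled <- sum(ws * theta) / sum(ws)
  z <- qnorm(1 - alpha / 2)
  list(pooled = pooled, ci = pooled + c(-1, 1) * z / sqrt(sum(ws)),
       tau2 = tau2, Q = Q,
       I2 = if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0)
}

# a cheap synthetic study for module tests
small_study <- function(seed, n_samples = 80, n_species = 12,
                        genes_per_species = 3, encoder_species = 3, ...) {
  simulate_study(simulation_config(
    n_samples = n_samples, n_species = n_species,
    genes_per_species = genes_per_species, encoder_species = encoder_species,
    seed = seed, ...))
}

# mutate a protein to roughly a target identity (independent of the
# package's family generator; used to build alignment test pairs)
mutate_to <- function(seq, target) {
  r <- strsplit(seq, "")[[1]]
  k <- round((1 - target) * length(r))
  for (p in sample(length(r), k)) r[p] <- sample(setdiff(AA_LETTERS, r[p]), 1)
  paste(r, collapse = "")
}
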