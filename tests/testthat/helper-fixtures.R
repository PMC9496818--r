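# Shared fixtures and independent oracles, built in code at test time.

# star on 4 nodes, node 1 at the center, encoded as strong weights
star_matrix <- function(w = 0.9) {
  m <- matrix(0, 4, 4)
  m[1, 2:4] <- m[2:4, 1] <- w
  diag(m) <- 1
  conn_matrix(m, "star")
}

path3_matrix <- function(w = 0.9) {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- m[2, 3] <- m[3, 2] <- w
  diag(m) <- 1
  conn_matrix(m, "path3")
}

complete_matrix <- function(n, w = 0.9) {
  m <- matrix(w, n, n)
  diag(m) <- 1
  conn_matrix(m, sprintf("complete%d", n))
}

random_symmetric_matrix <- function(n, subject_id = "rand") {
  w <- matrix(runif(n * n, -1, 1), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  conn_matrix(w, subject_id)
}

# Brute-force Shannon/Fisher oracle: explicit loops over the walk
# distribution, nodal entropy/Fisher and the network averages. Kept
# deliberately naive and independent of the package internals.
brute_hf <- function(adj) {
  n <- nrow(adj)
  hs <- numeric(n); fs <- numeric(n)
  for (i in seq_len(n)) {
    k <- 0
    for (j in seq_len(n)) if (j != i && adj[i, j] == 1) k <- k + 1
    probs <- numeric(0)
    for (j in seq_len(n)) {
      if (j == i) next
      probs <- c(probs, if (k > 0 && adj[i, j] == 1) 1 / k else 0)
    }
    if (k == 0) {
      hs[i] <- 0; fs[i] <- 1
      next
    }
    s <- 0
    for (p in probs) if (p > 0) s <- s - p * log(p)
    hs[i] <- s / log(n - 1)
    f <- 0
    for (j in seq_len(length(probs) - 1)) {
      f <- f + (sqrt(probs[j + 1]) - sqrt(probs[j]))^2
    }
    fs[i] <- f / 2
  }
  c(H = mean(hs), F = mean(fs))
}

random_adjacency <- function(n, p = 0.5) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- rbinom(length(up), 1, p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

as_adjacency <- function(a, threshold = 0.5) {
  structure(list(a = a, threshold_used = threshold, subject_id = "fixture"),
            class = "adjacency")
}

# small valid phenotype tibble
mini_phen <- function(ids, sites, ...) {
  n <- length(ids)
  tibble::tibble(subject_id = ids, site = sites,
                 age = seq(20, 60, length.out = n),
                 sex = rep(c("F", "M"), length.out = n),
                 diagnosis = rep("control", n), tr = 2, ...)
}

# cosine test signal sampled at tr seconds
tone <- function(freq, n = 2048, tr = 2, phase = 0) {
  sin(2 * pi * freq * (0:(n - 1)) * tr + phase)
}
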