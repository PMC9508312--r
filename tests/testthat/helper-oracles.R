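# Brute-force oracles, deliberately independent of the package's
# implementation paths: min-plus relaxation for distances (vs Dijkstra),
# scalar triple loops for clustering/strengths/blocks (vs matrix algebra).

# shortest directed path lengths by Bellman-Ford-style min-plus relaxation;
# edge s -> t exists iff W[t, s] > 0 with length 1 / W[t, s]
oracle_distances <- function(W) {
  K <- nrow(W)
  L <- matrix(Inf, K, K)
  for (s in seq_len(K)) {
    for (t in seq_len(K)) {
      if (s != t && W[t, s] > 0) L[s, t] <- 1 / W[t, s]
    }
  }
  D <- L
  diag(D) <- 0
  for (iter in seq_len(K)) {
    for (s in seq_len(K)) {
      for (t in seq_len(K)) {
        if (s == t) next
        D[s, t] <- min(D[s, t], min(D[s, ] + L[, t]))
      }
    }
  }
  D
}

oracle_global_efficiency <- function(D) {
  off <- D[row(D) != col(D)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

# directed-weighted clustering by exhaustive enumeration of ordered triples
oracle_clustering <- function(W) {
  K <- nrow(W)
  S <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      S[i, j] <- W[i, j]^(1 / 3) + W[j, i]^(1 / 3)
    }
  }
  diag(S) <- 0
  a <- (W > 0) * 1
  Ci <- numeric(K)
  for (i in seq_len(K)) {
    num <- 0
    for (j in seq_len(K)) {
      for (k in seq_len(K)) {
        num <- num + S[i, j] * S[j, k] * S[k, i]
      }
    }
    ki <- sum(a[i, ]) + sum(a[, i])
    recip <- 0
    for (j in seq_len(K)) recip <- recip + a[i, j] * a[j, i]
    den <- ki * (ki - 1) - 2 * recip
    Ci[i] <- if (den > 0) 0.5 * num / den else 0
  }
  list(per_node = Ci, global = mean(Ci))
}

oracle_strengths <- function(W) {
  K <- nrow(W)
  ins <- numeric(K)
  outs <- numeric(K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      ins[i] <- ins[i] + W[i, j]
      outs[j] <- outs[j] + W[i, j]
    }
  }
  list(in_strength = ins, out_strength = outs)
}

oracle_local_efficiency <- function(W) {
  K <- nrow(W)
  Le <- numeric(K)
  for (i in seq_len(K)) {
    nb <- which((W[i, ] > 0 | W[, i] > 0) & seq_len(K) != i)
    if (length(nb) < 2) next
    Le[i] <- oracle_global_efficiency(oracle_distances(W[nb, nb, drop = FALSE]))
  }
  Le
}

oracle_block_sum <- function(W, labels, sources, targets) {
  s <- 0
  for (j in seq_along(labels)) {
    for (i in seq_along(labels)) {
      if (i != j && labels[j] %in% sources && labels[i] %in% targets) {
        s <- s + W[i, j]
      }
    }
  }
  s
}

# random sparse weighted digraph with zero diagonal, weights in [0, 1]
random_digraph <- function(K, density = 0.5, seed) {
  set.seed(seed)
  W <- matrix(stats::runif(K * K), K, K)
  W[stats::runif(K * K) > density] <- 0
  diag(W) <- 0
  W
}

# a fixed stable 3-channel order-2 model used by the estimator tests
known_mvar3 <- function() {
  A1 <- matrix(c(0.5, 0.0, 0.0,
                 0.3, 0.4, 0.0,
                 0.0, 0.3, 0.5), nrow = 3, byrow = TRUE)
  A2 <- matrix(c(-0.2, 0.0, 0.0,
                 0.0, -0.2, 0.1,
                 0.0, 0.0, -0.2), nrow = 3, byrow = TRUE)
  list(A1, A2)
}

known_mvar3_spec <- function() {
  A <- known_mvar3()
  labels <- c("x1", "x2", "x3")
  rows <- list()
  self <- list()
  for (r in 1:2) {
    for (i in 1:3) {
      for (j in 1:3) {
        v <- A[[r]][i, j]
        if (v == 0) next
        if (i == j) {
          self[[length(self) + 1]] <- data.frame(channel = labels[i],
                                                 lag = r, coef = v)
        } else {
          rows[[length(rows) + 1]] <- data.frame(source = labels[j],
                                                 target = labels[i],
                                                 lag = r, coef = v)
        }
      }
    }
  }
  coupling_spec(labels, edges = do.call(rbind, rows),
                self = do.call(rbind, self), noise_sd = 1)
}

# small scaled-down cohort configuration shared by the recovery tests
small_cohort_config <- function(seed, attenuation) {
  default_config(
    seed = seed,
    cohort = list(n_patients = 15, n_controls = 15,
                  attenuation = attenuation,
                  duration_s = 120, fs = 120, hdrs_model = NULL),
    bandpass = NULL,
    freq_grid = c(lo = 1, hi = 45, step = 0.5),
    mvar = list(order = 3, max_order = 5))
}
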