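# Independent oracles used across the suite. Each one deliberately takes a
# different computational route from the package code it checks.

# Brute-force posterior P(het) at every position of a short chromosome by
# enumerating all 2^K hidden state paths. `obs` uses the package codes
# (0 hom / 1 het / NA missing), one entry per position (NA at pseudomarkers).
oracle_phet <- function(pos, obs, error_prob, map_function = "haldane") {
  K <- length(pos)
  stopifnot(K <= 12L)
  r <- if (K > 1L) ipqtl::map_to_recomb(diff(pos), map_function) else numeric(0)
  states <- as.matrix(expand.grid(rep(list(0:1), K)))
  w <- apply(states, 1L, function(s) {
    p <- 0.5
    if (K > 1L) for (k in seq_len(K - 1L))
      p <- p * if (s[k] == s[k + 1L]) 1 - r[k] else r[k]
    for (k in seq_len(K)) if (!is.na(obs[k]))
      p <- p * if (obs[k] == s[k]) 1 - error_prob else error_prob
    p
  })
  unname(colSums(states * w) / sum(w))
}

# Closed-form single-marker regression LOD: (n/2) * log10(RSS0/RSS1)
oracle_marker_lod <- function(y, g) {
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(stats::resid(stats::lm(y ~ g))^2)
  (n / 2) * log10(rss0 / rss1)
}

# Exhaustive double-loop Youden sweep, written independently of the package
oracle_youden <- function(scores, labels) {
  best_j <- -Inf; best_t <- NA
  for (t in sort(unique(scores))) {
    tp <- 0; fn <- 0; tn <- 0; fp <- 0
    for (i in seq_along(scores)) {
      pred <- scores[i] >= t
      if (labels[i] == 1) { if (pred) tp <- tp + 1 else fn <- fn + 1 }
      else { if (pred) fp <- fp + 1 else tn <- tn + 1 }
    }
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  list(cutoff = best_t, J = best_j)
}

# O(n^2) fixed-point interval clustering: merge any two cluster spans that
# overlap until nothing changes; returns the number of clusters
oracle_overlap_clusters <- function(chr, lo, hi) {
  cl <- seq_along(chr)
  repeat {
    changed <- FALSE
    for (i in seq_along(chr)) for (j in seq_along(chr)) {
      if (i != j && chr[i] == chr[j] && cl[i] != cl[j] &&
          lo[i] <= hi[j] && lo[j] <= hi[i]) {
        cl[cl == cl[j]] <- cl[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(cl))
}

# small fully typed cross on one chromosome for scan tests
make_typed_cross <- function(n = 80, n_mark = 6, len = 50, seed = 42) {
  map <- ipqtl::genetic_map(rep("1", n_mark), paste0("m", seq_len(n_mark)),
                            seq(0, len, length.out = n_mark))
  ipqtl::simulate_backcross_genotypes(map, n, seed = seed, missing_rate = 0)
}

# small multi-chromosome map for model tests
make_small_map <- function() {
  ipqtl::default_genetic_map(n_chr = 3L, chr_len_cM = 60, n_markers = 36L)
}
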