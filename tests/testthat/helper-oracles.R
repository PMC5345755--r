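# Independent oracles used to cross-check the implementation.  Each is
# a deliberately naive, separately written computation of the same
# quantity; none shares code with the package internals.

# Exact 1-D k-means by naive O(k n^2) dynamic programming on the sorted
# values; returns the minimal within-cluster sum of squares.
oracle_kmeans1d_wcss <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  seg <- function(l, r) {
    W <- r - l + 1
    S <- cs[r + 1] - cs[l]
    max(cs2[r + 1] - cs2[l] - S^2 / W, 0)
  }
  D <- matrix(Inf, k, n)
  for (i in seq_len(n)) D[1, i] <- seg(1, i)
  if (k >= 2) {
    for (j in 2:k) {
      for (i in j:n) {
        best <- Inf
        for (l in j:i) {
          v <- D[j - 1, l - 1] + seg(l, i)
          if (v < best) best <- v
        }
        D[j, i] <- best
      }
    }
  }
  D[k, n]
}

# WCSS realized by an intensity_clustering object.
realized_wcss <- function(x, cl) {
  sum(vapply(seq_len(cl$k), function(j) {
    v <- x[cl$labels == j]
    if (length(v)) sum((v - mean(v))^2) else 0
  }, numeric(1)))
}

# Brute-force sliding-window median with replicate padding.
oracle_median_filter <- function(x, radius) {
  h <- nrow(x)
  w <- ncol(x)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      rr <- pmin(pmax((r - radius):(r + radius), 1), h)
      cc <- pmin(pmax((c - radius):(c + radius), 1), w)
      win <- as.vector(x[rr, cc])
      out[r, c] <- sort(win)[(length(win) + 1) %/% 2]
    }
  }
  out
}

# Flood-fill (8-connected) component count by explicit BFS in R.
oracle_component_count <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  n <- 0L
  for (r0 in seq_len(h)) {
    for (c0 in seq_len(w)) {
      if (!mask[r0, c0] || seen[r0, c0]) next
      n <- n + 1L
      stack <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dr in -1:1) {
          for (dc in -1:1) {
            r <- p[1] + dr
            c <- p[2] + dc
            if (r >= 1 && r <= h && c >= 1 && c <= w &&
                mask[r, c] && !seen[r, c]) {
              seen[r, c] <- TRUE
              stack[[length(stack) + 1L]] <- c(r, c)
            }
          }
        }
      }
    }
  }
  n
}

# Weighted kappa by explicit definitional double summation.
oracle_weighted_kappa <- function(a, b, cats) {
  n <- length(a)
  k <- length(cats)
  num <- 0
  den <- 0
  pa <- vapply(cats, function(ci) mean(a == ci), numeric(1))
  pb <- vapply(cats, function(cj) mean(b == cj), numeric(1))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      wij <- (cats[i] - cats[j])^2
      oij <- mean(a == cats[i] & b == cats[j])
      num <- num + wij * oij
      den <- den + wij * pa[i] * pb[j]
    }
  }
  1 - num / den
}

# Tukey-Kramer adjusted p for one pair, from the studentized range.
oracle_tukey_p <- function(values, groups, ga, gb) {
  groups <- factor(groups)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  g <- nlevels(groups)
  df <- length(values) - g
  mse <- sum((values - means[groups])^2) / df
  se <- sqrt(mse / 2 * (1 / ns[[ga]] + 1 / ns[[gb]]))
  q <- abs(means[[ga]] - means[[gb]]) / se
  stats::ptukey(q, g, df, lower.tail = FALSE)
}

# Pooled-variance two-sample t-test, textbook closed form.
oracle_pooled_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), na + nb - 2))
}

# Map each detected nucleus to the planted nucleus holding the
# majority of its pixels (0 = unmatched).
match_to_truth <- function(nuclei, label_map) {
  h <- nrow(label_map)
  vapply(nuclei, function(r) {
    ids <- label_map[r$pixels[, 1] + 1 + r$pixels[, 2] * h]
    ids <- ids[ids > 0]
    if (!length(ids)) return(0L)
    as.integer(names(which.max(table(ids))))
  }, integer(1))
}

# Small deterministic helper scene for unit tests (few nuclei, small
# canvas, fast to render and quantify).
small_scene <- function(seed, ...) {
  generate_scene(scene_spec(height = 128L, width = 128L, n_nuclei = 6L,
                            n_artifacts = 2L, seed = seed, ...))
}
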