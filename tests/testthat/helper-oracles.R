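# Brute-force reference implementations, kept deliberately independent of
# the package internals: plain double loops and queue-based flood fills.

# Naive toxin deposition: full double loop over all sites, no truncation.
oracle_deposit_toxin <- function(toxin, origin, n_tox, lambda_um, pixel_um) {
  n <- nrow(toxin)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d_um <- sqrt((i - origin[1])^2 + (j - origin[2])^2) * pixel_um
      toxin[i, j] <- toxin[i, j] + n_tox * exp(-d_um / lambda_um)
    }
  }
  toxin
}

# Queue-based flood fill connected components of a logical mask.
oracle_flood_components <- function(mask, connectivity = 8) {
  n <- nrow(mask)
  labels <- matrix(0L, n, n)
  shifts <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  lab <- 0L
  for (si in seq_len(n)) for (sj in seq_len(n)) {
    if (!mask[si, sj] || labels[si, sj] != 0L) next
    lab <- lab + 1L
    queue <- matrix(c(si, sj), ncol = 2)
    labels[si, sj] <- lab
    while (nrow(queue) > 0) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (s in seq_len(nrow(shifts))) {
        ii <- cur[1] + shifts[s, 1]
        jj <- cur[2] + shifts[s, 2]
        if (ii >= 1 && ii <= n && jj >= 1 && jj <= n &&
            mask[ii, jj] && labels[ii, jj] == 0L) {
          labels[ii, jj] <- lab
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  list(labels = labels, n = lab)
}

# Edge-cluster count via the flood-fill oracle only.
oracle_edge_clusters <- function(state) {
  g <- state$grid
  n <- nrow(g)
  c_mask <- g == 1L | g == 2L
  if (!any(c_mask)) return(0L)
  agar <- g == 0L
  bg <- oracle_flood_components(agar, connectivity = 4)
  border_labels <- unique(c(bg$labels[1, ], bg$labels[n, ],
                            bg$labels[, 1], bg$labels[, n]))
  border_labels <- setdiff(border_labels, 0L)
  external <- matrix(bg$labels %in% border_labels, n, n)
  cl <- oracle_flood_components(c_mask, connectivity = 8)
  hits <- logical(cl$n)
  viable <- logical(cl$n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    lb <- cl$labels[i, j]
    if (lb == 0L) next
    if (g[i, j] == 1L) viable[lb] <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= n && external[ii, jj])
        hits[lb] <- TRUE
    }
  }
  sum(hits & viable)
}

# Spatial initial metrics via explicit loops.
oracle_spatial_metrics <- function(state) {
  g <- state$grid
  px <- state$pixel_um
  occ <- which(g != 0L, arr.ind = TRUE)
  cc <- which(g == 1L, arr.ind = TRUE)
  center <- c(mean(occ[, 1]), mean(occ[, 2]))
  rel <- cbind(cc[, 1] - center[1], cc[, 2] - center[2]) * px
  mv <- c(mean(rel[, 1]), mean(rel[, 2]))
  r_c0 <- sqrt(sum(mv^2))
  d_c0 <- mean(sqrt((rel[, 1] - mv[1])^2 + (rel[, 2] - mv[2])^2))
  list(n_c0 = nrow(cc), r_c0 = r_c0, d_c0 = d_c0)
}

# Block-counting coarse-grain oracle: explicit 5x5 loops.
oracle_coarse_grid <- function(grid) {
  n <- nrow(grid)
  nb <- n %/% 5
  small <- matrix(0L, nb, nb)
  prec <- c(X = 1L, X_STOP = 2L, C = 3L, C_ON = 4L) # low to high precedence
  prec_of <- function(s) c(0L, 3L, 4L, 1L, 2L)[s + 1L]
  for (bi in seq_len(nb)) for (bj in seq_len(nb)) {
    block <- grid[(5 * bi - 4):(5 * bi), (5 * bj - 4):(5 * bj)]
    occ <- sum(block != 0L)
    if (occ < 13) { small[bi, bj] <- 0L; next }
    counts <- sapply(1:4, function(s) sum(block == s))
    best <- which(counts == max(counts))
    if (length(best) > 1) best <- best[which.max(prec_of(best))]
    small[bi, bj] <- best
  }
  small
}

# Random lattice generator for oracle-equivalence tests.
random_lattice <- function(n = 40, p_occ = 0.4, p_c = 0.3, p_con = 0.1,
                           blob = TRUE) {
  g <- matrix(0L, n, n)
  if (blob) {
    # a few overlapping discs of X with embedded C blobs
    for (k in 1:sample(2:4, 1)) {
      ci <- sample(5:(n - 5), 1); cj <- sample(5:(n - 5), 1)
      r <- sample(4:10, 1)
      for (i in max(1, ci - r):min(n, ci + r))
        for (j in max(1, cj - r):min(n, cj + r))
          if ((i - ci)^2 + (j - cj)^2 <= r^2) g[i, j] <- 3L
    }
    for (k in 1:sample(2:5, 1)) {
      ci <- sample(2:(n - 1), 1); cj <- sample(2:(n - 1), 1)
      r <- sample(1:4, 1)
      st <- sample(c(1L, 2L), 1, prob = c(0.7, 0.3))
      for (i in max(1, ci - r):min(n, ci + r))
        for (j in max(1, cj - r):min(n, cj + r))
          if ((i - ci)^2 + (j - cj)^2 <= r^2) g[i, j] <- st
    }
    g[sample(n * n, round(0.02 * n * n))] <- 4L
  } else {
    occ <- runif(n * n) < p_occ
    st <- sample(1:4, n * n, replace = TRUE,
                 prob = c(p_c, p_con, 1 - p_c - p_con - 0.1, 0.1))
    g[occ] <- st[occ]
  }
  lattice_state(g, base_pixel_um = 2)
}

# Sequential (type I) ANOVA by successive nested-model RSS differences.
oracle_sequential_ss <- function(formula, data) {
  terms_all <- attr(terms(formula), "term.labels")
  response <- all.vars(formula)[1]
  rss <- function(f) sum(residuals(lm(f, data = data))^2)
  out <- numeric(length(terms_all))
  prev <- rss(reformulate("1", response = response))
  for (k in seq_along(terms_all)) {
    cur <- rss(reformulate(terms_all[seq_len(k)], response = response))
    out[k] <- prev - cur
    prev <- cur
  }
  names(out) <- terms_all
  c(out, Residuals = prev)
}
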