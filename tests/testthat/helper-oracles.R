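# Brute-force oracles, independent of the package implementation.

# per-pixel comparison
bf_threshold <- function(ch, cutoff) {
  out <- matrix(FALSE, nrow(ch), ncol(ch))
  for (i in seq_len(nrow(ch))) for (j in seq_len(ncol(ch)))
    out[i, j] <- ch[i, j] >= cutoff
  out
}

# per-pixel 8-neighbour count
bf_noise_reduce <- function(m, min_n = 1) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!m[i, j]) next
    cnt <- 0L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && m[ii, jj])
        cnt <- cnt + 1L
    }
    out[i, j] <- cnt >= min_n
  }
  out
}

# flood-fill connected components (8-connectivity), recursion-free
bf_label8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (s in which(m)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          q <- (jj - 1L) * nr + ii
          if (m[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# all-pairs minimum distance to boundary pixels; shell = floor(d / t)
bf_shell_labels <- function(m, thickness_um, ps = 1) {
  nr <- nrow(m); nc <- ncol(m)
  bd <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!m[i, j]) next
    edge <- i == 1 || i == nr || j == 1 || j == nc
    if (!edge)
      edge <- !(m[i - 1, j] && m[i + 1, j] && m[i, j - 1] && m[i, j + 1])
    bd[i, j] <- edge
  }
  bidx <- which(bd, arr.ind = TRUE)
  lab <- matrix(NA_integer_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!m[i, j]) next
    d <- sqrt(min((bidx[, 1] - i)^2 + (bidx[, 2] - j)^2)) * ps
    lab[i, j] <- as.integer(floor(d / thickness_um))
  }
  lab
}

# closed-form simple OLS via normal equations
bf_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  n <- length(y)
  se <- sqrt(ss_res / (n - 2) / sum((x - mean(x))^2))
  tval <- beta[2] / se
  list(intercept = beta[1], slope = beta[2],
       r2 = 1 - ss_res / ss_tot,
       p = 2 * stats::pt(-abs(tval), df = n - 2))
}

boundary_oracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  bd <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!m[i, j]) next
    edge <- i == 1 || i == nr || j == 1 || j == nc
    if (!edge)
      edge <- !(m[i - 1, j] && m[i + 1, j] && m[i, j - 1] && m[i, j + 1])
    bd[i, j] <- edge
  }
  bd
}

make_simply_connected <- function(m) {
  n <- nrow(m)
  lab <- bf_label8(m)
  if (max(lab) > 1) {
    big <- which.max(tabulate(lab[lab > 0]))
    m <- lab == big
  }
  bg <- bf_label8(!m)
  border <- unique(c(bg[1, ], bg[nrow(m), ], bg[, 1], bg[, ncol(m)]))
  hole <- setdiff(unique(bg[bg > 0]), border)
  m[bg %in% hole] <- TRUE
  m
}

# random simply connected mask: union of discs around a centre, largest
# component kept, holes filled
make_blob_mask <- function(n, seed) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  k <- sample(3:6, 1)
  cx <- stats::runif(k, n * 0.3, n * 0.7)
  cy <- stats::runif(k, n * 0.3, n * 0.7)
  r <- stats::runif(k, n * 0.15, n * 0.35)
  for (t in seq_len(k)) {
    for (i in seq_len(n)) for (j in seq_len(n))
      if ((i - cx[t])^2 + (j - cy[t])^2 <= r[t]^2) m[i, j] <- TRUE
  }
  make_simply_connected(m)
}

as_logical_matrix <- function(bm) {
  m <- unclass(bm)
  attributes(m) <- list(dim = dim(bm))
  m
}

rand_mask <- function(n, p, seed) {
  set.seed(seed)
  matrix(stats::runif(n * n) < p, n, n)
}

rand_channel <- function(n, seed) {
  set.seed(seed)
  matrix(sample(0:255, n * n, replace = TRUE), n, n)
}

# small low-noise generator config used across tests; any synthetic_config
# argument can be overridden
test_config <- function(..., seed = 1) {
  args <- list(compartment_side_um = 1000, pixel_size_um = 4,
               section_depths_um = seq(40, 800, by = 40),
               artifact_rate = 0, speckle_rate = 0, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}
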