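# Brute-force enumeration oracles for the texture-matrix families, written
# as direct loops over voxels and neighbors, independent of the compiled
# kernels they check.

dirs13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)

neighbors26 <- {
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb[rowSums(abs(nb)) > 0, ]
}

oracle_glcm <- function(lev, ng) {
  d <- dim(lev)
  out <- array(0, c(ng, ng, 13))
  for (dd in 1:13) {
    v <- dirs13[dd, ]
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      a <- lev[i, j, k]
      if (a == 0) next
      p <- c(i, j, k) + v
      if (any(p < 1) || any(p > d)) next
      b <- lev[p[1], p[2], p[3]]
      if (b == 0) next
      out[a, b, dd] <- out[a, b, dd] + 1
      out[b, a, dd] <- out[b, a, dd] + 1
    }
  }
  out
}

oracle_glrlm <- function(lev, ng, maxr) {
  d <- dim(lev)
  out <- array(0, c(ng, maxr, 13))
  for (dd in 1:13) {
    v <- dirs13[dd, ]
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      a <- lev[i, j, k]
      if (a == 0) next
      pr <- c(i, j, k) - v
      if (!(any(pr < 1) || any(pr > d)) && lev[pr[1], pr[2], pr[3]] == a) next
      len <- 0
      p <- c(i, j, k)
      while (!(any(p < 1) || any(p > d)) && lev[p[1], p[2], p[3]] == a) {
        len <- len + 1
        p <- p + v
      }
      out[a, len, dd] <- out[a, len, dd] + 1
    }
  }
  out
}

oracle_gldm <- function(lev, ng, alpha = 0) {
  d <- dim(lev)
  out <- matrix(0, ng, 27)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (a == 0) next
    dep <- 1
    for (r in 1:nrow(neighbors26)) {
      p <- c(i, j, k) + neighbors26[r, ]
      if (any(p < 1) || any(p > d)) next
      b <- lev[p[1], p[2], p[3]]
      if (b > 0 && abs(a - b) <= alpha) dep <- dep + 1
    }
    out[a, dep] <- out[a, dep] + 1
  }
  out
}

oracle_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  out <- matrix(0, ng, 2)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (a == 0) next
    s <- 0; cnt <- 0
    for (r in 1:nrow(neighbors26)) {
      p <- c(i, j, k) + neighbors26[r, ]
      if (any(p < 1) || any(p > d)) next
      b <- lev[p[1], p[2], p[3]]
      if (b > 0) { s <- s + b; cnt <- cnt + 1 }
    }
    if (cnt > 0) {
      out[a, 1] <- out[a, 1] + 1
      out[a, 2] <- out[a, 2] + abs(a - s / cnt)
    }
  }
  out
}

oracle_glszm <- function(lev, ng) {
  d <- dim(lev)
  lab <- array(0L, d)
  nextl <- 0
  zones <- list()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (a == 0 || lab[i, j, k] > 0) next
    nextl <- nextl + 1
    q <- list(c(i, j, k))
    lab[i, j, k] <- nextl
    size <- 0
    while (length(q)) {
      c0 <- q[[1]]; q <- q[-1]; size <- size + 1
      for (r in 1:nrow(neighbors26)) {
        p <- c0 + neighbors26[r, ]
        if (any(p < 1) || any(p > d)) next
        if (lev[p[1], p[2], p[3]] == a && lab[p[1], p[2], p[3]] == 0) {
          lab[p[1], p[2], p[3]] <- nextl
          q <- c(q, list(p))
        }
      }
    }
    zones[[nextl]] <- c(a, size)
  }
  if (!length(zones)) return(matrix(0, ng, 1))
  mz <- max(vapply(zones, `[`, 0, 2))
  out <- matrix(0, ng, mz)
  for (z in zones) out[z[1], z[2]] <- out[z[1], z[2]] + 1
  out
}

# compare a compiled family matrix to its oracle on one level array
expect_matches_oracle <- function(lev, ng) {
  dims <- dim(lev)
  expect_equal(as.numeric(texture_matrix("GLCM", lev, ng)),
               as.numeric(oracle_glcm(lev, ng)))
  m <- texture_matrix("GLRLM", lev, ng)
  expect_equal(as.numeric(m),
               as.numeric(oracle_glrlm(lev, dim(m)[1], dim(m)[2])))
  expect_equal(as.numeric(texture_matrix("GLDM", lev, ng)),
               as.numeric(oracle_gldm(lev, ng)))
  expect_equal(as.numeric(texture_matrix("NGTDM", lev, ng)),
               as.numeric(oracle_ngtdm(lev, ng)))
  a <- texture_matrix("GLSZM", lev, ng)
  b <- oracle_glszm(lev, ng)
  if (ncol(a) != ncol(b)) {  # pad the shorter zone axis
    mz <- max(ncol(a), ncol(b))
    a <- cbind(a, matrix(0, nrow(a), mz - ncol(a)))
    b <- cbind(b, matrix(0, nrow(b), mz - ncol(b)))
  }
  expect_equal(as.numeric(a), as.numeric(b))
}

# digitized ball mask of radius r voxels
make_ball <- function(r, n = 2 * r + 5) {
  g <- expand.grid(1:n, 1:n, 1:n)
  c0 <- (n + 1) / 2
  array(((g[, 1] - c0)^2 + (g[, 2] - c0)^2 + (g[, 3] - c0)^2) <= r^2,
        c(n, n, n))
}

# small fast extraction config for pipeline tests
tiny_config <- function()
  extraction_config(filters = list(filter_spec("original"),
                                   filter_spec("square")))
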