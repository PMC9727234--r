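# Shared fixtures, all generated in code.

rand_volume <- function(shape, seed = 1) {
  set.seed(seed)
  array(rnorm(prod(shape)), shape)
}

# tiny deterministic block atlas: grid split into nx x ny x nz boxes
block_atlas <- function(shape, splits = c(2L, 1L, 1L)) {
  lab <- array(0L, shape)
  cuts <- function(n, k) rep(seq_len(k), each = ceiling(n / k))[seq_len(n)]
  gx <- cuts(shape[1], splits[1]); gy <- cuts(shape[2], splits[2])
  gz <- cuts(shape[3], splits[3])
  for (x in seq_len(shape[1])) for (y in seq_len(shape[2]))
    for (z in seq_len(shape[3]))
      lab[x, y, z] <- gx[x] + splits[1] * (gy[y] - 1) +
        splits[1] * splits[2] * (gz[z] - 1)
  as_atlas(lab)
}

# independent brute-force single-level 1D DWT: explicit symmetric padding,
# direct convolution sums, dyadic downsampling (mirrors the documented
# scheme but shares no code with the package internals)
oracle_dwt1 <- function(x, f) {
  n <- length(x); L <- length(f); p <- L - 1
  ext_at <- function(t) {           # half-point symmetric extension
    while (t < 1 || t > n) {
      if (t < 1) t <- 1 - t
      if (t > n) t <- 2 * n + 1 - t
    }
    x[t]
  }
  full <- sapply(1:(n + p), function(i) {   # valid part of conv(ext, f)
    s <- 0
    for (j in 1:L) s <- s + f[j] * ext_at(i - p + L - j)
    s
  })
  full[seq(2, length(full), by = 2)]
}

# brute-force separable level-1 3D DWT via the 1D oracle
oracle_dwt3_level1 <- function(vol, flt) {
  d <- dim(vol)
  nc <- function(n) floor((n + flt$length - 1) / 2)
  apply_axis <- function(arr, ax, f) {
    dn <- dim(arr); dn[ax] <- nc(dn[ax])
    out <- array(0, dn)
    idx <- expand.grid(lapply(seq_along(dn)[-ax], function(k) seq_len(dim(arr)[k])))
    for (r in seq_len(nrow(idx))) {
      sel <- as.list(rep(TRUE, 3)); sel[-ax] <- as.list(idx[r, ])
      line <- do.call(`[`, c(list(arr), sel))
      osel <- sel
      out <- do.call(`[<-`, c(list(out), osel, list(oracle_dwt1(line, f))))
    }
    out
  }
  res <- list()
  for (o1 in c("L", "H")) for (o2 in c("L", "H")) for (o3 in c("L", "H")) {
    f1 <- if (o1 == "L") flt$dec_lo else flt$dec_hi
    f2 <- if (o2 == "L") flt$dec_lo else flt$dec_hi
    f3 <- if (o3 == "L") flt$dec_lo else flt$dec_hi
    a <- apply_axis(vol, 1, f1)
    a <- apply_axis(a, 2, f2)
    a <- apply_axis(a, 3, f3)
    res[[paste0(o1, o2, o3)]] <- a
  }
  res
}

# independent Benjamini-Hochberg oracle
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
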