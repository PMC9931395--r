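# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: Bloch-rotation isochromat summation for the EPG
# curves, brute-force neighbor enumeration for the morphology, and textbook
# closed forms for the statistics.

# Isochromat-summation CPMG: ideal crusher gradients realized as n_iso
# evenly spaced per-half-interval precession phases; exact (no sampling
# error) as long as n_iso exceeds twice the highest dephasing order.
oracle_iso_cpmg <- function(t2, t1, esp, alpha_deg, n_echoes,
                            n_iso = 4 * (n_echoes + 2)) {
  a <- alpha_deg * pi / 180
  E2 <- exp(-esp / 2 / t2)
  E1 <- exp(-esp / 2 / t1)
  th <- 2 * pi * (seq_len(n_iso) - 1) / n_iso
  m <- rep(complex(real = 0, imaginary = -1), n_iso) # after 90deg about x
  z <- rep(0, n_iso)
  R <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
              byrow = TRUE) # rotation about y
  out <- numeric(n_echoes)
  for (e in seq_len(n_echoes)) {
    m <- m * E2 * exp(1i * th)
    z <- z * E1
    Mn <- R %*% rbind(Re(m), Im(m), z)
    m <- complex(real = Mn[1, ], imaginary = Mn[2, ])
    z <- Mn[3, ]
    m <- m * E2 * exp(1i * th)
    z <- z * E1
    out[e] <- Mod(mean(m))
  }
  out
}

# brute-force 6-neighbor erosion: a voxel survives iff all six face
# neighbors exist (inside the volume) and are in the mask
oracle_erode <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    ok <- i > 1 && i < d[1] && j > 1 && j < d[2] && k > 1 && k < d[3]
    if (ok)
      ok <- mask[i - 1, j, k] && mask[i + 1, j, k] && mask[i, j - 1, k] &&
        mask[i, j + 1, k] && mask[i, j, k - 1] && mask[i, j, k + 1]
    out[i, j, k] <- ok
  }
  out
}

oracle_dilate <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k]) { out[i, j, k] <- TRUE; next }
    nb <- FALSE
    if (i > 1) nb <- nb || mask[i - 1, j, k]
    if (i < d[1]) nb <- nb || mask[i + 1, j, k]
    if (j > 1) nb <- nb || mask[i, j - 1, k]
    if (j < d[2]) nb <- nb || mask[i, j + 1, k]
    if (k > 1) nb <- nb || mask[i, j, k - 1]
    if (k < d[3]) nb <- nb || mask[i, j, k + 1]
    out[i, j, k] <- nb
  }
  out
}

# textbook pooled-variance two-sample t statistic and p value
oracle_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- cov(x, y) / sqrt(var(x) * var(y))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# projected-gradient NNLS (slow, independent of the Lawson-Hanson code)
oracle_nnls <- function(A, b, iters = 20000) {
  L <- max(eigen(crossprod(A), only.values = TRUE)$values)
  x <- rep(0, ncol(A))
  for (i in seq_len(iters)) {
    g <- crossprod(A, A %*% x - b)
    x <- pmax(x - as.vector(g) / L, 0)
  }
  x
}
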