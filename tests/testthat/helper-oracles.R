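# Independent oracles and shared fixtures for the suite.

# Dense assembly of A = D + alpha*L from a coefficient field, built directly
# from the stencil definition (never from apply_operator): row i couples
# pixel (y, x) to its four neighbors with -alpha*c_k, folding reflected
# out-of-bounds neighbors back into the diagonal.
dense_rad_matrix <- function(cf, alpha) {
  H <- nrow(cf$s); W <- ncol(cf$s); N <- H * W
  A <- matrix(0, N, N)
  id <- function(y, x) (x - 1L) * H + y     # column-major index
  clamp <- function(v, n) pmin(pmax(v, 1L), n)
  for (x in seq_len(W)) for (y in seq_len(H)) {
    i <- id(y, x)
    A[i, i] <- A[i, i] + 1 + alpha * cf$s[y, x]
    nbrs <- list(list(cf$c1[y, x], y, clamp(x - 1L, W)),
                 list(cf$c2[y, x], y, clamp(x + 1L, W)),
                 list(cf$c3[y, x], clamp(y - 1L, H), x),
                 list(cf$c4[y, x], clamp(y + 1L, H), x))
    for (b in nbrs) {
      j <- id(b[[2]], b[[3]])
      A[i, j] <- A[i, j] - alpha * b[[1]]
    }
  }
  A
}

# Textbook preconditioned conjugate gradient, recording every iterate; the
# independent reference that PBCG must reproduce on SPD systems.
pcg_reference <- function(A, b, Minv, tol = 1e-10, maxiter = 500L) {
  x <- b
  r <- b - A %*% x
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  iterates <- list(x)
  bnorm <- sqrt(sum(b^2))
  for (k in seq_len(maxiter)) {
    Ap <- A %*% p
    ak <- rz / sum(p * Ap)
    x <- x + ak * p
    r <- r - ak * Ap
    iterates[[k + 1L]] <- x
    if (sqrt(sum(r^2)) / bnorm <= tol) break
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iterates = iterates)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# Chebyshev-ball dilation of a logical mask (clamped borders).
dilate_mask <- function(m, r) {
  out <- m
  H <- nrow(m); W <- ncol(m)
  for (dy in -r:r) for (dx in -r:r)
    out <- out | m[pmin(pmax(seq_len(H) + dy, 1L), H),
                   pmin(pmax(seq_len(W) + dx, 1L), W)]
  out
}

# Step-edge + low-amplitude impulses: the fixture for the selectivity tests.
# Impulse amplitude is a fifth of the edge contrast (noise well below edge
# strength, the regime of a low-contrast radiograph); impulses are kept away
# from the edge so the two measurements do not interact.
selectivity_fixture <- function() {
  base <- make_step_edge(64, 64, 1000, 1100, 32)
  clean <- pixels(base)
  m <- clean
  set.seed(7)
  idx <- sample(which(col(m) < 28 | col(m) > 38), 40)
  m[idx] <- m[idx] + 20
  list(img = image2d(m), clean = clean, idx = idx,
       edge_cols = c(32L, 33L), impulse_amp = 20)
}

# mean |across-edge difference| and mean |impulse residual| attenuation factors
selectivity_factors <- function(smoothed, fx) {
  p <- pixels(smoothed)
  p0 <- pixels(fx$img)
  edge0 <- mean(abs(p0[, fx$edge_cols[2]] - p0[, fx$edge_cols[1]]))
  edge1 <- mean(abs(p[, fx$edge_cols[2]] - p[, fx$edge_cols[1]]))
  imp0 <- mean(abs(p0[fx$idx] - fx$clean[fx$idx]))
  imp1 <- mean(abs(p[fx$idx] - fx$clean[fx$idx]))
  c(edge = edge0 / edge1, impulse = imp0 / imp1)
}

# Standard phantom and derived products, computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())
std_phantom <- function() {
  if (is.null(.fixture_cache$ph)) .fixture_cache$ph <- make_phantom(phantom_spec())
  .fixture_cache$ph
}
std_rad_usm <- function() {
  if (is.null(.fixture_cache$fit)) .fixture_cache$fit <- rad_usm(std_phantom()$img)
  .fixture_cache$fit
}
# fraction of mask energy within Chebyshev distance 2 of the tube pixels
edge_energy_fraction <- function(mask, ph = std_phantom()) {
  near <- dilate_mask(ph$edge_map, 2L)
  sum(mask[near]^2) / sum(mask^2)
}
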