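# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched.  seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Half-normal: a Normal(mu, sd) truncated below at zero.  `mu` may be any
# real; the normalizing constant 1 - pnorm(-mu/sd) depends on it, so these
# are not the folded-normal formulas.
dhalfnorm <- function(x, mu, sd, log = FALSE) {
  if (any(sd < 0)) stop("sd must be non-negative")
  lo <- ifelse(x < 0, -Inf,
               dnorm(x, mu, sd, log = TRUE) -
                 pnorm(0, mu, sd, lower.tail = FALSE, log.p = TRUE))
  if (log) lo else exp(lo)
}

rhalfnorm <- function(n, mu, sd) {
  # inverse-CDF sampling so sd = 0 degenerates cleanly to max(mu, 0)
  mu <- rep_len(mu, n); sd <- rep_len(sd, n)
  u <- runif(n)
  out <- ifelse(sd == 0, pmax(mu, 0),
                qnorm(pnorm(0, mu, sd) + u * pnorm(0, mu, sd, lower.tail = FALSE),
                      mean = mu, sd = sd))
  pmax(out, 0)
}

# One Dirichlet draw per row of `alpha` (n x G matrix) via gamma ratios.
rdirichlet <- function(n, alpha) {
  alpha <- rbind(alpha)
  if (nrow(alpha) == 1L && n > 1L) alpha <- alpha[rep(1L, n), , drop = FALSE]
  g <- matrix(rgamma(length(alpha), shape = as.vector(t(alpha))),
              nrow = nrow(alpha), byrow = TRUE)
  g / rowSums(g)
}

# Mean of `mat` over a square window of half-width `hw` cells centred on
# each cell; edge cells average over the available cells only.  Implemented
# with summed-area tables, O(1) per cell.
box_mean <- function(mat, hw) {
  nr <- nrow(mat); nc <- ncol(mat)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- apply(apply(mat, 2L, cumsum), 1L, cumsum) |> t()
  r <- seq_len(nr); c <- seq_len(nc)
  r1 <- pmax(r - hw, 1L); r2 <- pmin(r + hw, nr)
  c1 <- pmax(c - hw, 1L); c2 <- pmin(c + hw, nc)
  # window sum via inclusion-exclusion on the padded cumulative table
  sums <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts
}

# Smooth standardized Gaussian field on an nr x nc grid: white noise passed
# twice through a box-mean filter of half-width `range_cells`, then rescaled
# to zero mean / unit sd.  Cheap stand-in for a geostatistical field.
smooth_field <- function(nr, nc, range_cells = 5L) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (range_cells >= 1L) z <- box_mean(box_mean(z, range_cells), range_cells)
  (z - mean(z)) / sd(z)
}

# stopifnot() with a readable message
check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
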