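# Shared fixtures: ground-truth models and synthetic records.
# All data are generated in code at test time.

seg3_wk <- function() windkessel(R1 = 0.26e8, R2 = 8.43e8, C = 10.5e-10,
                                 Pd = 1580)

celiac_wk <- function() windkessel(R1 = 1.99e8, R2 = 6.91e8, C = 4.36e-10,
                                   Pd = 1410)

# short record for unit tests; acceptance tests build their own 20-cycle ones
short_spec <- function(n_cycles = 8, dt = 1e-3, co = 0.75)
  inflow_spec(n_cycles = n_cycles, co_lmin = co, dt = dt)

seg3_data <- function(n_cycles = 8, dt = 1e-3, noise = NULL)
  synth_waveforms(short_spec(n_cycles, dt), seg3_wk(), noise = noise)

# random stable conjugate-closed pole-residue model
random_pr_model <- function(order, seed, Pd = 1000) {
  withr::local_seed(seed)
  npair <- order %/% 2
  nreal <- order %% 2
  poles <- complex(0); res <- complex(0)
  if (npair) {
    a <- complex(real = -stats::runif(npair, 1, 10),
                 imaginary = 2 * pi * stats::runif(npair, 1, 15))
    k <- stats::runif(npair, 0.1, 1) * 1e8
    cc <- -k * a
    poles <- c(poles, c(rbind(a, Conj(a))))
    res <- c(res, c(rbind(cc, Conj(cc))))
  }
  if (nreal) {
    poles <- c(poles, complex(real = -stats::runif(1, 0.5, 3)))
    res <- c(res, complex(real = stats::runif(1, 1, 10) * 1e8))
  }
  pole_residue(c0 = 0.3e8, poles = poles, residues = res, Pd = Pd)
}

# ascending-coefficient polynomial multiply (test oracle helper)
poly_mult <- function(p1, p2) {
  out <- complex(length(p1) + length(p2) - 1L)
  for (i in seq_along(p1))
    for (j in seq_along(p2))
      out[i + j - 1L] <- out[i + j - 1L] + p1[i] * p2[j]
  out
}

# zeros of D(s) = d0 + sum d_i/(s - a_i) by clearing denominators and
# brute-force polynomial rooting — independent oracle for relocate_poles
denominator_zeros_bruteforce <- function(d0, d, a) {
  lin <- function(ai) c(-ai, 1)
  full <- d0 * Reduce(poly_mult, lapply(a, lin))
  n <- length(a)
  for (i in seq_len(n)) {
    pr <- if (n == 1) complex(real = 1)
          else Reduce(poly_mult, lapply(a[-i], lin))
    full[seq_along(pr)] <- full[seq_along(pr)] + d[i] * pr
  }
  polyroot(full)
}

sort_poles <- function(z) z[order(Re(z), Im(z))]

# greedy nearest-neighbour matching distance between two root sets
# (robust to sort-order flips of conjugate pairs with near-equal Re)
match_dist <- function(x, y) {
  d <- 0
  left <- y
  for (g in x) {
    i <- which.min(Mod(left - g))
    d <- max(d, Mod(left[i] - g))
    left <- left[-i]
  }
  d
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-300)), tol)
}
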