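# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# direct Poisson-Gamma mixture summation of the Tweedie density
brute_tweedie_logpdf <- function(y, mu, phi, p, nmax = 2000) {
  lambda <- mu^(2 - p) / (phi * (2 - p))
  alpha <- (2 - p) / (p - 1)
  gam <- phi * (p - 1) * mu^(p - 1)
  if (y == 0) return(-lambda)
  terms <- vapply(seq_len(nmax), function(n) {
    dpois(n, lambda) * dgamma(y, shape = n * alpha, scale = gam)
  }, numeric(1))
  log(sum(terms))
}

# O(N^2) double-loop pair enumeration
brute_pairs <- function(coords, dmax, include_self = TRUE) {
  n <- nrow(coords)
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (!include_self && i == j) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d <= dmax) out[[length(out) + 1L]] <- c(i, j, d)
    }
  }
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# triple-loop interaction design
brute_design_X <- function(M, sender, receiver, distance, rho) {
  g <- ncol(M)
  X <- matrix(0, length(sender), 1 + g * g)
  X[, 1] <- 1
  for (p in seq_along(sender)) {
    w <- exp(-rho * distance[p])
    for (g1 in seq_len(g)) {
      for (g2 in seq_len(g)) {
        X[p, 1 + (g1 - 1) * g + g2] <- w * M[sender[p], g1] * M[receiver[p], g2]
      }
    }
  }
  X
}

# small random design with a planted coefficient, built on simulated scores
make_score_design <- function(seed, n_units = 40, g = 2, ngrid_axis = 2,
                              beta12 = 1, rho = 0.5, dmax = 3, n_rows = NULL) {
  b <- matrix(0, g, g)
  if (g >= 2) b[1, 2] <- beta12 else b[1, 1] <- beta12
  sim <- simulate_ccc(n_units = n_units, n_types = g, beta = b, rho = rho,
                      dmax = dmax, n_x = ngrid_axis, n_y = ngrid_axis,
                      seed = seed)
  sc <- sim$truth$scores
  if (!is.null(n_rows) && n_rows < nrow(sc)) {
    set.seed(seed + 99)
    sc <- sc[sort(sample(nrow(sc), n_rows)), ]
  }
  build_design(sim$dataset, pairs = sc[, c("sender", "receiver", "distance")],
               rho = rho, partition = sim$truth$partition,
               response = sc$score)
}

# penalized objective + gradient used by the generic-optimizer oracle
oracle_optimize <- function(design, p, lambda_L, lambda_R) {
  X <- design$X
  ng <- design$ngrid
  P <- nrow(X)
  ZL <- matrix(0, P, ng); ZR <- matrix(0, P, ng)
  ZL[cbind(seq_len(P), design$pairs$sender_grid)] <- 1
  ZR[cbind(seq_len(P), design$pairs$receiver_grid)] <- 1
  C <- cbind(X, ZL, ZR)
  y <- design$pairs$response
  nf <- ncol(X)
  fobj <- function(th) {
    mu <- exp(pmin(drop(C %*% th), 30))
    sum(tweedie_unit_deviance(y, mu, p)) / 2 +
      lambda_L * sum(th[nf + 1:ng]^2) + lambda_R * sum(th[nf + ng + 1:ng]^2)
  }
  grad <- function(th) {
    mu <- exp(pmin(drop(C %*% th), 30))
    drop(crossprod(C, (mu - y) * mu^(1 - p))) +
      c(rep(0, nf), 2 * lambda_L * th[nf + 1:ng], 2 * lambda_R * th[nf + ng + 1:ng])
  }
  optim(rep(0, ncol(C)), fobj, grad, method = "BFGS",
        control = list(maxit = 2000, reltol = 1e-14))$par
}
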