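# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (loops, explicit risk tables, pairwise counts) and do
# not touch the package's implementation paths.

unit_cube_mesh <- function(side = 1, clean = FALSE) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * side
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6)
  )
  triangle_mesh(v, f, clean = clean)
}

digitized_sphere_mask <- function(radius, spacing = c(1, 1, 1), margin = 3) {
  n <- 2 * radius + 2 * margin + 1
  cc <- (n + 1) / 2
  d2 <- outer(outer((1:n - cc)^2, (1:n - cc)^2, "+"), (1:n - cc)^2, "+")
  g <- array(0, c(n, n, n))
  g[d2 <= radius^2] <- 1
  voxel_mask(g, spacing = spacing)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  )
}

# Pairwise Mann-Whitney AUC: fraction of (event, non-event) pairs where the
# event case has the larger marker, ties counted one half.
auc_pairwise_oracle <- function(marker, event) {
  pos <- marker[event == 1]
  neg <- marker[event == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive Youden search over every midpoint threshold and both marker
# orientations; returns the maximal J.
youden_exhaustive_oracle <- function(marker, event) {
  sv <- sort(unique(marker))
  thr <- c(-Inf, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2, Inf)
  best <- -Inf
  for (t in thr) {
    sens_hi <- mean(marker[event == 1] > t)
    spec_hi <- mean(marker[event == 0] <= t)
    j_hi <- sens_hi + spec_hi - 1
    best <- max(best, j_hi, -j_hi)
  }
  best
}

# Hand product-limit estimator at each distinct event time.
km_oracle <- function(time, event, at) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(0)
  for (t in ts) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv <- c(surv, s)
  }
  vapply(at, function(tt) {
    below <- ts <= tt
    if (!any(below)) 1 else surv[max(which(below))]
  }, numeric(1))
}

# Multi-group log-rank statistic from explicit risk tables with
# hypergeometric variance, generalized inverse on the first k-1 groups.
logrank_oracle <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  lev <- levels(group)
  ts <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ts) {
    at <- time >= t
    N <- sum(at)
    d <- sum(event == 1 & time == t)
    ni <- vapply(lev, function(g) sum(at & group == g), numeric(1))
    di <- vapply(lev, function(g) sum(at & group == g & event == 1 & time == t),
                 numeric(1))
    O <- O + di
    E <- E + d * ni / N
    if (N > 1) {
      for (i in seq_len(k)) {
        for (j in seq_len(k)) {
          V[i, j] <- V[i, j] +
            d * (N - d) / (N - 1) * ((i == j) * ni[i] * N - ni[i] * ni[j]) / N^2
        }
      }
    }
  }
  x <- (O - E)[-k]
  Vm <- V[-k, -k, drop = FALSE]
  stat <- drop(t(x) %*% solve(Vm) %*% x)
  list(statistic = stat, observed = O, expected = E)
}

# Hand-written Breslow log partial likelihood for a single covariate.
cox_partial_loglik_oracle <- function(beta, time, event, x) {
  lp <- beta * x
  s <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    s <- s + lp[i] - log(sum(exp(lp[risk])))
  }
  s
}

# Fine-grid maximization of the hand-written partial likelihood.
cox_grid_oracle <- function(time, event, x, lo = -3, hi = 3, by = 1e-4) {
  grid <- seq(lo, hi, by = by)
  ll <- vapply(grid, cox_partial_loglik_oracle, numeric(1),
               time = time, event = event, x = x)
  grid[which.max(ll)]
}
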