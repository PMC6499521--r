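# Independent convex-optimization oracle for the elastic-net objective:
# accelerated proximal gradient (FISTA) with backtracking line search and
# adaptive restart. Deliberately shares no code with the package's
# coordinate-descent solver.

oracle_objective <- function(beta0, beta, X, y, lambda, alpha, family) {
  eta <- drop(beta0 + X %*% beta)
  loss <- if (family == "logistic") {
    mean(-y * eta + ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30)))))
  } else {
    mean((y - eta)^2) / 2
  }
  loss + lambda * ((1 - alpha) * sum(beta^2) / 2 + alpha * sum(abs(beta)))
}

# gradient of the smooth part (loss + ridge term) w.r.t. c(beta0, beta)
.oracle_grad <- function(beta0, beta, X, y, lambda, alpha, family) {
  eta <- drop(beta0 + X %*% beta)
  r <- if (family == "logistic") plogis(eta) - y else eta - y
  n <- length(y)
  c(mean(r), drop(crossprod(X, r)) / n + lambda * (1 - alpha) * beta)
}

fista_elnet <- function(X, y, lambda, alpha, family = "logistic",
                        max_iter = 400000, kkt_tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  smooth_val <- function(b0, b) {
    eta <- drop(b0 + X %*% b)
    l <- if (family == "logistic")
      mean(-y * eta + ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30)))))
    else mean((y - eta)^2) / 2
    l + lambda * (1 - alpha) * sum(b^2) / 2
  }
  prox <- function(v, step) {
    # soft-threshold all but the intercept
    c(v[1], sign(v[-1]) * pmax(abs(v[-1]) - step * lambda * alpha, 0))
  }
  x <- numeric(p + 1)   # c(beta0, beta)
  z <- x; tk <- 1
  L <- 1  # backtracked Lipschitz estimate
  f_old <- Inf
  for (it in seq_len(max_iter)) {
    g <- .oracle_grad(z[1], z[-1], X, y, lambda, alpha, family)
    fz <- smooth_val(z[1], z[-1])
    repeat {
      xn <- prox(z - g / L, 1 / L)
      d <- xn - z
      if (smooth_val(xn[1], xn[-1]) <=
          fz + sum(g * d) + L / 2 * sum(d^2) + 1e-15) break
      L <- L * 2
    }
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zn <- xn + ((tk - 1) / tn) * (xn - x)
    f_new <- oracle_objective(xn[1], xn[-1], X, y, lambda, alpha, family)
    if (f_new > f_old) { zn <- xn; tn <- 1 }  # adaptive restart
    if (it %% 100 == 0 &&
        kkt_residuals(xn[1], xn[-1], X, y, lambda, alpha, family) < kkt_tol) {
      x <- xn
      break
    }
    x <- xn; z <- zn; tk <- tn
    f_old <- f_new
    L <- max(L / 1.5, 1e-6)
  }
  list(beta0 = x[1], beta = x[-1],
       objective = oracle_objective(x[1], x[-1], X, y, lambda, alpha, family))
}

# KKT residuals of an elastic-net solution on standardized X:
# zero coefficients need |x_j' r| / n <= lambda * alpha (+eps),
# nonzero ones need x_j' r / n = lambda * alpha * sign(b_j) + lambda(1-a) b_j
kkt_residuals <- function(beta0, beta, X, y, lambda, alpha, family) {
  eta <- drop(beta0 + X %*% beta)
  r <- if (family == "logistic") y - plogis(eta) else y - eta
  g <- drop(crossprod(X, r)) / length(y)
  zero <- beta == 0
  res_zero <- if (any(zero)) pmax(abs(g[zero]) - lambda * alpha, 0) else 0
  res_nz <- if (any(!zero)) {
    abs(g[!zero] - lambda * alpha * sign(beta[!zero]) -
          lambda * (1 - alpha) * beta[!zero])
  } else 0
  max(res_zero, res_nz, abs(mean(r)))
}

# brute-force greedy clumping: a literal, index-at-a-time replay of the
# definition, O(p^2), independent of the compiled implementation
clump_bruteforce <- function(R2, chrom, pos, pval, r2_threshold, window_bp) {
  p <- length(pval)
  assigned <- rep(NA_integer_, p)
  kept <- integer(0)
  repeat {
    un <- which(is.na(assigned))
    if (!length(un)) break
    o <- un[order(pval[un], pos[un], un)]
    i <- o[1]
    assigned[i] <- i
    kept <- c(kept, i)
    for (j in which(is.na(assigned))) {
      if (chrom[j] == chrom[i] && abs(pos[j] - pos[i]) <= window_bp &&
          R2[i, j] > r2_threshold)
        assigned[j] <- i
    }
  }
  list(kept = kept, assigned = assigned)
}

# O(n^2) pairwise AUC oracle
auc_bruteforce <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (s in cs) tot <- tot + sum(s > ct) + 0.5 * sum(s == ct)
  tot / (length(cs) * length(ct))
}
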