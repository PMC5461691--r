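# Independent oracles, deliberately brute-force.

# Exhaustive matching oracle: enumerates every assignment of up to `ratio`
# feasible controls per case and returns the lexicographic optimum
# (max cardinality, then min total distance). d is a cases x controls matrix
# with Inf = infeasible.
brute_force_match <- function(d, ratio = 1) {
  nc <- nrow(d); nk <- ncol(d)
  best <- list(n = -1L, dist = Inf)
  subsets_of <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    if (length(v) < k) return(list())
    lapply(utils::combn(length(v), k, simplify = FALSE), function(i) v[i])
  }
  recurse <- function(i, avail, n, dist) {
    if (i > nc) {
      if (n > best$n || (n == best$n && dist < best$dist - 1e-9))
        best <<- list(n = n, dist = dist)
      return(invisible(NULL))
    }
    feas <- which(avail & is.finite(d[i, ]))
    for (k in 0:min(ratio, length(feas))) {
      for (s in subsets_of(feas, k)) {
        av <- avail; av[s] <- FALSE
        recurse(i + 1L, av, n + length(s), dist + sum(d[i, s]))
      }
    }
  }
  if (nc == 0 || nk == 0) return(list(n = 0L, dist = 0))
  recurse(1L, rep(TRUE, nk), 0L, 0)
  best
}

# Exact signed-rank two-sided p by full enumeration of all 2^n sign
# assignments (mid-ranks on |d|, zeros assumed already removed).
enumerate_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# 1:1 conditional-logistic oracle: the conditional likelihood of matched
# pairs equals an intercept-free logistic likelihood on within-pair exposure
# differences with all outcomes 1.
difference_logistic_beta <- function(sets, exposure = "x") {
  wide <- lapply(split(sets, sets$set_id), function(s) {
    s[[exposure]][s$delirium_case == 1] - s[[exposure]][s$delirium_case == 0]
  })
  xd <- unlist(wide)
  fit <- suppressWarnings(
    glm(rep(1, length(xd)) ~ xd - 1, family = binomial()))
  unname(coef(fit))
}
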