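# brute-force numerical oracles, independent of the closed-form code paths

oracle_grid <- function(half_width = 120, step = 0.02) {
  seq(-half_width, half_width, by = step)
}

# dense-grid marginal likelihoods p(Xa, Xv | C)
oracle_likelihood <- function(xa, xv, params, rel, common,
                              grid = oracle_grid()) {
  h <- grid[2] - grid[1]
  sa <- params$sigma_a
  sv <- params$sigma_v[[rel]]
  if (common) {
    f <- dnorm(xa, grid, sa) * dnorm(xv, grid, sv) *
      dnorm(grid, params$mu_a_prior, params$sigma_a_prior) *
      dnorm(grid, params$mu_v_prior, params$sigma_v_prior)
    sum(f) * h / dnorm(params$mu_a_prior, params$mu_v_prior,
                       sqrt(params$sigma_a_prior^2 + params$sigma_v_prior^2))
  } else {
    fa <- sum(dnorm(xa, grid, sa) *
                dnorm(grid, params$mu_a_prior, params$sigma_a_prior)) * h
    fv <- sum(dnorm(xv, grid, sv) *
                dnorm(grid, params$mu_v_prior, params$sigma_v_prior)) * h
    fa * fv
  }
}

# dense-grid posterior p(D = +1 | Xa, Xv): mixture over C of half-line
# posterior masses with truncated-prior normalizers and the choice prior.
# The grid is midpoint-centered around zero so the half-line truncation at
# the midline incurs O(h^2) rather than O(h) error.
oracle_midpoint_grid <- function(half_width = 150, step = 0.02) {
  seq(-half_width + step / 2, half_width - step / 2, by = step)
}

oracle_p_right <- function(xa, xv, params, rel,
                           grid = oracle_midpoint_grid()) {
  sa <- params$sigma_a
  sv <- params$sigma_v[[rel]]
  pch <- params$p_choice_implicit
  prior_a <- dnorm(grid, params$mu_a_prior, params$sigma_a_prior)
  prior_v <- dnorm(grid, params$mu_v_prior, params$sigma_v_prior)
  pos <- grid > 0
  # C = 1: shared source location
  f1 <- dnorm(xa, grid, sa) * dnorm(xv, grid, sv) * prior_a * prior_v
  r1 <- pch * sum(f1[pos]) / sum((prior_a * prior_v)[pos])
  l1 <- (1 - pch) * sum(f1[!pos]) / sum((prior_a * prior_v)[!pos])
  pd1 <- r1 / (r1 + l1)
  # C = 2: auditory source alone carries the task variable
  fa <- dnorm(xa, grid, sa) * prior_a
  r2 <- pch * sum(fa[pos]) / sum(prior_a[pos])
  l2 <- (1 - pch) * sum(fa[!pos]) / sum(prior_a[!pos])
  pd2 <- r2 / (r2 + l2)
  w1 <- posterior_common(xa, xv, params, rel)
  w1 * pd1 + (1 - w1) * pd2
}

# Monte-Carlo response probability (sampling oracle for the quadrature path)
oracle_mc_response <- function(eps_a, eps_v, params, rel, n = 1e5,
                               task = c("implicit", "explicit")) {
  task <- match.arg(task)
  xa <- rnorm(n, eps_a, params$sigma_a)
  xv <- rnorm(n, eps_v, params$sigma_v[[rel]])
  raw <- if (task == "implicit") {
    mean(implicit_decision(xa, xv, params, rel) == 1L)
  } else {
    mean(explicit_decision(xa, xv, params, rel) == 1L)
  }
  list(p = params$lapse_rate * params$lapse_bias +
         (1 - params$lapse_rate) * raw,
       se = (1 - params$lapse_rate) * sqrt(raw * (1 - raw) / n))
}
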