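#' Trial-level response probabilities
#'
#' Marginalizes the deterministic decision rules over the sensory noise of a
#' stimulus `(eps_a, eps_v)`, then applies the lapse mixture: with
#' probability `lapse_rate` the response is a coin flip landing on the
#' positive code with probability `lapse_bias`.
#'
#' The auditory measurement dimension is integrated in closed form - the
#' decision region in `x_a` at a fixed visual measurement is a half-line for
#' the implicit rule (its boundary located by bisection on the posterior
#' margin) and a quadratic-root interval for the explicit rule (the
#' log-likelihood ratio is an exact quadratic in `x_a`) - leaving only the
#' visual dimension to Gauss-Hermite quadrature. For unisensory trials the
#' decision threshold is a single parameter-dependent criterion and the
#' response probability is an exact Gaussian mass.
#'
#' @param eps_a,eps_v True (experimenter-defined) cue locations, degrees.
#'   Vectorized (recycled to a common length).
#' @inheritParams likelihood_common
#' @param quad_order Number of Gauss-Hermite nodes for the visual dimension
#'   (>= 3; default 61).
#' @return Probability of response +1 (right) for the localization tasks, or
#'   of response 1 (common source) for the explicit task.
#' @examples
#' p <- observer_params(p_common = 0.5, p_combined = 0.5)
#' response_prob_explicit(0, 0, p, "high") >
#'   response_prob_explicit(12, -12, p, "high")
#' @export
response_prob_implicit <- function(eps_a, eps_v, params, reliability,
                                   quad_order = 61L) {
  n <- max(length(eps_a), length(eps_v))
  raw <- resp_prob_implicit_batch(rep_len(eps_a, n), rep_len(eps_v, n),
                                  rep_len(params$sigma_v[[reliability]], n),
                                  params, quad_order)
  params$lapse_rate * params$lapse_bias + (1 - params$lapse_rate) * raw
}

#' @rdname response_prob_implicit
#' @export
response_prob_explicit <- function(eps_a, eps_v, params, reliability,
                                   quad_order = 61L) {
  n <- max(length(eps_a), length(eps_v))
  raw <- resp_prob_explicit_batch(rep_len(eps_a, n), rep_len(eps_v, n),
                                  rep_len(params$sigma_v[[reliability]], n),
                                  params, quad_order)
  params$lapse_rate * params$lapse_bias + (1 - params$lapse_rate) * raw
}

#' @rdname response_prob_implicit
#' @param modality `"auditory"` or `"visual"`: which single cue was shown.
#' @param eps True location of the single cue, degrees.
#' @export
response_prob_unisensory <- function(eps, params,
                                     modality = c("auditory", "visual"),
                                     reliability = "high", quad_order = 61L) {
  modality <- match.arg(modality)
  sig <- if (modality == "auditory") params$sigma_a
         else params$sigma_v[[reliability]]
  t <- unisensory_threshold(params, modality, sig^2)
  raw <- if (is.infinite(t)) as.numeric(t < 0) + 0 * eps
         else stats::pnorm((eps - t) / sig)
  params$lapse_rate * params$lapse_bias + (1 - params$lapse_rate) * raw
}

# criterion x* such that the unisensory observer answers "right" iff x >= x*
unisensory_threshold <- function(params, modality, s2) {
  g <- if (modality == "auditory") {
    function(x) logit_d_auditory(x, s2, params)
  } else {
    function(x) logit_d_visual(x, s2, params)
  }
  w <- 100 + 10 * sqrt(s2) +
    abs(params$mu_a_prior) + abs(params$mu_v_prior)
  lo <- -w
  hi <- w
  if (g(lo) >= 0) return(-Inf)
  if (g(hi) < 0) return(Inf)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (g(mid) >= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# ---- implicit task: half-line boundary in x_a per visual node ---------------

# P(decision = +1 | eps_a, eps_v) without lapses, vectorized over cells.
# For each visual quadrature node the decision region in x_a is the
# half-line above a boundary, located by vectorized bisection; the auditory
# mass of that half-line is an exact Gaussian tail. For speed, the posterior
# margin is evaluated from per-node constants: the cause log-likelihood
# ratio is an exact quadratic in x_a and the truncation z-scores are linear.
resp_prob_implicit_batch <- function(eps_a, eps_v, sigma_v, params,
                                     quad_order) {
  gh <- gh_nodes(quad_order)
  m <- length(eps_a)
  q <- length(gh$u)
  s2a <- params$sigma_a^2
  xv <- rep(eps_v, each = q) + sqrt(2) * rep(sigma_v, each = q) * rep(gh$u, m)
  sv <- rep(sigma_v, each = q)
  s2v <- sv^2
  w <- rep(gh$w, m)
  id <- rep(seq_len(m), each = q)

  # per-node constants
  s2ap <- params$sigma_a_prior^2
  s2vp <- params$sigma_v_prior^2
  mu_a <- params$mu_a_prior
  mu_v <- params$mu_v_prior
  v1 <- 1 / (1 / s2a + 1 / s2v)
  a1 <- v1 / s2a
  b1 <- v1 * xv / s2v
  vp <- 1 / (1 / s2ap + 1 / s2vp)
  mp <- vp * (mu_a / s2ap + mu_v / s2vp)
  S <- s2a + s2v
  V <- v1 + vp
  Tt <- s2a + s2ap
  # log L1 - log L2 = A0 x_a^2 + B0 x_a + C0
  A0 <- -1 / (2 * S) - a1^2 / (2 * V) + 1 / (2 * Tt)
  B0 <- xv / S - a1 * (b1 - mp) / V - mu_a / Tt
  C0 <- -xv^2 / (2 * S) - (b1 - mp)^2 / (2 * V) + mu_a^2 / (2 * Tt) -
    0.5 * log(S) - 0.5 * log(V) + 0.5 * log(Tt) - 0.5 * log(2 * pi) -
    stats::dnorm(xv, mu_v, sqrt(s2v + s2vp), log = TRUE)
  lo_common <- stats::qlogis(params$p_common)
  # z-scores of the fused (z1 = al1 x_a + be1) and auditory-only
  # (za = ala x_a + bea) posterior means over their half-line truncations
  v_post <- 1 / (1 / v1 + 1 / vp)
  al1 <- sqrt(v_post) * a1 / v1
  be1 <- sqrt(v_post) * (b1 / v1 + mp / vp)
  zp <- mp / sqrt(vp)
  va <- 1 / (1 / s2a + 1 / s2ap)
  ala <- sqrt(va) / s2a
  bea <- sqrt(va) * mu_a / s2ap
  zap <- mu_a / params$sigma_a_prior
  k_choice <- stats::qlogis(params$p_choice_implicit)
  k1 <- k_choice - stats::pnorm(zp, log.p = TRUE) +
    stats::pnorm(-zp, log.p = TRUE)
  k2 <- k_choice - stats::pnorm(zap, log.p = TRUE) +
    stats::pnorm(-zap, log.p = TRUE)

  margin <- function(xa) {
    w1 <- plogis_safe(lo_common + (A0 * xa + B0) * xa + C0)
    z1 <- al1 * xa + be1
    za <- ala * xa + bea
    pd1 <- plogis_safe(k1 + stats::pnorm(z1, log.p = TRUE) -
                         stats::pnorm(-z1, log.p = TRUE))
    pd2 <- plogis_safe(k2 + stats::pnorm(za, log.p = TRUE) -
                         stats::pnorm(-za, log.p = TRUE))
    w1 * pd1 + (1 - w1) * pd2 - 0.5
  }

  width <- 100 + abs(xv) + 10 * (params$sigma_a + sv) +
    abs(mu_a) + abs(mu_v)
  lo <- -width
  hi <- width
  # constant-decision nodes (e.g. extreme choice bias): no boundary to find
  all_pos <- margin(lo) >= 0
  all_neg <- margin(hi) < 0
  open <- !(all_pos | all_neg)
  inner <- numeric(length(xv))
  inner[all_pos] <- 1
  if (any(open)) {
    # bisect to a boundary tolerance far below the auditory noise scale
    iters <- min(45L, ceiling(log2(2 * max(width) /
                                     (params$sigma_a * 1e-4))))
    blo <- lo[open]
    bhi <- hi[open]
    sub <- function(v) if (length(v) > 1L) v[open] else v
    m_open <- function(xa) {
      w1 <- plogis_safe(lo_common + (sub(A0) * xa + sub(B0)) * xa + sub(C0))
      z1 <- sub(al1) * xa + sub(be1)
      za <- ala * xa + bea
      pd1 <- plogis_safe(k1 + stats::pnorm(z1, log.p = TRUE) -
                           stats::pnorm(-z1, log.p = TRUE))
      pd2 <- plogis_safe(k2 + stats::pnorm(za, log.p = TRUE) -
                           stats::pnorm(-za, log.p = TRUE))
      w1 * pd1 + (1 - w1) * pd2 - 0.5
    }
    for (i in seq_len(iters)) {
      mid <- (blo + bhi) / 2
      pos <- m_open(mid) >= 0
      bhi[pos] <- mid[pos]
      blo[!pos] <- mid[!pos]
    }
    bnd <- (blo + bhi) / 2
    ea <- rep(eps_a, each = q)
    inner[open] <- stats::pnorm((ea[open] - bnd) / params$sigma_a)
  }
  as.vector(rowsum(w * inner, id))
}

# ---- explicit task: quadratic-root interval in x_a per visual node ----------

resp_prob_explicit_batch <- function(eps_a, eps_v, sigma_v, params,
                                     quad_order) {
  qc <- params$p_combined
  m <- length(eps_a)
  if (qc >= 1) return(rep(1, m))
  if (qc <= 0) return(rep(0, m))
  gh <- gh_nodes(quad_order)
  q <- length(gh$u)
  s2a <- params$sigma_a^2
  xv <- rep(eps_v, each = q) + sqrt(2) * rep(sigma_v, each = q) * rep(gh$u, m)
  sv <- rep(sigma_v, each = q)
  s2v <- sv^2
  w <- rep(gh$w, m)
  id <- rep(seq_len(m), each = q)
  ea <- rep(eps_a, each = q)

  s2ap <- params$sigma_a_prior^2
  s2vp <- params$sigma_v_prior^2
  v1 <- 1 / (1 / s2a + 1 / s2v)
  a1 <- v1 / s2a                       # m1 = a1 * x_a + b1
  b1 <- v1 * xv / s2v
  vp <- 1 / (1 / s2ap + 1 / s2vp)
  mp <- vp * (params$mu_a_prior / s2ap + params$mu_v_prior / s2vp)
  S <- s2a + s2v
  V <- v1 + vp
  Tt <- s2a + s2ap
  # h(x_a) = log q + log L1 - log(1 - q) - log L2 = A x_a^2 + B x_a + C
  A <- -1 / (2 * S) - a1^2 / (2 * V) + 1 / (2 * Tt)
  B <- xv / S - a1 * (b1 - mp) / V - params$mu_a_prior / Tt
  C <- log(qc) - log1p(-qc) -
    xv^2 / (2 * S) - (b1 - mp)^2 / (2 * V) + params$mu_a_prior^2 / (2 * Tt) -
    0.5 * log(S) - 0.5 * log(V) + 0.5 * log(Tt) - 0.5 * log(2 * pi) -
    stats::dnorm(xv, params$mu_v_prior, sqrt(s2v + s2vp), log = TRUE)
  p_common_mass <- quad_region_mass(A, B, C, ea, params$sigma_a)
  as.vector(rowsum(w * p_common_mass, id))
}

# Gaussian N(center, sigma^2) mass of {x : A x^2 + B x + C >= 0}, vectorized
quad_region_mass <- function(A, B, C, center, sigma, tol = 1e-12) {
  n <- length(A)
  out <- numeric(n)
  lin <- abs(A) < tol
  if (any(lin)) {
    Bl <- B[lin]
    Cl <- C[lin]
    cl <- center[lin]
    flat <- abs(Bl) < tol
    ml <- ifelse(flat, as.numeric(Cl >= 0),
                 ifelse(Bl > 0, stats::pnorm((cl + Cl / Bl) / sigma),
                        stats::pnorm((-Cl / Bl - cl) / sigma)))
    out[lin] <- ml
  }
  qd <- !lin
  if (any(qd)) {
    Aq <- A[qd]
    Bq <- B[qd]
    Cq <- C[qd]
    cq <- center[qd]
    disc <- Bq^2 - 4 * Aq * Cq
    no_root <- disc <= 0
    sq <- sqrt(pmax(disc, 0))
    r1 <- (-Bq - sq) / (2 * Aq)
    r2 <- (-Bq + sq) / (2 * Aq)
    rlo <- pmin(r1, r2)
    rhi <- pmax(r1, r2)
    inside <- stats::pnorm((rhi - cq) / sigma) - stats::pnorm((rlo - cq) / sigma)
    mq <- ifelse(no_root, as.numeric(Aq > 0),
                 ifelse(Aq < 0, inside, 1 - inside))
    out[qd] <- mq
  }
  out
}
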