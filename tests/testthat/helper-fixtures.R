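# Shared fixtures and independent oracles for the test suite.

median_kin <- function(aI = 16e-5, aG = 0, Gb = NA_real_)
  kinetics_params(VI = 3.4, m1 = 0.15, CL = 1.16, HEb = 0.59,
                  aI = aI, aG = aG, Gb = Gb)

median_abs <- function() absorption_params(ka1 = 0.010, ka2 = 0.028)

# Independent right-hand side written directly from the model equations
# (states Qip1, Qip2, Qp, Ql); used as the fixed-point oracle.
ref_rhs <- function(y, model, abs, kin, inf, G = NA_real_, Qlb,
                    clamp = c(0, 0.95)) {
  m4 <- kin$CL / kin$VI - kin$HEb * kin$m2
  if (model$absorption == 1) {
    rai <- abs$ka1 * y[1]
    d1 <- -abs$ka1 * y[1] + inf
    d2 <- 0
  } else if (model$absorption == 2) {
    rai <- abs$ka2 * y[2]
    d1 <- -abs$kd * y[1] + inf
    d2 <- -abs$ka2 * y[2] + abs$kd * y[1]
  } else {
    rai <- abs$ka1 * y[1] + abs$ka2 * y[2]
    d1 <- -(abs$ka1 + abs$ka2) * y[1] + inf
    d2 <- -abs$ka2 * y[2] + abs$ka2 * y[1]
  }
  he <- switch(model$he,
               A = kin$HEb,
               B = -kin$aG * (G - kin$Gb) + kin$HEb,
               C = -kin$aI * (y[4] - Qlb) + kin$HEb)
  he <- min(max(he, clamp[1]), clamp[2])
  m3 <- he / (1 - he) * kin$m1
  c(d1, d2,
    -(kin$m2 + m4) * y[3] + kin$m1 * y[4],
    -(kin$m1 + m3) * y[4] + kin$m2 * y[3] + rai)
}

# Matrix-exponential solution of the constant-extraction (variant A) model,
# which is linear time-invariant between boluses: y(t) = e^{At}(y0 + A^-1 u)
# - A^-1 u, via eigendecomposition.
lti_solution <- function(times, y0, abs, kin, inf, absorption = 3) {
  m4 <- kin$CL / kin$VI - kin$HEb * kin$m2
  m3b <- kin$HEb / (1 - kin$HEb) * kin$m1
  A <- switch(absorption,
    rbind(c(-abs$ka1, 0, 0, 0),
          c(0, 0, 0, 0),
          c(0, 0, -(kin$m2 + m4), kin$m1),
          c(abs$ka1, 0, kin$m2, -(kin$m1 + m3b))),
    rbind(c(-abs$kd, 0, 0, 0),
          c(abs$kd, -abs$ka2, 0, 0),
          c(0, 0, -(kin$m2 + m4), kin$m1),
          c(0, abs$ka2, kin$m2, -(kin$m1 + m3b))),
    rbind(c(-(abs$ka1 + abs$ka2), 0, 0, 0),
          c(abs$ka2, -abs$ka2, 0, 0),
          c(0, 0, -(kin$m2 + m4), kin$m1),
          c(abs$ka1, abs$ka2, kin$m2, -(kin$m1 + m3b))))
  u <- c(inf, 0, 0, 0)
  ev <- eigen(A)
  Vi <- solve(ev$vectors)
  xp <- solve(A, u)         # particular solution: A x + u = 0 -> x = -A^-1 u
  z0 <- Vi %*% (y0 + xp)
  t(vapply(times, function(t)
    Re(ev$vectors %*% (exp(ev$values * t) * z0)) - xp, numeric(4)))
}

# Brute-force number-of-runs distribution by complete enumeration of all
# arrangements of n1 plus and n2 minus signs.
enumerate_runs <- function(n1, n2) {
  pos <- utils::combn(n1 + n2, n1)
  counts <- integer(n1 + n2)
  for (j in seq_len(ncol(pos))) {
    s <- rep(-1L, n1 + n2)
    s[pos[, j]] <- 1L
    counts[sum(diff(s) != 0) + 1L] <- counts[sum(diff(s) != 0) + 1L] + 1L
  }
  counts / ncol(pos)  # counts[r] = P(R = r), r = 1..n (r = 1 impossible)
}

# Cheap fit configuration used where the test exercises structure rather
# than estimation accuracy.
quick_control <- function(...) {
  args <- utils::modifyList(list(n_starts = 1, maxit = 800), list(...))
  do.call(ipk_control, args)
}
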