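# Minimal-coordinate (generalized-angle) oracle for planar chain pendulums,
# independent of the redundant-coordinate engine.  The chain hangs from a
# world pin; each link k has mass m, inertia I about its CoM, proximal
# attachment c_prox and distal attachment c_dist in the link frame.
#
# com_i = pin + sum_{k<i} R(th_k) Delta_k - R(th_i) c_prox_i
# with Delta_k = c_dist_k - c_prox_k.  Mass matrix and gravity terms are
# analytic; the Coriolis terms use central finite differences of M(theta).

rot2 <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
drot2 <- function(th) matrix(c(-sin(th), cos(th), -cos(th), -sin(th)), 2, 2)

chain_jacobians <- function(th, chain) {
  n <- length(th)
  J <- array(0, c(n, 2, n)) # J[i, , k] = d com_i / d th_k
  for (i in seq_len(n)) {
    for (k in seq_len(i)) {
      if (k < i) {
        J[i, , k] <- drot2(th[k]) %*% chain$delta[[k]]
      } else {
        J[i, , k] <- -drot2(th[i]) %*% chain$c_prox[[i]]
      }
    }
  }
  J
}

chain_mass_matrix <- function(th, chain) {
  n <- length(th)
  J <- chain_jacobians(th, chain)
  M <- diag(chain$inertia, n, n)
  for (i in seq_len(n)) {
    Ji <- t(J[i, , , drop = TRUE])
    if (n == 1) Ji <- matrix(J[1, , 1], 1, 2)
    M <- M + chain$mass[i] * (Ji %*% t(Ji))
  }
  M
}

chain_com <- function(th, chain, pin = c(0, 0)) {
  n <- length(th)
  out <- matrix(0, n, 2)
  joint <- pin
  for (i in seq_len(n)) {
    out[i, ] <- joint - rot2(th[i]) %*% chain$c_prox[[i]]
    joint <- joint + rot2(th[i]) %*% chain$delta[[i]]
  }
  out
}

# generalized accelerations of the hanging chain under gravity alone
chain_pendulum_accel <- function(th, thd, chain, g = 9.81) {
  n <- length(th)
  M <- chain_mass_matrix(th, chain)
  h <- 1e-5
  dM <- array(0, c(n, n, n))
  for (k in seq_len(n)) {
    e <- rep(0, n); e[k] <- h
    dM[, , k] <- (chain_mass_matrix(th + e, chain) -
                    chain_mass_matrix(th - e, chain)) / (2 * h)
  }
  # Coriolis: c_a = sum_bk (dM_ab/dth_k - 0.5 dM_bk/dth_a) thd_b thd_k
  cvec <- numeric(n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      for (k in seq_len(n)) {
        cvec[a] <- cvec[a] + (dM[a, b, k] - 0.5 * dM[b, k, a]) * thd[b] * thd[k]
      }
    }
  }
  J <- chain_jacobians(th, chain)
  gvec <- numeric(n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) gvec[k] <- gvec[k] + chain$mass[i] * g * J[i, 2, k]
  }
  solve(M, -cvec - gvec)
}

# build the matching redundant-coordinate mechanism + state for the engine
chain_mech <- function(chain, pin = c(0, 0)) {
  n <- length(chain$mass)
  joints <- matrix(0, n, 6)
  joints[1, ] <- c(-1, 0, pin, chain$c_prox[[1]])
  if (n > 1) {
    for (i in 2:n) {
      joints[i, ] <- c(i - 2, i - 1, chain$c_dist[[i - 1]], chain$c_prox[[i]])
    }
  }
  list(mass = chain$mass, inertia = chain$inertia, joints = joints)
}

chain_state <- function(th, thd, chain, pin = c(0, 0)) {
  n <- length(th)
  com <- chain_com(th, chain, pin)
  vel <- matrix(0, n, 2)
  J <- chain_jacobians(th, chain)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) vel[i, ] <- vel[i, ] + J[i, , k] * thd[k]
  }
  list(q = c(com[, 1], com[, 2], th), v = c(vel[, 1], vel[, 2], thd))
}

make_chain <- function(mass, len, com_frac = 0.5, rg_frac = 0.3) {
  n <- length(mass)
  com_frac <- rep(com_frac, length.out = n)
  rg_frac <- rep(rg_frac, length.out = n)
  list(
    mass = mass,
    inertia = mass * (rg_frac * len)^2,
    c_prox = lapply(seq_len(n), function(i) c(0, com_frac[i] * len[i])),
    c_dist = lapply(seq_len(n), function(i) c(0, -(1 - com_frac[i]) * len[i])),
    delta = lapply(seq_len(n), function(i) c(0, -len[i]))
  )
}
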