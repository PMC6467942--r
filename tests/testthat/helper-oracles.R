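# Independent reference implementations ("oracles") used to cross-check the
# package's algorithms. These deliberately share no code with the package:
# brute-force or textbook formulations only.

# Raw (unsuperposed) RMSD between two n x 3 coordinate sets.
rawRmsd <- function(a, b) sqrt(sum((a - b)^2) / nrow(a))

# Brute-force minimum RMSD over proper rotations + translations: center both
# sets, then numerically minimize over ZYZ Euler angles from many starts.
bruteForceRmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  rotz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  roty <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  f <- function(ang) {
    R <- rotz(ang[1]) %*% roty(ang[2]) %*% rotz(ang[3])
    sqrt(sum((ac %*% R - bc)^2) / nrow(ac))
  }
  starts <- as.matrix(expand.grid(a1 = seq(0, 2 * pi, length.out = 5)[-5],
                                  a2 = seq(0, pi, length.out = 4),
                                  a3 = seq(0, 2 * pi, length.out = 5)[-5]))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    r <- stats::optim(starts[i, ], f, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (r$value < best) best <- r$value
  }
  best
}

# Brute-force GROMOS/Daura clustering on a distance matrix: repeatedly take
# the frame with the most neighbours within the cutoff (ties -> lowest
# index), remove it and its neighbours. Returns list(members, centers).
bruteGromos <- function(m, cutoff) {
  remaining <- seq_len(nrow(m))
  members <- list(); centers <- integer(0)
  while (length(remaining) > 0) {
    counts <- vapply(remaining, function(i)
      sum(m[i, remaining] <= cutoff), integer(1))
    center <- remaining[which.max(counts)]    # which.max takes first = lowest
    cl <- remaining[m[center, remaining] <= cutoff]
    members[[length(members) + 1]] <- sort(cl)
    centers <- c(centers, center)
    remaining <- setdiff(remaining, cl)
  }
  list(members = members, centers = centers)
}

# Textbook dihedral angle (IUPAC sign convention) via the atan2 form,
# written independently of the package's vectorized implementation.
oracleDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(b2[2] * n1[3] - b2[3] * n1[2],
          b2[3] * n1[1] - b2[1] * n1[3],
          b2[1] * n1[2] - b2[2] * n1[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# Fraction of frames whose labels match after the best one-to-one relabeling
# (greedy on the contingency table; exact enough for well-separated cases).
labelAgreement <- function(found, truth) {
  tab <- table(found, truth)
  total <- 0
  while (length(tab) && max(tab) > 0) {
    ij <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    total <- total + tab[ij[1], ij[2]]
    tab[ij[1], ] <- -1; tab[, ij[2]] <- -1
  }
  total / length(truth)
}

# A trajectory whose selected-atom motion lies exactly along two planted
# displacement fields orthogonal to the rigid-body modes (3 translations +
# 3 infinitesimal rotations), with amplitude variances varHigh and varLow.
# Returns the trajectory plus the planted unit fields.
plantedTwoModeTrajectory <- function(template, varHigh = 9, varLow = 1,
                                     nFrames = 10000, seed = 1) {
  base <- coords(template)
  n <- nrow(base)
  centered <- sweep(base, 2, colMeans(base))
  # rigid-body basis in flattened (x1,y1,z1,x2,...) order
  basis <- matrix(0, 3 * n, 6)
  for (k in 1:3) basis[seq(k, 3 * n, by = 3), k] <- 1
  gens <- list(matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 0), 3, 3),
               matrix(c(0, 0, 1, 0, 0, 0, -1, 0, 0), 3, 3),
               matrix(c(0, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3))
  for (k in 1:3) basis[, 3 + k] <- as.vector(t(centered %*% gens[[k]]))
  q <- qr.Q(qr(basis))
  orth <- function(v) { v <- v - q %*% crossprod(q, v); v / sqrt(sum(v^2)) }
  set.seed(seed)
  v1 <- orth(rnorm(3 * n))
  v2 <- orth(rnorm(3 * n))
  v2 <- v2 - v1 * sum(v1 * v2)
  v2 <- v2 / sqrt(sum(v2^2))
  a <- rnorm(nFrames, sd = sqrt(varHigh))
  b <- rnorm(nFrames, sd = sqrt(varLow))
  flat <- matrix(rep(as.vector(t(base)), each = nFrames), nrow = nFrames)
  flat <- flat + outer(a, as.numeric(v1)) + outer(b, as.numeric(v2))
  arr <- aperm(array(flat, dim = c(nFrames, 3, n)), c(1, 3, 2))
  list(trajectory = Trajectory(topology(template), arr),
       v1 = v1, v2 = v2, amplitudesHigh = a, amplitudesLow = b)
}

# Atom keys of the template's gauge pair, as "chain:resid:name" strings.
gaugeKeys <- function(template) {
  at <- atoms(topology(template))[template@gaugePair, ]
  sprintf("%s:%d:%s", at$chain, at$resid, at$name)
}
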