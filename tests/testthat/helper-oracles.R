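# Independent oracles used across the suite. Each reimplements the quantity
# it checks by a different route than the package.

# dihedral by explicit frame rotation: align the central bond with z via a
# Rodrigues rotation, then take the difference of polar angles of the outer
# bonds' xy projections
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  z <- c(0, 0, 1)
  u <- b2 / sqrt(sum(b2^2))
  v <- c(u[2] * z[3] - u[3] * z[2], u[3] * z[1] - u[1] * z[3],
         u[1] * z[2] - u[2] * z[1])
  s <- sqrt(sum(v^2))
  cth <- sum(u * z)
  R <- if (s < 1e-12) {
    if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + K + K %*% K * ((1 - cth) / s^2)
  }
  a <- as.vector(R %*% (p1 - p2))
  b <- as.vector(R %*% (p4 - p3))
  d <- (atan2(b[2], b[1]) - atan2(a[2], a[1])) * 180 / pi
  d %% 360
}

random_rotation <- function() {
  qr_out <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_out)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# exhaustive information-gain search: every feature, every midpoint between
# consecutive distinct values, gain evaluated through the entropy() formula
brute_force_split <- function(X, y, features = colnames(X)) {
  n <- length(y)
  parent <- entropy(c(sum(y == 0), sum(y == 1)))
  best <- NULL
  for (f in features) {
    vals <- sort(unique(X[[f]]))
    if (length(vals) < 2) next
    for (th in (vals[-1] + vals[-length(vals)]) / 2) {
      l <- y[X[[f]] <= th]; r <- y[X[[f]] > th]
      g <- parent - length(l) / n * entropy(c(sum(l == 0), sum(l == 1))) -
        length(r) / n * entropy(c(sum(r == 0), sum(r == 1)))
      if (g > 0 && (is.null(best) || g > best$gain)) {
        best <- list(feature = f, threshold = th, gain = g)
      }
    }
  }
  best
}

# maximum training-set correct count achievable by any threshold tree of the
# given depth (dynamic-programming exhaustive search)
brute_force_tree_correct <- function(X, y, depth, features = colnames(X)) {
  majority <- max(sum(y == 0), sum(y == 1))
  if (depth == 0 || length(y) == 0 || majority == length(y)) return(majority)
  best <- majority
  for (f in features) {
    vals <- sort(unique(X[[f]]))
    if (length(vals) < 2) next
    for (th in (vals[-1] + vals[-length(vals)]) / 2) {
      go <- X[[f]] <= th
      cand <- brute_force_tree_correct(X[go, , drop = FALSE], y[go],
                                       depth - 1, features) +
        brute_force_tree_correct(X[!go, , drop = FALSE], y[!go],
                                 depth - 1, features)
      if (cand > best) best <- cand
    }
  }
  best
}

train_correct <- function(tree, ds) sum(predict(tree, ds) == ds$label)

# tiny labelled feature tables built in code
toy_dataset <- function(alpha0, alpha1, ...) {
  n0 <- length(alpha0); n1 <- length(alpha1)
  df <- data.frame(
    pdb_id = "TOY", chain = "A", resseq = as.character(seq_len(n0 + n1)),
    base = "G", class = c(rep("LHG4", n0), rep("RHG4", n1)),
    label = c(rep(0L, n0), rep(1L, n1)),
    alpha = c(alpha0, alpha1), beta = 150, gamma = 60, delta = 130,
    epsilon = 200, zeta = 260, chi = 250, stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  suppressMessages(build_dataset(df, name = "toy"))
}

g4_synthetic <- function(seed, n = NULL) {
  spec <- default_torsion_spec()
  sample_dataset(spec, seed = seed, n_per_class = n, classes = c("LHG4", "RHG4"))
}

dh_synthetic <- function(seed, n = NULL) {
  spec <- default_torsion_spec()
  sample_dataset(spec, seed = seed, n_per_class = n, classes = c("ZDNA", "BDNA"))
}

# convex-hull disjointness of two 2-d point clouds: no point of either cloud
# inside the other's hull and no hull edges crossing
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

hulls_disjoint <- function(A, B) {
  ha <- A[grDevices::chull(A), , drop = FALSE]
  hb <- B[grDevices::chull(B), , drop = FALSE]
  if (any(mgcv::in.out(rbind(ha, ha[1, ]), B)) ||
      any(mgcv::in.out(rbind(hb, hb[1, ]), A))) {
    return(FALSE)
  }
  na <- nrow(ha); nb <- nrow(hb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (segments_intersect(ha[i, ], ha[i %% na + 1, ],
                             hb[j, ], hb[j %% nb + 1, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}
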