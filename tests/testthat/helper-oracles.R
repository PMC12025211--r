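# Independent brute-force oracles used to cross-check the package's metric
# and surrogate implementations. These deliberately use naive enumeration
# (pixel loops, direct linear algebra, Monte Carlo) and never call the code
# paths they verify.

bf_confusion_class <- function(pred, true, k) {
  p <- as.vector(pred) == k
  t <- as.vector(true) == k
  c(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t))
}

bf_jaccard <- function(pred, true, k) {
  p <- as.vector(pred) == k; t <- as.vector(true) == k
  inter <- sum(p & t); uni <- sum(p | t)
  if (uni == 0) 1 else inter / uni
}

bf_dice <- function(pred, true, k) {
  p <- as.vector(pred) == k; t <- as.vector(true) == k
  den <- sum(p) + sum(t)
  if (den == 0) 1 else 2 * sum(p & t) / den
}

bf_sensitivity <- function(pred, true, k) {
  p <- as.vector(pred) == k; t <- as.vector(true) == k
  if (sum(t) == 0) 1 else sum(p & t) / sum(t)
}

bf_specificity <- function(pred, true, k) {
  p <- as.vector(pred) == k; t <- as.vector(true) == k
  if (sum(!t) == 0) 1 else sum(!p & !t) / sum(!t)
}

# boundary via explicit neighbour checks; image border counts as outside
bf_boundary <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  out <- NULL
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!mask[i, j]) next
    nb_out <- (i == 1 || !mask[i - 1, j]) || (i == n || !mask[i + 1, j]) ||
      (j == 1 || !mask[i, j - 1]) || (j == m || !mask[i, j + 1])
    if (nb_out) out <- rbind(out, c(i, j))
  }
  out
}

bf_msd <- function(pred, true, k, spacing = 1, mode = "directed") {
  a <- bf_boundary(pred == k)
  b <- bf_boundary(true == k)
  if (is.null(a) || is.null(b)) return(NA_real_)
  dir_ab <- function(p, q) {
    total <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        d <- sqrt(sum((p[i, ] - q[j, ])^2))
        if (d < best) best <- d
      }
      total <- total + best
    }
    total / nrow(p)
  }
  d <- if (mode == "directed") dir_ab(a, b) else (dir_ab(a, b) + dir_ab(b, a)) / 2
  d * spacing
}

bf_bland_altman <- function(pred, true) {
  d <- pred - true
  m <- sum(d) / length(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  lo <- m - 1.96 * s; hi <- m + 1.96 * s
  list(mean = m, sd = s, lo = lo, hi = hi,
       frac = sum(d > lo & d < hi) / length(d))
}

# direct GP posterior from the kernel matrix (no Cholesky shortcuts)
bf_gp_posterior <- function(fit, Xnew) {
  m52 <- function(A, B) {
    K <- matrix(0, nrow(A), nrow(B))
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      r <- sqrt(sum(((A[i, ] - B[j, ]) / fit$lengthscales)^2))
      K[i, j] <- fit$signal_var *
        (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
    }
    K
  }
  ys <- (fit$y - fit$y_mean) / fit$y_sd
  K <- m52(fit$X, fit$X) + diag(fit$noise_var, nrow(fit$X))
  Kinv <- solve(K)
  ks <- m52(Xnew, fit$X)
  mu <- as.numeric(ks %*% Kinv %*% ys)
  var_f <- pmax(fit$signal_var - diag(ks %*% Kinv %*% t(ks)), 0)
  list(mean = fit$y_mean + fit$y_sd * mu, sd = fit$y_sd * sqrt(var_f))
}

# small random multi-class masks for oracle suites
random_mask <- function(n = 16, n_classes = 5) {
  prob <- c(0.5, 0.2, 0.12, 0.1, 0.08)[seq_len(n_classes)]
  matrix(sample(0:(n_classes - 1), n * n, replace = TRUE, prob = prob),
         n, n)
}

tiny_phantom <- function(n_patients = 3, seed = 7, image_size = 32,
                         slices = 12, l3 = 0.1) {
  generate_cohort(phantom_params(image_size = image_size,
                                 slices_per_patient = slices,
                                 l3_fraction = l3),
                  n_patients, seed = seed)
}
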