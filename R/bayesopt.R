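#' Mixed design space for Bayesian optimisation
#'
#' A design space is a table of variables, each continuous, log-continuous
#' (searched on the log scale) or integer, with finite bounds. The default
#' hyperparameter block is: L2 regularisation and initial learning rate,
#' log-continuous on `[1e-4, 1e-2]`; batch size, integer `[10, 32]`;
#' gradient (clipping) threshold, integer `[1, 6]`; epochs, integer
#' `[5, 20]`; momentum, continuous `[0.7, 0.99]`.
#'
#' @param variables data frame with columns `name`, `kind`
#'   (`"continuous"`, `"log_continuous"`, `"integer"`), `lower`, `upper`.
#' @return a `design_space` object.
#' @export
design_space <- function(variables) {
  req <- c("name", "kind", "lower", "upper")
  if (!all(req %in% names(variables))) stop("missing design-space columns")
  if (!all(variables$kind %in% c("continuous", "log_continuous", "integer")))
    stop("unknown variable kind")
  if (any(!is.finite(variables$lower)) || any(!is.finite(variables$upper)))
    stop("bounds must be finite")
  if (any(variables$lower >= variables$upper))
    stop("'lower' must be < 'upper' for every variable")
  if (any(variables$kind == "log_continuous" & variables$lower <= 0))
    stop("log-continuous bounds must be strictly positive")
  variables$name <- as.character(variables$name)
  structure(variables, class = c("design_space", "data.frame"))
}

#' Default hyperparameter design space, optionally with correction design
#' variables
#'
#' @param task `"detection"` or `"segmentation"`.
#' @param include_cdv add the correction design variables: for detection an
#'   augmentation ratio `d_a` in `[n_minority / n_majority, 1]` and one
#'   weight `d_c_<k>` per class; for segmentation weights only (the
#'   augmentation factor is fixed). Each `d_c_k` ranges from the
#'   task-specific minimum `m_k` up to `10 * max(m)`.
#' @param class_frequencies per-class frequencies of the training set
#'   (required when `include_cdv = TRUE`): slice frequencies for detection
#'   (code order 0 = non-L3, 1 = L3), pixel frequencies for segmentation.
#' @param min_rule segmentation weight-minimum rule, see
#'   [compute_class_weights()].
#' @return a [design_space()].
#' @export
default_design_space <- function(task = c("detection", "segmentation"),
                                 include_cdv = FALSE,
                                 class_frequencies = NULL,
                                 min_rule = "pixel_ratio") {
  task <- match.arg(task)
  vars <- data.frame(
    name = c("l2_regularization", "initial_learning_rate", "batch_size",
             "gradient_threshold", "epochs", "momentum"),
    kind = c("log_continuous", "log_continuous", "integer", "integer",
             "integer", "continuous"),
    lower = c(1e-4, 1e-4, 10, 1, 5, 0.7),
    upper = c(1e-2, 1e-2, 32, 6, 20, 0.99),
    stringsAsFactors = FALSE
  )
  if (include_cdv) {
    if (is.null(class_frequencies))
      stop("'class_frequencies' is required to build CDV ranges")
    f <- class_frequencies
    cw <- compute_class_weights(f, task = task, min_rule = min_rule)
    m <- cw$minima
    hi <- 10 * max(m)
    if (task == "detection") {
      ratio <- f[2] / f[1]  # minority (code 1) over majority (code 0)
      vars <- rbind(vars, data.frame(
        name = "d_a", kind = "continuous",
        lower = min(ratio, 0.999), upper = 1, stringsAsFactors = FALSE))
    }
    vars <- rbind(vars, data.frame(
      name = paste0("d_c_", seq_along(m) - 1L),
      kind = "continuous", lower = as.numeric(m), upper = hi,
      stringsAsFactors = FALSE))
  }
  design_space(vars)
}

#' Encode a design as a point in the unit cube / decode it back
#'
#' Log-continuous variables are log-transformed before affine scaling to
#' `[0, 1]`; integers are scaled continuously and decoded by rounding to
#' the nearest feasible integer. `decode(encode(d)) = d` for continuous
#' variables and for integers already on the grid.
#'
#' @param design named list of variable values.
#' @param space a [design_space()].
#' @return `encode_design`: numeric vector in `[0, 1]^d`; `decode_design`:
#'   named list.
#' @export
encode_design <- function(design, space) {
  x <- numeric(nrow(space))
  for (i in seq_len(nrow(space))) {
    v <- design[[space$name[i]]]
    if (is.null(v)) stop(sprintf("design lacks variable '%s'", space$name[i]))
    lo <- space$lower[i]; hi <- space$upper[i]
    if (v < lo - 1e-9 || v > hi + 1e-9)
      stop(sprintf("'%s' = %g outside bounds [%g, %g]",
                   space$name[i], v, lo, hi))
    x[i] <- if (space$kind[i] == "log_continuous")
      (log(v) - log(lo)) / (log(hi) - log(lo))
    else (v - lo) / (hi - lo)
  }
  pmin(pmax(x, 0), 1)
}

#' @rdname encode_design
#' @param point numeric vector in `[0, 1]^d`.
#' @export
decode_design <- function(point, space) {
  stopifnot(length(point) == nrow(space))
  out <- vector("list", nrow(space))
  names(out) <- space$name
  for (i in seq_len(nrow(space))) {
    p <- min(max(point[i], 0), 1)
    lo <- space$lower[i]; hi <- space$upper[i]
    out[[i]] <- switch(space$kind[i],
      log_continuous = exp(log(lo) + p * (log(hi) - log(lo))),
      continuous = lo + p * (hi - lo),
      integer = as.integer(min(max(round(lo + p * (hi - lo)), lo), hi)))
  }
  out
}

#' Objective from confusion counts: inverse F1
#'
#' Precision `TP/(TP+FP)` and recall `TP/(TP+FN)` give
#' `objective = (precision + recall) / (2 precision recall) = 1 / F1`,
#' so a perfect classifier scores 1 and the objective is minimised.
#' Multi-class counts are reduced by averaging F1 over the selected
#' (foreground) classes before inversion, macro by default. A zero F1 (or a
#' class with no positive predictions and no positives in truth) yields the
#' capped objective.
#'
#' @param counts a [confusion()] object.
#' @param classes class codes to include (default: all but code 0 when
#'   multi-class, the positive class `1` when binary).
#' @param average `"macro"` (mean of per-class F1) or `"micro"` (pooled
#'   counts).
#' @param cap objective value used when F1 = 0 (keeps the surrogate
#'   finite).
#' @return scalar objective, `>= 1` (or `cap`).
#' @export
objective_from_counts <- function(counts, classes = NULL,
                                  average = c("macro", "micro"),
                                  cap = 1e6) {
  average <- match.arg(average)
  m <- .counts_mat(counts)
  codes <- as.integer(rownames(m))
  if (is.null(classes))
    classes <- if (nrow(m) == 2) 1L else codes[codes != 0L]
  sel <- match(classes, codes)
  if (any(is.na(sel))) stop("unknown class code in 'classes'")
  m <- m[sel, , drop = FALSE]
  f1_of <- function(tp, fp, fn) {
    if (tp + fp == 0 && tp + fn == 0) {
      warning("class with no predictions and no positives; objective capped")
      return(0)
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  f1 <- if (average == "macro") {
    mean(vapply(seq_len(nrow(m)), function(i)
      f1_of(m[i, "TP"], m[i, "FP"], m[i, "FN"]), 0))
  } else {
    f1_of(sum(m[, "TP"]), sum(m[, "FP"]), sum(m[, "FN"]))
  }
  if (f1 <= 0) cap else min(1 / f1, cap)
}

# ---------------------------------------------------------------------------
# Gaussian-process surrogate: Matern-5/2 kernel with per-dimension
# length-scales (ARD) on the encoded unit cube, hyperparameters by marginal
# likelihood maximisation with deterministic multistart.

matern52 <- function(X1, X2, lengthscales, signal_var) {
  X1s <- sweep(X1, 2, lengthscales, "/")
  X2s <- sweep(X2, 2, lengthscales, "/")
  d2 <- outer(rowSums(X1s^2), rowSums(X2s^2), "+") - 2 * tcrossprod(X1s, X2s)
  r <- sqrt(pmax(d2, 0))
  signal_var * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
}

.gp_chol <- function(K) {
  jit <- 0
  for (t in 0:6) {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- if (jit == 0) 1e-10 else jit * 10
  }
  stop("covariance matrix is singular even after jitter escalation")
}

#' Fit a Gaussian-process surrogate
#'
#' Matern-5/2 kernel with automatic-relevance-determination length-scales
#' on the encoded unit cube. Kernel hyperparameters (length-scales, signal
#' variance, observation noise) are set by maximising the log marginal
#' likelihood with L-BFGS-B from several fixed starting points. Targets are
#' standardised internally. An observation-noise floor of `1e-8` keeps the
#' Cholesky factorisation stable; pass `noise` to fix the noise variance
#' instead of optimising it.
#'
#' @param X numeric matrix of encoded designs (rows in `[0, 1]^d`).
#' @param y objective values (length `nrow(X)`, at least 2).
#' @param noise optional fixed observation-noise variance.
#' @param noise_floor lower bound for the noise variance.
#' @return a `gp_fit` object with elements `X`, `y`, `lengthscales`,
#'   `signal_var`, `noise_var`, `y_mean`, `y_sd`, and cached factorisations.
#' @export
gp_fit <- function(X, y, noise = NULL, noise_floor = 1e-8) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("at least 2 observations are required")
  if (length(y) != nrow(X)) stop("X/y length mismatch")
  d <- ncol(X)
  y_mean <- mean(y)
  y_sd <- sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (y - y_mean) / y_sd
  fix_noise <- !is.null(noise)

  nll <- function(par) {
    ell <- exp(par[1:d])
    s2 <- exp(par[d + 1])
    nv <- if (fix_noise) max(noise / y_sd^2, noise_floor)
          else max(exp(par[d + 2]), noise_floor)
    K <- matern52(X, X, ell, s2) + diag(nv, nrow(X))
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    alpha <- backsolve(L, forwardsolve(t(L), ys))
    as.numeric(0.5 * sum(ys * alpha) + sum(log(diag(L))) +
                 0.5 * nrow(X) * log(2 * pi))
  }

  starts <- lapply(c(0.3, 0.8, 2.0), function(l0) {
    c(rep(log(l0), d), log(1), if (!fix_noise) log(1e-4))
  })
  npar <- d + 1 + !fix_noise
  lower <- c(rep(log(0.02), d), log(1e-4), if (!fix_noise) log(noise_floor))
  upper <- c(rep(log(20), d), log(1e3), if (!fix_noise) log(10))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 100)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) best <- list(par = starts[[1]])
  par <- best$par
  ell <- exp(par[1:d])
  s2 <- exp(par[d + 1])
  nv <- if (fix_noise) max(noise / y_sd^2, noise_floor)
        else max(exp(par[d + 2]), noise_floor)
  K <- matern52(X, X, ell, s2) + diag(nv, nrow(X))
  L <- .gp_chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  structure(list(X = X, y = y, lengthscales = ell, signal_var = s2,
                 noise_var = nv, y_mean = y_mean, y_sd = y_sd,
                 L = L, alpha = alpha),
            class = "gp_fit")
}

#' Posterior mean and standard deviation of a fitted GP
#'
#' @param fit a [gp_fit()] object.
#' @param Xnew matrix of query points (rows).
#' @return list with `mean` and `sd` (latent-function posterior, on the
#'   original objective scale).
#' @export
gp_predict <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  ks <- matern52(Xnew, fit$X, fit$lengthscales, fit$signal_var)
  mu <- as.numeric(ks %*% fit$alpha)
  v <- forwardsolve(t(fit$L), t(ks))
  var_f <- pmax(fit$signal_var - colSums(v^2), 0)
  list(mean = fit$y_mean + fit$y_sd * mu,
       sd = fit$y_sd * sqrt(var_f))
}

#' Expected improvement (minimisation form)
#'
#' `z = (incumbent - mu) / sigma`;
#' `EI = (incumbent - mu) * Phi(z) + sigma * phi(z)`, and
#' `max(incumbent - mu, 0)` when `sigma = 0`. Always nonnegative.
#'
#' @param mu posterior mean(s).
#' @param sigma posterior standard deviation(s), `>= 0`.
#' @param incumbent best (lowest) observed objective.
#' @return expected improvement, same length as `mu`.
#' @export
expected_improvement <- function(mu, sigma, incumbent) {
  if (any(sigma < 0)) stop("'sigma' must be nonnegative")
  imp <- incumbent - mu
  out <- pmax(imp, 0)
  pos <- sigma > 0
  if (any(pos)) {
    z <- imp[pos] / sigma[pos]
    out[pos] <- imp[pos] * pnorm(z) + sigma[pos] * dnorm(z)
  }
  pmax(out, 0)
}

#' Propose the next design by maximising expected improvement
#'
#' EI is evaluated at `n_candidates` uniform samples of the unit cube
#' (drawn from the current RNG stream) and refined locally from the best
#' candidate with bounded BFGS; the winner is decoded to a feasible design.
#'
#' @param fit a [gp_fit()] object.
#' @param space the [design_space()].
#' @param n_candidates number of uniform candidates (default 2048).
#' @param refine run local refinement from the top candidate.
#' @return list with `design` (decoded), `point` (cube coordinates) and
#'   `ei`.
#' @export
propose_next <- function(fit, space, n_candidates = 2048, refine = TRUE) {
  d <- nrow(space)
  incumbent <- min(fit$y)
  cand <- matrix(runif(n_candidates * d), n_candidates, d)
  pr <- gp_predict(fit, cand)
  ei <- expected_improvement(pr$mean, pr$sd, incumbent)
  best <- which.max(ei)
  x0 <- cand[best, ]
  best_ei <- ei[best]
  if (refine) {
    neg_ei <- function(x) {
      p <- gp_predict(fit, matrix(x, 1))
      -expected_improvement(p$mean, p$sd, incumbent)
    }
    ref <- tryCatch(
      optim(x0, neg_ei, method = "L-BFGS-B", lower = 0, upper = 1,
            control = list(maxit = 50)),
      error = function(e) NULL)
    if (!is.null(ref) && -ref$value > best_ei) {
      x0 <- ref$par
      best_ei <- -ref$value
    }
  }
  list(design = decode_design(x0, space), point = x0, ei = best_ei)
}

#' Bayesian optimisation of a black-box objective
#'
#' Runs `n_init` space-filling initial evaluations (Latin hypercube on the
#' encoded cube), then the fit-surrogate / maximise-EI / evaluate loop
#' until `budget` evaluations in total. Objective errors are caught, logged
#' as a warning and recorded as the capped objective so the loop continues.
#' Fully reproducible given `seed`.
#'
#' @param objective_fn function taking a decoded design (named list) and
#'   returning a scalar objective to minimise.
#' @param space the [design_space()].
#' @param budget total number of evaluations, `> n_init`.
#' @param n_init number of initial designs; default
#'   `min(max(5, 2 d), floor(budget / 2))`, at least 2.
#' @param seed RNG seed controlling the whole run.
#' @param objective_cap value recorded for failed or non-finite
#'   evaluations.
#' @param n_candidates EI candidate count per iteration.
#' @return a `bo_result`: list with `best_design`, `best_objective`,
#'   `best_index`, `history` (data frame of cube coordinates + objective),
#'   `designs` (list), `seed`, `budget`, `n_init`.
#' @export
bo_optimize <- function(objective_fn, space, budget = 40, n_init = NULL,
                        seed = 1L, objective_cap = 1e6,
                        n_candidates = 2048) {
  d <- nrow(space)
  if (is.null(n_init))
    n_init <- max(2L, min(max(5L, 2L * d), as.integer(floor(budget / 2))))
  if (!(budget > n_init && n_init >= 2))
    stop("'budget' must exceed 'n_init' and 'n_init' must be >= 2")

  evaluate <- function(design) {
    val <- tryCatch(objective_fn(design), error = function(e) {
      warning(sprintf("objective evaluation failed (%s); recording cap",
                      conditionMessage(e)), call. = FALSE)
      objective_cap
    })
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val))
      val <- objective_cap
    min(val, objective_cap)
  }

  with_seed(seed, {
    X <- as.matrix(lhs::randomLHS(n_init, d))
    designs <- vector("list", budget)
    y <- numeric(budget)
    for (i in seq_len(n_init)) {
      designs[[i]] <- decode_design(X[i, ], space)
      y[i] <- evaluate(designs[[i]])
    }
    points <- matrix(NA_real_, budget, d)
    points[seq_len(n_init), ] <- X
    for (i in (n_init + 1):budget) {
      fit <- gp_fit(points[seq_len(i - 1), , drop = FALSE], y[seq_len(i - 1)])
      prop <- propose_next(fit, space, n_candidates = n_candidates)
      points[i, ] <- prop$point
      designs[[i]] <- prop$design
      y[i] <- evaluate(prop$design)
    }
    best <- which.min(y)
    history <- as.data.frame(points)
    names(history) <- space$name
    history$objective <- y
    history$evaluation <- seq_len(budget)
    structure(list(best_design = designs[[best]],
                   best_objective = y[best],
                   best_index = best,
                   history = history,
                   designs = designs,
                   seed = seed, budget = budget, n_init = n_init),
              class = "bo_result")
  })
}

#' @export
print.bo_result <- function(x, ...) {
  cat(sprintf("<bo_result: %d evaluations (%d initial), best objective %.4f at #%d>\n",
              x$budget, x$n_init, x$best_objective, x$best_index))
  invisible(x)
}

#' Best-so-far (incumbent) trace of a BO run
#'
#' @param result a `bo_result`.
#' @return numeric vector: running minimum of the objective history.
#' @export
incumbent_trace <- function(result) cummin(result$history$objective)
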