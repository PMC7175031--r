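# Constrained, decoupled extended Infomax ICA with augmented-Lagrangian
# reference constraints.

#' Configuration for constrained ICA
#'
#' @param threshold similarity bound per component (scalar, broadcast, or
#'   length-M vector); for correlation similarity it must lie in `[0, 1)`.
#' @param penalty augmented-Lagrangian penalty (scalar broadcast or
#'   per-component), > 0. The customary scalar value is 3.
#' @param learning_rate gradient step size, > 0; the customary value 0.5.
#' @param max_iter maximum full sweeps over the components.
#' @param tol convergence tolerance on the max absolute demixing-weight
#'   change per sweep.
#' @param tol_h slack tolerance when flagging constraints as satisfied.
#' @param seed seed for the small-random-value weight initialization.
#' @param similarity_kind `"correlation"` (mean product of standardized
#'   maps) or `"mse"` (negated mean squared error, so larger is more
#'   similar in both cases).
#' @param whiten optionally decorrelate the rows of the input before
#'   unmixing (off by default; the PCA-reduced rows are fed directly).
#' @return an object of class `cica_config`.
#' @export
cica_config <- function(threshold = 0.5, penalty = 3, learning_rate = 0.5,
                        max_iter = 1000L, tol = 1e-6, tol_h = 1e-3,
                        seed = NULL,
                        similarity_kind = c("correlation", "mse"),
                        whiten = FALSE) {
  similarity_kind <- match.arg(similarity_kind)
  stopifnot(all(penalty > 0), learning_rate > 0, max_iter >= 1, tol > 0)
  if (similarity_kind == "correlation" &&
      (any(threshold < 0) || any(threshold >= 1)))
    stop("correlation thresholds must lie in [0, 1)", call. = FALSE)
  structure(list(threshold = threshold, penalty = penalty,
                 learning_rate = learning_rate,
                 max_iter = as.integer(max_iter), tol = tol, tol_h = tol_h,
                 seed = seed, similarity_kind = similarity_kind,
                 whiten = whiten),
            class = "cica_config")
}

#' Standardize data and reference rows
#'
#' Transforms every row of the reduced data and of the reference set to
#' zero mean, unit (population) variance over the L spatial samples, the
#' form in which both enter the constrained ICA.
#'
#' @param x M x L matrix or `reduced_matrix`.
#' @param refs M x L matrix or `reference_set`.
#' @return list with standardized matrices `x` and `refs`.
#' @export
standardize_inputs <- function(x, refs) {
  xm <- row_values(x); rm_ <- row_values(refs)
  if (!all(dim(xm) == dim(rm_)))
    stop_shape("data and references must share dimensions M x L")
  list(x = standardize_rows(xm, what = "data row"),
       refs = standardize_rows(rm_, what = "reference row"))
}

#' Similarity between a component map and a reference map
#'
#' For standardized inputs the correlation kind equals the Pearson
#' correlation, `mean(y * r)`; the mse kind is the negated mean squared
#' error `-mean((y - r)^2)`, negated so that larger always means more
#' similar.
#'
#' @param y,r numeric vectors of equal length (standardized maps).
#' @param kind `"correlation"` or `"mse"`.
#' @return scalar similarity.
#' @export
similarity <- function(y, r, kind = c("correlation", "mse")) {
  kind <- match.arg(kind)
  if (length(y) != length(r))
    stop_shape("component and reference must have equal length")
  if (kind == "correlation") mean(y * r) else -mean((y - r)^2)
}

#' Constraint value of one weight row
#'
#' `h = threshold - epsilon(y, r)` where `y = w' x` is re-standardized
#' before comparison; the constraint is satisfied iff `h <= 0`. A
#' zero-variance component is maximally violated (`h = threshold`).
#'
#' @param w length-M weight row.
#' @param x M x L standardized data.
#' @param r length-L standardized reference.
#' @param threshold similarity bound.
#' @param kind similarity kind, see [similarity].
#' @return scalar `h`.
#' @export
constraint_value <- function(w, x, r, threshold,
                             kind = c("correlation", "mse")) {
  kind <- match.arg(kind)
  y <- as.vector(w %*% x)
  s <- sqrt(mean((y - mean(y))^2))
  if (s < 1e-300) {
    warning("zero-variance component: constraint maximally violated",
            call. = FALSE)
    return(threshold)
  }
  threshold - similarity((y - mean(y)) / s, r, kind)
}

#' Decoupling vector of a demixing matrix row
#'
#' The unit vector spanning the null space of the demixing matrix with row
#' `m` removed; its sign is chosen so `d' w_m > 0`. Substituting
#' `log|d' w_m|` for `log|det W|` decouples the rows of the likelihood.
#'
#' @param W M x M demixing matrix.
#' @param m row index.
#' @return length-M unit vector.
#' @export
decoupling_vector <- function(W, m) {
  M <- nrow(W)
  Wt <- W[-m, , drop = FALSE]
  sv <- svd(Wt, nu = 0, nv = M)
  if (M > 1L && sv$d[M - 1L] < 1e-10 * max(sv$d[1], 1e-300))
    stop(structure(class = c("cicaemd_rank_error", "error", "condition"),
                   list(message = sprintf(
                     "demixing matrix without row %d is rank deficient", m),
                     call = NULL)))
  d <- sv$v[, M]
  if (sum(d * W[m, ]) < 0) d <- -d
  d
}

# Extended-Infomax score function: the sign `k` switches the source prior
# (super-Gaussian k = +1: phi(y) = -y - tanh y; sub-Gaussian k = -1:
# phi(y) = -y + tanh y).
infomax_score <- function(y, k) -y - k * tanh(y)

infomax_logp <- function(y, k) -y^2 / 2 - k * log(cosh(y))

# Classical extended-Infomax stability criterion deciding the score sign
# per component from the current source estimate.
kurtosis_sign <- function(y) {
  ys <- y / max(sqrt(mean(y^2)), 1e-300)
  s <- mean(1 / cosh(ys)^2) * mean(ys^2) - mean(tanh(ys) * ys)
  if (s >= 0) 1 else -1
}

# Gradient of the similarity epsilon(std(w'x), r) w.r.t. w; accounts for
# the re-standardization of y by its own mean and standard deviation.
similarity_gradient <- function(w, x, r, kind) {
  L <- ncol(x)
  y <- as.vector(w %*% x)
  yc <- y - mean(y)
  s <- sqrt(mean(yc^2))
  if (s < 1e-300) return(list(eps = 0, grad = numeric(length(w))))
  eps_c <- mean(yc * r) / s
  g <- as.vector(x %*% r) / (L * s) - eps_c * as.vector(x %*% yc) / (L * s^2)
  if (kind == "mse") list(eps = 2 * eps_c - 2, grad = 2 * g)
  else list(eps = eps_c, grad = g)
}

# Scalar decoupled objective of one row (likelihood + decoupling barrier -
# augmented penalty); the reference point for the finite-difference
# gradient checks.
component_objective <- function(w, x, r, d, mu, gamma, threshold, k,
                                kind = "correlation") {
  y <- as.vector(w %*% x)
  sg <- similarity_gradient(w, x, r, kind)
  h <- threshold - sg$eps
  mean(infomax_logp(y, k)) + log(abs(sum(d * w))) -
    (max(0, gamma * h + mu)^2 - mu^2) / (2 * gamma)
}

component_gradient <- function(w, x, r, d, mu, gamma, threshold, k,
                               kind = "correlation") {
  L <- ncol(x)
  y <- as.vector(w %*% x)
  sg <- similarity_gradient(w, x, r, kind)
  h <- threshold - sg$eps
  grad <- as.vector(x %*% infomax_score(y, k)) / L + d / sum(d * w)
  act <- gamma * h + mu
  if (act > 0) grad <- grad - act * (-sg$grad)
  list(grad = grad, h = h, eps = sg$eps)
}

#' One gradient-ascent step on a decoupled component row
#'
#' Ascends the decoupled objective
#' `E{log p(w' x)} + log|d' w|` minus the augmented-Lagrangian penalty
#' `(max(0, gamma h + mu)^2 - mu^2) / (2 gamma)`: the step is
#' `eta * (E{phi(y) x} + d / (d' w) - 1[gamma h + mu > 0] (gamma h + mu) dh/dw)`
#' with the extended-Infomax score `phi`. When the constraint is inactive
#' (`gamma h + mu <= 0`) the step reduces to the unconstrained decoupled
#' extended Infomax update. Non-finite steps are rejected with the
#' learning rate halved.
#'
#' @param w current weight row.
#' @param x M x L standardized data.
#' @param r standardized reference row.
#' @param d decoupling vector from [decoupling_vector].
#' @param mu current Lagrange multiplier (>= 0).
#' @param cfg a [cica_config] (supplies penalty, threshold, learning rate,
#'   similarity kind).
#' @param m component index (selects per-component threshold/penalty).
#' @param supergaussian score sign: `+1` super-Gaussian, `-1` sub-Gaussian.
#' @return list with the updated `w`, the pre-update constraint value `h`
#'   and similarity `eps`.
#' @export
component_update <- function(w, x, r, d, mu, cfg, m = 1L, supergaussian = 1) {
  gamma <- broadcast_par(cfg$penalty, m)
  thr <- broadcast_par(cfg$threshold, m)
  cg <- component_gradient(w, x, r, d, mu, gamma, thr, supergaussian,
                           cfg$similarity_kind)
  eta <- cfg$learning_rate
  for (try in 1:8) {
    w_new <- w + eta * cg$grad
    if (all(is.finite(w_new)) && abs(sum(d * w_new)) > 1e-300) break
    eta <- eta / 2
    warning("non-finite or degenerate step rejected; learning rate halved",
            call. = FALSE)
  }
  if (!all(is.finite(w_new))) w_new <- w
  list(w = w_new, h = cg$h, eps = cg$eps)
}

broadcast_par <- function(par, m) {
  if (length(par) == 1L) par else par[m]
}

#' Closed-form multiplier update
#'
#' The slack-optimal update of the augmented-Lagrangian multipliers for
#' inequality constraints: `mu <- max(0, mu + gamma * h)`, keeping every
#' multiplier non-negative and leaving satisfied constraints
#' (`h <= -mu / gamma`) with `mu = 0`.
#'
#' @param mu length-M multiplier vector.
#' @param h length-M current constraint values.
#' @param gamma penalty (scalar or per-component).
#' @return updated multiplier vector.
#' @export
update_multipliers <- function(mu, h, gamma) {
  pmax(0, mu + gamma * h)
}

#' Run constrained, decoupled extended Infomax ICA
#'
#' Estimates the demixing matrix `W` (sources `Y = W X`) by sequentially
#' updating each row with [component_update] and the multipliers with
#' [update_multipliers], until the largest weight change per sweep falls
#' below `cfg$tol` or `cfg$max_iter` sweeps are reached. Weights start at
#' small seeded random values; the score sign per component is re-estimated
#' every sweep from the stability criterion. The step size starts at
#' `cfg$learning_rate` and is halved whenever the weight change plateaus
#' (a fixed step orbits the attractor at step-proportional amplitude, so
#' plateau halving is what lets the iteration actually reach `tol`). On
#' return each component's sign is flipped, if needed, so its similarity
#' to the reference is non-negative.
#'
#' @param x M x L reduced data (`reduced_matrix` or matrix); rows are
#'   standardized internally.
#' @param refs M references (`reference_set` or matrix), standardized
#'   internally.
#' @param cfg a [cica_config].
#' @return object of class `ic_result`: sources `Y` (exactly `W %*% x_std`),
#'   demixing `W`, per-component `similarity`, `constraint_satisfied`
#'   flags, multipliers `mu`, constraint values `h`, `n_iter` and
#'   `converged`.
#' @export
run_cica <- function(x, refs, cfg = cica_config()) {
  std <- standardize_inputs(x, refs)
  X <- std$x; R <- std$refs
  M <- nrow(X); L <- ncol(X)
  if (cfg$whiten && M > 1L) {
    e <- eigen(tcrossprod(X) / L, symmetric = TRUE)
    X <- diag(1 / sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors) %*% X
  }

  W <- with_seed(cfg$seed, matrix(rnorm(M * M, sd = 0.01), M, M))
  mu <- numeric(M)
  h <- rep(NA_real_, M)
  converged <- FALSE
  n_iter <- 0L
  jitter_count <- 0L
  # Plateau-triggered learning-rate halving: the fixed step size orbits the
  # attractor at an amplitude proportional to eta, so once the weight
  # change stops shrinking the step is halved until the update falls below
  # the convergence tolerance.
  cfg_step <- cfg
  best_dw <- Inf
  stall <- 0L

  for (iter in seq_len(cfg$max_iter)) {
    n_iter <- iter
    W_old <- W
    for (m in seq_len(M)) {
      d <- tryCatch(decoupling_vector(W, m), cicaemd_rank_error = function(e) e)
      if (inherits(d, "cicaemd_rank_error")) {
        jitter_count <- jitter_count + 1L
        if (jitter_count > 5L)
          stop("repeated rank failures of the demixing matrix", call. = FALSE)
        W <- W + matrix(rnorm(M * M, sd = 0.01 * max(abs(W), 0.01)), M, M)
        d <- decoupling_vector(W, m)
      }
      y <- as.vector(W[m, ] %*% X)
      k <- kurtosis_sign(y)
      upd <- component_update(W[m, ], X, R[m, ], d, mu[m], cfg_step, m, k)
      W[m, ] <- upd$w
      h[m] <- upd$h
    }
    for (m in seq_len(M)) {
      h[m] <- constraint_value(W[m, ], X, R[m, ],
                               broadcast_par(cfg$threshold, m),
                               cfg$similarity_kind)
    }
    mu <- update_multipliers(mu, h, cfg$penalty)
    dw <- max(abs(W - W_old))
    if (dw < cfg$tol) {
      converged <- TRUE
      break
    }
    if (dw < 0.5 * best_dw) {
      best_dw <- dw
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (stall >= 30L && cfg_step$learning_rate > 1e-4 * cfg$learning_rate) {
      cfg_step$learning_rate <- cfg_step$learning_rate / 2
      stall <- 0L
      best_dw <- dw
    }
  }

  # Resolve the ICA sign ambiguity against the references.
  eps <- numeric(M)
  for (m in seq_len(M)) {
    y <- as.vector(W[m, ] %*% X)
    s <- sqrt(mean((y - mean(y))^2))
    e0 <- if (s < 1e-300) 0 else similarity((y - mean(y)) / s, R[m, ],
                                            cfg$similarity_kind)
    if (cfg$similarity_kind == "correlation" && e0 < 0) {
      W[m, ] <- -W[m, ]
      e0 <- -e0
    }
    eps[m] <- e0
    h[m] <- broadcast_par(cfg$threshold, m) - e0
  }
  Y <- W %*% X
  structure(list(Y = Y, W = W, similarity = eps,
                 constraint_satisfied = h <= cfg$tol_h,
                 mu = mu, h = h, n_iter = n_iter, converged = converged,
                 config = cfg),
            class = "ic_result")
}

#' @export
print.ic_result <- function(x, ...) {
  cat(sprintf("<ic_result> %d components, %d iterations, %s\n",
              nrow(x$Y), x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat("  similarity to references:",
      paste(sprintf("%.3f", x$similarity), collapse = " "), "\n")
  invisible(x)
}
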