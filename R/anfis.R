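#' Initialize a first-order Sugeno ANFIS by grid partition
#'
#' Each input receives `mfs_per_input` Gaussian membership functions with
#' centers at empirical quantiles of the (min-max scaled) training data
#' (the extremes for two MFs) and a common width
#' `sigma = range / (2 (m - 1)) * spread`. The rule base is the full grid of
#' antecedent combinations (`m^d` rules: 64 for six inputs with two MFs
#' each), and all first-order consequents start at zero, so the model has
#' `m^d * (d + 1)` linear parameters (448 for the default architecture) and
#' `2 d m` premise parameters.
#'
#' @param X Numeric matrix or data.frame of inputs (columns are inputs).
#' @param y Response vector (used only for dimension checks here).
#' @param mfs_per_input Number of Gaussian membership functions per input
#'   (default 2; 1 gives the single-rule model that coincides with OLS).
#' @param spread Width multiplier for the Gaussian sigmas.
#' @return An untrained object of class `anfis`.
#' @export
anfis_init <- function(X, y = NULL, mfs_per_input = 2, spread = 1) {
  X <- as.matrix(X)
  d <- ncol(X)
  m <- as.integer(mfs_per_input)
  if (m < 1) stop("mfs_per_input must be at least 1")
  rng <- apply(X, 2, range)
  widths <- rng[2, ] - rng[1, ]
  if (any(widths <= 0)) {
    stop("zero-width input: column(s) ",
         paste(which(widths <= 0), collapse = ", "), " are constant")
  }
  scaling <- list(offset = rng[1, ], scale = widths)
  mf <- vector("list", d)
  for (j in seq_len(d)) {
    centers <- if (m == 1) 0.5 else seq(0, 1, length.out = m)
    sigma <- if (m == 1) 1 else (1 / (2 * (m - 1))) * spread
    mf[[j]] <- list(c = centers, sigma = rep(sigma, m))
  }
  rules <- as.matrix(expand.grid(rep(list(seq_len(m)), d),
                                 KEEP.OUT.ATTRS = FALSE))
  dimnames(rules) <- NULL
  consequents <- matrix(0, nrow = nrow(rules), ncol = d + 1)
  structure(list(n_inputs = d, mfs_per_input = m, mf = mf, rules = rules,
                 consequents = consequents, input_scaling = scaling,
                 input_names = colnames(X), trained = FALSE),
            class = "anfis")
}

.anfis_scale <- function(model, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, model$input_scaling$offset), 2,
        model$input_scaling$scale, "/")
}

# Layers 1-3: memberships, rule firing strengths, normalized strengths.
.anfis_firing <- function(model, Xs) {
  n <- nrow(Xs); d <- model$n_inputs; m <- model$mfs_per_input
  mu <- vector("list", d)
  for (j in seq_len(d)) {
    cj <- model$mf[[j]]$c; sj <- model$mf[[j]]$sigma
    mu[[j]] <- exp(-(outer(Xs[, j], cj, "-"))^2 /
                     matrix(2 * sj^2, n, m, byrow = TRUE))
  }
  R <- nrow(model$rules)
  W <- matrix(1, n, R)
  for (j in seq_len(d)) W <- W * mu[[j]][, model$rules[, j], drop = FALSE]
  S <- rowSums(W)
  Wbar <- W / S
  bad <- S < 1e-300
  if (any(bad)) Wbar[bad, ] <- 1 / R
  list(mu = mu, W = W, S = pmax(S, 1e-300), Wbar = Wbar)
}

#' Forward pass of a Sugeno ANFIS
#'
#' Five-layer evaluation: Gaussian memberships, product firing strengths,
#' normalization, first-order rule outputs
#' `f_r = p_{r,0} + sum_j p_{r,j} x_j` (on scaled inputs), and the weighted
#' average `sum_r wbar_r f_r`. When all firing strengths underflow, the
#' normalized weights fall back to uniform.
#'
#' @param model An `anfis` object.
#' @param X New inputs (matrix/data.frame in original units, or a single row
#'   vector).
#' @return Predicted response vector.
#' @export
anfis_forward <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Xs <- .anfis_scale(model, X)
  fir <- .anfis_firing(model, Xs)
  Fmat <- cbind(Xs, 1) %*% t(model$consequents)  # n x R rule outputs
  rowSums(fir$Wbar * Fmat)
}

# Ridge least squares for all consequents jointly; dual form when the system
# is underdetermined (fewer rows than consequent parameters).
.anfis_lse <- function(Phi, y, ridge) {
  p <- ncol(Phi); n <- nrow(Phi)
  if (n >= p) {
    A <- crossprod(Phi) + diag(ridge, p)
    solve(A, crossprod(Phi, y))
  } else {
    A <- tcrossprod(Phi) + diag(ridge, n)
    crossprod(Phi, solve(A, y))
  }
}

.anfis_design <- function(Xs, Wbar) {
  n <- nrow(Xs); d <- ncol(Xs); R <- ncol(Wbar)
  Xa <- cbind(Xs, 1)
  Phi <- matrix(0, n, R * (d + 1))
  for (r in seq_len(R)) {
    Phi[, ((r - 1) * (d + 1) + 1):(r * (d + 1))] <- Wbar[, r] * Xa
  }
  Phi
}

# Analytic gradient of the training SSE with respect to premise parameters.
.anfis_premise_grad <- function(model, Xs, y, fir, Fmat, yhat) {
  d <- model$n_inputs; m <- model$mfs_per_input
  e <- yhat - y
  # A[n, r] = e_n * (f_nr - yhat_n) * w_nr / S_n
  A <- (e / fir$S) * (Fmat - yhat) * fir$W
  gc_ <- matrix(0, d, m); gs_ <- matrix(0, d, m)
  for (j in seq_len(d)) {
    cj <- model$mf[[j]]$c; sj <- model$mf[[j]]$sigma
    for (k in seq_len(m)) {
      sel <- model$rules[, j] == k
      if (!any(sel)) next
      B <- rowSums(A[, sel, drop = FALSE])  # n-vector
      z <- Xs[, j] - cj[k]
      gc_[j, k] <- 2 * sum(B * z / sj[k]^2)
      gs_[j, k] <- 2 * sum(B * z^2 / sj[k]^3)
    }
  }
  list(gc = gc_, gs = gs_)
}

#' Train an ANFIS by hybrid learning
#'
#' Each epoch performs (a) a least-squares estimation of all rule consequents
#' jointly, from the design matrix of normalized firing strengths times the
#' augmented inputs, with a small ridge term for numerical stability, and
#' (b) one batch gradient-descent step on the Gaussian premise parameters
#' (centers and widths) against the training SSE, with Jang-style step-size
#' adaptation (x1.1 after an improving epoch, x0.5 after a worsening one).
#' Consequents are only accepted when they do not increase the training SSE,
#' and sigmas are floored at 1e-4.
#'
#' @param model An `anfis` from [anfis_init()].
#' @param X,y Training inputs and response.
#' @param epochs Training epochs (default 30).
#' @param holdout Fraction held out for validation (default 0.25, stratified
#'   by response level); 0 disables the holdout.
#' @param seed Integer seed controlling the row shuffling and the holdout
#'   split (default 42).
#' @param lr Initial step size along the normalized gradient (default 0.01).
#' @param ridge Ridge term of the consequent update (default 1e-8).
#' @return The trained `anfis` with `history` (per-epoch train/holdout RMSE),
#'   `holdout_idx`, `r2_holdout`, `lr_final`.
#' @export
anfis_train <- function(model, X, y, epochs = 30, holdout = 0.25, seed = 42,
                        lr = 0.01, ridge = 1e-8) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y are not aligned")
  set.seed(as.integer(seed))
  n <- nrow(X)
  ord <- sample.int(n)  # randomized presentation order
  X <- X[ord, , drop = FALSE]; y <- y[ord]

  hold_idx <- integer(0)
  if (holdout > 0) {
    strata <- if (length(unique(y)) <= 10) factor(y) else
      cut(y, stats::quantile(y, seq(0, 1, 0.25)), include.lowest = TRUE)
    hold_idx <- unlist(lapply(split(seq_len(n), strata), function(ix) {
      k <- max(1, round(length(ix) * holdout))
      if (length(ix) <= 1) return(integer(0))
      sample(ix, k)
    }), use.names = FALSE)
  }
  tr <- setdiff(seq_len(n), hold_idx)
  Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
  Xho <- X[hold_idx, , drop = FALSE]; yho <- y[hold_idx]

  Xs <- .anfis_scale(model, Xtr)
  history <- data.frame(epoch = integer(0), train_rmse = numeric(0),
                        holdout_rmse = numeric(0))
  sse_prev <- Inf
  for (ep in seq_len(epochs)) {
    fir <- .anfis_firing(model, Xs)
    # SSE before the consequent update, under the current consequents
    Fmat <- cbind(Xs, 1) %*% t(model$consequents)
    sse_before <- sum((rowSums(fir$Wbar * Fmat) - ytr)^2)
    Phi <- .anfis_design(Xs, fir$Wbar)
    beta <- .anfis_lse(Phi, ytr, ridge)
    cons_new <- matrix(beta, nrow = nrow(model$rules),
                       ncol = model$n_inputs + 1, byrow = TRUE)
    Fnew <- cbind(Xs, 1) %*% t(cons_new)
    yhat <- rowSums(fir$Wbar * Fnew)
    sse_after <- sum((yhat - ytr)^2)
    if (sse_after <= sse_before) {
      model$consequents <- cons_new
      Fmat <- Fnew
    } else {  # keep previous consequents; never worsen the fit
      yhat <- rowSums(fir$Wbar * Fmat)
      sse_after <- sse_before
    }
    if (!is.finite(sse_after)) {
      stop("non-finite training loss at epoch ", ep,
           "; sigma floor or ridge too small for this data")
    }

    # premise update: one normalized gradient step
    gr <- .anfis_premise_grad(model, Xs, ytr, fir, Fmat, yhat)
    gnorm <- sqrt(sum(gr$gc^2) + sum(gr$gs^2))
    if (gnorm > 0 && ep < epochs) {
      for (j in seq_len(model$n_inputs)) {
        model$mf[[j]]$c <- model$mf[[j]]$c - lr * gr$gc[j, ] / gnorm
        model$mf[[j]]$sigma <- pmax(model$mf[[j]]$sigma -
                                      lr * gr$gs[j, ] / gnorm, 1e-4)
      }
    }
    lr <- if (sse_after < sse_prev) lr * 1.1 else lr * 0.5
    sse_prev <- sse_after

    ho_rmse <- if (length(hold_idx)) {
      sqrt(mean((anfis_forward(model, Xho) - yho)^2))
    } else NA_real_
    history <- rbind(history, data.frame(
      epoch = ep, train_rmse = sqrt(sse_after / length(ytr)),
      holdout_rmse = ho_rmse))
  }
  model$trained <- TRUE
  model$history <- history
  model$holdout_idx <- ord[hold_idx]
  model$lr_final <- lr
  if (length(hold_idx)) {
    pred <- anfis_forward(model, Xho)
    model$r2_holdout <- 1 - sum((yho - pred)^2) / sum((yho - mean(yho))^2)
  } else {
    model$r2_holdout <- NA_real_
  }
  model
}

#' Fit a Sugeno ANFIS to data
#'
#' Convenience wrapper combining [anfis_init()] and [anfis_train()], with a
#' formula interface. The model is a first-order Sugeno fuzzy system with
#' Gaussian membership functions, grid-partition rule base and hybrid
#' least-squares/gradient learning.
#'
#' @param formula Model formula, e.g. `sha ~ st + pp + sv + hr + w + crest`.
#' @param data Data frame holding the variables.
#' @param mfs_per_input Gaussian membership functions per input (default 2).
#' @param epochs Training epochs (default 30).
#' @param holdout Validation fraction (default 0.25).
#' @param seed Seed for the shuffle and split (default 42).
#' @param ... Passed to [anfis_train()].
#' @return A trained `anfis` object.
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = runif(60), x2 = runif(60))
#' d$y <- 2 * d$x1 - d$x2 + rnorm(60, 0, 0.05)
#' m <- anfis(y ~ x1 + x2, d, epochs = 5)
#' m$r2_holdout
#' @export
anfis <- function(formula, data, mfs_per_input = 2, epochs = 30,
                  holdout = 0.25, seed = 42, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  model <- anfis_init(X, y, mfs_per_input = mfs_per_input)
  model <- anfis_train(model, X, y, epochs = epochs, holdout = holdout,
                       seed = seed, ...)
  model$call <- match.call()
  model$terms <- attr(mf, "terms")
  model
}

#' @export
print.anfis <- function(x, ...) {
  R <- nrow(x$rules)
  cat("Sugeno ANFIS:", x$n_inputs, "inputs,", x$mfs_per_input,
      "Gaussian MFs/input,", R, "rules\n")
  cat("  linear (consequent) parameters:", length(x$consequents),
      "; premise parameters:", 2 * x$n_inputs * x$mfs_per_input, "\n")
  if (isTRUE(x$trained)) {
    cat(sprintf("  trained %d epochs; final train RMSE %.4g",
                nrow(x$history), utils::tail(x$history$train_rmse, 1)))
    if (is.finite(x$r2_holdout)) {
      cat(sprintf("; holdout R^2 %.3f", x$r2_holdout))
    }
    cat("\n")
  } else cat("  (untrained)\n")
  invisible(x)
}

#' @export
summary.anfis <- function(object, ...) {
  print(object)
  if (isTRUE(object$trained)) {
    cat("\nPer-epoch error history:\n")
    print(utils::head(object$history, 10))
    if (nrow(object$history) > 10) cat("  ...\n")
  }
  invisible(object)
}

#' @export
coef.anfis <- function(object, ...) {
  list(membership = object$mf, consequents = object$consequents,
       rules = object$rules)
}

#' @export
predict.anfis <- function(object, newdata, ...) {
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata)
    X <- stats::model.matrix(tt, mf)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  } else {
    X <- as.matrix(newdata)
  }
  anfis_forward(object, X)
}

#' @export
residuals.anfis <- function(object, X, y, ...) {
  y - anfis_forward(object, X)
}

#' Plot ANFIS membership functions and training history
#'
#' @param x A trained `anfis`.
#' @param which `"mf"` for membership functions (scaled input domain) or
#'   `"history"` for the per-epoch RMSE curves.
#' @param ... Passed to plotting primitives.
#' @export
plot.anfis <- function(x, which = c("mf", "history"), ...) {
  which <- match.arg(which)
  if (which == "mf") {
    d <- x$n_inputs
    op <- graphics::par(mfrow = c(ceiling(d / 2), 2), mar = c(3, 3, 2, 1))
    on.exit(graphics::par(op))
    z <- seq(-0.2, 1.2, length.out = 200)
    for (j in seq_len(d)) {
      graphics::plot(NULL, xlim = range(z), ylim = c(0, 1),
                     xlab = "", ylab = "",
                     main = x$input_names[j] %||% paste("input", j))
      for (k in seq_len(x$mfs_per_input)) {
        graphics::lines(z, exp(-(z - x$mf[[j]]$c[k])^2 /
                                 (2 * x$mf[[j]]$sigma[k]^2)), col = k)
      }
    }
  } else {
    if (!isTRUE(x$trained)) stop("model is untrained")
    h <- x$history
    graphics::plot(h$epoch, h$train_rmse, type = "b", pch = 16,
                   xlab = "epoch", ylab = "RMSE", ...)
    if (any(is.finite(h$holdout_rmse))) {
      graphics::lines(h$epoch, h$holdout_rmse, type = "b", col = 2, pch = 1)
      graphics::legend("topright", c("train", "holdout"), col = 1:2,
                       pch = c(16, 1), bty = "n")
    }
  }
  invisible(x)
}
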