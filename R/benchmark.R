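#' Snap a continuous prediction to the nearest ordinal class
#'
#' Nearest value on the discrete Shore A grid; exact midpoints round to the
#' higher class and out-of-range values clamp to the nearest endpoint.
#'
#' @param value Numeric prediction(s).
#' @param grid Sorted class grid (default `c(10, 20, 30, 40, 50)`).
#' @return Snapped class value(s).
#' @examples
#' snap_to_class(c(23.4, 25, 57))  # 20 30 50
#' @export
snap_to_class <- function(value, grid = c(10, 20, 30, 40, 50)) {
  if (length(grid) == 0) stop("class grid is empty")
  grid <- sort(grid)
  vapply(value, function(v) {
    d <- abs(grid - v)
    cand <- which(d == min(d))
    grid[max(cand)]  # midpoint ties go to the higher class
  }, numeric(1))
}

#' Classification metrics for ordinal hardness prediction
#'
#' Macro-averaged one-vs-rest F1, sensitivity (recall) and specificity, with
#' the zero-division convention that an undefined per-class precision/recall
#' contributes 0. MAE and RMSE treat the class labels as numeric Shore A
#' values.
#'
#' @param y_true,y_pred Aligned label vectors.
#' @param classes The full class set (defaults to the union observed).
#' @return A list: `f1_macro`, `sens_macro`, `spec_macro`, `mae_sha`,
#'   `rmse_sha`.
#' @export
classification_metrics <- function(y_true, y_pred,
                                   classes = sort(unique(c(y_true, y_pred)))) {
  if (length(y_true) != length(y_pred)) stop("label vectors are not aligned")
  if (!all(y_true %in% classes) || !all(y_pred %in% classes)) {
    stop("labels outside the declared class set")
  }
  f1 <- sens <- spec <- numeric(length(classes))
  for (i in seq_along(classes)) {
    k <- classes[i]
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    tn <- sum(y_true != k & y_pred != k)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    sens[i] <- rec
    spec[i] <- if (tn + fp > 0) tn / (tn + fp) else 0
  }
  list(f1_macro = mean(f1), sens_macro = mean(sens), spec_macro = mean(spec),
       mae_sha = mean(abs(y_true - y_pred)),
       rmse_sha = sqrt(mean((y_true - y_pred)^2)))
}

#' Stratified k-fold assignment
#'
#' @param y Class labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer fold id per observation; every class appears in every
#'   fold's training portion.
#' @export
stratified_folds <- function(y, k = 5, seed = 1) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ix <- which(y == cls)
    if (length(ix) < k) {
      stop("class ", cls, " has fewer members than folds")
    }
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  fold
}

# ---- small dense MLP engine (softmax / CORAL / MC-dropout) -----------------

.mlp_init <- function(sizes, seed) {
  set.seed(as.integer(seed))
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

.mlp_forward <- function(par, X, dropout = 0, train_mode = FALSE) {
  L <- length(par$W)
  a <- X
  cache <- list(a)
  for (l in seq_len(L - 1)) {
    z <- sweep(a %*% par$W[[l]], 2, par$b[[l]], "+")
    a <- pmax(z, 0)  # ReLU
    if (dropout > 0 && train_mode) {
      mask <- matrix(stats::rbinom(length(a), 1, 1 - dropout) / (1 - dropout),
                     nrow(a), ncol(a))
      a <- a * mask
    }
    cache[[l + 1]] <- a
  }
  logits <- sweep(a %*% par$W[[L]], 2, par$b[[L]], "+")
  list(logits = logits, cache = cache)
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Backprop given the gradient of the loss w.r.t. the logits.
.mlp_backward <- function(par, cache, dlogits) {
  L <- length(par$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dlogits
  for (l in L:1) {
    gW[[l]] <- crossprod(cache[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(par$W[[l]])) * (cache[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

# Adam with early stopping on an inner stratified split.
.mlp_train <- function(X, y, task = c("softmax", "coral"), classes,
                       hidden = c(32, 16), dropout = 0, epochs = 500,
                       lr = 1e-2, patience = 20, seed = 1) {
  task <- match.arg(task)
  set.seed(as.integer(seed))
  K <- length(classes)
  ycls <- match(y, classes)
  # inner stratified 80/20 early-stopping split
  val <- unlist(lapply(split(seq_along(y), ycls), function(ix) {
    if (length(ix) < 2) return(integer(0))
    sample(ix, max(1, round(0.2 * length(ix))))
  }), use.names = FALSE)
  tr <- setdiff(seq_along(y), val)
  out_dim <- if (task == "softmax") K else K - 1
  par <- .mlp_init(c(ncol(X), hidden, out_dim), seed)
  if (task == "coral") {
    # shared weight vector with independent ordered biases: collapse the
    # output weight matrix to one column replicated across the K-1 logits
    L <- length(par$W)
    par$W[[L]] <- matrix(par$W[[L]][, 1], nrow(par$W[[L]]), out_dim)
  }
  mom <- lapply(par, function(g) lapply(g, function(m) m * 0))
  vel <- lapply(par, function(g) lapply(g, function(m) m * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, par = par, wait = 0)
  loss_fn <- function(par, ix, train_mode = FALSE) {
    fw <- .mlp_forward(par, X[ix, , drop = FALSE], dropout, train_mode)
    if (task == "softmax") {
      P <- .softmax(fw$logits)
      ll <- -mean(log(pmax(P[cbind(seq_along(ix), ycls[ix])], 1e-12)))
      dlog <- P
      dlog[cbind(seq_along(ix), ycls[ix])] <-
        dlog[cbind(seq_along(ix), ycls[ix])] - 1
      dlog <- dlog / length(ix)
    } else {
      tgt <- outer(ycls[ix], seq_len(K - 1), ">")  # cumulative binary targets
      P <- 1 / (1 + exp(-fw$logits))
      ll <- -mean(tgt * log(pmax(P, 1e-12)) +
                    (1 - tgt) * log(pmax(1 - P, 1e-12)))
      dlog <- (P - tgt) / length(ix) / (K - 1)
    }
    list(loss = ll, dlogits = dlog, cache = fw$cache)
  }
  t_step <- 0
  for (ep in seq_len(epochs)) {
    fw <- loss_fn(par, tr, train_mode = dropout > 0)
    gr <- .mlp_backward(par, fw$cache, fw$dlogits)
    if (task == "coral") {
      L <- length(par$W)
      shared <- rowMeans(gr$W[[L]])
      gr$W[[L]] <- matrix(shared, length(shared), ncol(gr$W[[L]]))
    }
    t_step <- t_step + 1
    for (g in c("W", "b")) {
      for (l in seq_along(par[[g]])) {
        mom[[g]][[l]] <- beta1 * mom[[g]][[l]] + (1 - beta1) * gr[[g]][[l]]
        vel[[g]][[l]] <- beta2 * vel[[g]][[l]] + (1 - beta2) * gr[[g]][[l]]^2
        mhat <- mom[[g]][[l]] / (1 - beta1^t_step)
        vhat <- vel[[g]][[l]] / (1 - beta2^t_step)
        par[[g]][[l]] <- par[[g]][[l]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    if (length(val)) {
      vloss <- loss_fn(par, val)$loss
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, par = par, wait = 0)
      } else {
        best$wait <- best$wait + 1
        if (best$wait >= patience) break
      }
    } else best$par <- par
  }
  list(par = best$par, task = task, classes = classes, dropout = dropout)
}

.mlp_predict_class <- function(fit, X, mc_passes = 0, seed = 1) {
  K <- length(fit$classes)
  if (mc_passes > 0) {
    set.seed(as.integer(seed))
    acc <- 0
    for (i in seq_len(mc_passes)) {
      fw <- .mlp_forward(fit$par, X, fit$dropout, train_mode = TRUE)
      acc <- acc + (if (fit$task == "softmax") .softmax(fw$logits)
                    else 1 / (1 + exp(-fw$logits)))
    }
    out <- acc / mc_passes
  } else {
    fw <- .mlp_forward(fit$par, X, 0, train_mode = FALSE)
    out <- if (fit$task == "softmax") .softmax(fw$logits) else
      1 / (1 + exp(-fw$logits))
  }
  if (fit$task == "softmax") {
    fit$classes[max.col(out, ties.method = "first")]
  } else {
    fit$classes[1 + rowSums(out > 0.5)]
  }
}

#' CORAL ordinal head: cumulative probabilities and predicted class
#'
#' K-1 binary logits sharing one weight vector with independent ordered
#' biases give cumulative probabilities `P(y > k)`; the predicted class index
#' is one plus the number of cumulative probabilities above 0.5.
#'
#' @param logits Matrix (or vector) of K-1 logits per observation.
#' @param classes Ordered class values, length K.
#' @return A list with `cum_prob` (matrix) and `class` (predicted values).
#' @examples
#' coral_head(c(2, -2), classes = c(10, 20, 30))$class  # middle class
#' @export
coral_head <- function(logits, classes) {
  if (length(classes) < 2) stop("need at least 2 classes")
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  if (ncol(logits) != length(classes) - 1) {
    stop("need K-1 logits per observation")
  }
  p <- 1 / (1 + exp(-logits))
  # enforce monotone non-increasing cumulative probabilities
  p <- t(apply(p, 1, cummin))
  if (nrow(logits) == 1) p <- matrix(p, nrow = 1)
  list(cum_prob = p, class = classes[1 + rowSums(p > 0.5)])
}

# ---- model family wrappers -------------------------------------------------

.poly2_expand <- function(X) {
  d <- ncol(X)
  out <- X
  nms <- colnames(X)
  for (i in seq_len(d)) for (j in i:d) {
    out <- cbind(out, X[, i] * X[, j])
    nms <- c(nms, paste0(colnames(X)[i], ":", colnames(X)[j]))
  }
  colnames(out) <- nms
  out
}

.bench_families <- function() {
  c("ML_LogReg", "ML_SVC_RBF", "ML_kNN", "ML_RF", "ML_HistGB",
    "ML_RidgeSnap", "ML_Poly_RidgeSnap", "ML_Poly_LassoSnap",
    "ML_SVR_RBF_Snap", "ML_RF_Reg_Snap", "ML_HistGB_Reg_Snap",
    "DL_MLP_softmax", "DL_Ordinal_CORAL", "DL_MC_Dropout_MLP")
}

# Train on (Xtr, ytr), predict class labels for Xte. All inputs already
# standardized with training-fold statistics.
.bench_fit_predict <- function(name, Xtr, ytr, Xte, classes, seed) {
  set.seed(as.integer(seed))
  yf <- factor(ytr, levels = classes)
  snap <- function(v) snap_to_class(v, classes)
  switch(name,
    ML_LogReg = {
      fit <- nnet::multinom(y ~ ., data = data.frame(Xtr, y = yf),
                            trace = FALSE, maxit = 200)
      as.numeric(as.character(stats::predict(fit, data.frame(Xte))))
    },
    ML_SVC_RBF = {
      fit <- e1071::svm(Xtr, yf, kernel = "radial")
      as.numeric(as.character(stats::predict(fit, Xte)))
    },
    ML_kNN = {
      k <- max(3, min(5, length(ytr) - 1))
      as.numeric(as.character(class::knn(Xtr, Xte, yf, k = k)))
    },
    ML_RF = {
      fit <- randomForest::randomForest(Xtr, yf, ntree = 300)
      as.numeric(as.character(stats::predict(fit, Xte)))
    },
    ML_HistGB = {
      fit <- xgboost::xgboost(Xtr, yf, nrounds = 80, max_depth = 3,
                              learning_rate = 0.2, tree_method = "hist",
                              nthreads = 1, seed = seed %% 100000)
      pr <- stats::predict(fit, Xte)
      as.numeric(colnames(pr)[max.col(pr, ties.method = "first")])
    },
    ML_RidgeSnap = {
      fit <- glmnet::cv.glmnet(Xtr, ytr, alpha = 0, nfolds = 4)
      snap(as.numeric(stats::predict(fit, Xte, s = "lambda.min")))
    },
    ML_Poly_RidgeSnap = {
      fit <- glmnet::cv.glmnet(.poly2_expand(Xtr), ytr, alpha = 0, nfolds = 4)
      snap(as.numeric(stats::predict(fit, .poly2_expand(Xte), s = "lambda.min")))
    },
    ML_Poly_LassoSnap = {
      fit <- glmnet::cv.glmnet(.poly2_expand(Xtr), ytr, alpha = 1, nfolds = 4)
      snap(as.numeric(stats::predict(fit, .poly2_expand(Xte), s = "lambda.min")))
    },
    ML_SVR_RBF_Snap = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", type = "eps-regression")
      snap(as.numeric(stats::predict(fit, Xte)))
    },
    ML_RF_Reg_Snap = {
      fit <- randomForest::randomForest(Xtr, ytr, ntree = 300)
      snap(as.numeric(stats::predict(fit, Xte)))
    },
    ML_HistGB_Reg_Snap = {
      fit <- xgboost::xgboost(Xtr, ytr, nrounds = 80, max_depth = 3,
                              learning_rate = 0.2, tree_method = "hist",
                              nthreads = 1, seed = seed %% 100000)
      snap(as.numeric(stats::predict(fit, Xte)))
    },
    DL_MLP_softmax = {
      fit <- .mlp_train(Xtr, ytr, "softmax", classes, seed = seed)
      .mlp_predict_class(fit, Xte)
    },
    DL_Ordinal_CORAL = {
      fit <- .mlp_train(Xtr, ytr, "coral", classes, seed = seed)
      .mlp_predict_class(fit, Xte)
    },
    DL_MC_Dropout_MLP = {
      fit <- .mlp_train(Xtr, ytr, "softmax", classes, dropout = 0.2,
                        seed = seed)
      .mlp_predict_class(fit, Xte, mc_passes = 100, seed = seed)
    },
    stop("unknown model family: ", name)
  )
}

#' Benchmark model families for hardness-level prediction
#'
#' Stratified 5-fold cross-validation over the chosen scenario
#' (`FULL_10_50`: five Shore A classes; `LOW_10_30`: the three softest).
#' Features are standardized within each training fold, out-of-fold
#' predictions are pooled, and metrics are computed once per model family
#' over the pooled predictions. Regression-family predictions are snapped to
#' the nearest class on the scenario grid.
#'
#' @param features A [feature_table()] (must contain `sha` plus the base and
#'   engineered feature columns).
#' @param scenario `"FULL_10_50"` or `"LOW_10_30"`.
#' @param seed Integer seed fixing fold assignment and every stochastic
#'   learner.
#' @param models Character vector of family names (default: all 14).
#' @param k Number of folds (default 5).
#' @return A data.frame of class `benchmark_result`: one row per model with
#'   `scenario`, `model_name`, `f1_macro`, `sens_macro`, `spec_macro`,
#'   `mae_sha`, `rmse_sha`, `seed`.
#' @export
run_benchmark <- function(features, scenario = c("FULL_10_50", "LOW_10_30"),
                          seed = 1, models = .bench_families(), k = 5) {
  scenario <- match.arg(scenario)
  classes <- if (scenario == "FULL_10_50") c(10, 20, 30, 40, 50) else
    c(10, 20, 30)
  dat <- features[features$sha %in% classes, , drop = FALSE]
  feat_cols <- c("sv", "hr", "w", "crest_pct", "systole_pct", "pp",
                 engineered_feature_names())
  feat_cols <- intersect(feat_cols, names(dat))
  X <- as.matrix(dat[, feat_cols])
  y <- dat$sha
  fold <- stratified_folds(y, k, seed)
  results <- vector("list", length(models))
  for (mi in seq_along(models)) {
    pred <- numeric(length(y))
    for (f in seq_len(k)) {
      te <- fold == f; tr <- !te
      mu <- colMeans(X[tr, , drop = FALSE])
      sd_ <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sd_[sd_ == 0] <- 1
      Xtr <- scale(X[tr, , drop = FALSE], mu, sd_)
      Xte <- scale(X[te, , drop = FALSE], mu, sd_)
      pred[te] <- .bench_fit_predict(models[mi], Xtr, y[tr], Xte, classes,
                                     seed = seed * 1000 + f)
    }
    m <- classification_metrics(y, snap_to_class(pred, classes), classes)
    results[[mi]] <- data.frame(scenario = scenario,
                                model_name = models[mi],
                                f1_macro = m$f1_macro,
                                sens_macro = m$sens_macro,
                                spec_macro = m$spec_macro,
                                mae_sha = m$mae_sha,
                                rmse_sha = m$rmse_sha,
                                seed = seed)
  }
  out <- do.call(rbind, results)
  class(out) <- c("benchmark_result", "data.frame")
  out
}
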