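# The candidate-regressor registry. Each entry provides
#   sample_config(default)  -> named list of hyperparameters
#   fit(X, y, cfg, seed)    -> opaque model
#   predict(model, X)       -> numeric vector
# X is the scaled selected-feature matrix. All fits are deterministic given
# (X, y, cfg, seed). The suite mirrors the standard QSRR toolbox: an
# RBF-kernel method, linear/regularized linear, k-NN, two tree ensembles and
# a small neural network.

# ---- linear ridge (closed form; lambda = 0 is exact OLS) ----

fit_ridge <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (lambda <= 0) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    list(type = "ridge", intercept = beta[1], beta = beta[-1])
  } else {
    mu <- mean(y)
    A <- crossprod(X) + diag(lambda, ncol(X))
    b <- crossprod(X, y - mu)
    beta <- drop(solve(A, b))
    list(type = "ridge", intercept = mu, beta = beta)
  }
}

predict_ridge <- function(model, X) {
  drop(as.matrix(X) %*% model$beta) + model$intercept
}

# ---- RBF kernel ridge regression ----

sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}

fit_krr <- function(X, y, gamma, lambda) {
  X <- as.matrix(X)
  K <- exp(-gamma * sqdist(X, X))
  mu <- mean(y)
  alpha <- solve(K + diag(lambda, nrow(K)), y - mu)
  list(type = "krr", X = X, alpha = drop(alpha), gamma = gamma, intercept = mu)
}

predict_krr <- function(model, X) {
  K <- exp(-model$gamma * sqdist(as.matrix(X), model$X))
  drop(K %*% model$alpha) + model$intercept
}

# ---- regression stumps and gradient boosting ----

# Best single split of `r` over columns of X; ord is the list of per-column
# sort orders (precomputed once per training matrix).
best_stump <- function(X, r, ord, min_leaf = 3L) {
  n <- length(r)
  best <- list(gain = -Inf)
  for (j in seq_len(ncol(X))) {
    o <- ord[[j]]
    x <- X[o, j]
    rs <- cumsum(r[o])
    tot <- rs[n]
    nl <- seq_len(n - 1)
    valid <- which(x[nl] < x[nl + 1] & nl >= min_leaf & (n - nl) >= min_leaf)
    if (!length(valid)) next
    sl <- rs[valid]
    gain <- sl^2 / valid + (tot - sl)^2 / (n - valid) - tot^2 / n
    b <- which.max(gain)
    if (gain[b] > best$gain) {
      i <- valid[b]
      best <- list(
        gain = gain[b], feature = j,
        threshold = (x[i] + x[i + 1]) / 2,
        left = sl[b] / i, right = (tot - sl[b]) / (n - i)
      )
    }
  }
  if (!is.finite(best$gain)) return(NULL)
  best
}

fit_gbs <- function(X, y, n_rounds, shrinkage) {
  X <- as.matrix(X)
  ord <- lapply(seq_len(ncol(X)), function(j) order(X[, j]))
  f0 <- mean(y)
  f <- rep(f0, length(y))
  stumps <- matrix(NA_real_, nrow = n_rounds, ncol = 4,
                   dimnames = list(NULL, c("feature", "threshold", "left", "right")))
  used <- 0L
  for (t in seq_len(n_rounds)) {
    s <- best_stump(X, y - f, ord)
    if (is.null(s)) break
    used <- used + 1L
    stumps[used, ] <- c(s$feature, s$threshold, s$left, s$right)
    f <- f + shrinkage * ifelse(X[, s$feature] <= s$threshold, s$left, s$right)
  }
  list(type = "gbs", f0 = f0, shrinkage = shrinkage,
       stumps = stumps[seq_len(used), , drop = FALSE])
}

predict_gbs <- function(model, X) {
  X <- as.matrix(X)
  f <- rep(model$f0, nrow(X))
  S <- model$stumps
  for (t in seq_len(nrow(S))) {
    f <- f + model$shrinkage *
      ifelse(X[, S[t, "feature"]] <= S[t, "threshold"], S[t, "left"], S[t, "right"])
  }
  f
}

# ---- depth-limited CART and bagging ----

fit_cart <- function(X, y, max_depth, min_split = 10L) {
  nodes <- list()
  grow <- function(idx, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(value = mean(y[idx])) # placeholder; may become a split
    if (depth >= max_depth || length(idx) < min_split ||
        max(y[idx]) - min(y[idx]) == 0) {
      return(id)
    }
    Xs <- X[idx, , drop = FALSE]
    ord <- lapply(seq_len(ncol(Xs)), function(j) order(Xs[, j]))
    s <- best_stump(Xs, y[idx], ord)
    if (is.null(s)) return(id)
    left <- idx[X[idx, s$feature] <= s$threshold]
    right <- setdiff(idx, left)
    if (!length(left) || !length(right)) return(id)
    lid <- grow(left, depth + 1L)
    rid <- grow(right, depth + 1L)
    nodes[[id]] <<- list(feature = s$feature, threshold = s$threshold,
                         left = lid, right = rid)
    id
  }
  root <- grow(seq_along(y), 0L)
  list(nodes = nodes, root = root)
}

predict_cart <- function(tree, X) {
  X <- as.matrix(X)
  out <- numeric(nrow(X))
  walk <- function(id, rows) {
    nd <- tree$nodes[[id]]
    if (!is.null(nd$value)) {
      out[rows] <<- nd$value
      return(invisible())
    }
    go_left <- X[rows, nd$feature] <= nd$threshold
    if (any(go_left)) walk(nd$left, rows[go_left])
    if (any(!go_left)) walk(nd$right, rows[!go_left])
  }
  walk(tree$root, seq_len(nrow(X)))
  out
}

fit_bag <- function(X, y, n_trees, max_depth, seed) {
  X <- as.matrix(X)
  n <- nrow(X)
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    fit_cart(X[idx, , drop = FALSE], y[idx], max_depth = max_depth)
  }))
  list(type = "bag", trees = trees)
}

predict_bag <- function(model, X) {
  preds <- sapply(model$trees, function(tr) predict_cart(tr, X))
  if (is.null(dim(preds))) return(mean(preds))
  rowMeans(preds)
}

# ---- single-hidden-layer MLP (tanh, BFGS, weight decay) ----

fit_mlp <- function(X, y, hidden, decay, maxit, seed) {
  X <- as.matrix(X)
  p <- ncol(X)
  mu_y <- mean(y)
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  ys <- (y - mu_y) / sd_y
  h <- hidden
  npar <- p * h + h + h + 1
  unpack <- function(w) {
    list(
      W1 = matrix(w[seq_len(p * h)], p, h),
      b1 = w[p * h + seq_len(h)],
      w2 = w[p * h + h + seq_len(h)],
      b2 = w[npar]
    )
  }
  fwd <- function(pm, X) {
    Z <- tanh(sweep(X %*% pm$W1, 2, pm$b1, "+"))
    list(Z = Z, yhat = drop(Z %*% pm$w2) + pm$b2)
  }
  obj <- function(w) {
    pm <- unpack(w)
    f <- fwd(pm, X)
    e <- f$yhat - ys
    mean(e^2) / 2 + decay * (sum(pm$W1^2) + sum(pm$w2^2)) / 2
  }
  grad <- function(w) {
    pm <- unpack(w)
    f <- fwd(pm, X)
    n <- length(ys)
    e <- (f$yhat - ys) / n
    gw2 <- drop(crossprod(f$Z, e)) + decay * pm$w2
    gb2 <- sum(e)
    D <- (e %o% pm$w2) * (1 - f$Z^2)
    gW1 <- crossprod(X, D) + decay * pm$W1
    gb1 <- colSums(D)
    c(as.vector(gW1), gb1, gw2, gb2)
  }
  w0 <- with_seed(seed, stats::runif(npar, -0.5, 0.5))
  opt <- stats::optim(w0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  list(type = "mlp", w = opt$par, p = p, h = h, mu_y = mu_y, sd_y = sd_y,
       unpacker = NULL)
}

predict_mlp <- function(model, X) {
  X <- as.matrix(X)
  p <- model$p
  h <- model$h
  w <- model$w
  W1 <- matrix(w[seq_len(p * h)], p, h)
  b1 <- w[p * h + seq_len(h)]
  w2 <- w[p * h + h + seq_len(h)]
  b2 <- w[p * h + h + h + 1]
  Z <- tanh(sweep(X %*% W1, 2, b1, "+"))
  (drop(Z %*% w2) + b2) * model$sd_y + model$mu_y
}

# ---- registry ----

#' The candidate-algorithm registry
#'
#' Seven regression families evaluated per compound class; the global
#' validation-MAE argmin over (algorithm, hyperparameter configuration)
#' becomes that class's expert submodel. Each entry exposes
#' `sample_config(default)`, `fit(X, y, cfg, seed)` and `predict(model, X)`,
#' so the registry is pluggable: pass a subset (or a superset) to
#' [train_submodel()] / [train_ensemble()].
#'
#' @param names optional character vector restricting the registry.
#' @return named list of registry entries.
#' @export
default_registry <- function(names = NULL) {
  reg <- list(
    svr_rbf = list( # RBF kernel ridge: the kernel-machine family
      sample_config = function(default = FALSE) {
        if (default) return(list(gamma = 0.01, lambda = 0.1))
        list(gamma = 10^stats::runif(1, -3, 0), lambda = 10^stats::runif(1, -3, 1))
      },
      fit = function(X, y, cfg, seed) fit_krr(X, y, cfg$gamma, cfg$lambda),
      predict = predict_krr
    ),
    random_forest = list( # bagged depth-limited CART
      sample_config = function(default = FALSE) {
        if (default) return(list(n_trees = 25L, max_depth = 4L))
        list(n_trees = sample(c(15L, 25L, 40L), 1), max_depth = sample(2:5, 1))
      },
      fit = function(X, y, cfg, seed) fit_bag(X, y, cfg$n_trees, cfg$max_depth, seed),
      predict = predict_bag
    ),
    gradient_boosting = list(
      sample_config = function(default = FALSE) {
        if (default) return(list(n_rounds = 150L, shrinkage = 0.1))
        list(n_rounds = sample(c(50L, 100L, 150L, 250L), 1),
             shrinkage = stats::runif(1, 0.05, 0.3))
      },
      fit = function(X, y, cfg, seed) fit_gbs(X, y, cfg$n_rounds, cfg$shrinkage),
      predict = predict_gbs
    ),
    knn = list(
      sample_config = function(default = FALSE) {
        if (default) return(list(k = 5L))
        list(k = sample(c(1L, 3L, 5L, 7L, 10L, 15L), 1))
      },
      fit = function(X, y, cfg, seed) {
        list(type = "knn", X = as.matrix(X), y = y, k = cfg$k)
      },
      predict = function(model, X) {
        k <- min(model$k, nrow(model$X))
        FNN::knn.reg(train = model$X, test = as.matrix(X), y = model$y, k = k)$pred
      }
    ),
    ridge_linear = list(
      sample_config = function(default = FALSE) {
        if (default) return(list(lambda = 0))
        list(lambda = sample(c(0, 10^stats::runif(1, -4, 2)), 1))
      },
      fit = function(X, y, cfg, seed) fit_ridge(X, y, cfg$lambda),
      predict = predict_ridge
    ),
    elastic_net = list(
      sample_config = function(default = FALSE) {
        if (default) return(list(alpha = 0.5, lambda = 0.1))
        list(alpha = stats::runif(1, 0.05, 1), lambda = 10^stats::runif(1, -4, 1))
      },
      fit = function(X, y, cfg, seed) {
        fit <- glmnet::glmnet(as.matrix(X), y, alpha = cfg$alpha)
        list(type = "enet", fit = fit, lambda = cfg$lambda)
      },
      predict = function(model, X) {
        drop(stats::predict(model$fit, newx = as.matrix(X), s = model$lambda))
      }
    ),
    mlp = list(
      sample_config = function(default = FALSE) {
        if (default) return(list(hidden = 8L, decay = 1e-3, maxit = 200L))
        list(hidden = sample(c(4L, 8L, 12L, 16L), 1),
             decay = 10^stats::runif(1, -4, -1), maxit = 200L)
      },
      fit = function(X, y, cfg, seed) fit_mlp(X, y, cfg$hidden, cfg$decay, cfg$maxit, seed),
      predict = predict_mlp
    )
  )
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(reg))
    if (length(missing)) stopf("unknown registry entries: %s", paste(missing, collapse = ", "))
    reg <- reg[names]
  }
  reg
}
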