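# columns of a feature tibble that hold features (not metadata)
feature_columns <- function(data) {
  meta <- c("record", "t_start", "t_end", "label", "group", "trial")
  nm <- setdiff(names(data), meta)
  nm[vapply(data[nm], is.numeric, logical(1))]
}

#' PCA summary of a feature matrix
#'
#' Standardizes the feature columns (zero-variance columns dropped with a
#' warning), computes principal components, and returns the explained
#' variance ratios together with low-dimensional scores for plotting.
#'
#' @param data Feature tibble (metadata columns `record, t_start, t_end,
#'   label, group` are ignored as features; `label` is carried into the
#'   scores).
#' @param n_components Number of score dimensions returned (default 2).
#' @return A `pca_summary` list: `explained` (tibble `component, ratio,
#'   cumulative`, ratios non-increasing and summing to 1), `scores`
#'   (tibble `PC1..PCk` + `label` if available).
#' @export
pca_summary <- function(data, n_components = 2) {
  cols <- feature_columns(data)
  X <- as.matrix(data[, cols])
  if (nrow(X) < 2 || ncol(X) < 2) stop("need at least 2 rows and 2 feature columns")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature column(s): ",
            paste(cols[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  scores <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  if ("label" %in% names(data)) scores$label <- data$label
  structure(list(explained = tibble::tibble(component = seq_along(ratio),
                                            ratio = ratio,
                                            cumulative = cumsum(ratio)),
                 scores = scores),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat("<pca_summary>\n")
  k <- min(5, nrow(x$explained))
  for (i in seq_len(k))
    cat(sprintf("  PC%d: %.2f%% (cum %.2f%%)\n", i,
                100 * x$explained$ratio[i], 100 * x$explained$cumulative[i]))
  invisible(x)
}

#' Neighbourhood component analysis feature weights
#'
#' Learns one non-negative weight per feature by gradient ascent on the
#' regularized leave-one-out stochastic-neighbour classification objective
#' with a diagonal metric `d_w(i,j) = sum_k w_k^2 |x_ik - x_jk|`:
#' each point votes for neighbours with probability proportional to
#' `exp(-d_w/sigma)`, and the expected leave-one-out accuracy minus an L2
#' weight penalty is maximized. Features whose learned weight exceeds the
#' selection threshold are flagged for retention.
#'
#' @param data Feature tibble (standardized internally).
#' @param labels Class label per row (used instead of a `label` column if
#'   supplied).
#' @param lambda L2 regularization (default `1 / n`).
#' @param sigma Kernel width of the neighbour probabilities (default 1).
#' @param threshold Selection threshold on the weights (default 0.1).
#' @param max_iter,learning_rate Optimizer controls (monotone gradient
#'   ascent with step halving).
#' @param seed Seed for the initial weights.
#' @return An `nca_weights` object: tibble `feature, weight, selected` with
#'   attributes `objective` and `lambda`.
#' @export
nca_feature_weights <- function(data, labels = NULL, lambda = NULL, sigma = 1,
                                threshold = 0.1, max_iter = 100,
                                learning_rate = 0.5, seed = 1) {
  if (is.null(labels)) {
    if (!"label" %in% names(data)) stop("supply labels or a 'label' column")
    labels <- data$label
  }
  y <- as.factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  cols <- feature_columns(data)
  X <- scale(as.matrix(data[, cols]))
  X[, attr(X, "scaled:scale") == 0] <- 0
  n <- nrow(X); p <- ncol(X)
  if (is.null(lambda)) lambda <- 1 / n
  same <- outer(y, y, "==") * 1
  diag(same) <- 0
  # per-feature absolute-difference matrices
  absd <- lapply(seq_len(p), function(k) abs(outer(X[, k], X[, k], "-")))

  objective_grad <- function(w) {
    D <- matrix(0, n, n)
    for (k in seq_len(p)) D <- D + w[k]^2 * absd[[k]]
    K <- exp(-D / sigma)
    diag(K) <- 0
    rs <- rowSums(K)
    rs[rs == 0] <- 1
    P <- K / rs
    pi_i <- rowSums(P * same)
    obj <- mean(pi_i) - lambda * sum(w^2)
    grad <- numeric(p)
    for (k in seq_len(p)) {
      A <- P * absd[[k]]
      grad[k] <- (2 * w[k] / sigma) *
        (sum(pi_i * rowSums(A)) - sum(A * same)) / n - 2 * lambda * w[k]
    }
    list(obj = obj, grad = grad)
  }

  w <- with_seed(seed, stats::runif(p, 0.9, 1.1))
  og <- objective_grad(w)
  lr <- learning_rate
  for (it in seq_len(max_iter)) {
    w_new <- pmax(0, w + lr * og$grad)
    og_new <- objective_grad(w_new)
    if (og_new$obj > og$obj) {
      w <- w_new; og <- og_new; lr <- lr * 1.1
    } else {
      lr <- lr / 2
      if (lr < 1e-6) break
    }
  }
  out <- tibble::tibble(feature = cols, weight = w, selected = w > threshold)
  attr(out, "objective") <- og$obj
  attr(out, "lambda") <- lambda
  class(out) <- c("nca_weights", class(out))
  out
}

#' Participant-level train/validation/test split
#'
#' Splits records so that no participant (group) appears in more than one
#' of train and test; the validation subset is drawn record-wise from the
#' training records. Stratified by class where group counts allow.
#'
#' @param data Feature tibble with `label` and (for group-level splits)
#'   `group` columns.
#' @param train_fraction Fraction of groups (or records) for training
#'   (default 0.75).
#' @param validation_fraction Fraction of training records held out for
#'   hyperparameter validation (default 0.10).
#' @param group_level If `TRUE` (default) split whole participants;
#'   requires >= 2 groups per class, otherwise errors suggesting
#'   `group_level = FALSE`.
#' @param seed Seed; identical seeds give identical partitions.
#' @return List of tibbles `train`, `validation`, `test` (disjoint,
#'   covering all rows).
#' @export
split_dataset <- function(data, train_fraction = 0.75,
                          validation_fraction = 0.10,
                          group_level = TRUE, seed = 1) {
  stopifnot("label" %in% names(data),
            train_fraction > 0, train_fraction < 1,
            validation_fraction >= 0, validation_fraction < 1)
  with_seed(seed, {
    if (group_level) {
      if (!"group" %in% names(data)) stop("group-level split needs a 'group' column")
      tab <- unique(data[, c("group", "label")])
      if (any(table(tab$label) < 2))
        stop("fewer than 2 participants in some class; ",
             "use group_level = FALSE for a record-level split")
      train_groups <- character(0)
      for (cls in unique(tab$label)) {
        g <- tab$group[tab$label == cls]
        k <- max(1, round(train_fraction * length(g)))
        if (k >= length(g)) k <- length(g) - 1L
        train_groups <- c(train_groups, sample(g, k))
      }
      is_train <- data$group %in% train_groups
    } else {
      idx <- sample.int(nrow(data))
      k <- max(1, round(train_fraction * nrow(data)))
      is_train <- seq_len(nrow(data)) %in% idx[seq_len(k)]
    }
    train <- data[is_train, ]
    test <- data[!is_train, ]
    nv <- floor(validation_fraction * nrow(train))
    vi <- if (nv > 0) sample.int(nrow(train), nv) else integer(0)
    list(train = train[setdiff(seq_len(nrow(train)), vi), ],
         validation = train[vi, ],
         test = test)
  })
}

#' Default hyperparameter grids
#'
#' @return Named list of data frames, one grid per algorithm.
#' @export
default_grids <- function() {
  list(
    svm = expand.grid(cost = c(1, 10, 100, 1000, 2000),
                      gamma = c(0.001, 0.01, 0.1)),
    logistic = expand.grid(C = c(0.1, 1, 10, 50)),
    tree = expand.grid(maxdepth = 2:8),
    xgboost = expand.grid(nrounds = c(10, 30, 50), max_depth = c(2, 3),
                          eta = 0.25)
  )
}

#' ROC curve and AUC from continuous scores
#'
#' @param scores Numeric decision scores (larger = more positive).
#' @param truth Logical vector (TRUE = positive class).
#' @return List with `roc` (tibble `threshold, fpr, tpr`) and `auc`
#'   (trapezoidal; `NA` if only one class is present).
#' @export
roc_curve <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  if (length(unique(truth)) < 2)
    return(list(roc = tibble::tibble(threshold = numeric(0), fpr = numeric(0),
                                     tpr = numeric(0)), auc = NA_real_))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)  # one point per distinct score
  tpr <- c(0, tp[last] / sum(truth))
  fpr <- c(0, fp[last] / sum(!truth))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = tibble::tibble(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr),
       auc = auc)
}

fit_predict <- function(algorithm, params, Xtr, ytr, Xte, seed = 1) {
  pos <- levels(ytr)[2]
  with_seed(seed, switch(
    algorithm,
    svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = params$cost,
                        gamma = params$gamma, scale = FALSE)
      pr <- stats::predict(fit, Xte, decision.values = TRUE)
      dv <- as.numeric(attr(pr, "decision.values"))
      # orient decision values so larger means the positive class
      if (colnames(attr(pr, "decision.values"))[1] == paste0(pos, "/", levels(ytr)[1]))
        dv <- dv else dv <- -dv
      list(model = fit, scores = dv, pred = as.character(pr))
    },
    logistic = {
      lam <- 1 / (params$C * nrow(Xtr))
      if (ncol(Xtr) == 1) {  # glmnet requires >= 2 columns
        Xtr <- cbind(Xtr, .pad = 0)
        Xte <- cbind(Xte, .pad = 0)
      }
      fit <- glmnet::glmnet(Xtr, ytr, family = "binomial", alpha = 0,
                            lambda = lam)
      pr <- as.numeric(stats::predict(fit, Xte, type = "response"))
      list(model = fit, scores = pr,
           pred = ifelse(pr > 0.5, pos, levels(ytr)[1]))
    },
    tree = {
      df <- data.frame(Xtr, .y = ytr, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = params$maxdepth, minsplit = 5,
                            cp = 0.001, xval = 0))
      pr <- stats::predict(fit, data.frame(Xte, check.names = FALSE))[, pos]
      list(model = fit, scores = pr,
           pred = ifelse(pr > 0.5, pos, levels(ytr)[1]))
    },
    xgboost = {
      dtr <- xgboost::xgb.DMatrix(Xtr, label = as.numeric(ytr == pos))
      fit <- xgboost::xgb.train(params = list(max_depth = params$max_depth,
                                              eta = params$eta,
                                              objective = "binary:logistic",
                                              nthread = 1),
                                data = dtr, nrounds = params$nrounds,
                                verbose = 0)
      pr <- stats::predict(fit, xgboost::xgb.DMatrix(Xte))
      list(model = fit, scores = pr,
           pred = ifelse(pr > 0.5, pos, levels(ytr)[1]))
    },
    stop("unknown algorithm: ", algorithm)))
}

#' Train and evaluate classifiers with grid search
#'
#' For each requested algorithm: every grid point is fitted on the training
#' subset and scored (accuracy) on the validation subset; the best point is
#' refitted on train + validation and evaluated on the held-out test
#' subset, reporting accuracy, trapezoidal AUC from the continuous decision
#' scores, and the ROC curve. Feature standardization (zero mean, unit
#' variance) is fitted on the training data only.
#'
#' @param split A [split_dataset()] result.
#' @param algorithms Subset of `c("svm", "logistic", "tree", "xgboost")`.
#' @param grids Hyperparameter grids, as [default_grids()].
#' @param selection Optional [nca_feature_weights()] result; if given, only
#'   selected features are used.
#' @param seed Seed for the (otherwise deterministic) fits.
#' @return Named list of `model_report` objects (one per algorithm), each
#'   with `algorithm`, `params`, `accuracy`, `auc`, `roc`,
#'   `selected_features`, plus the fitted model and scaler for
#'   [predict_phases()].
#' @export
train_and_evaluate <- function(split,
                               algorithms = c("svm", "logistic", "tree", "xgboost"),
                               grids = default_grids(), selection = NULL,
                               seed = 1) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  train <- split$train; val <- split$validation; test <- split$test
  stopifnot(nrow(train) > 0, nrow(test) > 0)
  cols <- feature_columns(train)
  if (!is.null(selection)) {
    stopifnot(inherits(selection, "nca_weights"))
    cols <- intersect(cols, selection$feature[selection$selected])
    if (!length(cols)) stop("feature selection retained no features")
  }
  y_all <- as.factor(c(train$label, val$label, test$label))
  lev <- levels(y_all)
  if (length(lev) != 2) stop("binary classification expected")

  mu <- colMeans(as.matrix(train[, cols]))
  sd_ <- apply(as.matrix(train[, cols]), 2, stats::sd)
  sd_[sd_ == 0] <- 1
  scale_mat <- function(d) {
    X <- sweep(sweep(as.matrix(d[, cols]), 2, mu), 2, sd_, "/")
    colnames(X) <- cols
    X
  }
  Xtr <- scale_mat(train); ytr <- factor(train$label, levels = lev)
  Xva <- if (nrow(val)) scale_mat(val) else NULL
  Xte <- scale_mat(test); yte <- factor(test$label, levels = lev)

  reports <- list()
  for (alg in algorithms) {
    grid <- grids[[alg]]
    if (is.null(grid)) stop("no grid for algorithm ", alg)
    best <- 1L
    if (!is.null(Xva) && nrow(val) > 0 && nrow(grid) > 1) {
      yva <- factor(val$label, levels = lev)
      acc <- vapply(seq_len(nrow(grid)), function(i) {
        fp <- fit_predict(alg, grid[i, , drop = FALSE], Xtr, ytr, Xva, seed)
        mean(fp$pred == as.character(yva))
      }, 0)
      best <- which.max(acc)
    }
    params <- grid[best, , drop = FALSE]
    Xfull <- rbind(Xtr, if (!is.null(Xva)) Xva)
    yfull <- factor(c(as.character(ytr), as.character(val$label)), levels = lev)
    fp <- fit_predict(alg, params, Xfull, yfull, Xte, seed)
    rc <- roc_curve(fp$scores, yte == lev[2])
    reports[[alg]] <- structure(list(
      algorithm = alg,
      params = as.list(params),
      accuracy = mean(fp$pred == as.character(yte)),
      auc = rc$auc,
      roc = rc$roc,
      selected_features = if (is.null(selection)) NULL else cols,
      n_train = nrow(Xfull), n_test = nrow(Xte),
      model = fp$model, feature_cols = cols, center = mu, scale = sd_,
      levels = lev, seed = seed), class = "model_report")
  }
  reports
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report>", x$algorithm, "\n")
  cat("  params  :", paste(names(x$params), unlist(x$params), sep = "=",
                           collapse = ", "), "\n")
  cat(sprintf("  accuracy: %.4f  AUC: %.4f  (n_test = %d)\n",
              x$accuracy, x$auc, x$n_test))
  invisible(x)
}

#' Predict phase/class labels for new feature records
#'
#' @param report A `model_report` from [train_and_evaluate()].
#' @param data Feature tibble containing at least the feature columns the
#'   model was trained on.
#' @return Character vector with one predicted label per row.
#' @export
predict_phases <- function(report, data) {
  stopifnot(inherits(report, "model_report"))
  missing <- setdiff(report$feature_cols, names(data))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  X <- sweep(sweep(as.matrix(data[, report$feature_cols]), 2, report$center),
             2, report$scale, "/")
  colnames(X) <- report$feature_cols
  lev <- report$levels
  pos <- lev[2]
  pred <- switch(report$algorithm,
    svm = as.character(stats::predict(report$model, X)),
    logistic = {
      if (ncol(X) == 1) X <- cbind(X, .pad = 0)
      pr <- as.numeric(stats::predict(report$model, X, type = "response"))
      ifelse(pr > 0.5, pos, lev[1])
    },
    tree = {
      pr <- stats::predict(report$model, data.frame(X, check.names = FALSE))[, pos]
      ifelse(pr > 0.5, pos, lev[1])
    },
    xgboost = {
      pr <- stats::predict(report$model, xgboost::xgb.DMatrix(X))
      ifelse(pr > 0.5, pos, lev[1])
    })
  unname(pred)
}
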