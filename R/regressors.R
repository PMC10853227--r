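# Gradient of the Breslow Cox partial log-likelihood w.r.t. per-sample
# scores f (used by the component-wise gradient-boosting regressor).
cox_score_gradient <- function(time, event, f) {
  n <- length(time)
  ef <- exp(f - max(f))
  g <- numeric(n)
  event_times <- which(event == 1)
  if (length(event_times) == 0) return(g)
  # cumulative hazard increments at each event time
  for (k in event_times) {
    at_risk <- time >= time[k]
    s0 <- sum(ef[at_risk])
    g[at_risk] <- g[at_risk] - ef[at_risk] / s0
  }
  g + event
}

fit_coxph_linear <- function(x, time, event, ridge_theta = 1e-5) {
  df <- as.data.frame(x)
  safe <- paste0("V", seq_len(ncol(x)))
  names(df) <- safe
  df$.time <- time; df$.event <- event
  rhs <- paste0("ridge(", paste(safe, collapse = ", "),
                ", theta = ", format(ridge_theta, scientific = FALSE), ", scale = FALSE)")
  f <- stats::as.formula(paste0("survival::Surv(.time, .event) ~ ", rhs))
  fit <- tryCatch(
    suppressWarnings(survival::coxph(f, data = df,
                                     control = survival::coxph.control(iter.max = 100))),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(coef(fit)))) {
    abort("coxph fit failed to converge", class = "ds_convergence_error")
  }
  setNames(as.numeric(coef(fit)), colnames(x))
}

fit_coxnet_linear <- function(x, time, event, l1_ratio = 0.5, penalty = NULL) {
  if (ncol(x) < 2) {
    # glmnet requires >= 2 columns; a single feature reduces to ridge Cox
    return(fit_coxph_linear(x, time, event, ridge_theta = max(penalty %||% 1e-2, 1e-5)))
  }
  y <- survival::Surv(time, event)
  fit <- tryCatch(glmnet::glmnet(x, y, family = "cox", alpha = l1_ratio,
                                 nlambda = 50, standardize = FALSE),
                  error = function(e) NULL)
  if (is.null(fit)) abort("coxnet fit failed", class = "ds_convergence_error")
  lam <- fit$lambda
  if (is.null(penalty)) {
    mid <- lam[ceiling(length(lam) / 2)]
    nz <- colSums(as.matrix(fit$beta != 0))
    cand <- which(lam <= mid & nz > 0)
    penalty <- if (length(cand) > 0) lam[cand[1]] else lam[length(lam)]
  }
  b <- as.numeric(coef(fit, s = penalty))
  setNames(b, colnames(x))
}

fit_survsvm_linear <- function(x, time, event, alpha = 1) {
  comp <- which(outer(time, time, "<") & (event == 1), arr.ind = TRUE)
  if (nrow(comp) == 0) abort("no comparable pairs for the ranking SVM",
                             class = "ds_convergence_error")
  D <- x[comp[, 1], , drop = FALSE] - x[comp[, 2], , drop = FALSE]
  obj <- function(w) {
    m <- 1 - D %*% w
    0.5 * sum(w^2) + alpha * sum(pmax(m, 0)^2)
  }
  grad <- function(w) {
    m <- pmax(1 - drop(D %*% w), 0)
    w - 2 * alpha * drop(crossprod(D, m))
  }
  res <- optim(rep(0, ncol(x)), obj, grad, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-10))
  setNames(res$par, colnames(x))
}

fit_gb_linear <- function(x, time, event, n_estimators = 100, learning_rate = 0.1) {
  n <- nrow(x); p <- ncol(x)
  f <- numeric(n)
  beta <- setNames(numeric(p), colnames(x))
  xs <- colSums(x^2)
  for (it in seq_len(n_estimators)) {
    r <- cox_score_gradient(time, event, f)
    b <- drop(crossprod(x, r)) / pmax(xs, 1e-12)
    gain <- b^2 * xs
    j <- which.max(gain)
    beta[j] <- beta[j] + learning_rate * b[j]
    f <- f + learning_rate * b[j] * x[, j]
  }
  beta
}

#' Fit a time-to-event regressor on selected features
#'
#' All four regressor kinds produce a linear risk score
#' \code{risk = X \%*\% coef}, with the orientation contract that a higher
#' score predicts earlier progression: Cox proportional hazards with a small
#' ridge (1e-5) for stability, ElasticNet Cox (glmnet path, penalty at the
#' path midpoint by default), the linear ranking-objective survival SVM
#' (squared hinge on comparable pairs), and gradient-boosted Cox with
#' component-wise least-squares base learners.
#'
#' @param kind \code{"coxph"}, \code{"coxnet"}, \code{"svm"} or
#'   \code{"gb_linear"}.
#' @param x Matrix (or feature tibble) of selected, standardized features.
#' @param time,event Right-censored outcomes.
#' @param hyperparams Named list; recognised entries: \code{ridge_theta}
#'   (coxph), \code{l1_ratio}, \code{penalty} (coxnet), \code{alpha} (svm),
#'   \code{n_estimators}, \code{learning_rate} (gb_linear).
#' @param model_id Identifier carried in convergence errors.
#' @return A \code{ds_model} with fields \code{kind}, \code{features},
#'   \code{coef}, \code{background} (training feature means, the SHAP
#'   reference), \code{hyperparams}.
#' @export
fit_regressor <- function(kind = c("coxph", "coxnet", "svm", "gb_linear"),
                          x, time, event, hyperparams = list(),
                          model_id = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(x)) x <- feature_matrix(x)
  assert_that(sum(event) >= 2, "need at least two events to fit")
  assert_that(!anyNA(x), "missing values in the feature matrix")
  hp <- hyperparams
  w <- withCallingHandlers(
    switch(kind,
      coxph = fit_coxph_linear(x, time, event, hp$ridge_theta %||% 1e-5),
      coxnet = fit_coxnet_linear(x, time, event, hp$l1_ratio %||% 0.5, hp$penalty),
      svm = fit_survsvm_linear(x, time, event, hp$alpha %||% 1),
      gb_linear = fit_gb_linear(x, time, event, hp$n_estimators %||% 100,
                                hp$learning_rate %||% 0.1)),
    error = function(e) {
      if (inherits(e, "ds_convergence_error") && !is.null(model_id)) {
        abort(paste0("[", model_id, "] ", conditionMessage(e)),
              class = "ds_convergence_error")
      }
    })
  if (any(!is.finite(w))) {
    abort(paste0("non-finite coefficients",
                 if (!is.null(model_id)) paste0(" in model ", model_id) else ""),
          class = "ds_convergence_error")
  }
  structure(list(kind = kind, features = colnames(x), coef = w,
                 background = colMeans(x), hyperparams = hp),
            class = "ds_model")
}

#' Predict risk scores from a fitted model
#'
#' @param object A \code{ds_model}.
#' @param newdata Matrix or feature tibble containing the model's features.
#' @param ... Unused.
#' @return Numeric risk scores (higher = earlier predicted progression).
#' @export
predict.ds_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  drop(x[, object$features, drop = FALSE] %*% object$coef)
}

#' @export
print.ds_model <- function(x, ...) {
  cat(sprintf("<ds_model %s> %d feature(s): %s\n", x$kind, length(x$features),
              paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Tidy a fitted survival regressor
#'
#' @param x A \code{ds_model}.
#' @param ... Unused.
#' @return A tibble with \code{term} and \code{estimate}.
#' @export
tidy.ds_model <- function(x, ...) {
  tibble(term = x$features, estimate = unname(x$coef))
}

#' One-row model overview
#'
#' @param x A \code{ds_model}.
#' @param ... Unused.
#' @return A tibble with the regressor kind and feature count.
#' @export
glance.ds_model <- function(x, ...) {
  tibble(kind = x$kind, n_features = length(x$features),
         max_abs_coef = max(abs(x$coef)))
}

#' Exact SHAP attributions for a linear risk model
#'
#' For a linear score the Shapley value of feature j on row i is
#' \code{phi_ij = w_j (x_ij - mean_j(background))}; rows then satisfy local
#' accuracy: the attributions sum to the prediction minus the mean background
#' prediction.
#'
#' @param model A \code{ds_model}.
#' @param x Rows to explain (matrix or tibble).
#' @param background Background matrix; defaults to the training means stored
#'   in the model.
#' @return Matrix of per-row, per-feature attributions.
#' @export
shap_values <- function(model, x, background = NULL) {
  xm <- if (is.matrix(x)) x else feature_matrix(x)
  xm <- xm[, model$features, drop = FALSE]
  bg <- if (is.null(background)) model$background else colMeans(
    (if (is.matrix(background)) background else feature_matrix(background))[, model$features, drop = FALSE])
  sweep(xm, 2, bg, "-") %*% diag(model$coef, nrow = length(model$coef)) |>
    (\(m) { colnames(m) <- model$features; m })()
}
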