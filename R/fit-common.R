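# Shared nonlinear least-squares machinery: multi-start Levenberg-Marquardt
# fits (minpack.lm), linearised covariance, prediction intervals, broom-style
# accessors, and the prediction-interval outlier-rejection rule.

num_jacobian <- function(fn, par, data) {
  p <- length(par)
  f0 <- fn(par, data)
  J <- matrix(0, nrow = length(f0), ncol = p,
              dimnames = list(NULL, names(par)))
  for (j in seq_len(p)) {
    h <- max(abs(par[j]) * 1e-7, 1e-9)
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (fn(up, data) - fn(dn, data)) / (2 * h)
  }
  J
}

# Fit fn(par, data) ~ data$y by weighted Levenberg-Marquardt from several
# starts; keeps the lowest-deviance solution. `data` must hold `y` and may
# hold `w` (weights, default 1).
zf_nls <- function(data, starts, fn, lower = NULL, upper = NULL,
                   maxiter = 200) {
  if (!"w" %in% names(data)) data$w <- 1
  sw <- sqrt(data$w)
  resid_fn <- function(p) sw * (data$y - fn(p, data))
  best <- NULL
  for (st in starts) {
    ans <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(ans)) next
    if (is.null(best) || ans$deviance < best$deviance) best <- ans
  }
  if (is.null(best)) abort("nonlinear least-squares fit failed from all starts.")
  best
}

# Assemble the common fit object. `refit` is a closure(data) reproducing the
# same fitting procedure on a data subset (used by reject_outliers()).
new_zf_fit <- function(data, par, fn, refit, subclass, extra = list()) {
  if (!"w" %in% names(data)) data$w <- 1
  n <- nrow(data)
  p <- length(par)
  if (n <= p) abort("more parameters than data points.")
  J <- num_jacobian(fn, par, data)
  Jw <- sqrt(data$w) * J
  fitted <- fn(par, data)
  res <- data$y - fitted
  rss <- sum(data$w * res^2)
  sigma2 <- rss / (n - p)
  # column-equilibrated inversion: parameter scales can differ by many
  # orders of magnitude (nanomolar amplitudes vs log10 constants)
  cn <- sqrt(colSums(Jw^2))
  if (any(cn == 0) || any(!is.finite(cn))) {
    abort("fit is non-identifiable: a parameter has no effect on the model.")
  }
  Js <- sweep(Jw, 2, cn, "/")
  Vsc <- tryCatch(
    sweep(sweep(solve(crossprod(Js)), 1, cn, "/"), 2, cn, "/"),
    error = function(e) {
      abort("fit is non-identifiable: singular information matrix.")
    })
  vcov <- sigma2 * Vsc
  hat <- rowSums((Jw %*% Vsc) * Jw)
  obj <- structure(
    c(list(par = par, vcov = vcov, sigma = sqrt(sigma2),
           df_residual = n - p, data = data, fn = fn, refit = refit,
           fitted = fitted, residuals = res, hat = hat,
           rss = rss, n = n), extra),
    class = c(subclass, "zf_fit"))
  obj
}

zf_se <- function(object) sqrt(pmax(diag(object$vcov), 0))

#' @export
coef.zf_fit <- function(object, ...) object$par

#' @export
vcov.zf_fit <- function(object, ...) object$vcov

#' @export
fitted.zf_fit <- function(object, ...) object$fitted

#' @export
residuals.zf_fit <- function(object, type = c("response", "studentized"),
                             ...) {
  type <- match.arg(type)
  if (type == "response") return(object$residuals)
  sqrt(object$data$w) * object$residuals /
    (object$sigma * sqrt(pmax(1 - object$hat, 1e-12)))
}

#' Tidy a zincfold model fit
#'
#' Returns one row per parameter with its estimate and standard error from
#' the linearised covariance of the nonlinear least-squares fit. Fits that
#' estimate transformed parameters (log10 dissociation constants) also report
#' the natural-scale quantity via the delta method.
#'
#' @param x A fit object produced by one of the `fit_*()` functions.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.zf_fit <- function(x, ...) {
  out <- tibble(term = names(x$par), estimate = unname(x$par),
                std.error = unname(zf_se(x)))
  if (!is.null(x$derived)) out <- dplyr::bind_rows(out, x$derived)
  out
}

#' Glance at a zincfold model fit
#'
#' @param x A fit object produced by one of the `fit_*()` functions.
#' @param ... Unused.
#' @return One-row tibble with `sigma`, `rss`, `df.residual`, `nobs`.
#' @export
glance.zf_fit <- function(x, ...) {
  tibble(sigma = x$sigma, rss = x$rss, df.residual = x$df_residual,
         nobs = x$n)
}

#' @export
print.zf_fit <- function(x, ...) {
  cat(sprintf("<%s> %d points, residual sd %.4g\n",
              class(x)[1], x$n, x$sigma))
  print(tidy(x), n = Inf)
  invisible(x)
}

# Predict with delta-method standard errors on new rows of predictors.
# interval = "prediction" adds the residual variance (scaled by the new
# point's weight when given).
predict_zf <- function(object, newdata, level = 0.95,
                       interval = c("none", "confidence", "prediction")) {
  interval <- match.arg(interval)
  if (!"w" %in% names(newdata)) newdata$w <- 1
  pred <- object$fn(object$par, newdata)
  if (interval == "none") return(tibble(fit = pred))
  G <- num_jacobian(object$fn, object$par, newdata)
  v_conf <- rowSums((G %*% object$vcov) * G)
  if (isTRUE(object$known_sigma)) {
    # weights encode known measurement errors: use them directly instead of
    # the (possibly contaminated) estimated residual variance
    v_conf <- v_conf / object$sigma^2
    v <- if (interval == "prediction") v_conf + 1 / newdata$w else v_conf
    tq <- stats::qnorm(1 - (1 - level) / 2)
  } else {
    v <- if (interval == "prediction") {
      v_conf + object$sigma^2 / newdata$w
    } else v_conf
    tq <- qt(1 - (1 - level) / 2, df = object$df_residual)
  }
  tibble(fit = pred, se = sqrt(pmax(v, 0)),
         lwr = pred - tq * sqrt(pmax(v, 0)),
         upr = pred + tq * sqrt(pmax(v, 0)))
}

#' Leave-one-out deletion z-scores of a fit
#'
#' For each point, refits the model without it and scores the point's
#' deviation from the deletion fit's prediction. When the fit was weighted
#' by known measurement errors (`known_sigma = TRUE`), the score uses the
#' known error (a true z-score); otherwise it falls back to the deletion
#' fit's estimated residual sd. Deletion residuals are not absorbed by the
#' fit, so gross errors keep their full magnitude even when the direct fit
#' residual understates them.
#'
#' @param fit A zincfold fit object.
#' @return Numeric vector of absolute deletion z-scores (NA where the
#'   deletion refit fails).
#' @export
deletion_zscores <- function(fit) {
  stopifnot(inherits(fit, "zf_fit"))
  d <- fit$data
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    trial <- tryCatch(suppressWarnings(fit$refit(d[-i, , drop = FALSE])),
                      error = function(e) NULL)
    if (is.null(trial)) return(NA_real_)
    nd <- d[i, , drop = FALSE]
    pred <- trial$fn(trial$par, nd)
    G <- num_jacobian(trial$fn, trial$par, nd)
    v_par <- rowSums((G %*% trial$vcov) * G)
    if (isTRUE(trial$known_sigma)) {
      # unscale the parameter covariance and use the known noise
      v <- v_par / trial$sigma^2 + 1 / nd$w
    } else {
      v <- v_par + trial$sigma^2 / nd$w
    }
    abs(d$y[i] - pred) / sqrt(v)
  }, numeric(1))
}

#' Outlier rejection by refit and adjusted prediction interval
#'
#' Deterministic replacement for by-eye outlier screening in nonlinear assay
#' fits, in two stages. Nomination: points whose leave-one-out deletion
#' z-score ([deletion_zscores()]) exceeds `candidate_threshold` (default 5,
#' a gross-anomaly cut far beyond plausible Gaussian extremes at these
#' sample sizes) are candidates, taken in decreasing order. Confirmation: the
#' model is refitted without the whole candidate set (so one gross point
#' cannot contaminate the interval used to judge another) and a candidate is
#' excluded only if (1) it falls outside the Holm-Bonferroni-adjusted
#' `level` prediction interval of that suspect-free refit (the j-th of m
#' candidates is tested at adjusted alpha = (1 - level) / (m - j + 1)), and
#' (2) the resulting exclusion decreases the average relative standard error
#' of the fit parameters -- otherwise all candidates are restored. Rounds of
#' nomination and confirmation repeat until nothing new is rejected; the
#' suspect-free fit always keeps at least two more points than parameters.
#'
#' @param fit A fit object from [fit_linkage_profile()],
#'   [fit_stability_curve()], [fit_lem_curve()] or any other zincfold fit.
#' @param level Prediction-interval level before adjustment (default 0.95).
#' @param candidate_threshold Deletion z-score cutoff defining the
#'   candidate set (default 5).
#' @return List with elements `fit` (the final, possibly refitted model),
#'   `data` (input rows flagged with `outlier`), and `audit` (one row per
#'   candidate tested: deletion z, adjusted alpha, interval, decision).
#' @export
reject_outliers <- function(fit, level = 0.95, candidate_threshold = 5) {
  stopifnot(inherits(fit, "zf_fit"))
  data0 <- fit$data
  data0$.row <- seq_len(nrow(data0))
  audit <- list()
  current <- fit
  kept_rows <- data0$.row
  rejected <- integer(0)
  rel_se <- function(f) mean(zf_se(f) / pmax(abs(f$par), 1e-12))
  empty_audit <- tibble(round = integer(), row = integer(),
                        deletion_z = numeric(), alpha_adj = numeric(),
                        pi_lwr = numeric(), pi_upr = numeric(),
                        decision = character())
  for (round in seq_len(nrow(data0))) {
    # re-nominate from the current fit: a gross point can mask another
    stud <- deletion_zscores(current)
    cand_local <- order(abs(stud), decreasing = TRUE, na.last = TRUE)
    cand_local <- cand_local[!is.na(stud[cand_local]) &
                               abs(stud[cand_local]) > candidate_threshold]
    # never leave the suspect-free fit with fewer points than pars + 2
    max_cand <- length(kept_rows) - (length(fit$par) + 2)
    if (max_cand < 1 || length(cand_local) == 0) break
    cand_local <- head(cand_local, max_cand)
    cand <- kept_rows[cand_local]       # original row ids
    zval <- stud[cand_local]
    m <- length(cand)
    # confirmation against the suspect-free fit: excluding the whole
    # candidate set at once avoids one gross point contaminating the
    # interval used to judge another
    base_rows <- setdiff(kept_rows, cand)
    base_fit <- tryCatch(
      suppressWarnings(fit$refit(data0[data0$.row %in% base_rows, ])),
      error = function(e) NULL)
    if (is.null(base_fit)) break
    confirmed <- integer(0)
    for (j in seq_along(cand)) {
      idx <- cand[j]
      alpha_j <- (1 - level) / (m - j + 1)
      pi <- predict_zf(base_fit, data0[data0$.row == idx, , drop = FALSE],
                       level = 1 - alpha_j, interval = "prediction")
      outside <- data0$y[data0$.row == idx] < pi$lwr ||
        data0$y[data0$.row == idx] > pi$upr
      if (outside) confirmed <- c(confirmed, idx)
      audit[[length(audit) + 1]] <-
        tibble(round = round, row = idx, deletion_z = zval[j],
               alpha_adj = alpha_j, pi_lwr = pi$lwr, pi_upr = pi$upr,
               decision = if (outside) "outside_pi" else "restored")
    }
    if (length(confirmed) == 0) break
    # condition (1): the exclusion must improve the average relative
    # standard error of the refit, else everything is restored
    new_rows <- setdiff(kept_rows, confirmed)
    new_fit <- tryCatch(
      suppressWarnings(fit$refit(data0[data0$.row %in% new_rows, ])),
      error = function(e) NULL)
    if (is.null(new_fit) || rel_se(new_fit) >= rel_se(current)) {
      audit[[length(audit) + 1]] <-
        tibble(round = round, row = NA_integer_, deletion_z = NA_real_,
               alpha_adj = NA_real_, pi_lwr = NA_real_, pi_upr = NA_real_,
               decision = "restored_all_se")
      break
    }
    for (k in seq_along(audit)) {
      if (audit[[k]]$round[1] == round &&
          !is.na(audit[[k]]$row[1]) &&
          audit[[k]]$row[1] %in% confirmed) {
        audit[[k]]$decision <- "rejected"
      }
    }
    current <- new_fit
    kept_rows <- new_rows
    rejected <- c(rejected, confirmed)
  }
  data0$outlier <- data0$.row %in% rejected
  list(fit = current, data = data0,
       audit = if (length(audit)) dplyr::bind_rows(audit) else empty_audit)
}

# Normalise assorted column namings onto internal x/y (keeping weights and
# reported SEs when present).
standardise_xy <- function(data, x_names, y_names) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  xn <- intersect(x_names, names(data))
  yn <- intersect(y_names, names(data))
  if (length(xn) == 0 || length(yn) == 0) {
    abort(sprintf("`data` needs columns %s and %s.",
                  paste(x_names, collapse = "/"),
                  paste(y_names, collapse = "/")))
  }
  d <- tibble(x = as.numeric(data[[xn[1]]]), y = as.numeric(data[[yn[1]]]))
  if ("w" %in% names(data)) d$w <- data$w
  if ("se" %in% names(data)) d$se <- data$se
  if (anyNA(d$x) || anyNA(d$y)) abort("`data` contains missing values.")
  d
}
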