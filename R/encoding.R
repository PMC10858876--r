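# Encoding model: how much does each peri-seizure activity epoch contribute
# to explaining seizure EEG power?
#
# A Gaussian identity-link GLM (ordinary least squares with intercept)
# predicts seizure band power from pre-seizure and during-seizure activity.
# Per bootstrap iteration: rows are split 70/30 into training and validation,
# the training rows are resampled with replacement, the full model and each
# drop-one model are fit, and each model's R-squared is computed on the
# held-out validation rows. A predictor's contribution is the decline in
# mean validation R-squared when it is dropped; negative declines are set to
# zero, and contributions are also reported normalized to sum to one.

#' Assemble the encoding-model design matrix
#'
#' One row per seizure recording: the two activity predictors and the
#' seizure band-power response.
#'
#' @param pre_mean Pre-seizure mean activity (z-units), one per session.
#' @param during_mean During-seizure mean activity (z-units).
#' @param seizure_power Seizure band power (uV^2), the response.
#' @param ids Optional session identifiers.
#' @return A data frame of class `design_matrix` with columns `id`,
#'   `pre_mean`, `during_mean`, `seizure_power`.
#' @export
design_matrix <- function(pre_mean, during_mean, seizure_power, ids = NULL) {
  n <- length(seizure_power)
  if (length(pre_mean) != n || length(during_mean) != n) {
    stop("argument error: predictor and response lengths differ", call. = FALSE)
  }
  if (n < 6L) {
    stop("argument error: need >= 6 rows to support a 70/30 split", call. = FALSE)
  }
  dm <- data.frame(id = if (is.null(ids)) seq_len(n) else ids,
                   pre_mean = pre_mean, during_mean = during_mean,
                   seizure_power = seizure_power)
  if (anyNA(dm)) stop("argument error: design matrix contains missing values",
                      call. = FALSE)
  for (col in c("pre_mean", "during_mean", "seizure_power")) {
    if (stats::sd(dm[[col]]) == 0) {
      stop(sprintf("argument error: column `%s` is constant", col), call. = FALSE)
    }
  }
  class(dm) <- c("design_matrix", "data.frame")
  dm
}

#' Read a design matrix from CSV
#'
#' Expects columns `pre_mean`, `during_mean`, `seizure_power` and optionally
#' `id`.
#' @param path Path to the CSV file.
#' @return A `design_matrix`.
#' @export
read_design_matrix <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("pre_mean", "during_mean", "seizure_power") %in% names(d)))
  design_matrix(d$pre_mean, d$during_mean, d$seizure_power, ids = d$id)
}

#' Fit the Gaussian identity-link GLM
#'
#' Ordinary least squares with intercept (the Gaussian/identity case of a
#' GLM). On a constant response the in-sample R-squared is defined as 0.
#'
#' @param X Numeric predictor matrix or data frame (no intercept column).
#' @param y Numeric response.
#' @return An object of class `glm_fit`: `coefficients` (intercept first)
#'   and `r_squared` (in-sample).
#' @export
fit_glm <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("argument error: X/y length mismatch", call. = FALSE)
  if (nrow(X) < ncol(X) + 2L) {
    stop("argument error: need at least p + 2 rows", call. = FALSE)
  }
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xi, y)
  if (fit$rank < ncol(Xi)) {
    stop("singular-design error: rank-deficient predictor matrix", call. = FALSE)
  }
  sst <- sum((y - mean(y))^2)
  sse <- sum(fit$residuals^2)
  r2 <- if (sst <= 0) 0 else 1 - sse / sst
  structure(list(coefficients = fit$coefficients, r_squared = r2),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("<glm_fit> R^2 =", format(x$r_squared, digits = 4), "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.glm_fit <- function(object, ...) object$coefficients

# validation R^2 of coefficients `beta` (intercept first) on held-out rows;
# SST is about the validation set's own mean, so R^2 may be negative.
validation_r2 <- function(beta, Xval, yval) {
  pred <- cbind(1, Xval) %*% beta
  sst <- sum((yval - mean(yval))^2)
  if (sst <= 0) return(0)
  1 - sum((yval - pred)^2) / sst
}

#' Bootstrap drop-one contribution analysis
#'
#' The relative-contribution statistic: over `n_boot` iterations the rows are
#' split into training (`train_fraction`) and validation sets, the training
#' rows are resampled with replacement, and the full and each drop-one GLM
#' are scored by validation R-squared. The contribution of predictor `j` is
#' `max(0, mean R2_full - mean R2_without_j)`; relative contributions
#' normalize these to sum to 1 (all 0 when no predictor helps). A fresh
#' split is drawn each iteration by default; set `resplit = FALSE` to fix a
#' single split drawn once from the seed.
#'
#' @param dm A [design_matrix()] (or data frame with columns `pre_mean`,
#'   `during_mean`, `seizure_power`).
#' @param n_boot Number of bootstrap iterations (default 5000, as used for
#'   the published statistic).
#' @param train_fraction Fraction of rows used for training (default 0.7).
#' @param seed Integer seed; the result is bit-reproducible given the seed.
#' @param resplit Draw a new train/validation split each iteration
#'   (default TRUE).
#' @return An object of class `contribution_result`: `r_squared_full` (mean
#'   validation R-squared of the full model), `contributions` (named,
#'   clipped at 0), `relative_contributions` (sum to 1 or all 0),
#'   `coefficients` (mean full-model coefficients), `draws` (per-iteration
#'   validation R-squared matrix), `n_boot`, `train_fraction`, `seed`.
#' @examples
#' dm <- design_matrix(rnorm(30), rnorm(30), rnorm(30) + 1:30)
#' contribution_analysis(dm, n_boot = 200, seed = 1)
#' @export
contribution_analysis <- function(dm, n_boot = 5000, train_fraction = 0.7,
                                  seed = 1, resplit = TRUE) {
  stopifnot(is.data.frame(dm))
  preds <- c("pre_mean", "during_mean")
  X <- as.matrix(dm[, preds, drop = FALSE])
  y <- dm$seizure_power
  n <- nrow(X)
  check_scalar(train_fraction, "train_fraction", min = 0, max = 1,
               strict_min = TRUE)
  if (train_fraction >= 1) {
    stop("argument error: `train_fraction` must be < 1", call. = FALSE)
  }
  if (n_boot < 1) stop("argument error: `n_boot` must be >= 1", call. = FALSE)
  n_train <- round(train_fraction * n)
  n_val <- n - n_train
  if (n_val < 2L || n_train < ncol(X) + 2L) {
    stop("split error: too few rows for a 70/30 train/validation split",
         call. = FALSE)
  }
  p <- ncol(X)
  r2 <- matrix(NA_real_, nrow = n_boot, ncol = p + 1L,
               dimnames = list(NULL, c("full", preds)))
  coefsum <- numeric(p + 1L)
  with_seed(seed, {
    split0 <- sample.int(n, n_train)
    for (b in seq_len(n_boot)) {
      tr <- if (resplit && b > 1L) sample.int(n, n_train) else split0
      val <- setdiff(seq_len(n), tr)
      bs <- tr[sample.int(n_train, n_train, replace = TRUE)]
      Xb <- X[bs, , drop = FALSE]; yb <- y[bs]
      Xv <- X[val, , drop = FALSE]; yv <- y[val]
      bf <- stats::lm.fit(cbind(1, Xb), yb)$coefficients
      bf[is.na(bf)] <- 0                     # degenerate resample: drop term
      r2[b, 1L] <- validation_r2(bf, Xv, yv)
      coefsum <- coefsum + bf
      for (j in seq_len(p)) {
        bj <- stats::lm.fit(cbind(1, Xb[, -j, drop = FALSE]), yb)$coefficients
        bj[is.na(bj)] <- 0
        r2[b, j + 1L] <- validation_r2(bj, Xv[, -j, drop = FALSE], yv)
      }
    }
  })
  m <- colMeans(r2)
  contrib <- pmax(0, m[1L] - m[-1L])
  names(contrib) <- preds
  rel <- if (sum(contrib) > 0) contrib / sum(contrib) else contrib * 0
  coefs <- coefsum / n_boot
  names(coefs) <- c("(Intercept)", preds)
  structure(list(r_squared_full = unname(m[1L]),
                 contributions = contrib,
                 relative_contributions = rel,
                 coefficients = coefs,
                 draws = r2,
                 n_boot = as.integer(n_boot),
                 train_fraction = train_fraction,
                 resplit = resplit,
                 n = n,
                 seed = as.integer(seed)),
            class = "contribution_result")
}

#' @export
print.contribution_result <- function(x, ...) {
  cat(sprintf(
    "<contribution_result> n = %d, %d bootstrap iterations (train fraction %.2f)\n",
    x$n, x$n_boot, x$train_fraction))
  cat(sprintf("  validation R^2 (full model): %.3f\n", x$r_squared_full))
  for (nm in names(x$contributions)) {
    cat(sprintf("  %-12s decline %.4f  relative %.3f\n",
                nm, x$contributions[[nm]], x$relative_contributions[[nm]]))
  }
  invisible(x)
}

#' @export
summary.contribution_result <- function(object, ...) {
  qs <- apply(object$draws, 2L, stats::quantile,
              probs = c(0.25, 0.5, 0.75), names = FALSE)
  out <- list(result = object,
              r2_quartiles = qs)
  class(out) <- "summary.contribution_result"
  out
}

#' @export
print.summary.contribution_result <- function(x, ...) {
  print(x$result)
  cat("  validation R^2 quartiles per model:\n")
  q <- x$r2_quartiles
  for (j in seq_len(ncol(q))) {
    nm <- colnames(x$result$draws)[j]
    lbl <- if (nm == "full") "full" else paste("without", nm)
    cat(sprintf("    %-20s %.3f / %.3f / %.3f\n", lbl, q[1L, j], q[2L, j], q[3L, j]))
  }
  invisible(x)
}

#' @export
coef.contribution_result <- function(object, ...) object$coefficients

#' @export
plot.contribution_result <- function(x, ...) {
  # per-iteration performance decline when each predictor is dropped
  decl <- x$draws[, 1L] - x$draws[, -1L, drop = FALSE]
  graphics::boxplot(as.data.frame(decl),
                    ylab = "Validation R-squared decline",
                    main = "Predictor contributions", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' Standard product-moment correlation between two equal-length series, as
#' used to relate epoch activity to seizure power across recordings.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `r` and `p_value`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("argument error: need equal lengths >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate error: zero variance in a series", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
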