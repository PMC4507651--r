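#' Threshold statistics of terrain-induced height differences
#'
#' For the per-point differences `corrected - conventional` and each
#' threshold k, computes `p_k`, the proportion of points whose absolute
#' difference exceeds k, and `mean_k`, the mean absolute difference over
#' that subset (0 when no difference exceeds k).
#'
#' @param conventional,corrected equal-length height vectors (m).
#' @param thresholds difference thresholds k in metres.
#' @return A data frame of class `difference_stats` with columns `k`,
#'   `p_k` (fraction) and `mean_k` (m); `p_k` is non-increasing in k and
#'   `mean_k >= k` wherever `p_k > 0`.
#' @export
difference_stats <- function(conventional, corrected,
                             thresholds = c(0.3, 0.5, 0.8, 1.0, 1.2, 1.5)) {
  if (length(conventional) != length(corrected))
    stop("height vectors must have equal length")
  n <- length(conventional)
  if (n == 0L) stop("no points")
  d <- abs(corrected - conventional)
  out <- data.frame(
    k = thresholds,
    p_k = vapply(thresholds, function(k) mean(d > k), 0),
    mean_k = vapply(thresholds, function(k)
      if (any(d > k)) mean(d[d > k]) else 0, 0))
  class(out) <- c("difference_stats", "data.frame")
  out
}

#' Height percentiles of vegetation returns
#'
#' Deciles h10..h90 and the mean height of the normalized heights above a
#' cutoff (1.8 m by default, excluding shrub-layer returns), the standard
#' plot-level LiDAR forest metrics. Percentiles use the linear-interpolation
#' quantile definition (type 7).
#'
#' @param heights normalized heights (m).
#' @param above cutoff in metres; only heights strictly above it are used.
#' @return Named numeric vector `h10`..`h90`, `hmean`.
#' @export
height_percentiles <- function(heights, above = 1.8) {
  h <- heights[heights > above]
  if (length(h) == 0L) stop("no heights above ", above, " m")
  q <- quantile(h, probs = seq(0.1, 0.9, by = 0.1), names = FALSE, type = 7)
  c(stats::setNames(q, paste0("h", seq(10, 90, by = 10))), hmean = mean(h))
}

#' Lorey's (basal-area-weighted) mean stand height
#'
#' `Lh = sum(G_i h_i) / sum(G_i)` with basal area
#' `G_i = pi (dbh_i / 200)^2` in square metres for dbh in centimetres.
#'
#' @param dbh stem diameters at breast height (cm), > 0.
#' @param height stem heights (m).
#' @return Lorey's height in metres (always within the range of `height`).
#' @examples
#' lorey_height(c(10, 20), c(10, 20))  # 18: basal-area ratio 1:4
#' @export
lorey_height <- function(dbh, height) {
  if (length(dbh) == 0L) stop("need at least one stem")
  if (length(dbh) != length(height)) stop("dbh and height lengths differ")
  if (any(dbh <= 0)) stop("all dbh must be positive")
  G <- pi * (dbh / 200)^2
  sum(G * height) / sum(G)
}

# pooled K-fold cross-validated R^2 for an OLS formula
.kfold_r2 <- function(data, terms, folds) {
  y <- data$Lh
  pred <- numeric(length(y))
  fml <- stats::reformulate(terms, response = "Lh")
  for (f in unique(folds)) {
    hold <- folds == f
    fit <- stats::lm(fml, data = data[!hold, , drop = FALSE])
    pred[hold] <- stats::predict(fit, newdata = data[hold, , drop = FALSE])
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Stepwise Lorey's-height regression on LiDAR height percentiles
#'
#' Fits `Lh = b0 + b1 h10 + ... + b9 h90 + b10 hmean + e` by forward
#' stepwise ordinary least squares: at each step the candidate predictor
#' that most improves the pooled K-fold cross-validated R-squared is added,
#' and selection stops when no addition improves it. Fold assignment is
#' seeded and stratified by response decile so the selection is
#' deterministic and stable at small n.
#'
#' @param plots data frame with response column `Lh` and predictor columns
#'   `h10`..`h90`, `hmean` (one row per field plot).
#' @param k_folds number of cross-validation folds (default 10); requires
#'   at least `k_folds` plots.
#' @param seed integer seed for the fold assignment.
#' @return An object of class `lorey_model`: the selected terms, the final
#'   [stats::lm()] fit, in-sample and adjusted R-squared, residual RMSE and
#'   the final (maximum) K-fold R-squared. Supports `print`, `summary`,
#'   `coef`, `predict`, `fitted` and `residuals`.
#' @export
fit_lorey_model <- function(plots, k_folds = 10L, seed = 1L) {
  preds <- c(paste0("h", seq(10, 90, by = 10)), "hmean")
  miss <- setdiff(c("Lh", preds), names(plots))
  if (length(miss)) stop("plots is missing column(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(plots)
  if (n < k_folds) stop("need at least k_folds = ", k_folds, " plots")
  X <- as.matrix(plots[preds])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    dropped <- preds[qrX$pivot[-seq_len(qrX$rank)] - 1L]
    stop("singular design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  # folds stratified by response decile
  folds <- .with_seed(seed, {
    dec <- cut(rank(plots$Lh, ties.method = "first"),
               breaks = k_folds, labels = FALSE)
    f <- integer(n)
    for (d in unique(dec)) {
      i <- which(dec == d)
      f[i] <- sample(rep_len(seq_len(k_folds), length(i)))
    }
    f
  })
  selected <- character(0)
  best_cv <- .kfold_r2(plots, "1", folds)   # intercept-only baseline
  repeat {
    remaining <- setdiff(preds, selected)
    if (!length(remaining)) break
    cvs <- vapply(remaining, function(p)
      .kfold_r2(plots, c(selected, p), folds), 0)
    if (max(cvs) <= best_cv) break
    best_cv <- max(cvs)
    selected <- c(selected, remaining[which.max(cvs)])
  }
  fml <- if (length(selected)) stats::reformulate(selected, response = "Lh")
         else Lh ~ 1
  fit <- stats::lm(fml, data = plots)
  sm <- summary(fit)
  structure(list(terms = selected, fit = fit,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 rmse = sqrt(sum(resid(fit)^2) / fit$df.residual),
                 kfold_r_squared = best_cv,
                 k_folds = k_folds, seed = seed, n = n),
            class = "lorey_model")
}

#' @export
print.lorey_model <- function(x, ...) {
  cat("Lorey's height model (forward stepwise OLS, K-fold selection)\n")
  cat("  terms:", paste(x$terms, collapse = " + "), "\n")
  cat(sprintf("  n = %d, R2 = %.3f (adj %.3f), RMSE = %.3f m, %d-fold R2 = %.3f\n",
              x$n, x$r_squared, x$adj_r_squared, x$rmse, x$k_folds,
              x$kfold_r_squared))
  invisible(x)
}

#' @export
summary.lorey_model <- function(object, ...) {
  print(object)
  cat("\nCoefficients:\n")
  print(summary(object$fit)$coefficients)
  invisible(object)
}

#' @export
coef.lorey_model <- function(object, ...) coef(object$fit)

#' @export
predict.lorey_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::fitted(object$fit)
  else stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
fitted.lorey_model <- function(object, ...) stats::fitted(object$fit)

#' @export
residuals.lorey_model <- function(object, ...) stats::residuals(object$fit)

#' Read a per-stem field plot table
#'
#' CSV with one row per stem and columns `plot_id`, `slope_deg`, `dbh_cm`,
#' `height_m`.
#'
#' @param path CSV file.
#' @return Data frame with those columns.
#' @export
read_plot_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("plot_id", "slope_deg", "dbh_cm", "height_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plot table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$dbh_cm <= 0) || any(df$height_m <= 0))
    stop("dbh_cm and height_m must be positive")
  df
}

#' Per-plot Lorey's heights from a stem table
#'
#' @param stems data frame as returned by [read_plot_table()].
#' @return Data frame with one row per plot: `plot_id`, `slope_deg`, `Lh`.
#' @export
lorey_by_plot <- function(stems) {
  ids <- unique(stems$plot_id)
  do.call(rbind, lapply(ids, function(id) {
    s <- stems[stems$plot_id == id, ]
    data.frame(plot_id = id, slope_deg = s$slope_deg[1],
               Lh = lorey_height(s$dbh_cm, s$height_m))
  }))
}

#' Linear regression of exceedance proportion on slope gradient
#'
#' Simple OLS of the plot-level proportion `p_k` (fraction of points whose
#' terrain-induced height difference exceeds k) on plot slope gradient.
#'
#' @param slope_deg plot slope gradients (degrees), length >= 3.
#' @param p proportions `p_k` (fractions).
#' @return A list with `slope` (per degree), `intercept` and `r_squared`
#'   (0 when the response has zero variance).
#' @export
slope_proportion_regression <- function(slope_deg, p) {
  if (length(slope_deg) != length(p)) stop("input lengths differ")
  if (length(p) < 3L) stop("need at least 3 plots")
  if (stats::var(slope_deg) == 0) stop("slope gradients have zero variance")
  if (stats::var(p) == 0)
    return(list(slope = 0, intercept = mean(p), r_squared = 0))
  fit <- stats::lm(p ~ slope_deg)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = summary(fit)$r.squared)
}
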