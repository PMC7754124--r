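#' Partial least squares discriminant analysis (NIPALS)
#'
#' Fits a PLS2 model of the column-mean-centred feature matrix against the
#' one-hot class-membership matrix, by the NIPALS algorithm with deflation of
#' X (and Y) after each component.  The fit is deterministic: the inner loop
#' is initialized from the Y column of maximal variance and iterated to a
#' relative score-change tolerance of 1e-10 (at most 500 iterations, after
#' which a diagnostic error is raised).  PLS-DA is used here as the
#' separation diagnostic behind score plots; classification itself is done by
#' SVM/RF under cross-validation.
#'
#' @param x A [pesi_features()] (TIC-normalized or not) or a numeric matrix.
#' @param labels Class labels, one per row; taken from the feature matrix
#'   metadata when omitted.  At least two classes must be present.
#' @param ncomp Number of components (default 2, what a score plot shows);
#'   must not exceed `min(nrow - 1, ncol)`.
#' @param scale Divide columns by their standard deviation in addition to
#'   mean-centring (default `FALSE`).
#' @param tol,max_iter Inner NIPALS convergence controls.
#' @return An object of class `plsda` with weights `W`, x-loadings `P`,
#'   y-loadings `Q`, scores `T` (columns mutually orthogonal), per-component
#'   explained X-variance fractions, the class encoding, and per-row
#'   metadata.
#' @export
plsda <- function(x, labels = NULL, ncomp = 2, scale = FALSE,
                  tol = 1e-10, max_iter = 500) {
  meta <- NULL
  if (inherits(x, "pesi_features")) {
    meta <- x$meta
    if (is.null(labels)) labels <- x$meta$tissue_label
    x <- x$x
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop("need one label per row: ", length(labels), " labels, ",
         nrow(x), " rows")
  lev <- sort(unique(labels))
  if (length(lev) < 2) stop("PLS-DA needs at least 2 classes, got 1")
  if (ncomp > min(nrow(x) - 1, ncol(x)))
    stop("ncomp must be <= min(nrow - 1, ncol) = ",
         min(nrow(x) - 1, ncol(x)))
  if (is.null(meta))
    meta <- data.frame(sample_id = rownames(x) %||%
                         paste0("row", seq_len(nrow(x))),
                       tissue_label = labels, stringsAsFactors = FALSE)
  y <- outer(labels, lev, `==`) + 0
  colnames(y) <- lev
  x_center <- colMeans(x)
  xc <- sweep(x, 2, x_center)
  x_scale <- rep(1, ncol(x))
  if (scale) {
    x_scale <- apply(xc, 2, sd)
    x_scale[x_scale == 0] <- 1
    xc <- sweep(xc, 2, x_scale, "/")
  }
  yc <- sweep(y, 2, colMeans(y))
  ssx <- sum(xc^2)
  n <- nrow(xc); p <- ncol(xc); g <- ncol(yc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, g, ncomp); Tm <- matrix(0, n, ncomp)
  r2x <- numeric(ncomp); iters <- integer(ncomp)
  for (a in seq_len(ncomp)) {
    u <- yc[, which.max(apply(yc, 2, var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(xc, u))
      w <- w / sqrt(sum(w^2))
      t_new <- drop(xc %*% w)
      q <- drop(crossprod(yc, t_new)) / sum(t_new^2)
      u <- drop(yc %*% q) / sum(q^2)
      if (sqrt(sum((t_new - t_old)^2)) <= tol * sqrt(sum(t_new^2))) break
      t_old <- t_new
      if (it == max_iter)
        stop("NIPALS did not converge for component ", a, " after ",
             max_iter, " iterations (last relative score change ",
             format(sqrt(sum((t_new - t_old)^2)) / sqrt(sum(t_new^2))), ")")
    }
    iters[a] <- it
    pv <- drop(crossprod(xc, t_new)) / sum(t_new^2)
    xc <- xc - tcrossprod(t_new, pv)
    yc <- yc - tcrossprod(t_new, q)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- q; Tm[, a] <- t_new
    r2x[a] <- sum(t_new^2) * sum(pv^2) / ssx
  }
  structure(list(W = W, P = P, Q = Q, T = Tm,
                 explained_x_variance = r2x, levels = lev,
                 x_center = x_center, x_scale = x_scale, scaled = scale,
                 meta = meta, labels = labels, iterations = iters),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA (NIPALS): %d components, %d fragments x %d bins, classes: %s\n",
              ncol(x$T), nrow(x$T), length(x$x_center),
              paste(x$levels, collapse = ", ")))
  cat("  explained X-variance per component:",
      paste(sprintf("%.1f%%", 100 * x$explained_x_variance), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
summary.plsda <- function(object, ...) {
  print(object)
  cat("  NIPALS iterations per component:",
      paste(object$iterations, collapse = " "), "\n")
  invisible(object)
}

#' Project new spectra onto a fitted PLS-DA model
#'
#' @param object A [plsda()] fit.
#' @param newdata Matrix or `pesi_features` over the same bins.
#' @param ... Unused.
#' @return The score matrix of `newdata`.
#' @export
predict.plsda <- function(object, newdata, ...) {
  if (inherits(newdata, "pesi_features")) newdata <- newdata$x
  xc <- sweep(as.matrix(newdata), 2, object$x_center)
  if (object$scaled) xc <- sweep(xc, 2, object$x_scale, "/")
  xc %*% object$W %*% solve(crossprod(object$P, object$W))
}

#' Score-plot table
#'
#' One row per fragment with its identity, class label and the scores on two
#' chosen components — the table behind a PLS-DA score plot.
#'
#' @param model A [plsda()] fit.
#' @param component_i,component_j Component indices (default 1 and 2).
#' @return A data frame with columns `sample_id`, `label`, `score_i`,
#'   `score_j`.
#' @export
scores_table <- function(model, component_i = 1, component_j = 2) {
  k <- ncol(model$T)
  if (component_i > k || component_j > k)
    stop("model has only ", k, " components")
  data.frame(sample_id = model$meta$sample_id, label = model$labels,
             score_i = model$T[, component_i],
             score_j = model$T[, component_j], stringsAsFactors = FALSE)
}

#' @export
plot.plsda <- function(x, components = c(1, 2), ...) {
  st <- scores_table(x, components[1], components[2])
  cls <- factor(st$label)
  plot(st$score_i, st$score_j, col = as.integer(cls), pch = 19,
       xlab = sprintf("component %d (%.1f%% X-var)", components[1],
                      100 * x$explained_x_variance[components[1]]),
       ylab = sprintf("component %d (%.1f%% X-var)", components[2],
                      100 * x$explained_x_variance[components[2]]), ...)
  legend("topright", legend = levels(cls), col = seq_along(levels(cls)),
         pch = 19, bty = "n")
  invisible(x)
}
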