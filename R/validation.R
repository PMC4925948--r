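# Evaluation machinery: Hausdorff distance between point sets / curves and
# maximum-likelihood fusion of multiple annotators' binary edge labels
# (two-class confusion-matrix EM, Dawid-Skene form).

#' Hausdorff distance between two point sets
#'
#' \eqn{\delta_H(X, Y) = \max\{\max_{x} \min_{y} d(x,y),\;
#' \max_{y} \min_{x} d(x,y)\}} under the Euclidean metric.
#'
#' @param X,Y numeric matrices of points (rows), same number of columns.
#' @return scalar distance.
#' @export
hausdorff_distance <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0 || nrow(Y) == 0) stop("point sets must be nonempty")
  if (ncol(X) != ncol(Y)) stop("dimension mismatch")
  # cross-distance matrix via the expanded form, then an exact recomputation
  # of the selected nearest pairs (the expansion cancels catastrophically
  # for near-identical points)
  xx <- rowSums(X^2); yy <- rowSums(Y^2)
  D2 <- outer(xx, yy, "+") - 2 * tcrossprod(X, Y)
  exact <- function(i, j) sqrt(sum((X[i, ] - Y[j, ])^2))
  jmin <- max.col(-D2, ties.method = "first")
  dxy <- max(vapply(seq_len(nrow(X)), function(i) exact(i, jmin[i]), numeric(1)))
  imin <- max.col(-t(D2), ties.method = "first")
  dyx <- max(vapply(seq_len(nrow(Y)), function(j) exact(imin[j], j), numeric(1)))
  max(dxy, dyx)
}

#' Hausdorff discrepancy between an extracted and a reference curve
#'
#' Both curves are densely resampled along their polylines (default step
#' 0.25 px) so the set-based Hausdorff distance approximates the distance
#' between the continuous curves, then compared with [hausdorff_distance()].
#'
#' @param extracted,reference n x 2 point matrices or `wall_curve`s /
#'   `centreline_curve`s.
#' @param pixel_spacing_mm spacing used to also report the distance in mm.
#' @param resample_step resampling step in px.
#' @return list with `px` and `mm`.
#' @export
compare_walls <- function(extracted, reference, pixel_spacing_mm = 1,
                          resample_step = 0.25) {
  px <- hausdorff_distance(resample_polyline2d(curve_points(extracted), resample_step),
                           resample_polyline2d(curve_points(reference), resample_step))
  list(px = px, mm = px * mean(pixel_spacing_mm))
}

# Crop a reference polyline to the span covered by an extracted curve:
# the reference is cut at the arc positions nearest the extracted endpoints
# (skeleton-based curves are slightly shorter than the full ground-truth
# silhouette; the uncovered ends are not delineation errors).
crop_reference_to_span <- function(reference, extracted, step = 0.25) {
  R <- resample_polyline2d(curve_points(reference), step)
  E <- curve_points(extracted)
  near <- function(p) which.min((R[, 1] - p[1])^2 + (R[, 2] - p[2])^2)
  i1 <- near(E[1, ]); i2 <- near(E[nrow(E), ])
  R[sort(c(i1, i2))[1]:sort(c(i1, i2))[2], , drop = FALSE]
}

curve_points <- function(x) {
  if (inherits(x, c("wall_curve", "centreline_curve"))) x$points
  else as.matrix(x)
}

resample_polyline2d <- function(P, step) {
  if (nrow(P) < 2) return(P)
  seg <- sqrt(rowSums(diff(P)^2))
  keep <- c(TRUE, seg > 0)
  P <- P[keep, , drop = FALSE]
  if (nrow(P) < 2) return(P)
  al <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  s <- unique(c(seq(0, al[length(al)], by = step), al[length(al)]))
  cbind(stats::approx(al, P[, 1], xout = s)$y,
        stats::approx(al, P[, 2], xout = s)$y)
}

#' Maximum-likelihood consensus of multiple binary annotators
#'
#' EM in the two-class Dawid-Skene form. The E-step computes each item's
#' posterior probability of being a true edge from the current per-annotator
#' confusion matrices and class priors; the M-step re-estimates confusion
#' matrices and priors from the posteriors. Initialization is the majority
#' vote; iteration stops when the largest posterior change drops below `tol`.
#' Degenerate confusion rows (a truth class with no posterior mass, or rows
#' that would put zero probability on an observed label and so break the
#' E-step) are regularized with a pseudocount, with a warning.
#'
#' @param labels items x annotators matrix of 0/1 labels (1 = edge).
#' @param max_iter maximum EM iterations (default 100).
#' @param tol convergence tolerance on posteriors (default 1e-6).
#' @param pseudocount regularizer for degenerate rows (default 0.5).
#' @return a `consensus_result`: list with `posterior` (per item P(edge)),
#'   `labels` (hard consensus, posterior >= 0.5), `confusion` (list of 2 x 2
#'   matrices, rows = truth 0/1, cols = label 0/1, rows sum to 1),
#'   `error_rate` (per annotator, prior-weighted off-diagonal mass), `prior`
#'   (P(edge)), `loglik` (trace across iterations), `iterations`.
#' @export
ml_consensus <- function(labels, max_iter = 100, tol = 1e-6,
                         pseudocount = 0.5) {
  L <- as.matrix(labels)
  if (!all(L %in% c(0, 1))) stop("labels must be 0/1")
  n <- nrow(L); m <- ncol(L)
  if (n < 2 || m < 2) stop("need at least 2 items and 2 annotators")
  p <- rowMeans(L)                       # majority-vote initialization
  loglik <- numeric(0)
  warned <- FALSE
  constant <- apply(L, 2L, function(x) length(unique(x)) == 1L)
  if (any(constant)) {
    warning("annotator(s) with constant labels: confusion rows regularized with pseudocount")
    warned <- TRUE
  }
  theta <- vector("list", m)
  for (it in seq_len(max_iter)) {
    # M-step
    w1 <- p; w0 <- 1 - p
    prior <- mean(p)
    counts <- vector("list", m)
    for (j in seq_len(m)) {
      c11 <- sum(w1 * L[, j]); c10 <- sum(w1 * (1 - L[, j]))
      c01 <- sum(w0 * L[, j]); c00 <- sum(w0 * (1 - L[, j]))
      counts[[j]] <- rbind(c(c00, c01), c(c10, c11))
      th <- counts[[j]] / pmax(rowSums(counts[[j]]), .Machine$double.eps)
      if (constant[j])
        th <- (counts[[j]] + pseudocount) /
          (rowSums(counts[[j]]) + 2 * pseudocount)
      # a truth class with no posterior mass leaves an undefined row
      for (t in 1:2) if (sum(counts[[j]][t, ]) < 1e-12) {
        th[t, ] <- (counts[[j]][t, ] + pseudocount) /
          (sum(counts[[j]][t, ]) + 2 * pseudocount)
        if (!warned) {
          warning("degenerate confusion row(s) regularized with pseudocount")
          warned <- TRUE
        }
      }
      theta[[j]] <- th
    }
    prior <- min(max(prior, 1e-12), 1 - 1e-12)
    # E-step (log domain)
    estep <- function(theta) {
      lp1 <- log(prior); lp0 <- log1p(-prior)
      for (j in seq_len(m)) {
        lp1 <- lp1 + ifelse(L[, j] == 1, log(theta[[j]][2, 2]), log(theta[[j]][2, 1]))
        lp0 <- lp0 + ifelse(L[, j] == 1, log(theta[[j]][1, 2]), log(theta[[j]][1, 1]))
      }
      list(lp1 = lp1, lp0 = lp0)
    }
    e <- estep(theta)
    if (any(!is.finite(pmax(e$lp1, e$lp0)))) {
      # some item is impossible under both truth classes: zero cells from
      # conflicting deterministic annotators; soften every affected matrix
      theta <- lapply(counts, function(cnt) {
        if (any(cnt / pmax(rowSums(cnt), .Machine$double.eps) == 0))
          (cnt + pseudocount) / (rowSums(cnt) + 2 * pseudocount)
        else cnt / pmax(rowSums(cnt), .Machine$double.eps)
      })
      if (!warned) {
        warning("degenerate confusion row(s) regularized with pseudocount")
        warned <- TRUE
      }
      e <- estep(theta)
    }
    lp1 <- e$lp1; lp0 <- e$lp0
    mx <- pmax(lp1, lp0)
    loglik <- c(loglik, sum(mx + log(exp(lp1 - mx) + exp(lp0 - mx))))
    p_new <- 1 / (1 + exp(lp0 - lp1))
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
  }
  prior <- mean(p)
  err <- vapply(theta, function(th) prior * th[2, 1] + (1 - prior) * th[1, 2],
                numeric(1))
  dimnames_th <- list(truth = c("0", "1"), label = c("0", "1"))
  theta <- lapply(theta, function(th) { dimnames(th) <- dimnames_th; th })
  structure(list(posterior = p, labels = as.integer(p >= 0.5),
                 confusion = theta, error_rate = err, prior = prior,
                 loglik = loglik, iterations = length(loglik)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d items, %d annotators, prior %.3f, %d EM iteration(s)\n",
              length(x$posterior), length(x$confusion), x$prior, x$iterations))
  cat("per-annotator error rates:", sprintf("%.4f", x$error_rate), "\n")
  invisible(x)
}

#' ROC operating point of a confusion matrix
#'
#' @param confusion 2 x 2 matrix, rows = truth (0, 1), columns = label
#'   (0, 1), rows summing to 1.
#' @return named vector `c(FPR, TPR)`: TPR = P(label 1 | truth 1),
#'   FPR = P(label 1 | truth 0).
#' @export
roc_point <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(abs(rowSums(confusion) - 1) > 1e-8))
    stop("confusion matrix rows must sum to 1")
  c(FPR = confusion[1, 2], TPR = confusion[2, 2])
}

#' Read / write annotator labels as CSV
#'
#' Long format with columns `item`, `annotator`, `label`.
#'
#' @param path CSV file path.
#' @return for the reader, an items x annotators 0/1 matrix.
#' @export
read_labels_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("item", "annotator", "label") %in% names(d)))
  tab <- stats::xtabs(label ~ item + annotator, data = d)
  m <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

#' @rdname read_labels_csv
#' @param labels items x annotators matrix.
#' @export
write_labels_csv <- function(labels, path) {
  L <- as.matrix(labels)
  items <- rownames(L); if (is.null(items)) items <- seq_len(nrow(L))
  ann <- colnames(L); if (is.null(ann)) ann <- seq_len(ncol(L))
  d <- data.frame(item = rep(items, times = ncol(L)),
                  annotator = rep(ann, each = nrow(L)),
                  label = as.vector(L))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
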