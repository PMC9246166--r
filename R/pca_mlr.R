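#' Principal-component source identification
#'
#' Correlation-matrix PCA of a sample-by-compound concentration table with
#' the retention and reporting conventions of the receptor-modelling
#' literature: compounds are standardized to z-scores, components with
#' eigenvalue > 1 are retained (Kaiser criterion), and retained loadings are
#' varimax-rotated with Kaiser normalization.  Each rotated component is
#' sign-flipped so its largest-magnitude loading is positive.  Constant
#' compounds carry no correlation information and are dropped with a
#' warning.
#'
#' @param x concentration matrix (n samples x 16 compounds,
#'   ng g\eqn{^{-1}}); n must be at least 3.
#' @param eigenvalue_cutoff retention threshold on the eigenvalues
#'   (default 1, the Kaiser criterion).
#' @return Object of class \code{pah_pca}: list with \code{n_retained},
#'   \code{loadings} (compounds x retained PCs, rotated), \code{rotation}
#'   (orthogonal rotation matrix), \code{eigenvalues} (all), \code{variance}
#'   and \code{cumulative_variance} (fractions of total standardized
#'   variance per retained PC, rotated sums of squared loadings),
#'   \code{scores} (rotated standardized component scores),
#'   \code{communalities}, \code{dropped} (compound abbreviations removed as
#'   constant).
#' @export
run_pca <- function(x, eigenvalue_cutoff = 1.0) {
  x <- as_concentration_matrix(x)
  if (nrow(x) < 3L) stop("PCA needs at least 3 samples")
  sds <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant compound column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  z <- scale(x)
  m <- ncol(z)
  eg <- eigen(stats::cor(x), symmetric = TRUE)
  eigenvalues <- pmax(eg$values, 0)
  keep <- which(eigenvalues > eigenvalue_cutoff)
  if (!length(keep)) keep <- 1L
  k <- length(keep)
  loadings <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eigenvalues[keep]), k)
  # unit-variance (standardized) component scores
  scores <- z %*% eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eigenvalues[keep]), k)
  rotation <- diag(1, k)
  if (k > 1L) {
    vm <- stats::varimax(loadings, normalize = TRUE)
    rotation <- vm$rotmat
    loadings <- loadings %*% rotation
    scores <- scores %*% rotation
  }
  flip <- vapply(seq_len(k), function(j) {
    sign(loadings[which.max(abs(loadings[, j])), j])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2L, flip, `*`)
  scores <- sweep(scores, 2L, flip, `*`)
  ss <- colSums(loadings^2)
  ord <- order(ss, decreasing = TRUE)
  loadings <- loadings[, ord, drop = FALSE]
  scores <- scores[, ord, drop = FALSE]
  rotation <- rotation[, ord, drop = FALSE]
  ss <- ss[ord]
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(rownames(x), colnames(loadings))
  structure(list(
    n_retained = k,
    loadings = loadings,
    rotation = rotation,
    eigenvalues = eigenvalues,
    variance = ss / m,
    cumulative_variance = cumsum(ss / m),
    scores = scores,
    communalities = rowSums(loadings^2),
    dropped = dropped
  ), class = "pah_pca")
}

#' Apportion total PAHs to principal components by multiple linear
#' regression
#'
#' Regresses the standardized per-sample total PAH concentration on the
#' rotated component scores.  Each component's share of the total is its
#' regression coefficient over the sum of positive coefficients; components
#' with non-positive coefficients are assigned a zero share.
#'
#' @param result a \code{pah_pca} fit from [run_pca()].
#' @param totals numeric vector of per-sample total PAH concentrations,
#'   aligned with the rows used in the PCA.
#' @param scores component score matrix; defaults to the scores stored in
#'   \code{result}.
#' @return List with \code{coefficients} (per retained PC),
#'   \code{contributions} (non-negative fractions summing to 1) and
#'   \code{r_squared} of the regression.
#' @export
apportion_mlr <- function(result, totals, scores = result$scores) {
  stopifnot(inherits(result, "pah_pca"))
  if (length(totals) != nrow(scores)) {
    stop("'totals' must align with the score rows")
  }
  z_total <- as.numeric(scale(totals))
  fit <- stats::lm(z_total ~ scores)
  b <- stats::coef(fit)[-1L]
  names(b) <- colnames(scores)
  pos <- pmax(b, 0)
  if (sum(pos) <= 0) {
    stop("apportionment undefined: no component has a positive coefficient")
  }
  list(coefficients = b,
       contributions = pos / sum(pos),
       r_squared = summary(fit)$r.squared)
}

#' @export
print.pah_pca <- function(x, digits = 3, ...) {
  cat("Correlation PCA:", x$n_retained,
      "component(s) retained (eigenvalue > 1)\n")
  cat("Cumulative variance:",
      paste(sprintf("%.1f%%", 100 * x$cumulative_variance),
            collapse = ", "), "\n")
  bold <- abs(x$loadings) >= 0.5
  disp <- format(round(x$loadings, digits))
  disp[bold] <- paste0(disp[bold], "*")
  print(disp, quote = FALSE, ...)
  cat("(* |loading| >= 0.50)\n")
  invisible(x)
}
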