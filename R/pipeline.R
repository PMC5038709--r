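# Feature pipeline: min-max normalization -> mutual-information screening
# and mRMR selection -> PCA -> kernel (generalized) discriminant analysis.

#' Min-max normalization
#'
#' Maps each column through `(x - min) / (max - min)` onto `[0, 1]`.
#' Constant columns map to 0.  The training bounds are returned so the
#' same affine map (with clipping to `[0, 1]`) can be applied
#' out-of-sample via [apply_minmax()].
#'
#' @param x Numeric matrix or data frame (columns = features).
#' @return List with `scaled` (matrix in `[0,1]`) and `bounds` (2 x p
#'   matrix of column minima and maxima).
#' @examples
#' minmax_normalize(cbind(a = c(2, 4, 6)))$scaled  # 0, 0.5, 1
#' @export
minmax_normalize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("need at least one row")
  all_na <- apply(x, 2, function(v) all(is.na(v)))
  if (any(all_na))
    stop("all-missing feature column(s): ",
         paste(colnames(x)[all_na], collapse = ", "))
  lo <- apply(x, 2, min, na.rm = TRUE)
  hi <- apply(x, 2, max, na.rm = TRUE)
  bounds <- rbind(min = lo, max = hi)
  list(scaled = apply_minmax(x, bounds), bounds = bounds)
}

#' @rdname minmax_normalize
#' @param bounds Bounds matrix from a previous fit.
#' @export
apply_minmax <- function(x, bounds) {
  x <- as.matrix(x)
  lo <- bounds["min", colnames(x)]
  hi <- bounds["max", colnames(x)]
  rng <- hi - lo
  rng[rng == 0] <- 1  # constant training column -> 0 after shift
  out <- sweep(sweep(x, 2, lo, "-"), 2, rng, "/")
  pmin(pmax(out, 0), 1)
}

bin_variable <- function(v, n_bins) {
  if (is.numeric(v)) {
    rng <- range(v, finite = TRUE)
    if (!all(is.finite(rng)) || diff(rng) == 0) return(factor(rep(1L, length(v))))
    cut(v, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
        include.lowest = TRUE)
  } else factor(v)
}

#' Mutual information between a feature and labels
#'
#' Equal-width-binned mutual information in bits.  Numeric inputs are
#' binned into `n_bins` equal-width bins over their observed range;
#' categorical inputs are used as-is.  Pairs with a missing value are
#' dropped.
#'
#' @param x Feature column (numeric or categorical).
#' @param y Labels (or a second feature, for redundancy terms).
#' @param n_bins Number of equal-width bins for numeric inputs.
#' @return Mutual information in bits (>= 0).
#' @export
mutual_information <- function(x, y, n_bins = 10) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) return(0)
  tab <- table(bin_variable(x, n_bins), bin_variable(y, n_bins))
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  ind <- outer(px, py)
  nz <- p > 0
  max(sum(p[nz] * log2(p[nz] / ind[nz])), 0)
}

#' Minimal-redundancy maximal-relevance feature selection
#'
#' Greedy forward mRMR with the difference (MID) criterion: after
#' discarding every feature whose mutual information with the label is
#' zero, repeatedly add the feature maximizing
#' `MI(feature, label) - mean MI(feature, already-selected)`.
#' Ties break by feature name order.
#'
#' @param x Feature matrix/data frame (columns named).
#' @param labels Class labels, one per row.
#' @param k Number of features to select; must not exceed the number of
#'   nonzero-MI features.
#' @param n_bins Bins for the MI estimator.
#' @return Character vector of selected names (in selection order) with
#'   the relevance scores as the `"relevance"` attribute.
#' @export
mrmr_select <- function(x, labels, k, n_bins = 10) {
  x <- as.matrix(x)
  rel <- vapply(colnames(x), function(f)
    mutual_information(x[, f], labels, n_bins), numeric(1))
  avail <- names(rel)[rel > 1e-12]
  if (k > length(avail))
    stop("k = ", k, " exceeds the ", length(avail),
         " features with nonzero mutual information")
  avail <- avail[order(-rel[avail], avail)]
  selected <- avail[1]
  avail <- setdiff(avail, selected)
  red_cache <- list()
  while (length(selected) < k) {
    newest <- selected[length(selected)]
    for (f in avail)
      red_cache[[f]] <- c(red_cache[[f]],
                          mutual_information(x[, f], x[, newest], n_bins))
    score <- vapply(avail, function(f) rel[f] - mean(red_cache[[f]]),
                    numeric(1))
    pick <- avail[order(-score, avail)][1]
    selected <- c(selected, pick)
    avail <- setdiff(avail, pick)
  }
  structure(selected, relevance = rel[selected])
}

#' Principal component analysis with a fixed sign convention
#'
#' Centers the data and projects it onto the top-variance orthonormal
#' directions.  Each component's sign is fixed so that its
#' largest-magnitude loading is positive, making the decomposition
#' reproducible across BLAS implementations.
#'
#' @param x Numeric matrix.
#' @param n_components Number of components; if `NULL`, the smallest
#'   number covering `var_target` of the variance.
#' @param var_target Explained-variance target used when `n_components`
#'   is `NULL`.
#' @return List with `scores`, `basis` (p x d orthonormal loadings),
#'   `explained` (variance fractions, non-increasing), `center`.
#' @export
pca_fit_transform <- function(x, n_components = NULL, var_target = 0.95) {
  x <- as.matrix(x)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  if (is.null(n_components))
    n_components <- which(cumsum(frac) >= var_target - 1e-12)[1]
  n_components <- min(n_components, ncol(pc$rotation))
  basis <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(basis)))
    if (basis[which.max(abs(basis[, j])), j] < 0) basis[, j] <- -basis[, j]
  scores <- sweep(x, 2, pc$center, "-") %*% basis
  list(scores = scores, basis = basis,
       explained = frac[seq_len(n_components)], center = pc$center)
}

rbf_kernel <- function(a, b, sigma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

median_heuristic <- function(x, max_points = 500) {
  n <- nrow(x)
  idx <- if (n > max_points) round(seq(1, n, length.out = max_points)) else seq_len(n)
  d <- stats::dist(x[idx, , drop = FALSE])
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Generalized (kernel) discriminant analysis
#'
#' Kernel Fisher discriminant: finds projection directions in the
#' feature space induced by the kernel that maximize between-class over
#' within-class scatter, concentrating same-class points.  With a
#' linear kernel and vanishing regularization the directions coincide
#' with classical LDA.  For large training sets the scatter problem is
#' solved on a stratified subset of at most `max_points` landmark rows;
#' all data are projected through the landmarks.
#'
#' @param x Numeric matrix (e.g. PCA scores).
#' @param labels Class labels, one per row.
#' @param n_components Number of discriminant directions (at most
#'   number of classes - 1).
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param sigma RBF bandwidth; default is the median pairwise distance.
#' @param eps Within-class scatter regularization (> 0).
#' @param max_points Landmark cap for the eigenproblem.
#' @param seed Seed for the stratified landmark draw.
#' @return List of class `psych_gda` with `scores`, `alpha`
#'   (landmark coefficients), `landmarks`, `kernel`, `sigma`, `eps`,
#'   `classes`.
#' @export
gda_fit_transform <- function(x, labels, n_components = NULL,
                              kernel = c("rbf", "linear"), sigma = NULL,
                              eps = 1e-6, max_points = 750, seed = 1L) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (is.null(n_components)) n_components <- length(classes) - 1
  if (n_components > length(classes) - 1)
    stop("n_components must be at most number of classes - 1")
  if (eps < 0) stop("regularization eps must be positive")
  n <- nrow(x)
  if (n > max_points) {
    set.seed(as.integer(seed))
    idx <- unlist(lapply(classes, function(cl) {
      rows <- which(labels == cl)
      take <- max(2L, round(max_points * length(rows) / n))
      sort(sample(rows, min(take, length(rows))))
    }))
    idx <- sort(idx)
  } else idx <- seq_len(n)
  xl <- x[idx, , drop = FALSE]
  ll <- labels[idx]
  if (kernel == "rbf" && is.null(sigma)) sigma <- median_heuristic(xl)
  K <- if (kernel == "rbf") rbf_kernel(xl, xl, sigma) else tcrossprod(xl)
  nl <- length(idx)
  m_all <- rowMeans(K)
  M <- matrix(0, nl, nl)
  N <- matrix(0, nl, nl)
  for (cl in classes) {
    cols <- which(ll == cl)
    nc <- length(cols)
    mc <- rowMeans(K[, cols, drop = FALSE])
    dm <- mc - m_all
    M <- M + nc * tcrossprod(dm)
    Kc <- K[, cols, drop = FALSE]
    cKc <- Kc - matrix(mc, nl, nc)
    N <- N + tcrossprod(cKc)
  }
  N <- (N + t(N)) / 2 + eps * diag(nl)
  R <- tryCatch(chol(N), error = function(e)
    stop("within-class scatter is singular; raise the regularization eps"))
  # generalized eigenproblem M a = lambda N a via symmetric whitening
  S <- backsolve(R, t(backsolve(R, t(M), transpose = TRUE)), transpose = TRUE)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  alpha <- backsolve(R, es$vectors[, seq_len(n_components), drop = FALSE])
  for (j in seq_len(ncol(alpha))) {
    nrm <- sqrt(sum(alpha[, j]^2))
    if (nrm > 0) alpha[, j] <- alpha[, j] / nrm
    if (alpha[which.max(abs(alpha[, j])), j] < 0) alpha[, j] <- -alpha[, j]
  }
  model <- structure(list(alpha = alpha, landmarks = xl, kernel = kernel,
                          sigma = sigma, eps = eps, classes = classes,
                          eigenvalues = es$values[seq_len(n_components)]),
                     class = "psych_gda")
  model$scores <- gda_project(model, x)
  model
}

gda_project <- function(model, x) {
  x <- as.matrix(x)
  Kn <- if (model$kernel == "rbf") rbf_kernel(x, model$landmarks, model$sigma)
        else tcrossprod(x, model$landmarks)
  Kn %*% model$alpha
}

#' Fisher separation ratio
#'
#' Trace of the between-class scatter over the trace of the
#' within-class scatter of a score matrix — the quantity the
#' discriminant step of the pipeline is meant to increase.
#'
#' @param x Score matrix (rows = observations).
#' @param labels Class labels.
#' @return Non-negative scalar.
#' @export
fisher_ratio <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  mu <- colMeans(x)
  sb <- 0; sw <- 0
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    mc <- colMeans(x[rows, , drop = FALSE])
    sb <- sb + length(rows) * sum((mc - mu)^2)
    sw <- sw + sum(sweep(x[rows, , drop = FALSE], 2, mc, "-")^2)
  }
  sb / max(sw, .Machine$double.eps)
}

#' Fit the full feature pipeline
#'
#' Median-imputes flagged-missing values, min-max normalizes, screens
#' and orders features by mRMR (zero-MI features discarded), reduces
#' with PCA to the components covering `pca_var` of the variance, then
#' applies kernel discriminant analysis.  The fitted object transforms
#' new feature tables through exactly the stored maps.
#'
#' @param x Feature matrix/data frame.
#' @param labels Per-row class labels.
#' @param k_features Features to keep in mRMR (capped at the number of
#'   nonzero-MI features).
#' @param n_bins MI estimator bins.
#' @param pca_var PCA explained-variance target.
#' @param gda_components Discriminant components (default classes - 1).
#' @param kernel,sigma,eps,gda_max_points Passed to
#'   [gda_fit_transform()].
#' @param seed Seed for the GDA landmark draw.
#' @return Object of class `psych_pipeline` with a `predict` method;
#'   `$scores` holds the training discriminant scores.
#' @export
fit_pipeline <- function(x, labels, k_features = 30, n_bins = 10,
                         pca_var = 0.95, gda_components = NULL,
                         kernel = "rbf", sigma = NULL, eps = 1e-6,
                         gda_max_points = 750, seed = 1L) {
  x <- as.matrix(x)
  medians <- apply(x, 2, stats::median, na.rm = TRUE)
  xi <- impute_median(x, medians)
  mm <- minmax_normalize(xi)
  k <- min(k_features, count_nonzero_mi(mm$scaled, labels, n_bins))
  sel <- mrmr_select(mm$scaled, labels, k, n_bins)
  pca <- pca_fit_transform(mm$scaled[, sel, drop = FALSE],
                           var_target = pca_var)
  gda <- gda_fit_transform(pca$scores, labels, n_components = gda_components,
                           kernel = kernel, sigma = sigma, eps = eps,
                           max_points = gda_max_points, seed = seed)
  structure(list(medians = medians, bounds = mm$bounds,
                 selected = as.character(sel),
                 relevance = attr(sel, "relevance"),
                 pca = pca[c("basis", "explained", "center")],
                 gda = gda, scores = gda$scores, labels = labels),
            class = "psych_pipeline")
}

count_nonzero_mi <- function(x, labels, n_bins) {
  sum(vapply(seq_len(ncol(x)), function(j)
    mutual_information(x[, j], labels, n_bins), numeric(1)) > 1e-12)
}

impute_median <- function(x, medians) {
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- medians[colnames(x)[j]]
  }
  x
}

#' @export
predict.psych_pipeline <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, names(object$medians), drop = FALSE]
  x <- impute_median(x, object$medians)
  x <- apply_minmax(x, object$bounds)
  x <- x[, object$selected, drop = FALSE]
  pc <- sweep(x, 2, object$pca$center, "-") %*% object$pca$basis
  gda_project(object$gda, pc)
}

#' @export
print.psych_pipeline <- function(x, ...) {
  cat("Feature pipeline: ", length(x$selected), " mRMR features -> ",
      ncol(x$pca$basis), " PCs (", round(100 * sum(x$pca$explained), 1),
      "% var) -> ", ncol(x$gda$alpha), " ", x$gda$kernel,
      "-kernel discriminant component(s)\n", sep = "")
  cat("  top features:", paste(utils::head(x$selected, 8), collapse = ", "),
      "\n")
  invisible(x)
}
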