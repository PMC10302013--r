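# Low-dimensional embeddings of the trait space: PCA per trait category
# and t-SNE over all thirteen traits, plus a silhouette-based
# cluster-separation score for treated-vs-unstressed discrimination.

#' Build a z-scored feature matrix from a wide trait table
#'
#' Selects one (day, view) slice, keeps the requested trait subset,
#' drops rows with any missing trait (never imputes silently) and
#' z-scores every column. Zero-variance columns are dropped with a
#' warning before scaling.
#'
#' @param traits wide trait table ([trial_trait_table()]).
#' @param subset `"all13"`, `"area"`, `"boundary"` or `"color"`.
#' @param day,view optional filters (single values).
#' @return Numeric matrix with attributes `labels` (treatment) and
#'   `meta` (the retained metadata rows).
#' @export
feature_matrix <- function(traits, subset = c("all13", "area", "boundary", "color"),
                           day = NULL, view = NULL) {
  subset <- match.arg(subset)
  cols <- if (subset == "all13") trait_names() else trait_names(subset)
  if (!is.null(day)) traits <- traits[traits$day == day, ]
  if (!is.null(view)) traits <- traits[traits$view == view, ]
  X <- as.matrix(traits[, cols])
  keep <- stats::complete.cases(X)
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("feature_matrix: dropped %d row(s) with missing traits", dropped))
  }
  X <- X[keep, , drop = FALSE]
  meta <- traits[keep, setdiff(names(traits), cols), drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(colnames(X)[sds == 0], collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  X <- scale(X)
  attr(X, "labels") <- meta$treatment
  attr(X, "meta") <- meta
  X
}

#' Principal component analysis of a feature matrix
#'
#' Eigendecomposition of the column covariance of the (already z-scored)
#' matrix; scores are projections on the top eigenvectors. The sign of
#' each component is fixed by making its largest-magnitude loading
#' positive, so results are invariant to row order.
#'
#' @param fm numeric matrix (rows = plants, columns = scaled traits).
#' @param n_components number of components to keep.
#' @return An `embedding_result`: list with `coordinates`,
#'   `explained_variance` (all fractions, non-increasing), `loadings`,
#'   `method = "pca"`.
#' @export
pca_embed <- function(fm, n_components = 2) {
  X <- as.matrix(fm)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance column(s) before PCA")
    X <- X[, sds > 0, drop = FALSE]
  }
  X <- scale(X)
  cv <- stats::cov(X)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  load <- eg$vectors
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  k <- min(n_components, ncol(load))
  structure(list(coordinates = X %*% load[, seq_len(k), drop = FALSE],
                 explained_variance = ev / sum(ev),
                 loadings = load, method = "pca",
                 labels = attr(fm, "labels")),
            class = "embedding_result")
}

# conditional Gaussian affinities calibrated to a target perplexity by
# binary search on the per-row bandwidth (precision beta)
.tsne_affinities <- function(X, perplexity, tol = 1e-5, max_iter = 100L) {
  n <- nrow(X)
  ss <- rowSums(X^2)
  D2 <- pmax(outer(ss, ss, "+") - 2 * tcrossprod(X), 0)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  perp_row <- numeric(n)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in seq_len(max_iter)) {
      w <- exp(-d * beta)
      sw <- sum(w)
      p <- w / sw
      # Shannon entropy of the conditional distribution (nats)
      Hent <- -sum(ifelse(p > 0, p * log(p), 0))
      diff <- Hent - target
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
    perp_row[i] <- exp(Hent)
  }
  list(P = P, perplexity = perp_row)
}

#' t-distributed stochastic neighbour embedding
#'
#' Symmetric affinities from per-row Gaussian kernels calibrated so each
#' row's conditional perplexity matches the target (binary search on the
#' bandwidth); low-dimensional similarities from the Student-t kernel
#' with one degree of freedom; KL divergence minimized by momentum
#' gradient descent with early exaggeration and adaptive per-coordinate
#' gains. Deterministic for a fixed seed.
#'
#' @param fm numeric matrix (rows = plants, columns = scaled traits).
#' @param perplexity target perplexity; must be < `nrow(fm) / 3`.
#' @param dim embedding dimension.
#' @param seed integer seed for the random initialization (required).
#' @param max_iter gradient-descent iterations.
#' @return An `embedding_result` with `coordinates`, `kl_divergence`,
#'   `perplexity`, `seed`, `method = "tsne"`.
#' @export
tsne_embed <- function(fm, perplexity = 30, dim = 2, seed, max_iter = 600L) {
  X <- as.matrix(fm)
  n <- nrow(X)
  if (missing(seed) || is.null(seed)) stop("tsne_embed requires an explicit seed")
  if (perplexity >= n / 3) {
    stop(sprintf("perplexity %.0f too large for %d rows; use a value below %.0f",
                 perplexity, n, n / 3))
  }
  aff <- .tsne_affinities(X, perplexity)
  P <- aff$P
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, .Machine$double.xmin)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * dim, sd = 1e-4), n, dim)

  exaggeration <- 12; stop_exag <- 120L
  eta <- 200; momentum <- 0.5
  update <- matrix(0, n, dim)
  gains <- matrix(1, n, dim)
  Pe <- P * exaggeration
  for (iter in seq_len(max_iter)) {
    if (iter == stop_exag + 1L) Pe <- P
    if (iter == 250L) momentum <- 0.8
    ss <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(ss, ss, "+") - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.xmin)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- pmax(ifelse(sign(grad) != sign(update), gains + 0.2, gains * 0.8), 0.01)
    update <- momentum * update - eta * gains * grad
    Y <- Y + update
    Y <- sweep(Y, 2, colMeans(Y))
  }
  ss <- rowSums(Y^2)
  num <- 1 / (1 + pmax(outer(ss, ss, "+") - 2 * tcrossprod(Y), 0))
  diag(num) <- 0
  Q <- pmax(num / sum(num), .Machine$double.xmin)
  kl <- sum(P * log(P / Q))
  structure(list(coordinates = Y, method = "tsne", perplexity = perplexity,
                 row_perplexity = aff$perplexity, seed = seed,
                 kl_divergence = kl, labels = attr(fm, "labels")),
            class = "embedding_result")
}

#' Silhouette-based cluster separation of an embedding
#'
#' Mean silhouette coefficient of the label partition under the Euclidean
#' metric, in \[-1, 1\]; higher means better treated/unstressed
#' separation. A single present label yields a missing value.
#'
#' @param emb an `embedding_result` or bare coordinate matrix.
#' @param labels group labels (defaults to the embedding's stored labels).
#' @return Mean silhouette width, or `NA_real_`.
#' @export
cluster_separation <- function(emb, labels = NULL) {
  Y <- if (inherits(emb, "embedding_result")) emb$coordinates else as.matrix(emb)
  if (is.null(labels)) labels <- if (inherits(emb, "embedding_result")) emb$labels else NULL
  if (is.null(labels)) stop("labels are required")
  f <- factor(labels)
  if (nlevels(f) < 2L) return(NA_real_)
  sil <- cluster::silhouette(as.integer(f), stats::dist(Y))
  mean(sil[, "sil_width"])
}

#' Timepoint class of a trial day
#'
#' Maps days to the four panels used for per-timepoint embeddings:
#' before treatment (day <= 0), during treatment, end of treatment,
#' recovering, and after recovery.
#'
#' @param day numeric day(s) relative to treatment start.
#' @param stress a [stress_model()] (window lengths).
#' @return Character vector of classes.
#' @export
timepoint_class <- function(day, stress = stress_model()) {
  tend <- stress$treatment_days
  rend <- tend + stress$recovery_days
  out <- character(length(day))
  out[day <= 0] <- "before"
  out[day > 0 & day < tend] <- "during_treatment"
  out[day == tend] <- "after_treatment"
  out[day > tend & day < rend] <- "recovering"
  out[day >= rend] <- "after_recovery"
  out
}
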