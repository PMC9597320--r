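# Multivariate screening: sampling adequacy (KMO), correlation-matrix PCA
# with supplementary variables, direct oblimin rotation by gradient
# projection, and hierarchical k-means clustering of genotypes on retained
# component scores.

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2) over i != j, where q are
#' the anti-image partial correlations obtained from the inverse of the
#' correlation matrix.  Values above ~0.6 are conventionally considered
#' adequate for factor analysis.
#'
#' @param x numeric observations x variables matrix, or a correlation
#'   matrix (square, symmetric, unit diagonal).
#' @return KMO in [0, 1].  A near-singular correlation matrix is ridged by
#'   1e-8 on the diagonal with a warning.
#' @export
kmo <- function(x) {
  x <- as.matrix(x)
  iscor <- nrow(x) == ncol(x) && isTRUE(all.equal(diag(x), rep(1, ncol(x)),
                                                  check.attributes = FALSE)) &&
    isSymmetric(unname(x), tol = 1e-8)
  r <- if (iscor) x else stats::cor(x)
  p <- ncol(r)
  if (p < 3) stop("KMO needs at least 3 variables")
  inv <- tryCatch(solve(r), error = function(e) NULL)
  if (is.null(inv) || rcond(r) < 1e-12) {
    warning("near-singular correlation matrix: ridge 1e-8 added")
    inv <- solve(r + diag(1e-8, p))
  }
  q <- -inv / sqrt(outer(diag(inv), diag(inv)))
  diag(q) <- 0; diag(r) <- 0
  sum(r^2) / (sum(r^2) + sum(q^2))
}

#' Correlation-matrix PCA with supplementary variables
#'
#' Active variables are standardized (mean 0, unit SD); components are the
#' eigenvectors of their correlation matrix, scores the projections of the
#' standardized data.  Supplementary variables do not influence the axes:
#' their loadings are the Pearson correlations of each supplementary
#' variable with each score vector.  Components are retained up to the
#' smallest number whose cumulative explained variance reaches
#' `retain_pct` percent.
#'
#' @param x_active observations x active-variables matrix/data.frame.
#' @param x_supplementary optional matrix with the same rows.
#' @param retain_pct cumulative explained-variance retention threshold
#'   (percent, default 80).
#' @param n_retain optional fixed number of retained components
#'   (overrides `retain_pct`).
#' @return object of class `pca_screen`: eigenvalues, explained_pct,
#'   cum_explained_pct, loadings_unrotated (correlation-scaled:
#'   eigenvector x sqrt(eigenvalue)), eigenvectors, scores,
#'   supplementary_loadings, kmo, n_retained, dropped (constant active
#'   variables removed with a warning).
#' @export
pca_with_supplementary <- function(x_active, x_supplementary = NULL,
                                   retain_pct = 80, n_retain = NULL) {
  X <- as.matrix(x_active)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning("constant active variable(s) dropped: ", paste(dropped, collapse = ", "))
    X <- X[, !(colnames(X) %in% dropped), drop = FALSE]
    sds <- sds[!(names(sds) %in% dropped)]
  }
  if (ncol(X) < 2) stop("need at least 2 non-constant active variables")
  Xs <- scale(X)
  R <- stats::cor(X)
  ei <- eigen(R, symmetric = TRUE)
  ev <- pmax(ei$values, 0)
  vecs <- ei$vectors
  # deterministic eigenvector sign: largest-|entry| coordinate positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- colnames(X)
  colnames(vecs) <- paste0("PC", seq_len(ncol(vecs)))
  explained <- 100 * ev / sum(ev)
  cum <- cumsum(explained)
  nr <- if (!is.null(n_retain)) min(n_retain, ncol(vecs))
        else max(1L, which(cum >= retain_pct)[1])
  scores <- Xs %*% vecs
  loadings <- sweep(vecs, 2, sqrt(ev), `*`)
  supp <- NULL
  if (!is.null(x_supplementary)) {
    S <- as.matrix(x_supplementary)
    if (nrow(S) != nrow(X)) stop("supplementary variables must share the observations")
    supp <- suppressWarnings(stats::cor(S, scores))
  }
  structure(list(eigenvalues = ev, explained_pct = explained,
                 cum_explained_pct = cum, loadings_unrotated = loadings,
                 eigenvectors = vecs, scores = scores,
                 supplementary_loadings = supp,
                 kmo = if (ncol(X) >= 3) kmo(R) else NA_real_,
                 n_retained = nr, dropped = dropped),
            class = "pca_screen")
}

#' @export
print.pca_screen <- function(x, ...) {
  cat(sprintf("<pca_screen> %d variables, %d observations; KMO = %.2f\n",
              nrow(x$loadings_unrotated), nrow(x$scores), x$kmo))
  k <- min(5, length(x$explained_pct))
  cat("explained %:", paste(sprintf("%.1f", x$explained_pct[seq_len(k)]), collapse = ", "),
      "...;", x$n_retained, "retained\n")
  invisible(x)
}

# oblimin criterion and its gradient (gamma = 0 is direct quartimin)
oblimin_criterion <- function(L, gamma = 0) {
  k <- ncol(L); p <- nrow(L)
  L2 <- L^2
  X <- L2 %*% (matrix(1, k, k) - diag(k))
  if (gamma != 0) X <- (diag(p) - matrix(gamma / p, p, p)) %*% X
  list(f = sum(L2 * X) / 4, G = L * X)
}

#' Direct oblimin rotation by gradient projection
#'
#' Minimizes the oblimin criterion at the given gamma (0 = direct
#' quartimin) over oblique rotations using the gradient-projection
#' algorithm, starting from the identity.  Column signs are fixed so each
#' factor's largest-magnitude pattern loading is positive; variable
#' contributions are squared pattern loadings scaled so every factor
#' column sums to 100.
#'
#' @param loadings variables x m unrotated loading matrix, m >= 2.
#' @param gamma oblimin gamma (default 0).
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   projected-gradient norm.
#' @return list: pattern, structure, factor_correlations,
#'   contributions_pct, criterion (final value), iterations, converged.
#'   Raises an error with the criterion trace when not converged.
#' @export
oblimin_rotation <- function(loadings, gamma = 0, max_iter = 1000, tol = 1e-6) {
  A <- as.matrix(loadings)
  k <- ncol(A)
  if (k < 2) stop("rotation needs at least 2 factors")
  Tm <- diag(k)
  al <- 1
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  vg <- oblimin_criterion(L, gamma)
  f <- vg$f
  G <- -t(t(L) %*% vg$G %*% Ti)
  trace_f <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G), k)
    s <- sqrt(sum(Gp^2))
    trace_f <- c(trace_f, f)
    if (s < tol) { converged <- TRUE; break }
    al <- 2 * al
    for (half in 1:50) {
      X <- Tm - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Tti <- solve(Tt)
      Lt <- A %*% t(Tti)
      vgt <- oblimin_criterion(Lt, gamma)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Tt; f <- vgt$f; L <- Lt
    G <- -t(t(L) %*% vgt$G %*% Tti)
  }
  if (!converged)
    stop("oblimin rotation did not converge in ", max_iter,
         " iterations; criterion trace tail: ",
         paste(signif(utils::tail(trace_f, 5), 8), collapse = ", "))
  Phi <- t(Tm) %*% Tm
  # sign convention: largest |pattern| entry per column positive
  sgn <- vapply(seq_len(k), function(j) {
    i <- which.max(abs(L[, j])); if (L[i, j] < 0) -1 else 1
  }, 0)
  L <- sweep(L, 2, sgn, `*`)
  Phi <- diag(sgn) %*% Phi %*% diag(sgn)
  structure_m <- L %*% Phi
  contrib <- sweep(L^2, 2, colSums(L^2), `/`) * 100
  dimnames(L) <- dimnames(structure_m) <- dimnames(contrib) <-
    list(rownames(A), paste0("F", seq_len(k)))
  dimnames(Phi) <- list(paste0("F", seq_len(k)), paste0("F", seq_len(k)))
  list(pattern = L, structure = structure_m, factor_correlations = Phi,
       contributions_pct = contrib, criterion = f, iterations = iter,
       converged = converged)
}

#' Hierarchical k-means clustering of genotypes on component scores
#'
#' Ward-linkage agglomerative clustering (Euclidean distance, ward.D2) is
#' cut at k; the cut clusters' centroids then initialize Lloyd k-means
#' iterated to convergence.  With `k = "auto"` the k in 2..min(8, n-1)
#' maximizing the mean silhouette width of the refined solution is chosen.
#' The procedure is deterministic for a given input (k-means starts from
#' fixed centroids); `seed` is accepted for interface uniformity.
#'
#' @param scores genotypes x components numeric matrix with rownames.
#' @param k integer number of clusters or "auto".
#' @param seed integer, recorded in the result.
#' @return object of class `cluster_assignment`: labels (named integer
#'   vector, ids contiguous from 1), k, centroids, silhouette (mean width,
#'   NA for k = 1), linkage_merge_heights, tried (k -> mean silhouette
#'   when auto).
#' @export
hierarchical_kmeans <- function(scores, k = "auto", seed = 1L) {
  X <- as.matrix(scores)
  n <- nrow(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_len(n))
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  refine <- function(kk) {
    cut <- stats::cutree(hc, k = kk)
    cent <- do.call(rbind, lapply(seq_len(kk), function(ci)
      colMeans(X[cut == ci, , drop = FALSE])))
    if (kk == 1 || nrow(unique(X)) <= kk) {
      km_cluster <- cut
      km_centers <- cent
    } else {
      km <- suppressWarnings(
        stats::kmeans(X, centers = cent, iter.max = 1000, algorithm = "Lloyd"))
      km_cluster <- km$cluster
      km_centers <- km$centers
    }
    list(labels = km_cluster, centroids = km_centers)
  }
  tried <- NULL
  if (identical(k, "auto")) {
    ks <- 2:min(8, n - 1)
    if (length(ks) == 0 || n < 3) { k <- 1L } else {
      d <- stats::dist(X)
      sil <- vapply(ks, function(kk) {
        lab <- refine(kk)$labels
        if (length(unique(lab)) < 2) return(-Inf)
        mean(cluster::silhouette(lab, d)[, "sil_width"])
      }, 0)
      tried <- stats::setNames(sil, ks)
      k <- ks[which.max(sil)]
    }
  }
  k <- as.integer(k)
  if (k > n) stop("k = ", k, " exceeds the number of genotypes (", n, ")")
  if (k < 1) stop("k must be >= 1")
  res <- refine(k)
  # relabel so cluster ids are contiguous, ordered by first appearance
  remap <- stats::setNames(seq_along(unique(res$labels)), unique(res$labels))
  labels <- unname(remap[as.character(res$labels)])
  names(labels) <- rownames(X)
  centroids <- res$centroids[as.integer(names(remap)), , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  msil <- if (k >= 2 && k < n) {
    mean(cluster::silhouette(labels, stats::dist(X))[, "sil_width"])
  } else NA_real_
  structure(list(labels = labels, k = k, centroids = centroids,
                 silhouette = msil, linkage_merge_heights = hc$height,
                 tried = tried, seed = as.integer(seed)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d over %d genotypes (mean silhouette %.3f)\n",
              x$k, length(x$labels), x$silhouette))
  print(split(names(x$labels), x$labels))
  invisible(x)
}
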