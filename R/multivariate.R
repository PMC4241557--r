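#' Assemble the spontaneous-activity matrix
#'
#' Builds the neurons x 8 matrix of spontaneous-activity parameters in the
#' canonical column order and divides each column by the absolute value of
#' its population mean (so mixed-unit columns become commensurable while
#' signs are preserved). The divisors are recorded for the inverse
#' transform and for supplementary projection.
#'
#' @param cohort feature data.frame (must have no missing values in the 8
#'   spontaneous columns)
#' @param normalization `"mean"` (divide by |column mean|), `"zscore"`, or
#'   `"none"`
#' @return object of class `spontaneous_matrix`: list with `x` (normalized
#'   matrix), `divisors`, `centers` (for zscore), `neuron_id`, `age_days`,
#'   `stage`, `normalization`
#' @export
spontaneous_matrix <- function(cohort, normalization = c("mean", "zscore",
                                                         "none")) {
  normalization <- match.arg(normalization)
  cols <- spontaneous_feature_names()
  miss <- setdiff(cols, names(cohort))
  if (length(miss))
    abort("cohort lacks spontaneous columns: %s", "validation_error",
          paste(miss, collapse = ", "))
  x <- as.matrix(cohort[, cols])
  if (anyNA(x))
    abort("spontaneous features must be complete (no NA)", "validation_error")
  centers <- rep(0, ncol(x))
  divisors <- rep(1, ncol(x))
  if (normalization == "mean") {
    divisors <- abs(colMeans(x))
    if (any(divisors <= 1e-8 * colMeans(abs(x))))
      abort("a column population mean is zero", "validation_error")
  } else if (normalization == "zscore") {
    centers <- colMeans(x)
    divisors <- apply(x, 2, sd)
    if (any(divisors == 0))
      abort("a column has zero variance", "validation_error")
  }
  xn <- sweep(sweep(x, 2, centers, "-"), 2, divisors, "/")
  structure(list(x = xn, divisors = divisors, centers = centers,
                 neuron_id = cohort$neuron_id, age_days = cohort$age_days,
                 stage = cohort$stage, normalization = normalization),
            class = "spontaneous_matrix")
}

#' Invert the normalization of a spontaneous matrix
#' @param m a [spontaneous_matrix()]
#' @return raw-unit matrix
#' @export
denormalize <- function(m) {
  sweep(sweep(m$x, 2, m$divisors, "*"), 2, m$centers, "+")
}

#' Ward agglomerative hierarchical clustering
#'
#' Ward's minimum-variance agglomeration on Euclidean distances
#' (Lance-Williams recurrence on squared distances). Merge dissimilarities
#' are reported as the increase in within-cluster sum of squares at each
#' merge, which is non-decreasing.
#'
#' @param m a [spontaneous_matrix()] or numeric matrix
#' @return object of class `ephys_dendrogram`: list with `merge`, `height`
#'   (delta-SSE per merge), `labels`, `order` and the underlying `hclust`
#' @export
ahc_ward <- function(m) {
  x <- if (inherits(m, "spontaneous_matrix")) m$x else as.matrix(m)
  if (nrow(x) < 2) abort("need at least 2 observations", "validation_error")
  hc <- hclust(dist(x)^2, method = "ward.D")
  # ward.D on squared distances yields twice the SSE increase per merge
  structure(list(merge = hc$merge, height = hc$height / 2,
                 labels = if (is.null(hc$labels)) as.character(seq_len(nrow(x)))
                          else hc$labels,
                 order = hc$order, hclust = hc, n = nrow(x)),
            class = "ephys_dendrogram")
}

#' Export a dendrogram as Newick
#' @param d an `ephys_dendrogram`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_dendrogram_newick <- function(d, path) {
  hc <- d$hclust
  hc$height <- d$height            # branch lengths on the delta-SSE scale
  hc$labels <- d$labels
  ph <- ape::as.phylo(hc)
  ape::write.tree(ph, file = path)
  invisible(path)
}

#' Cut a dendrogram automatically and describe the classes
#'
#' The cut is placed in the largest gap between consecutive merge
#' dissimilarities among the top `min(n - 1, 10)` merges; classes are the
#' connected components below the cut. For each class the centroid (in the
#' clustered feature space), the central object (member closest to the
#' centroid, ties to the lowest id) and the mean age are reported. If all
#' candidate merge heights are equal the cut falls back to 2 classes with a
#' warning.
#'
#' @param d an `ephys_dendrogram`
#' @param m the [spontaneous_matrix()] that was clustered (for centroids,
#'   ids and ages); optional when `k` is given and only memberships matter
#' @param k fixed number of classes, overriding the automatic cut
#' @return object of class `cluster_classes`: list with `k`, `membership`,
#'   `centroids`, `central_objects`, `class_age` (mean, sd, n per class),
#'   `cut_gap`
#' @export
auto_cut <- function(d, m = NULL, k = NULL) {
  n <- d$n
  if (n < 3) abort("need at least 3 leaves", "validation_error")
  h <- d$height
  gap <- NA_real_
  if (is.null(k)) {
    kmax <- min(n - 1L, 10L)
    # candidate k classes <-> gap between merge n-k and merge n-k+1
    ks <- 2:kmax
    gaps <- h[n - ks + 1L] - h[n - ks]
    if (max(gaps) <= 0 || all(abs(gaps - gaps[1]) < 1e-12 * max(h))) {
      if (length(unique(h[n - ks])) <= 1L)
        warning("flat dendrogram: falling back to 2 classes")
    }
    k <- ks[which.max(gaps)]
    gap <- max(gaps)
  }
  memb <- cutree(d$hclust, k = k)
  out <- list(k = k, membership = memb, cut_gap = gap)
  if (!is.null(m)) {
    x <- m$x
    cents <- t(vapply(seq_len(k), function(c)
      colMeans(x[memb == c, , drop = FALSE]), numeric(ncol(x))))
    colnames(cents) <- colnames(x)
    central <- vapply(seq_len(k), function(c) {
      i <- which(memb == c)
      dists <- sqrt(rowSums((x[i, , drop = FALSE] -
                             matrix(cents[c, ], length(i), ncol(x),
                                    byrow = TRUE))^2))
      i[which.min(dists)]          # which.min takes the first (lowest id)
    }, integer(1))
    ages <- if (!is.null(m$age_days))
      t(vapply(seq_len(k), function(c) {
        a <- m$age_days[memb == c]
        c(mean = mean(a), sd = sd(a), n = length(a))
      }, numeric(3)))
    else NULL
    out$centroids <- cents
    out$central_objects <-
      if (!is.null(m$neuron_id)) m$neuron_id[central] else central
    out$class_age <- ages
  }
  class(out) <- "cluster_classes"
  out
}

#' Principal component analysis on the population covariance matrix
#'
#' Columns are centered and the eigendecomposition of the divisor-n
#' (population) covariance matrix is taken; components are sorted by
#' decreasing eigenvalue and signed so that each component's
#' largest-magnitude entry is positive. Scores (factor loadings F1, F2, ...)
#' are the centered data projected on the components.
#'
#' @param m a [spontaneous_matrix()] or numeric matrix
#' @param divisor `"n"` (population, default) or `"n-1"`; eigenvector
#'   directions are identical, only the eigenvalue scale changes
#' @return object of class `pca_model`: list with `means`, `components`,
#'   `eigenvalues`, `variance_fraction`, `scores`, `divisors`,
#'   `normalization`
#' @export
pca_covariance <- function(m, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  x <- if (inherits(m, "spontaneous_matrix")) m$x else as.matrix(m)
  if (nrow(x) < 3) abort("need at least 3 observations", "validation_error")
  if (ncol(x) < 2) abort("need at least 2 variables", "validation_error")
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  S <- crossprod(xc) / if (divisor == "n") n else (n - 1)
  eg <- eigen(S, symmetric = TRUE)
  vec <- eg$vectors
  for (j in seq_len(ncol(vec))) {            # reproducible sign convention
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  ev <- pmax(eg$values, 0)
  if (sum(ev > 1e-12 * max(ev)) < 2)
    warning("data rank < 2: PC2 carries no variance")
  rownames(vec) <- colnames(x)
  colnames(vec) <- paste0("PC", seq_len(ncol(vec)))
  scores <- xc %*% vec
  colnames(scores) <- paste0("F", seq_len(ncol(scores)))
  structure(list(means = mu, components = vec, eigenvalues = ev,
                 variance_fraction = ev / sum(ev), scores = scores,
                 divisor = divisor,
                 divisors = if (inherits(m, "spontaneous_matrix")) m$divisors,
                 centers = if (inherits(m, "spontaneous_matrix")) m$centers,
                 normalization = if (inherits(m, "spontaneous_matrix"))
                   m$normalization else "none",
                 neuron_id = if (inherits(m, "spontaneous_matrix")) m$neuron_id,
                 age_days = if (inherits(m, "spontaneous_matrix")) m$age_days,
                 stage = if (inherits(m, "spontaneous_matrix")) m$stage),
            class = "pca_model")
}

#' Project supplementary observations into a fitted PCA space
#'
#' New observations (raw units) are normalized with the *training* divisors,
#' centered with the training means and projected on the training
#' components; the model is never refitted.
#'
#' @param model a [pca_model][pca_covariance()]
#' @param newdata data.frame or matrix with the 8 canonical spontaneous
#'   columns in raw units
#' @return score matrix (columns `F1`, `F2`, ...)
#' @export
project_supplementary <- function(model, newdata) {
  cols <- spontaneous_feature_names()
  if (is.data.frame(newdata)) {
    miss <- setdiff(cols, names(newdata))
    if (length(miss))
      abort("supplementary data lack columns: %s", "validation_error",
            paste(miss, collapse = ", "))
    newdata <- as.matrix(newdata[, cols])
  }
  if (ncol(newdata) != length(model$means))
    abort("supplementary data have the wrong number of columns",
          "validation_error")
  xn <- newdata
  if (!is.null(model$divisors))
    xn <- sweep(sweep(xn, 2, model$centers, "-"), 2, model$divisors, "/")
  s <- sweep(xn, 2, model$means, "-") %*% model$components
  colnames(s) <- paste0("F", seq_len(ncol(s)))
  s
}

#' Per-stage trajectory in the PC1/PC2 plane
#'
#' Mean, SD and SEM of the factor loadings F1 and F2 for every stage, in
#' developmental order, plus the mean age of the stage's neurons.
#'
#' @param model a fitted [pca_model][pca_covariance()] carrying stages/ages,
#'   or a score matrix
#' @param stage,age_days stage label and age per observation (taken from the
#'   model when omitted)
#' @return data.frame of class `stage_trajectory`
#' @export
stage_trajectory <- function(model, stage = NULL, age_days = NULL) {
  scores <- if (inherits(model, "pca_model")) model$scores else model
  stage <- stage %||% model$stage
  age_days <- age_days %||% model$age_days
  stages <- intersect(stage_levels(), unique(stage))
  rows <- lapply(stages, function(st) {
    i <- stage == st
    n <- sum(i)
    if (n < 2) warning(sprintf("stage %s has a single neuron: SD undefined",
                               st))
    sd1 <- if (n >= 2) sd(scores[i, 1]) else NA_real_
    sd2 <- if (n >= 2) sd(scores[i, 2]) else NA_real_
    data.frame(stage = st, n = n, age_mean = mean(age_days[i]),
               f1_mean = mean(scores[i, 1]), f2_mean = mean(scores[i, 2]),
               f1_sd = sd1, f2_sd = sd2,
               f1_sem = sd1 / sqrt(n), f2_sem = sd2 / sqrt(n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stage_trajectory", class(out))
  out
}

#' Per-stage phenotype-variability ellipses
#'
#' The variability of a stage is summarized by the ellipse with semi-axes
#' a = SD(PC1), b = SD(PC2) and area A = pi * a * b.
#'
#' @param traj a [stage_trajectory()]
#' @return data.frame `stage`, `a`, `b`, `area`
#' @export
variability_ellipse <- function(traj) {
  keep <- !is.na(traj$f1_sd) & !is.na(traj$f2_sd)
  if (any(!keep)) warning("stages without SDs skipped")
  t2 <- traj[keep, ]
  data.frame(stage = t2$stage, a = t2$f1_sd, b = t2$f2_sd,
             area = pi * t2$f1_sd * t2$f2_sd, stringsAsFactors = FALSE)
}

#' Correlation of phenotype variability (SD of PC1) with age
#'
#' Pearson correlation of the per-stage SD(PC1) against the stage mean age,
#' with the two-sided p value from the t transform. The signed r is
#' reported.
#'
#' @param traj a [stage_trajectory()]
#' @return list(`r`, `p`, `n`)
#' @export
sd_age_correlation <- function(traj) {
  keep <- !is.na(traj$f1_sd)
  if (sum(keep) < 3)
    abort("need >= 3 stages with SDs", "insufficient_data_error")
  if (sd(traj$f1_sd[keep]) == 0 || sd(traj$age_mean[keep]) == 0)
    abort("zero-variance input: correlation undefined", "degenerate_error")
  ct <- cor.test(traj$age_mean[keep], traj$f1_sd[keep])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}
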