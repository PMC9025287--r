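# Population-level habitat discovery: quantization, k-means over pooled
# perfusion feature vectors, cluster-number selection, habitat maps.

#' Fit a 256-bin uniform quantizer on the development PFV pool
#'
#' Each perfusion feature (wash-in, washout, washout ratio) is quantized on
#' a uniform grid of \code{n_bins} bins spanning the pooled development
#' minimum to maximum; quantization replaces a value with its bin center.
#' Bins are left-closed with the last bin right-closed, so the pooled
#' maximum lands in the last bin.  Values outside the fitted range (e.g.
#' from a propagated validation cohort) clamp to the extreme bins.
#'
#' @param pfv matrix or data.frame of pooled PFVs with columns
#'   \code{ein}, \code{eout}, \code{rwo} (any numeric columns work).
#' @param n_bins number of histogram bins (default 256).
#' @return an object of class \code{habitat_quantizer}.
#' @export
fit_quantizer <- function(pfv, n_bins = 256) {
  x <- as.matrix(pfv[, intersect(c("ein", "eout", "rwo"), colnames(pfv)),
                     drop = FALSE])
  if (ncol(x) == 0) x <- as.matrix(pfv)
  if (nrow(x) == 0) stop("empty PFV pool", call. = FALSE)
  feats <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  qz <- lapply(seq_len(ncol(x)), function(j) {
    lo <- min(x[, j]); hi <- max(x[, j])
    if (lo == hi) {
      warning(sprintf("feature '%s' is constant; using one degenerate bin",
                      feats[j]), call. = FALSE)
      return(list(min = lo, max = hi, edges = c(lo, hi), centers = lo))
    }
    edges <- seq(lo, hi, length.out = n_bins + 1)
    list(min = lo, max = hi, edges = edges,
         centers = (edges[-1] + edges[-(n_bins + 1)]) / 2)
  })
  names(qz) <- feats
  structure(list(features = feats, n_bins = n_bins, bins = qz),
            class = "habitat_quantizer")
}

#' Quantize PFVs with a fitted quantizer
#'
#' @param quantizer a \code{habitat_quantizer}.
#' @param pfv matrix/data.frame with the quantizer's feature columns.
#' @return numeric matrix of bin-center values (raw units).
#' @export
apply_quantizer <- function(quantizer, pfv) {
  stopifnot(inherits(quantizer, "habitat_quantizer"))
  x <- as.matrix(as.data.frame(pfv)[, quantizer$features, drop = FALSE])
  out <- x
  for (j in seq_along(quantizer$features)) {
    b <- quantizer$bins[[j]]
    if (length(b$centers) == 1L) { out[, j] <- b$centers; next }
    idx <- findInterval(x[, j], b$edges, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), length(b$centers))
    out[, j] <- b$centers[idx]
  }
  out
}

# ---- k-means ---------------------------------------------------------------

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (c in seq_len(k - 1)) {
    if (all(d2 <= 0))
      stop("fewer distinct rows than clusters (k too large)", call. = FALSE)
    i <- sample.int(n, 1, prob = d2)
    centers[c + 1, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[i, ])^2))
  }
  centers
}

#' Population-level k-means over pooled, quantized PFVs
#'
#' Clustering is applied at the cohort level (all patients' ROI voxels
#' pooled) so the habitat labels are directly comparable across patients.
#' Each repetition draws a k-means++ initialization from its own seed and
#' runs Lloyd iterations (Euclidean distance); the repetition with the
#' lowest within-cluster inertia supplies the retained centers.  Features
#' are clustered in raw quantized units without per-feature
#' standardization (the habitat centers are reported in raw intensity
#' units); set \code{standardize = TRUE} to rescale to unit variance first.
#'
#' @param x quantized PFV matrix (rows = voxels).
#' @param k number of clusters.
#' @param n_reps number of random restarts (default 100).
#' @param seed integer seed; repetition \code{r} uses \code{seed + r}.
#' @param iter_max Lloyd iteration cap per repetition (default 300).
#' @param standardize cluster on per-feature unit-variance copies.
#' @param score logical; also compute per-repetition Calinski-Harabasz and
#'   silhouette scores (see \code{\link{score_partition}}).
#' @param silhouette_n silhouette subsample cap per repetition.
#' @return an object of class \code{habitat_model} with elements
#'   \code{centers} (k x p, canonical order: ascending wash-in, ties by
#'   washout), \code{k}, \code{inertia}, \code{cluster} (assignment of the
#'   input rows) and, when \code{score = TRUE}, a data.frame \code{scores}
#'   with one row per repetition.
#' @export
population_kmeans <- function(x, k, n_reps = 100, seed = 1, iter_max = 300,
                              standardize = FALSE, score = FALSE,
                              silhouette_n = 2000) {
  x <- as.matrix(x)
  if (nrow(x) < k) stop("fewer rows than clusters", call. = FALSE)
  xs <- if (standardize) scale(x) else x
  best <- NULL
  scores <- if (score) data.frame(rep = seq_len(n_reps), ch = NA_real_,
                                  silhouette = NA_real_) else NULL
  for (r in seq_len(n_reps)) {
    km <- local_seed(derive_seed(seed, r), {
      fit <- NULL
      for (try in 1:3) {
        init <- kmeanspp_init(xs, k)
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(xs, centers = init,
                                         iter.max = iter_max,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit) && !any(fit$size == 0)) break
      }
      if (is.null(fit)) stop("k-means failed to produce a valid partition",
                             call. = FALSE)
      fit
    })
    if (score) {
      sc <- score_partition(xs, km$cluster, silhouette_n = silhouette_n,
                            seed = derive_seed(seed, 100000 + r))
      scores$ch[r] <- sc[["calinski_harabasz"]]
      scores$silhouette[r] <- sc[["silhouette"]]
    }
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  centers <- best$centers
  if (standardize) {
    ctr <- attr(xs, "scaled:center"); scl <- attr(xs, "scaled:scale")
    centers <- sweep(sweep(centers, 2, scl, `*`), 2, ctr, `+`)
  }
  ord <- order(centers[, 1], centers[, 2])
  relabel <- match(seq_len(k), ord)
  structure(list(k = k,
                 centers = unname(centers[ord, , drop = FALSE]),
                 feature_names = colnames(x),
                 inertia = best$tot.withinss,
                 cluster = relabel[best$cluster],
                 scores = scores,
                 quantizer = NULL),
            class = "habitat_model")
}

#' @export
print.habitat_model <- function(x, ...) {
  cat(sprintf("Habitat model: k = %d perfusion habitats\n", x$k))
  cn <- x$feature_names %||% c("ein", "eout", "rwo")
  m <- round(x$centers, 3)
  dimnames(m) <- list(paste0("habitat_", seq_len(x$k)), cn)
  print(m)
  invisible(x)
}

#' Score a clustering partition (Calinski-Harabasz and silhouette)
#'
#' CH is computed on the full data from between/within scatter,
#' \eqn{[B/(k-1)] / [W/(n-k)]}.  The mean silhouette \eqn{(b-a)/\max(a,b)}
#' is exact when \eqn{n \le} \code{silhouette_n} and otherwise computed on
#' a seeded subsample (the silhouette is quadratic in the number of
#' voxels, and cohort pools reach millions).  Singleton-cluster points get
#' silhouette 0.
#'
#' @param x numeric matrix.
#' @param cluster integer assignment vector.
#' @param silhouette_n subsample cap (default 2000).
#' @param seed subsampling seed.
#' @return named numeric vector \code{c(calinski_harabasz, silhouette)};
#'   CH is \code{NA} when \code{n == k} (degenerate all-singleton case).
#' @export
score_partition <- function(x, cluster, silhouette_n = 2000, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  cl <- as.integer(factor(cluster))
  k <- max(cl)
  if (k < 2) stop("need at least two clusters", call. = FALSE)
  if (any(tabulate(cl, k) == 0)) stop("empty cluster", call. = FALSE)
  sizes <- tabulate(cl, k)
  mu <- colMeans(x)
  cmu <- rowsum(x, cl) / sizes
  B <- sum(sizes * rowSums(sweep(cmu, 2, mu)^2))
  W <- sum((x - cmu[cl, , drop = FALSE])^2)
  ch <- if (n > k) (B / (k - 1)) / (W / (n - k)) else NA_real_
  idx <- if (n > silhouette_n)
    local_seed(seed, sample.int(n, silhouette_n)) else seq_len(n)
  xs <- x[idx, , drop = FALSE]
  cls <- cl[idx]
  m <- length(idx)
  d <- as.matrix(stats::dist(xs))
  ind <- outer(cls, seq_len(k), `==`) + 0            # m x k membership
  csum <- d %*% ind                                   # sum dist to each cluster
  csz <- colSums(ind)
  sil <- vapply(seq_len(m), function(i) {
    g <- cls[i]
    if (csz[g] <= 1) return(0)
    a <- csum[i, g] / (csz[g] - 1)
    bs <- csum[i, -g] / csz[-g]
    bs <- bs[csz[-g] > 0]
    b <- min(bs)
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  c(calinski_harabasz = ch, silhouette = mean(sil))
}

#' Sweep candidate cluster numbers and collect selection diagnostics
#'
#' For each k in \code{k_range}, runs \code{\link{population_kmeans}} with
#' \code{n_reps} scored repetitions and records the repetition-averaged
#' Calinski-Harabasz score and silhouette coefficient, retaining the
#' best-inertia model per k.
#'
#' @inheritParams population_kmeans
#' @param k_range integer candidate ks (default 2:32).
#' @return list with \code{diagnostics} (data.frame k, mean_ch,
#'   mean_silhouette) and \code{models} (per-k \code{habitat_model}s).
#' @export
habitat_diagnostics <- function(x, k_range = 2:32, n_reps = 100, seed = 1,
                                silhouette_n = 2000, iter_max = 300) {
  models <- list()
  diag <- data.frame(k = k_range, mean_ch = NA_real_,
                     mean_silhouette = NA_real_)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- population_kmeans(x, k, n_reps = n_reps,
                             seed = derive_seed(seed, k), score = TRUE,
                             silhouette_n = silhouette_n,
                             iter_max = iter_max)
    diag$mean_ch[i] <- mean(fit$scores$ch, na.rm = TRUE)
    diag$mean_silhouette[i] <- mean(fit$scores$silhouette, na.rm = TRUE)
    models[[as.character(k)]] <- fit
  }
  list(diagnostics = diag, models = models)
}

#' Select the number of habitats from sweep diagnostics
#'
#' The selected k is the smallest k whose repetition-averaged
#' Calinski-Harabasz score is never exceeded at any larger k (the last
#' point before the score starts a sustained decrease).  Agreement with the
#' top two ks by mean silhouette is checked and a disagreement is warned,
#' but the CH knee is kept: the mean silhouette is dominated by the voxels
#' of large clusters, so it systematically favors merging rare habitats
#' (removing a 2 percent habitat barely moves it), whereas the
#' between-cluster scatter in CH still registers a rare cluster's
#' centroid.  Ties always resolve to the smaller k.  A monotonically increasing CH curve returns
#' the largest candidate with a warning.  When the best mean silhouette is
#' below 0.5 the diagnostics carry no reliable cluster structure (the CH
#' knee of an unstructured cloud is noise); the selection then falls back
#' to the smallest candidate k with a weak-structure warning.
#'
#' @param diagnostics data.frame with columns \code{k}, \code{mean_ch},
#'   \code{mean_silhouette} (from \code{\link{habitat_diagnostics}}).
#' @return the selected k (integer).
#' @export
select_k <- function(diagnostics) {
  d <- diagnostics[order(diagnostics$k), ]
  if (any(is.na(d$mean_ch)))
    stop("diagnostics must cover every candidate k", call. = FALSE)
  n <- nrow(d)
  if (n == 1L) return(d$k[1])
  if (all(diff(d$mean_ch) > 0)) {
    warning("CH score still increasing at the largest k; structure unresolved",
            call. = FALSE)
    return(d$k[n])
  }
  if (max(d$mean_silhouette) < 0.5) {
    warning("weak cluster structure (best mean silhouette < 0.5); ",
            "defaulting to the smallest candidate k", call. = FALSE)
    return(as.integer(d$k[1]))
  }
  suffix_max <- rev(cummax(rev(d$mean_ch)))
  k_ch <- d$k[which(d$mean_ch >= suffix_max)[1]]
  sil_top2 <- d$k[order(-d$mean_silhouette, d$k)][seq_len(min(2, n))]
  if (!(k_ch %in% sil_top2))
    warning(sprintf(paste0("CH knee (k = %d) is not in the silhouette ",
                           "top-2 (k = %s); keeping the CH knee"),
                    k_ch, paste(sil_top2, collapse = ", ")),
            call. = FALSE)
  as.integer(k_ch)
}

#' Match recovered cluster centers to reference centers
#'
#' One-to-one assignment minimizing total squared Euclidean distance
#' (exhaustive over permutations for k <= 8, greedy otherwise).  Habitat
#' numbering out of clustering is arbitrary, so comparisons against a
#' reference table should always match centers first.
#'
#' @param centers recovered k x p center matrix.
#' @param reference reference k x p center matrix.
#' @return integer vector m, where recovered center i corresponds to
#'   reference row m[i].
#' @export
match_centers <- function(centers, reference) {
  centers <- as.matrix(centers); reference <- as.matrix(reference)
  k <- nrow(centers)
  stopifnot(nrow(reference) == k, ncol(reference) == ncol(centers))
  cost <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j)
    sum((centers[i, ] - reference[j, ])^2)))
  if (k <= 8) {
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    best <- NULL; bestc <- Inf
    for (p in perms(seq_len(k))) {
      cc <- sum(cost[cbind(seq_len(k), p)])
      if (cc < bestc) { bestc <- cc; best <- p }
    }
    best
  } else {
    m <- integer(k)
    for (step in seq_len(k)) {
      w <- which(cost == min(cost), arr.ind = TRUE)[1, ]
      m[w[1]] <- w[2]
      cost[w[1], ] <- Inf; cost[, w[2]] <- Inf
    }
    m
  }
}

#' Label a patient's ROI voxels with the nearest habitat center
#'
#' Quantizes the patient's PFVs with the model's quantizer and assigns each
#' ROI voxel to the nearest center (Euclidean distance in raw quantized
#' units); ties break to the lowest canonical label.  Propagation to a
#' validation cohort uses the development centers and quantizer verbatim.
#'
#' @param maps a \code{perfusion_maps} object.
#' @param model a \code{habitat_model} whose \code{quantizer} field is set
#'   (see \code{\link{fit_quantizer}}); pass \code{quantizer} explicitly to
#'   override.
#' @param quantizer optional \code{habitat_quantizer}.
#' @return an object of class \code{habitat_map}: list with \code{labels}
#'   (3D integer volume, 0 outside ROI), \code{proportions} (per-habitat
#'   voxel fraction), \code{k}, \code{pid}, \code{spacing}.
#' @export
build_habitat_map <- function(maps, model, quantizer = NULL) {
  stopifnot(inherits(maps, "perfusion_maps"),
            inherits(model, "habitat_model"))
  quantizer <- quantizer %||% model$quantizer
  tab <- pfv_table(maps)
  x <- if (!is.null(quantizer)) apply_quantizer(quantizer, tab)
       else as.matrix(tab[, c("ein", "eout", "rwo")])
  d2 <- outer(rowSums(x^2), rep(1, model$k)) -
    2 * x %*% t(model$centers) +
    outer(rep(1, nrow(x)), rowSums(model$centers^2))
  lab <- max.col(-d2, ties.method = "first")
  labels <- array(0L, dim(maps$ein))
  labels[tab$voxel] <- lab
  prop <- tabulate(lab, model$k) / length(lab)
  names(prop) <- paste0("habitat_", seq_len(model$k))
  structure(list(labels = labels, proportions = prop, k = model$k,
                 pid = maps$pid, spacing = maps$spacing),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("Habitat map%s: %d habitats over %d ROI voxels\n",
              if (!is.null(x$pid)) paste0(" ", x$pid) else "",
              x$k, sum(x$labels > 0)))
  print(round(x$proportions, 3))
  invisible(x)
}

#' Serialize / read a habitat model (quantizer, centers, diagnostics)
#' @param model a \code{habitat_model}.
#' @param path JSON file path.
#' @param diagnostics optional diagnostics data.frame stored alongside.
#' @return \code{path} (write) or the \code{habitat_model} (read).
#' @export
write_habitat_model <- function(model, path, diagnostics = NULL) {
  payload <- list(k = model$k, centers = model$centers,
                  feature_names = model$feature_names,
                  inertia = model$inertia,
                  quantizer = if (!is.null(model$quantizer))
                    unclass(model$quantizer),
                  diagnostics = diagnostics)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_habitat_model
#' @export
read_habitat_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  qz <- NULL
  if (!is.null(x$quantizer)) {
    bins <- lapply(x$quantizer$bins, function(b)
      list(min = b$min, max = b$max, edges = b$edges, centers = b$centers))
    qz <- structure(list(features = x$quantizer$features,
                         n_bins = x$quantizer$n_bins, bins = bins),
                    class = "habitat_quantizer")
  }
  structure(list(k = x$k, centers = as.matrix(x$centers),
                 feature_names = x$feature_names, inertia = x$inertia,
                 cluster = NULL, scores = NULL, quantizer = qz),
            class = "habitat_model")
}
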