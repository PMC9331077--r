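# Exploratory ordination and supervised classification of samples from
# per-sample trinucleotide spectra: binomial distance, non-metric
# multidimensional scaling, Mantel matrix correlation, nearest shrunken
# centroids, and the two-class Gaussian discriminant.

#' Binomial distance between two count vectors
#'
#' `d = sum_i [x_i ln(x_i/m_i) + y_i ln(y_i/m_i)] / n_i` over channels with
#' `n_i = x_i + y_i > 0` and `m_i = n_i / 2`, with the convention
#' `0 * ln 0 = 0`. This is the binomial dissimilarity index used for
#' community count data.
#'
#' @param x,y Non-negative count vectors of equal length, not both all-zero.
#' @return A non-negative scalar; 0 when `x == y`.
#' @export
#' @examples
#' binomial_distance(c(2, 0), c(0, 2)) # 2 * log(2)
binomial_distance <- function(x, y) {
  if (length(x) != length(y)) stop_fmt("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop_fmt("counts must be non-negative")
  n <- x + y
  keep <- n > 0
  if (!any(keep)) stop_fmt("both vectors are all-zero")
  x <- x[keep]; y <- y[keep]; n <- n[keep]
  m <- n / 2
  tx <- ifelse(x > 0, x * log(x / m), 0)
  ty <- ifelse(y > 0, y * log(y / m), 0)
  sum((tx + ty) / n)
}

#' Pairwise binomial distance matrix
#'
#' @param mat Count matrix, samples x channels (row names = sample ids).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
binomial_dist_matrix <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  out <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      out[i, j] <- out[j, i] <- binomial_distance(mat[i, ], mat[j, ])
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Non-metric multidimensional scaling
# ---------------------------------------------------------------------------

# Pool-adjacent-violators: disparities are the monotone (non-decreasing) fit
# of the configuration distances taken in observed-dissimilarity rank order.
pav_disparities <- function(conf_d, obs_order) {
  fit <- stats::isoreg(seq_along(obs_order), conf_d[obs_order])$yf
  out <- numeric(length(conf_d))
  out[obs_order] <- fit
  out
}

#' Non-metric multidimensional scaling
#'
#' Kruskal-style NMDS of a dissimilarity matrix: alternating
#' pool-adjacent-violators (isotonic) regression of the configuration
#' distances on the observed dissimilarity ranks, and Guttman-transform
#' updates of the coordinates. Stress is
#' `sqrt(sum((D - dhat)^2) / sum(D^2))` over sample pairs, where `D` are
#' configuration distances and `dhat` the monotone disparities; it vanishes
#' exactly when a configuration reproduces the observed ordering perfectly
#' and is non-increasing over iterations within a restart. The first restart
#' starts from classical metric scaling (principal coordinates), the others
#' from seeded Gaussian configurations; the lowest-stress solution is
#' returned.
#'
#' @param dist_mat Symmetric dissimilarity matrix (or `dist`).
#' @param k Embedding dimension.
#' @param n_restarts Number of restarts (first one is PCoA-initialized).
#' @param max_iter Maximum iterations per restart.
#' @param tol Relative stress-change convergence tolerance.
#' @param seed Seed for the random restarts.
#' @return An `nmds_result`: `coords` (n x k), `fitted` (disparities),
#'   `observed` (input dissimilarities), `stress`, `stress_trace`,
#'   `converged`, `n_restarts`, `seed`.
#' @export
nmds <- function(dist_mat, k = 2L, n_restarts = 20L, max_iter = 200L,
                 tol = 1e-6, seed = NULL) {
  m <- as.matrix(dist_mat)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8) || any(diag(m) != 0)) {
    stop_fmt("`dist_mat` must be a symmetric matrix with zero diagonal")
  }
  n <- nrow(m)
  if (n < k + 1L) stop_fmt("need at least k + 1 samples")
  d_obs <- m[lower.tri(m)]
  obs_order <- order(d_obs)
  ss_obs <- sum(d_obs^2)
  if (ss_obs == 0) stop_fmt("all dissimilarities are zero")

  run_once <- function(X) {
    pair_d <- function(X) {
      dm <- as.matrix(stats::dist(X))
      dm[lower.tri(dm)]
    }
    trace <- numeric(0)
    D <- pair_d(X)
    X_prev <- X
    for (it in seq_len(max_iter)) {
      dhat <- pav_disparities(D, obs_order)
      # normalize disparities to the scale of the configuration distances so
      # the metric step cannot collapse the configuration
      ssD <- sum(D^2)
      if (ssD == 0) break
      dhat <- dhat * sqrt(ssD / max(sum(dhat^2), .Machine$double.eps))
      stress <- sqrt(sum((D - dhat)^2) / ssD)
      if (it > 1L && stress > trace[it - 1L]) {
        # a (numerically) uphill step: keep the previous configuration
        return(list(X = X_prev, stress = trace[it - 1L],
                    trace = trace, converged = TRUE))
      }
      trace <- c(trace, stress)
      if (stress < 1e-12) {
        return(list(X = X, stress = stress, trace = trace, converged = TRUE))
      }
      if (it > 1L && abs(trace[it - 1L] - stress) < tol * max(stress, 1e-12)) {
        return(list(X = X, stress = stress, trace = trace, converged = TRUE))
      }
      X_prev <- X
      # Guttman transform with target disparities dhat
      full_D <- matrix(0, n, n)
      full_D[lower.tri(full_D)] <- D
      full_D <- full_D + t(full_D)
      full_hat <- matrix(0, n, n)
      full_hat[lower.tri(full_hat)] <- dhat
      full_hat <- full_hat + t(full_hat)
      ratio <- ifelse(full_D > 0, full_hat / full_D, 0)
      B <- -ratio
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- B %*% X / n
      D <- pair_d(X)
    }
    dhat <- pav_disparities(D, obs_order)
    ssD <- sum(D^2)
    dhat <- dhat * sqrt(ssD / max(sum(dhat^2), .Machine$double.eps))
    stress <- sqrt(sum((D - dhat)^2) / max(ssD, .Machine$double.eps))
    list(X = X, stress = stress, trace = c(trace, stress), converged = FALSE)
  }

  init_pcoa <- function() {
    cm <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = k))
    if (ncol(cm) < k) {
      cm <- cbind(cm, matrix(0, n, k - ncol(cm)))
    }
    cm
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    X0 <- if (r == 1L) {
      init_pcoa()
    } else {
      with_seed(if (is.null(seed)) NULL else child_seed(seed, r),
                matrix(stats::rnorm(n * k), n, k))
    }
    res <- run_once(X0)
    if (is.null(best) || res$stress < best$stress) best <- res
  }

  D_best <- as.matrix(stats::dist(best$X))[lower.tri(m)]
  dhat <- pav_disparities(D_best, obs_order)
  structure(
    list(
      coords = {
        X <- best$X
        rownames(X) <- rownames(m)
        colnames(X) <- paste0("NMDS", seq_len(k))
        X
      },
      fitted = dhat,
      observed = d_obs,
      stress = best$stress,
      stress_trace = best$trace,
      converged = best$converged,
      n_restarts = n_restarts,
      seed = seed
    ),
    class = "nmds_result"
  )
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dimensions, stress %.4f (%s, %d restarts)\n",
              nrow(x$coords), ncol(x$coords), x$stress,
              if (x$converged) "converged" else "not converged", x$n_restarts))
  invisible(x)
}

#' Mantel test
#'
#' Pearson correlation of the off-diagonal upper triangles of two distance
#' matrices, with a one-sided (greater) permutation p-value obtained by
#' permuting the labels of the second matrix:
#' `p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)`.
#'
#' @param d1,d2 Distance matrices over the same labels in the same order.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Permutation seed.
#' @return List with `r`, `p` and `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = NULL) {
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop_fmt("distance matrices must match in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop_fmt("distance matrices must share labels in the same order")
  }
  if (n_perm < 99L) stop_fmt("use at least 99 permutations")
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  v2 <- m2[ut]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop_fmt("a distance matrix is constant; the Mantel correlation is undefined")
  }
  r_obs <- stats::cor(v1, v2)
  n <- nrow(m1)
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(v1, m2[p, p][ut]) >= r_obs
    }, logical(1)))
  })
  list(r = r_obs, p = (1 + count) / (n_perm + 1), n_perm = n_perm)
}

# ---------------------------------------------------------------------------
# Nearest shrunken centroids
# ---------------------------------------------------------------------------

nsc_stats <- function(x, labels) {
  classes <- sort(unique(labels))
  n <- nrow(x)
  K <- length(classes)
  overall <- colMeans(x)
  centroids <- t(vapply(classes, function(k) colMeans(x[labels == k, , drop = FALSE]),
                        numeric(ncol(x))))
  rownames(centroids) <- classes
  wss <- Reduce(`+`, lapply(classes, function(k) {
    xs <- x[labels == k, , drop = FALSE]
    colSums(sweep(xs, 2L, colMeans(xs))^2)
  }))
  pooled_sd <- sqrt(wss / (n - K))
  s0 <- stats::median(pooled_sd)
  nk <- vapply(classes, function(k) sum(labels == k), numeric(1))
  mk <- sqrt(1 / nk - 1 / n)
  d <- sweep(centroids, 2L, overall) /
    (outer(mk, pooled_sd + s0))
  list(classes = classes, overall = overall, centroids = centroids,
       pooled_sd = pooled_sd, s0 = s0, nk = nk, mk = mk, d = d)
}

nsc_shrink <- function(st, delta) {
  d_shrunk <- sign(st$d) * pmax(abs(st$d) - delta, 0)
  shrunk_centroids <- sweep(
    d_shrunk * outer(st$mk, st$pooled_sd + st$s0), 2L, st$overall, `+`
  )
  list(d_shrunk = d_shrunk, shrunk_centroids = shrunk_centroids)
}

nsc_score <- function(x, model) {
  # discriminant score per class: squared standardized distance to the
  # shrunken centroid minus 2 log prior
  scale_ <- model$pooled_sd + model$s0
  vapply(seq_along(model$classes), function(k) {
    sum(((x - model$shrunk_centroids[k, ]) / scale_)^2) -
      2 * log(model$priors[k])
  }, numeric(1))
}

#' Train a nearest-shrunken-centroid classifier
#'
#' Computes per-class centroids of per-sample channel proportions, shrinks
#' their standardized differences from the overall centroid toward zero by
#' soft thresholding at delta, and selects delta from a grid by
#' cross-validated error, breaking ties toward the largest delta (the most
#' parsimonious model). The standardized difference of channel i for class k
#' is `d_ik = (centroid_ik - overall_i) / (m_k * (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)`, `s_i` the pooled within-class SD and `s0` the
#' median of the `s_i`.
#'
#' @param x Matrix of per-sample channel values (samples x channels),
#'   typically percent proportions.
#' @param labels Class label per sample (two or more classes).
#' @param delta_grid Candidate thresholds; default 30 evenly spaced values
#'   from 0 to `max(abs(d_ik))`.
#' @param cv_folds Cross-validation folds (reduced with a warning when a
#'   class is smaller).
#' @param seed Seed for the deterministic fold assignment.
#' @param priors Class priors (default equal).
#' @return An `nsc_model` with centroids, pooled SDs, `s0`, the selected
#'   `delta`, shrunken differences, active channels, priors, and the CV
#'   error path.
#' @export
nsc_train <- function(x, labels, delta_grid = NULL, cv_folds = 6L,
                      seed = NULL, priors = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop_fmt("labels must match rows of x")
  tab <- table(labels)
  if (any(tab < 2L)) stop_fmt("every class needs at least 2 samples")
  st <- nsc_stats(x, labels)
  if (is.null(priors)) {
    priors <- rep(1 / length(st$classes), length(st$classes))
  }
  names(priors) <- st$classes
  if (is.null(delta_grid)) {
    delta_grid <- seq(0, max(abs(st$d)), length.out = 30L)
  }
  delta_grid <- sort(unique(delta_grid))

  if (min(tab) < cv_folds) {
    warn_fmt("smallest class has %d samples; reducing cv_folds from %d to %d",
             min(tab), cv_folds, min(tab))
    cv_folds <- min(tab)
  }

  # deterministic stratified fold assignment
  folds <- integer(nrow(x))
  with_seed(seed, {
    for (k in st$classes) {
      idx <- which(labels == k)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(cv_folds), length(idx))
    }
  })

  cv_err <- vapply(delta_grid, function(delta) {
    errs <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      te <- !tr
      if (length(unique(labels[tr])) < length(st$classes)) return(NA_real_)
      st_f <- nsc_stats(x[tr, , drop = FALSE], labels[tr])
      sh_f <- nsc_shrink(st_f, delta)
      model_f <- list(classes = st_f$classes, pooled_sd = st_f$pooled_sd,
                      s0 = st_f$s0, shrunk_centroids = sh_f$shrunk_centroids,
                      priors = priors)
      pred <- apply(x[te, , drop = FALSE], 1L, function(row) {
        st_f$classes[which.min(nsc_score(row, model_f))]
      })
      sum(pred != labels[te])
    }, numeric(1))
    sum(errs, na.rm = TRUE)
  }, numeric(1))

  best_err <- min(cv_err)
  delta <- max(delta_grid[cv_err == best_err]) # most parsimonious tie-break

  sh <- nsc_shrink(st, delta)
  active <- colnames(x)[colSums(abs(sh$d_shrunk)) > 0]
  structure(
    list(
      classes = st$classes,
      centroids = st$centroids,
      overall_centroid = st$overall,
      pooled_sd = st$pooled_sd,
      s0 = st$s0,
      delta = delta,
      delta_grid = delta_grid,
      cv_error = cv_err,
      shrunken_d = sh$d_shrunk,
      shrunk_centroids = sh$shrunk_centroids,
      active_channels = active,
      priors = priors,
      n_per_class = st$nk,
      seed = seed
    ),
    class = "nsc_model"
  )
}

#' @export
print.nsc_model <- function(x, ...) {
  cat(sprintf(
    "Nearest-shrunken-centroid model: %d classes, delta %.4g, %d active channel(s)\n",
    length(x$classes), x$delta, length(x$active_channels)
  ))
  if (length(x$active_channels) > 0L) {
    cat("active:", paste(utils::head(x$active_channels, 10L), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict classes with an NSC model
#'
#' @param object An `nsc_model`.
#' @param newx Matrix of new samples (samples x channels, same columns as
#'   training).
#' @param ... Unused.
#' @return A `data.frame` with the predicted class and the Gaussian
#'   posterior probability of each class.
#' @export
predict.nsc_model <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  scores <- t(apply(newx, 1L, function(row) nsc_score(row, object)))
  if (nrow(newx) == 1L) scores <- matrix(scores, nrow = 1L)
  colnames(scores) <- object$classes
  # softmax of -score/2 in log space
  prob <- t(apply(scores, 1L, function(s) {
    ls <- -s / 2
    ls <- ls - max(ls)
    exp(ls) / sum(exp(ls))
  }))
  if (nrow(newx) == 1L) prob <- matrix(prob, nrow = 1L,
                                       dimnames = list(NULL, object$classes))
  colnames(prob) <- object$classes
  out <- data.frame(
    sample_id = rownames(newx) %||% seq_len(nrow(newx)),
    class = object$classes[apply(scores, 1L, which.min)],
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(prob, optional = TRUE))
}

# ---------------------------------------------------------------------------
# Two-class Gaussian discriminant on selected channels
# ---------------------------------------------------------------------------

#' Discriminant parameters for two-class exposure calling
#'
#' Bundles the per-channel class means and pooled SDs of the selected
#' discriminative channels (typically the NSC-surviving channels, in percent
#' units).
#'
#' @param exposed_mean,control_mean Class mean per channel.
#' @param scale Pooled SD per channel (positive).
#' @param channels Optional channel labels.
#' @return A `discriminant_params` list.
#' @export
discriminant_params <- function(exposed_mean, control_mean, scale,
                                channels = NULL) {
  if (length(exposed_mean) != length(control_mean) ||
      length(exposed_mean) != length(scale)) {
    stop_fmt("means and scales must have equal length")
  }
  if (any(scale <= 0)) stop_fmt("scales must be positive")
  structure(
    list(exposed_mean = as.numeric(exposed_mean),
         control_mean = as.numeric(control_mean),
         scale = as.numeric(scale),
         channels = channels),
    class = "discriminant_params"
  )
}

#' Probability of exposure from the Gaussian discriminant
#'
#' With `A` and `B` the squared standardized distances of the observation to
#' the exposed and control centroids,
#' `P(exposed) = exp(-A/2) / (exp(-A/2) + exp(-B/2))`, computed in log-space
#' for stability. `prob_exposed(x) + prob_control(x) = 1` by construction.
#'
#' @param x Channel values (same units/length as the parameter vectors).
#' @param params A `discriminant_params`.
#' @return Probability in `(0, 1)`.
#' @export
#' @examples
#' p <- discriminant_params(c(4.23, 10.3, 4.00), c(1.38, 1.64, 0.80),
#'                          c(1.81, 4.11, 1.93))
#' prob_exposed(c(4.23, 10.3, 4.00), p)
prob_exposed <- function(x, params) {
  if (length(x) != length(params$exposed_mean)) {
    stop_fmt("`x` must have %d value(s)", length(params$exposed_mean))
  }
  A <- sum(((x - params$exposed_mean) / params$scale)^2)
  B <- sum(((x - params$control_mean) / params$scale)^2)
  stats::plogis((B - A) / 2)
}

#' @rdname prob_exposed
#' @export
prob_control <- function(x, params) {
  prob_exposed(x, discriminant_params(params$control_mean, params$exposed_mean,
                                      params$scale, params$channels))
}
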