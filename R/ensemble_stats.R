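# Geometry-space statistics: full-covariance Gaussian-mixture clustering
# with BIC model selection and representative selection, 2-D density maps
# with homotypic symmetrization, and the tautomer census.

mvn_logdens <- function(X, mean, cov) {
  d <- ncol(X)
  ch <- chol(cov)
  cent <- sweep(X, 2, mean)
  z <- forwardsolve(t(ch), t(cent))
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

logsumexp_rows <- function(M) {
  m <- apply(M, 1, max)
  m + log(rowSums(exp(M - m)))
}

fit_gmm <- function(X, k, seed, max_iter = 500, tol = 1e-8, reg = 1e-6) {
  n <- nrow(X); d <- ncol(X)
  set.seed(seed + k)               # distinct but reproducible init per k
  km <- stats::kmeans(X, centers = k, nstart = 5, iter.max = 100)
  means <- km$centers
  covs <- array(0, c(d, d, k))
  wts <- as.numeric(table(factor(km$cluster, levels = 1:k))) / n
  for (j in 1:k) {
    Xi <- X[km$cluster == j, , drop = FALSE]
    cv <- if (nrow(Xi) > 1) stats::cov(Xi) else diag(d)
    covs[, , j] <- cv + reg * diag(d)
  }
  trace <- numeric(0)
  ll_old <- -Inf
  resp <- NULL
  for (it in seq_len(max_iter)) {
    logp <- sapply(1:k, function(j)
      log(wts[j]) + mvn_logdens(X, means[j, ], covs[, , j]))
    if (k == 1) logp <- matrix(logp, ncol = 1)
    lse <- logsumexp_rows(logp)
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logp - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
    nk <- colSums(resp)
    wts <- nk / n
    for (j in 1:k) {
      means[j, ] <- colSums(X * resp[, j]) / nk[j]
      cent <- sweep(X, 2, means[j, ])
      covs[, , j] <- crossprod(cent * sqrt(resp[, j]), cent * sqrt(resp[, j])) / nk[j] +
        reg * diag(d)
    }
  }
  n_par <- (k - 1) + k * d + k * d * (d + 1) / 2
  list(k = k, means = means, covariances = covs, weights = wts,
       responsibilities = resp, loglik = trace[length(trace)],
       loglik_trace = trace, bic = -2 * trace[length(trace)] + n_par * log(n))
}

#' Cluster pair geometries with a Gaussian mixture model
#'
#' Full-covariance mixture (clusters can take non-spherical, correlated
#' shapes in descriptor space), EM-fitted from a seeded k-means start, with
#' a small diagonal regularization (1e-6). With `k = "auto"` the component
#' count is selected by minimum BIC over `k_range`. The representative of
#' each component is the input member nearest the component mean by
#' Mahalanobis distance under the component covariance. Refitting with the
#' same seed reproduces assignments and representatives exactly.
#'
#' @param features numeric matrix or data.frame of descriptors, one row per
#'   pair (e.g. aromatic: D, P, T_theta1, T_theta2; cation-pi: D, theta1
#'   and, when defined, theta2). Row names, if present, are used as pair ids.
#' @param k integer or `"auto"`.
#' @param seed integer seed controlling initialization.
#' @param k_range candidate k values for `"auto"`.
#' @param standardize z-score columns before fitting (off by default;
#'   angles enter in degrees unscaled).
#' @return a `hispi_gmm`: list(k, means, covariances, weights, seed,
#'   assignment, representatives (row indices), representative_ids,
#'   loglik_trace, bic).
#' @export
cluster_geometries <- function(features, k = "auto", seed = 1,
                               k_range = 2:12, standardize = FALSE) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (any(apply(X, 2, stats::sd) < 1e-12))
    stop("degenerate (zero-variance) feature column")
  scl <- NULL
  if (standardize) {
    scl <- list(center = colMeans(X), sd = apply(X, 2, stats::sd))
    X <- scale(X, scl$center, scl$sd)
  }
  if (identical(k, "auto")) {
    k_range <- k_range[k_range <= nrow(X)]
    if (!length(k_range)) stop("fewer observations than the smallest candidate k")
    fits <- lapply(k_range, function(kk) fit_gmm(X, kk, seed))
    fit <- fits[[which.min(vapply(fits, `[[`, 0, "bic"))]]
  } else {
    k <- as.integer(k)
    if (k > nrow(X)) stop("k exceeds the number of observations")
    fit <- fit_gmm(X, k, seed)
  }
  assignment <- max.col(fit$responsibilities, ties.method = "first")
  reps <- integer(fit$k)
  for (j in seq_len(fit$k)) {
    inv <- solve(fit$covariances[, , j])
    cent <- sweep(X, 2, fit$means[j, ])
    maha <- rowSums((cent %*% inv) * cent)
    reps[j] <- which.min(maha)
  }
  ids <- rownames(features)
  structure(list(k = fit$k, means = fit$means, covariances = fit$covariances,
                 weights = fit$weights, seed = seed, assignment = assignment,
                 representatives = reps,
                 representative_ids = if (!is.null(ids)) ids[reps] else NULL,
                 loglik_trace = fit$loglik_trace, bic = fit$bic,
                 standardize = scl),
            class = "hispi_gmm")
}

#' 2-D density map of pair descriptors
#'
#' Integer count grid over fixed half-open bins `[a, b)`. For homotypic
#' pair families (e.g. His-His), the assignment of "reference" and
#' "partner" is arbitrary, so with `symmetrize_homotypic = TRUE` each
#' homotypic pair contributes a second observation with `T_theta1` and
#' `T_theta2` swapped, exactly doubling its contribution.
#'
#' @param pairs data.frame holding the descriptor columns (and, when
#'   symmetrizing, `resname1`/`resname2` to detect homotypic rows; if
#'   absent, all rows are treated as homotypic).
#' @param x_param,y_param descriptor column names.
#' @param bin_width_x,bin_width_y bin widths (defaults: 0.25 A for `D`,
#'   5 degrees otherwise).
#' @param symmetrize_homotypic logical.
#' @return a `hispi_density_map`: list(x_param, y_param, x_edges, y_edges,
#'   counts (matrix), symmetrized, n_obs).
#' @export
density_map <- function(pairs, x_param, y_param,
                        bin_width_x = if (x_param == "D") 0.25 else 5,
                        bin_width_y = if (y_param == "D") 0.25 else 5,
                        symmetrize_homotypic = FALSE) {
  if (!nrow(pairs)) stop("empty input")
  df <- pairs
  if (symmetrize_homotypic) {
    homo <- if (all(c("resname1", "resname2") %in% names(df)))
      df$resname1 == df$resname2 else rep(TRUE, nrow(df))
    sw <- df[homo, , drop = FALSE]
    if (all(c("T_theta1", "T_theta2") %in% names(sw))) {
      tmp <- sw$T_theta1; sw$T_theta1 <- sw$T_theta2; sw$T_theta2 <- tmp
    }
    df <- rbind(df, sw)
  }
  x <- df[[x_param]]; y <- df[[y_param]]
  edges <- function(v, bw) {
    lo <- floor(min(v) / bw) * bw
    hi <- ceiling(max(v) / bw) * bw
    if (hi <= max(v)) hi <- hi + bw          # keep bins half-open [a, b)
    seq(lo, hi, by = bw)
  }
  xe <- edges(x, bin_width_x); ye <- edges(y, bin_width_y)
  xi <- findInterval(x, xe)                  # [e_i, e_{i+1})
  yi <- findInterval(y, ye)
  counts <- matrix(0L, length(xe) - 1, length(ye) - 1)
  for (i in seq_along(xi)) counts[xi[i], yi[i]] <- counts[xi[i], yi[i]] + 1L
  structure(list(x_param = x_param, y_param = y_param, x_edges = xe,
                 y_edges = ye, counts = counts,
                 symmetrized = symmetrize_homotypic, n_obs = nrow(df)),
            class = "hispi_density_map")
}

#' Tautomer census over neutron-like structures
#'
#' Applies [tautomer_from_deuterium()] to every His of every structure.
#' Not-determinable His are excluded from the three tautomer counts but
#' reported separately.
#'
#' @param structures list of `hispi_structure`.
#' @return list(epsilon0, delta0, positive, not_determinable) integer counts.
#' @export
tautomer_census <- function(structures) {
  counts <- c(epsilon0 = 0L, delta0 = 0L, positive = 0L, not_determinable = 0L)
  for (s in structures) {
    res <- structure_residues(s)
    for (k in res$key[!res$is_hetero & res$resname == "HIS"]) {
      st <- tautomer_from_deuterium(residue_atoms(s, k))$state
      counts[st] <- counts[st] + 1L
    }
  }
  as.list(counts)
}

#' Export representative pairs as coordinate bundles
#'
#' Writes one PDB per mixture component holding the representative pair's
#' two residues, plus a JSON provenance record (structure id, residue keys,
#' feature vector, component id).
#'
#' @param model a `hispi_gmm` fitted on `pairs`.
#' @param pairs data.frame the model was fitted on, with columns
#'   structure_id, res1, res2 and the feature columns.
#' @param structures named list of `hispi_structure` keyed by structure_id.
#' @param out_dir output directory (created if needed).
#' @param feature_cols names of the feature columns (for provenance).
#' @return data.frame: component, pair_index, structure_id, res1, res2,
#'   pdb_file, json_file.
#' @export
representative_export <- function(model, pairs, structures, out_dir,
                                  feature_cols) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (j in seq_len(model$k)) {
    idx <- model$representatives[j]
    p <- pairs[idx, , drop = FALSE]
    s <- structures[[p$structure_id]]
    if (is.null(s)) stop("structure not found: ", p$structure_id)
    atoms <- rbind(residue_atoms(s, p$res1), residue_atoms(s, p$res2))
    sub <- new_structure(atoms, id = sprintf("%s_rep%d", p$structure_id, j),
                         method = attr(s, "method"))
    pdb <- file.path(out_dir, sprintf("representative_%02d.pdb", j))
    write_pdb(sub, pdb)
    js <- file.path(out_dir, sprintf("representative_%02d.json", j))
    jsonlite::write_json(list(component = j, pair_index = idx,
                              structure_id = p$structure_id,
                              res1 = p$res1, res2 = p$res2,
                              features = as.list(p[, feature_cols, drop = FALSE])),
                         js, auto_unbox = TRUE, digits = NA)
    rows[[j]] <- data.frame(component = j, pair_index = idx,
                            structure_id = p$structure_id, res1 = p$res1,
                            res2 = p$res2, pdb_file = pdb, json_file = js,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
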