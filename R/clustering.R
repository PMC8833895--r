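#' Normalise recipes to per-ingredient consumption fractions
#'
#' Divides every amount by its ingredient's stock, mapping each dimension to
#' `[0, 1]` so that heavy base malts do not dominate hop-scale dimensions in
#' clustering and profile analysis.
#'
#' @inheritParams recipe_distances
#' @return A numeric matrix in `[0, 1]` (recipes in rows).
#' @export
normalise_recipes <- function(solutions, inventory) {
  if (is.list(solutions) && !is.data.frame(solutions)) {
    solutions <- do.call(rbind, solutions)
  }
  X <- as_recipe_matrix(solutions, inventory, check_bounds = FALSE)
  scale <- ifelse(inventory$stock_amount > 0, inventory$stock_amount, 1)
  sweep(X, 2, scale, "/")
}

# ---- cluster validity indices -------------------------------------------
# Each takes the normalised data matrix, the label vector and (where
# needed) the per-k within-cluster sums of squares; each vote_* helper
# turns the per-k scores into a single voted k.

wss_of <- function(X, labels) {
  sum(vapply(split.data.frame(X, labels), function(m) {
    sum(sweep(m, 2, colMeans(m), "-")^2)
  }, numeric(1)))
}

index_calinski_harabasz <- function(X, labels) {
  n <- nrow(X)
  k <- length(unique(labels))
  if (k < 2) return(NA_real_)
  w <- wss_of(X, labels)
  tot <- sum(sweep(X, 2, colMeans(X), "-")^2)
  ((tot - w) / (k - 1)) / (w / (n - k))
}

index_silhouette <- function(X, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  mean(cluster::silhouette(labels, dist(X))[, "sil_width"])
}

index_davies_bouldin <- function(X, labels) {
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(NA_real_)
  cents <- t(vapply(ks, function(g) colMeans(X[labels == g, , drop = FALSE]),
                    numeric(ncol(X))))
  scat <- vapply(seq_along(ks), function(j) {
    m <- X[labels == ks[j], , drop = FALSE]
    mean(sqrt(rowSums(sweep(m, 2, cents[j, ], "-")^2)))
  }, numeric(1))
  dmat <- as.matrix(dist(cents))
  mean(vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j) {
      (scat[i] + scat[j]) / dmat[i, j]
    }, numeric(1)))
  }, numeric(1)))
}

index_dunn <- function(X, labels) {
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(NA_real_)
  dmat <- as.matrix(dist(X))
  inter <- Inf
  intra <- 0
  for (i in seq_along(ks)) {
    ii <- labels == ks[i]
    di <- dmat[ii, ii, drop = FALSE]
    if (sum(ii) > 1) intra <- max(intra, max(di))
    for (j in seq_along(ks)) {
      if (j <= i) next
      jj <- labels == ks[j]
      inter <- min(inter, min(dmat[ii, jj, drop = FALSE]))
    }
  }
  if (intra == 0) return(NA_real_)
  inter / intra
}

index_c <- function(X, labels) {
  dmat <- as.matrix(dist(X))
  up <- upper.tri(dmat)
  same <- outer(labels, labels, "==") & up
  s_w <- sum(dmat[same])
  n_w <- sum(same)
  if (n_w == 0) return(NA_real_)
  all_d <- sort(dmat[up])
  s_min <- sum(all_d[seq_len(n_w)])
  s_max <- sum(all_d[seq.int(length(all_d) - n_w + 1, length(all_d))])
  if (s_max == s_min) return(NA_real_)
  (s_w - s_min) / (s_max - s_min)
}

# seeded K-means; k = n degenerates to singleton clusters (stats::kmeans
# requires k < n)
kmeans_fit <- function(X, k, nstart) {
  if (k >= nrow(X)) {
    return(list(cluster = seq_len(nrow(X)), tot.withinss = 0))
  }
  suppressWarnings(kmeans(X, k, nstart = nstart, iter.max = 100))
}

vote_max <- function(scores, ks) ks[which.max(scores)]
vote_min <- function(scores, ks) ks[which.min(scores)]

# Hartigan's rule: smallest k with H(k) <= 10, H(k) = (W(k)/W(k+1) - 1)(n-k-1)
vote_hartigan <- function(wss, ks, n) {
  H <- (wss[as.character(ks)] / wss[as.character(ks + 1)] - 1) * (n - ks - 1)
  ok <- which(H <= 10)
  if (length(ok)) ks[ok[1]] else ks[length(ks)]
}

# elbow on total within-cluster SS: k with the largest second difference
vote_elbow <- function(wss, ks) {
  d2 <- wss[as.character(ks - 1)] - 2 * wss[as.character(ks)] +
    wss[as.character(ks + 1)]
  ks[which.max(d2)]
}

# gap statistic (uniform reference over the data's bounding box)
vote_gap <- function(X, fits, ks, wss, B = 25) {
  n <- nrow(X)
  rng_lo <- apply(X, 2, min)
  rng_hi <- apply(X, 2, max)
  log_w_ref <- matrix(0, B, length(ks))
  for (b in seq_len(B)) {
    Xb <- sapply(seq_len(ncol(X)), function(j) {
      runif(n, rng_lo[j], rng_hi[j])
    })
    for (ki in seq_along(ks)) {
      fit <- suppressWarnings(kmeans(Xb, ks[ki], nstart = 3, iter.max = 50))
      log_w_ref[b, ki] <- log(max(fit$tot.withinss, 1e-12))
    }
  }
  gap <- colMeans(log_w_ref) - log(pmax(wss[as.character(ks)], 1e-12))
  se <- apply(log_w_ref, 2, sd) * sqrt(1 + 1 / B)
  # first k whose gap is within one SE of the next k's gap (firstSEmax)
  for (ki in seq_along(ks)) {
    if (ki == length(ks) || gap[ki] >= gap[ki + 1] - se[ki + 1]) {
      return(ks[ki])
    }
  }
  ks[length(ks)]
}

#' Choose the number of recipe clusters by majority vote
#'
#' Partitions the normalised solution vectors with K-means for every
#' candidate `k`, scores each partition with a battery of cluster-validity
#' indices, lets each index vote for its optimal `k`, and applies the
#' majority rule (ties broken towards the smaller `k`). The default battery
#' holds eight indices: Calinski-Harabasz, mean silhouette width,
#' Davies-Bouldin, Dunn, Hartigan's rule, the C-index, the gap statistic
#' and the within-cluster-SS elbow.
#'
#' @inheritParams recipe_distances
#' @param k_range Candidate cluster counts (default `2:6`). If there are
#'   fewer solutions than `max(k_range) + 1` the range is shrunk with a
#'   warning.
#' @param indices Character vector naming the indices to use, a subset of
#'   `c("calinski_harabasz", "silhouette", "davies_bouldin", "dunn",
#'   "hartigan", "c_index", "gap", "elbow")`.
#' @param seed Integer seed for the K-means restarts and the gap statistic's
#'   reference draws.
#' @param nstart K-means restarts per `k` (the best of `nstart` runs by
#'   within-cluster SS is kept).
#' @return An object of class `cluster_selection`: list with `k` (the voted
#'   count), `labels` (assignment at the chosen `k`), `votes` (tibble
#'   `index`/`k_vote`), `vote_counts`, `majority_strength` (votes for the
#'   winner) and `fits` (the per-k `kmeans` objects). [tidy()] returns the
#'   vote table.
#' @export
select_cluster_count <- function(solutions, inventory, k_range = 2:6,
                                 indices = c("calinski_harabasz",
                                             "silhouette", "davies_bouldin",
                                             "dunn", "hartigan", "c_index",
                                             "gap", "elbow"),
                                 seed = 1L, nstart = 10) {
  X <- normalise_recipes(solutions, inventory)
  n <- nrow(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (n < max(k_range) + 1) {
    k_range <- k_range[k_range <= n - 1]
    if (length(k_range) == 0) abort("too few solutions to cluster")
    warn(paste0("fewer solutions than the requested maximum k; ",
                "shrinking k_range to {", paste(k_range, collapse = ", "),
                "}"))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # fits for k_range plus the flanking k needed by Hartigan and the elbow
  k_all <- sort(unique(c(1L, k_range, max(k_range) + 1L)))
  k_all <- k_all[k_all <= n]
  fits <- lapply(k_all, function(k) kmeans_fit(X, k, nstart))
  names(fits) <- k_all
  wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  score_fun <- list(calinski_harabasz = index_calinski_harabasz,
                    silhouette = index_silhouette,
                    davies_bouldin = index_davies_bouldin,
                    dunn = index_dunn, c_index = index_c)
  direction <- c(calinski_harabasz = "max", silhouette = "max",
                 davies_bouldin = "min", dunn = "max", c_index = "min")
  votes <- vapply(indices, function(idx) {
    if (idx %in% names(score_fun)) {
      sc <- vapply(as.character(k_range), function(kc) {
        score_fun[[idx]](X, fits[[kc]]$cluster)
      }, numeric(1))
      if (direction[[idx]] == "max") vote_max(sc, k_range)
      else vote_min(sc, k_range)
    } else if (idx == "hartigan") {
      vote_hartigan(wss, k_range, n)
    } else if (idx == "elbow") {
      vote_elbow(wss, k_range)
    } else if (idx == "gap") {
      vote_gap(X, fits, k_range, wss)
    } else {
      abort(paste0("unknown validity index: ", idx))
    }
  }, integer(1))
  counts <- table(factor(votes, levels = k_range))
  winners <- as.integer(names(counts)[counts == max(counts)])
  k_best <- min(winners)  # tie -> smaller k
  structure(list(
    k = k_best,
    labels = fits[[as.character(k_best)]]$cluster,
    votes = tibble(index = indices, k_vote = unname(votes)),
    vote_counts = tibble(k = as.integer(names(counts)),
                         votes = as.integer(counts)),
    majority_strength = as.integer(max(counts)),
    n_indices = length(indices),
    fits = fits[as.character(k_range)]), class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("Majority vote over %d validity indices: k = %d (%d/%d votes)\n",
              x$n_indices, x$k, x$majority_strength, x$n_indices))
  print(x$vote_counts)
  invisible(x)
}

#' @describeIn select_cluster_count Vote table, one row per index.
#' @param x A `cluster_selection`.
#' @param ... Unused.
#' @method tidy cluster_selection
#' @export
tidy.cluster_selection <- function(x, ...) x$votes

#' K-means partition of discovered recipes
#'
#' Seeded K-means (best of `nstart` restarts by within-cluster sum of
#' squares) on the normalised solution vectors.
#'
#' @inheritParams select_cluster_count
#' @param k Number of clusters (`k <=` number of solutions).
#' @return Integer vector of cluster labels.
#' @export
cluster_recipes <- function(solutions, inventory, k, seed = 1L,
                            nstart = 10) {
  X <- normalise_recipes(solutions, inventory)
  if (k > nrow(X)) abort("k cannot exceed the number of solutions")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  unname(kmeans_fit(X, k, nstart)$cluster)
}

#' Per-cluster ingredient-consumption profiles
#'
#' For each cluster and each ingredient, the mean normalised consumption
#' (fraction of stock used). An ingredient is flagged `high` in a cluster
#' when that cluster's mean exceeds every other cluster's mean by at least
#' `high_margin` — the ingredients that make a recipe family distinctive.
#'
#' @inheritParams select_cluster_count
#' @param labels Cluster labels, one per solution.
#' @param high_margin Minimum lead over all other clusters for a `high`
#'   flag (normalised-consumption units, default 0.25).
#' @return A tibble with `cluster`, `name` (ingredient), `category`,
#'   `mean_consumption` and `high`.
#' @export
cluster_profiles <- function(solutions, labels, inventory,
                             high_margin = 0.25) {
  X <- normalise_recipes(solutions, inventory)
  if (length(labels) != nrow(X)) {
    abort("labels must have one entry per solution")
  }
  ks <- sort(unique(labels))
  means <- t(vapply(ks, function(g) {
    colMeans(X[labels == g, , drop = FALSE])
  }, numeric(ncol(X))))
  high <- matrix(FALSE, length(ks), ncol(X))
  if (length(ks) > 1) {
    for (i in seq_along(ks)) {
      others <- means[-i, , drop = FALSE]
      high[i, ] <- means[i, ] >= apply(others, 2, max) + high_margin
    }
  }
  tidyr::crossing(cluster = ks, name = inventory$name) |>
    dplyr::mutate(
      category = inventory$category[match(.data$name, inventory$name)],
      mean_consumption = as.vector(t(means))[
        match(paste(.data$cluster, .data$name),
              paste(rep(ks, each = ncol(X)),
                    rep(inventory$name, length(ks))))],
      high = as.vector(t(high))[
        match(paste(.data$cluster, .data$name),
              paste(rep(ks, each = ncol(X)),
                    rep(inventory$name, length(ks))))])
}

#' Hierarchical linkage of discovered recipes
#'
#' Agglomerative clustering of the normalised solution vectors (Euclidean
#' distance), returning the standard `hclust` merge tree for dendrogram
#' rendering; merge heights are non-decreasing. Cutting the tree at `k`
#' clusters (`stats::cutree`) gives a partition comparable to K-means on
#' well-separated data.
#'
#' @inheritParams select_cluster_count
#' @param method Linkage criterion passed to [stats::hclust()] (default
#'   `"ward.D2"`, the squared-Euclidean criterion matching K-means).
#' @return An object of class `hclust`.
#' @export
recipe_linkage <- function(solutions, inventory, method = "ward.D2") {
  X <- normalise_recipes(solutions, inventory)
  if (nrow(X) < 2) abort("need at least two solutions for a linkage tree")
  hclust(dist(X), method = method)
}

#' @method autoplot cluster_selection
#' @export
autoplot.cluster_selection <- function(object, ...) {
  ggplot2::ggplot(object$vote_counts,
                  ggplot2::aes(factor(.data$k), .data$votes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "number of clusters",
                  y = "validity-index votes",
                  title = sprintf("Majority vote: k = %d", object$k))
}

#' Plot per-cluster ingredient consumption profiles
#'
#' @param profiles Output of [cluster_profiles()].
#' @return A ggplot: ingredients on the x axis, one facet row per cluster,
#'   bar height the mean normalised consumption, distinctive (`high`)
#'   ingredients highlighted.
#' @export
plot_cluster_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(.data$name, .data$mean_consumption,
                               fill = .data$high)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "mean normalised consumption",
                  fill = "distinctive") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
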