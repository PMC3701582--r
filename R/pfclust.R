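# Parameter-free clustering of items from a similarity matrix, in the
# PFClust style: candidate similarity thresholds are estimated from the
# distribution of mean pairwise similarities of random subsets, clusters are
# grown agglomeratively at each candidate threshold, and the clustering with
# the best mean silhouette wins. No cluster count is ever supplied.

#' Parameter-free clustering of a similarity matrix
#'
#' Procedure: (1) sample `n_rounds` random subsets of the items and record
#' each subset's mean pairwise similarity; the `percentiles` of that
#' empirical distribution become candidate thresholds. (2) For each
#' candidate threshold, build clusters agglomeratively: seed a cluster with
#' the most similar unassigned pair (requiring positive similarity at or
#' above the threshold), repeatedly add the unassigned item with the highest
#' mean similarity to the cluster while that mean stays at or above the
#' threshold; items never absorbed become singletons. (3) Score each
#' candidate clustering by the mean silhouette of the items in clusters of
#' size >= 2 (distances `1 - s`; singletons participate as their own groups);
#' return the best, ties broken toward fewer clusters.
#'
#' @param sim symmetric similarity matrix in `[0,1]` with unit diagonal and
#'   ids as dimnames.
#' @param seed integer seed for the randomized threshold estimation.
#' @param n_rounds number of random subsets used to estimate thresholds.
#' @param percentiles upper percentiles of the subset-mean distribution used
#'   as candidate thresholds.
#' @return object of class `"clustering"`: `clusters` (list of id vectors,
#'   each of size >= 2), `singletons` (id vector), `quality` (mean silhouette
#'   of clustered items; `NA` when nothing clustered), `threshold` (the
#'   selected candidate).
#' @export
pfclust <- function(sim, seed = 1, n_rounds = 100,
                    percentiles = c(0.50, 0.60, 0.70, 0.75, 0.80,
                                    0.85, 0.90, 0.95, 0.97, 0.99)) {
  assert_simmat(sim)
  ids <- rownames(sim)
  n <- length(ids)
  if (n == 1) {
    return(new_clustering(list(), ids, NA_real_, NA_real_))
  }
  thresholds <- with_seed(seed, candidate_thresholds(sim, n_rounds, percentiles))
  candidates <- lapply(thresholds, function(th) build_at_threshold(sim, th))
  quality <- vapply(candidates, function(cl) silhouette_quality(sim, cl),
                    numeric(1))
  # Candidate selection averages the silhouette over *all* items, scoring
  # singletons as 0 (the standard convention); this stops a candidate from
  # looking better merely by demoting borderline items to singletons. The
  # reported quality stays the mean over clustered items.
  score <- vapply(seq_along(candidates), function(k) {
    cl <- candidates[[k]]
    n_cl <- length(unlist(cl$clusters))
    if (is.na(quality[k])) 0
    else quality[k] * n_cl / (n_cl + length(cl$singletons))
  }, numeric(1))
  n_groups <- vapply(candidates, function(cl) length(cl$clusters), numeric(1))
  best <- max(score)
  pick <- which(score >= best - 1e-12)
  pick <- pick[which.min(n_groups[pick])]
  cl <- candidates[[pick]]
  new_clustering(lapply(cl$clusters, function(ix) ids[ix]),
                 ids[cl$singletons],
                 quality[pick], thresholds[pick])
}

new_clustering <- function(clusters, singletons, quality, threshold) {
  structure(list(clusters = clusters, singletons = singletons,
                 quality = quality, threshold = threshold),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat(sprintf("<clustering: %d clusters (sizes %s), %d singletons, quality %.3f>\n",
              length(x$clusters),
              paste(vapply(x$clusters, length, integer(1)), collapse = ","),
              length(x$singletons), as.numeric(x$quality)))
  invisible(x)
}

#' Cluster membership as a label vector
#'
#' @param clustering a `"clustering"`.
#' @return named integer vector of group labels over all items; singletons
#'   get their own labels.
#' @export
cluster_labels <- function(clustering) {
  labs <- integer(0)
  g <- 0L
  for (cl in clustering$clusters) {
    g <- g + 1L
    labs[cl] <- g
  }
  for (s in clustering$singletons) {
    g <- g + 1L
    labs[s] <- g
  }
  labs
}

candidate_thresholds <- function(sim, n_rounds, percentiles) {
  n <- nrow(sim)
  means <- numeric(n_rounds)
  for (r in seq_len(n_rounds)) {
    size <- if (n == 2) 2 else sample(2:n, 1)
    ix <- sample.int(n, size)
    sub <- sim[ix, ix]
    means[r] <- mean(sub[upper.tri(sub)])
  }
  unname(stats::quantile(means, probs = percentiles, type = 7))
}

# Agglomerative construction at one threshold. Returns integer index sets.
build_at_threshold <- function(sim, threshold) {
  n <- nrow(sim)
  unassigned <- seq_len(n)
  clusters <- list()
  while (length(unassigned) >= 2) {
    sub <- sim[unassigned, unassigned, drop = FALSE]
    diag(sub) <- -Inf
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair_sim <- sub[best[1], best[2]]
    if (pair_sim < threshold || pair_sim <= 0) break
    members <- unassigned[c(best[1], best[2])]
    unassigned <- setdiff(unassigned, members)
    repeat {
      if (length(unassigned) == 0) break
      mean_sim <- colMeans(sim[members, unassigned, drop = FALSE])
      k <- which.max(mean_sim)
      if (mean_sim[k] < threshold || mean_sim[k] <= 0) break
      members <- c(members, unassigned[k])
      unassigned <- unassigned[-k]
    }
    clusters[[length(clusters) + 1]] <- sort(members)
  }
  list(clusters = clusters, singletons = sort(unassigned))
}

# Mean silhouette of clustered items, computed from the similarity matrix
# (distance 1 - s). Singletons act as their own groups when computing the
# nearest-other-group separation. NA when no item is in a cluster of size
# >= 2; 0 when the partition has a single group (no separation is defined).
silhouette_quality <- function(sim, cl) {
  clustered <- unlist(cl$clusters)
  if (length(clustered) == 0) return(NA_real_)
  groups <- c(cl$clusters, as.list(cl$singletons))
  if (length(groups) < 2) return(0)
  d <- 1 - sim
  s_vals <- numeric(0)
  for (gi in seq_along(cl$clusters)) {
    g <- cl$clusters[[gi]]
    for (i in g) {
      a <- mean(d[i, setdiff(g, i)])
      b <- min(vapply(seq_along(groups), function(gj) {
        if (gj == gi) return(Inf)
        mean(d[i, groups[[gj]]])
      }, numeric(1)))
      s_vals <- c(s_vals, if (max(a, b) == 0) 0 else (b - a) / max(a, b))
    }
  }
  mean(s_vals)
}

#' Split filtered families into scaffold-coherent refined families
#'
#' Runs [pfclust()] on the members' Tanimoto similarity matrix within each
#' filtered family. Every structural cluster becomes one refined family and
#' every singleton its own refined (singleton) family, all carrying the
#' parent filtered family's id; the union of a parent's refined members
#' equals the parent's membership exactly.
#'
#' @param filtered a `"family_set"` of filtered families.
#' @param fps named list of `"fingerprint"` objects covering every member.
#' @param seed integer master seed; each family derives its own stream.
#' @param ... passed on to [pfclust()].
#' @return a `"family_set"` of refined families.
#' @export
refine_families <- function(filtered, fps, seed = 1, ...) {
  if (length(filtered) == 0) stopf("empty filtered family set")
  out <- list()
  for (fam in filtered) {
    missing_fp <- setdiff(fam$member_ids, names(fps))
    if (length(missing_fp) > 0) {
      stopf("missing fingerprints for members of %s: %s", fam$family_id,
            paste(missing_fp, collapse = ", "))
    }
    if (length(fam$member_ids) == 1) {
      out[[length(out) + 1]] <- new_family(
        paste0(fam$family_id, ".s1"), fam$member_ids, stage = "refined",
        target_name = fam$target_name, parent_id = fam$family_id)
      next
    }
    sim <- similarity_matrix(fps[fam$member_ids])
    cl <- pfclust(sim, seed = derive_seed(seed, fam$family_id), ...)
    for (ci in seq_along(cl$clusters)) {
      out[[length(out) + 1]] <- new_family(
        sprintf("%s.c%d", fam$family_id, ci), cl$clusters[[ci]],
        stage = "refined", target_name = fam$target_name,
        parent_id = fam$family_id)
    }
    for (si in seq_along(cl$singletons)) {
      out[[length(out) + 1]] <- new_family(
        sprintf("%s.s%d", fam$family_id, si), cl$singletons[si],
        stage = "refined", target_name = fam$target_name,
        parent_id = fam$family_id)
    }
  }
  family_set(out)
}
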