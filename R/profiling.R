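# Batch profiling of a compound panel: PR-score matrix against a family set,
# clustering of the panel by structure and by predicted-activity profile, and
# the concordance between the two groupings.

#' PR-score profile matrix of a compound panel
#'
#' `scores[i, j]` is the PR-score of panel compound `j` against family `i`.
#' With `exclude_self = TRUE` (the default), a compound that is itself a
#' member of a family is removed from that family before scoring; a family
#' emptied this way gets `NA` for that compound and is listed in the
#' `"omitted"` attribute.
#'
#' @param panel_fps named list of panel `"fingerprint"`s (columns).
#' @param families a `"family_set"` (rows).
#' @param fps named list of fingerprints covering all family members.
#' @param params a [scoring_params()] object.
#' @param exclude_self drop a panel compound from its own families before
#'   scoring.
#' @param significant_only keep only rows whose column-wise minimum score is
#'   at most `params$alpha`.
#' @return numeric matrix (families x compounds) of class `"profile_matrix"`
#'   with `alpha` attribute.
#' @export
profile_matrix <- function(panel_fps, families, fps,
                           params = scoring_params(),
                           exclude_self = TRUE, significant_only = FALSE) {
  if (length(panel_fps) == 0) stopf("empty compound panel")
  if (length(families) == 0) stopf("empty family set")
  fam_ids <- names(families)
  cmp_ids <- unname(vapply(panel_fps, function(f) f$compound_id, ""))
  m <- matrix(NA_real_, nrow = length(fam_ids), ncol = length(cmp_ids),
              dimnames = list(fam_ids, cmp_ids))
  omitted <- character(0)
  for (fi in seq_along(families)) {
    fam <- families[[fi]]
    for (ci in seq_along(panel_fps)) {
      member_ids <- fam$member_ids
      if (exclude_self) member_ids <- setdiff(member_ids, cmp_ids[ci])
      if (length(member_ids) == 0) {
        omitted <- c(omitted, sprintf("%s/%s", fam$family_id, cmp_ids[ci]))
        next
      }
      m[fi, ci] <- pr_score(panel_fps[[ci]], fps[member_ids], params)
    }
  }
  if (significant_only) {
    keep <- apply(m, 1, function(r) any(r <= params$alpha, na.rm = TRUE))
    m <- m[keep, , drop = FALSE]
  }
  attr(m, "alpha") <- params$alpha
  attr(m, "omitted") <- omitted
  class(m) <- c("profile_matrix", class(m))
  m
}

#' Cluster panel compounds by activity profile
#'
#' Treats each compound's column of PR-scores as a position vector, converts
#' pairwise Euclidean distances `d` between columns to similarities
#' `s = 1 / (1 + d)` (monotone, bounded in `(0, 1]`, parameter-free) and
#' clusters with [pfclust()].
#'
#' @param profile a [profile_matrix()].
#' @param seed integer seed for [pfclust()].
#' @param ... passed on to [pfclust()].
#' @return a `"clustering"` of the panel compound ids.
#' @export
activity_cluster <- function(profile, seed = 1, ...) {
  if (ncol(profile) == 0) stopf("profile matrix has no compound columns")
  cols <- t(unclass(profile))
  cols[is.na(cols)] <- 1  # an unscorable family is maximally insignificant
  d <- as.matrix(stats::dist(cols, method = "euclidean"))
  sim <- 1 / (1 + d)
  diag(sim) <- 1
  dimnames(sim) <- list(colnames(profile), colnames(profile))
  pfclust(sim, seed = seed, ...)
}

#' Cluster panel compounds by chemical structure
#'
#' [pfclust()] applied to the panel's all-against-all Tanimoto similarity
#' matrix.
#'
#' @param panel_fps named list of `"fingerprint"`s.
#' @param seed integer seed for [pfclust()].
#' @param ... passed on to [pfclust()].
#' @return a `"clustering"` of the panel compound ids.
#' @export
structure_cluster <- function(panel_fps, seed = 1, ...) {
  if (length(panel_fps) == 0) stopf("empty compound panel")
  pfclust(similarity_matrix(panel_fps), seed = seed, ...)
}

#' Concordance between two clusterings of one panel
#'
#' Cross-tabulates the group memberships of two clusterings (e.g. structure-
#' vs activity-based) over their common items, reconstructing the
#' co-membership comparison exactly from the two partitions.
#'
#' @param a,b `"clustering"` objects over the same items.
#' @return a contingency `table` (groups of `a` x groups of `b`).
#' @export
cluster_concordance <- function(a, b) {
  la <- cluster_labels(a)
  lb <- cluster_labels(b)
  common <- intersect(names(la), names(lb))
  if (length(common) == 0) stopf("clusterings share no items")
  table(a = paste0("a", la[common]), b = paste0("b", lb[common]))
}
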