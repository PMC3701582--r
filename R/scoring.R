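# The core molecule-family score: a Gaussian transform turns a Tanimoto
# similarity t into the exceedance probability p(X > t) = exp(-t^2 / (2 h^2)),
# and the Parzen-Rosenblatt (PR) score of a query against a family is the
# mean of those pairwise p-values over the family's members. Lower scores are
# more significant; the family-level PR-score and "p-value" are the same
# number and the code uses pr_score throughout.

#' Scoring parameters
#'
#' @param h bandwidth (smoothing factor) of the Gaussian similarity kernel;
#'   dimensionless, default 0.125.
#' @param alpha significance cut-off on PR-scores, default 0.05.
#' @return list of class `"scoring_params"`.
#' @export
scoring_params <- function(h = 0.125, alpha = 0.05) {
  if (!is.numeric(h) || length(h) != 1 || is.na(h) || h <= 0) {
    stopf("h must be a positive number")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stopf("alpha must lie in (0, 1)")
  }
  structure(list(h = h, alpha = alpha), class = "scoring_params")
}

#' Gaussian similarity-to-probability transform
#'
#' `p(X > t) = exp(-t^2 / (2 h^2))`: the probability that a random pairwise
#' Tanimoto similarity exceeds `t`, under a Gaussian exceedance model with
#' bandwidth `h`. Strictly decreasing in `t`, with `p(0) = 1`.
#'
#' @param t Tanimoto similarity (vectorized), in `[0, 1]`.
#' @param h bandwidth, `> 0`.
#' @return exceedance probability in `(0, 1]`.
#' @export
gaussian_pvalue <- function(t, h = 0.125) {
  if (!is.numeric(h) || length(h) != 1 || is.na(h) || h <= 0) {
    stopf("h must be a positive number")
  }
  if (any(is.na(t)) || any(t < 0) || any(t > 1)) {
    stopf("similarities must lie in [0, 1]")
  }
  exp(-t^2 / (2 * h^2))
}

#' Fit the kernel bandwidth to a sample of similarities
#'
#' Finds the `h` minimizing the squared error between the sample's empirical
#' exceedance fraction `P(X > x)` and the model `exp(-x^2 / (2 h^2))` over a
#' fixed grid of `x` values.
#'
#' @param similarities numeric vector of pairwise Tanimoto similarities in
#'   `[0, 1]`; at least 100 values, not all equal.
#' @param grid evaluation grid for the exceedance curve.
#' @return fitted bandwidth `h`.
#' @export
fit_smoothing_factor <- function(similarities, grid = seq(0.01, 0.99, by = 0.01)) {
  s <- similarities[!is.na(similarities)]
  if (length(s) < 100) stopf("need at least 100 similarity values")
  if (any(s < 0) || any(s > 1)) stopf("similarities must lie in [0, 1]")
  if (length(unique(s)) == 1) {
    stopf("degenerate similarity sample (all values equal)")
  }
  emp <- vapply(grid, function(x) mean(s > x), numeric(1))
  sse <- function(h) sum((emp - exp(-grid^2 / (2 * h^2)))^2)
  stats::optimize(sse, interval = c(1e-3, 2), tol = 1e-7)$minimum
}

#' Parzen-Rosenblatt score of a query against a family
#'
#' The arithmetic mean, over the `n` family members, of the Gaussian
#' exceedance p-value of the query's Tanimoto similarity to each member.
#' Lower values mean the query is more similar to the family than random
#' pairs would be.
#'
#' @param query a `"fingerprint"`.
#' @param members non-empty list of member `"fingerprint"`s at the same
#'   radius.
#' @param params a [scoring_params()] object.
#' @return PR-score in `(0, 1]`.
#' @export
pr_score <- function(query, members, params = scoring_params()) {
  if (length(members) == 0) stopf("family has no members")
  mean(vapply(members, function(m) {
    gaussian_pvalue(tanimoto(query, m), params$h)
  }, numeric(1)))
}

#' Rank families for a query molecule
#'
#' Scores the query against every family and returns one prediction per
#' family, ranked ascending by PR-score (ties broken by family id). When the
#' query compound is itself a member of a family, its fingerprint is removed
#' from that family before scoring (self-exclusion); a family emptied by
#' self-exclusion is omitted and listed in the `"omitted"` attribute. Known
#' activity per family is annotated from `activities` when supplied.
#'
#' @param query a `"fingerprint"` (its `compound_id` drives self-exclusion),
#'   or a single SMILES string.
#' @param families a `"family_set"`.
#' @param fps named list of fingerprints covering all family members.
#' @param params a [scoring_params()] object.
#' @param activities optional activity record data.frame used to annotate
#'   `known_activity` (`active`, `inactive` or `untested`).
#' @param exclude_self drop the query compound from family memberships before
#'   scoring (default `TRUE`).
#' @return data.frame with columns `query_id`, `family_id`, `target_name`,
#'   `pr_score`, `rank`, `significant`, `known_activity`.
#' @export
predict_targets <- function(query, families, fps, params = scoring_params(),
                            activities = NULL, exclude_self = TRUE) {
  if (length(families) == 0) stopf("empty family set")
  if (is.character(query)) {
    query <- compute_fingerprint(query, radius = fps[[1]]$radius)
  }
  qid <- query$compound_id
  rows <- list()
  omitted <- character(0)
  for (fam in families) {
    member_ids <- fam$member_ids
    if (exclude_self) member_ids <- setdiff(member_ids, qid)
    if (length(member_ids) == 0) {
      omitted <- c(omitted, fam$family_id)
      next
    }
    missing_fp <- setdiff(member_ids, names(fps))
    if (length(missing_fp) > 0) {
      stopf("missing fingerprints for members of %s: %s", fam$family_id,
            paste(missing_fp, collapse = ", "))
    }
    rows[[length(rows) + 1]] <- data.frame(
      query_id = qid, family_id = fam$family_id,
      target_name = fam$target_name,
      pr_score = pr_score(query, fps[member_ids], params),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) stopf("every family was emptied by self-exclusion")
  out <- do.call(rbind, rows)
  ord <- order(out$pr_score, out$family_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$significant <- out$pr_score <= params$alpha
  out$known_activity <- "untested"
  if (!is.null(activities) && nrow(activities) > 0) {
    mine <- activities[activities$compound_id == qid, , drop = FALSE]
    if (nrow(mine) > 0) {
      lab <- classify_record(mine)
      for (i in seq_len(nrow(out))) {
        fam_id <- known_activity_family(families[[out$family_id[i]]])
        rel <- lab[mine$family_id == fam_id]
        if (any(rel == "active")) {
          out$known_activity[i] <- "active"
        } else if (any(rel == "inactive")) {
          out$known_activity[i] <- "inactive"
        }
      }
    }
  }
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  out
}

# Activity records are keyed by the target family id; refined families map
# back to their parent filtered family for known-activity annotation.
known_activity_family <- function(fam) {
  if (fam$stage == "refined" && !is.na(fam$parent_id)) fam$parent_id
  else fam$family_id
}
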