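# Monte Carlo cross-validation with top-1/top-4 retrieval and the Matthews
# correlation coefficient, comparable across the original / filtered /
# refined family definitions.

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; returns 0
#' when any factor of the denominator is 0 (standard convention).
#'
#' @param counts list or data.frame row with non-negative `TP`, `FP`, `TN`,
#'   `FN`.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  vals <- c(tp, fp, tn, fn)
  if (any(is.na(vals)) || any(vals < 0)) stopf("counts must be non-negative")
  if (sum(vals) == 0) stopf("all confusion counts are zero")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Monte Carlo cross-validation of family retrieval
#'
#' Runs `runs` independent random-subsampling rounds. Per round, every family
#' with at least `holdout_min` members has `ceiling(fraction * n)` members
#' held out; each held-out compound is scored as a query against all families
#' with that round's holdouts (and the query itself) removed from the
#' training memberships. A query counts as a top-1 hit when its parent family
#' ranks first and a top-4 hit when it ranks within the first four.
#'
#' Confusion accounting: each query contributes one positive prediction, its
#' top-ranked family — a TP when it is the parent, otherwise one FP (the
#' wrong family) plus one FN (the missed parent); every other family scored
#' for that query contributes a TN.
#'
#' @param families a `"family_set"` (one stage).
#' @param fps named list of fingerprints covering all members.
#' @param params a [scoring_params()] object.
#' @param fraction holdout proportion per family and round (default 0.1).
#' @param runs number of Monte Carlo rounds (default 5).
#' @param seed integer seed; the full report is reproducible from it.
#' @param holdout_min families with fewer members are never queried
#'   (default 2: holding out the only member would leave nothing to score
#'   against); they still serve as ranking competitors.
#' @return object of class `"cv_report"`: `stage`, `runs` (per-run
#'   data.frame with `queries`, `top1_hits`, `top4_hits`, `TP`, `FP`, `TN`,
#'   `FN`, `mcc`), `aggregate` (means over runs), `skipped` (family ids too
#'   small to query).
#' @export
monte_carlo_cv <- function(families, fps, params = scoring_params(),
                           fraction = 0.1, runs = 5, seed = 1,
                           holdout_min = 2) {
  if (length(families) == 0) stopf("empty family set")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stopf("fraction must lie in (0, 1)")
  }
  sizes <- vapply(families, function(f) length(f$member_ids), integer(1))
  eligible <- names(families)[sizes >= holdout_min]
  skipped <- setdiff(names(families), eligible)
  if (length(eligible) == 0) stopf("all families too small to hold out from")
  stages <- unique(vapply(families, function(f) f$stage, ""))
  stage <- if (length(stages) == 1) stages else NA_character_

  per_run <- vector("list", runs)
  for (r in seq_len(runs)) {
    holdouts <- with_seed(derive_seed(seed, paste0("cv-run-", r)), {
      lapply(families, function(f) {
        if (!(f$family_id %in% eligible)) return(character(0))
        k <- max(1L, ceiling(fraction * length(f$member_ids)))
        sample(f$member_ids, k)
      })
    })
    train <- lapply(families, function(f) {
      setdiff(f$member_ids, holdouts[[f$family_id]])
    })
    names(train) <- names(families)
    top1 <- 0L; top4 <- 0L; nq <- 0L
    TP <- 0L; FP <- 0L; TN <- 0L; FN <- 0L
    for (fam_id in eligible) {
      for (qid in holdouts[[fam_id]]) {
        scores <- vapply(names(families), function(g) {
          mem <- setdiff(train[[g]], qid)
          if (length(mem) == 0) return(NA_real_)
          pr_score(fps[[qid]], fps[mem], params)
        }, numeric(1))
        scores <- scores[!is.na(scores)]
        if (!(fam_id %in% names(scores))) next
        ord <- order(scores, names(scores))
        ranked <- names(scores)[ord]
        prank <- match(fam_id, ranked)
        nq <- nq + 1L
        if (prank == 1L) {
          top1 <- top1 + 1L
          TP <- TP + 1L
          TN <- TN + length(ranked) - 1L
        } else {
          FP <- FP + 1L
          FN <- FN + 1L
          TN <- TN + length(ranked) - 2L
        }
        if (prank <= 4L) top4 <- top4 + 1L
      }
    }
    counts <- list(TP = TP, FP = FP, TN = TN, FN = FN)
    per_run[[r]] <- data.frame(
      run = r, queries = nq, top1_hits = top1, top4_hits = top4,
      TP = TP, FP = FP, TN = TN, FN = FN,
      mcc = if (nq > 0) mcc(counts) else NA_real_
    )
  }
  runs_df <- do.call(rbind, per_run)
  structure(list(
    stage = stage,
    runs = runs_df,
    aggregate = list(
      mean_top1_rate = mean(runs_df$top1_hits / runs_df$queries),
      mean_top4_rate = mean(runs_df$top4_hits / runs_df$queries),
      mean_mcc = mean(runs_df$mcc),
      pooled_mcc = mcc(list(TP = sum(runs_df$TP), FP = sum(runs_df$FP),
                            TN = sum(runs_df$TN), FN = sum(runs_df$FN)))
    ),
    skipped = skipped,
    params = list(fraction = fraction, runs = runs, seed = seed,
                  holdout_min = holdout_min)
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report [%s]: %d runs>\n", x$stage, nrow(x$runs)))
  print(x$runs, row.names = FALSE)
  cat(sprintf("mean top-1 %.1f%%  mean top-4 %.1f%%  mean MCC %.3f\n",
              100 * x$aggregate$mean_top1_rate,
              100 * x$aggregate$mean_top4_rate,
              x$aggregate$mean_mcc))
  if (length(x$skipped) > 0) {
    cat(sprintf("skipped (too small to query): %s\n",
                paste(x$skipped, collapse = ", ")))
  }
  invisible(x)
}
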