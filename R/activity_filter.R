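# Rule-based bioactivity curation: classify records as active/inactive and
# build the original and filtered family definitions.

#' The bioactivity rule table
#'
#' One rule per supported activity type. Concentration thresholds are
#' upper bounds ("at_most" is non-strict, "less_than" strict); the two
#' percent-based read-outs use non-strict lower bounds ("at_least"):
#' IC50 active at <= 50 uM, Ki < 20 uM, Kd <= 10 uM, EC50 <= 40 uM,
#' ED50 <= 10 uM, Potency <= 10 uM, Activity >= 40 %, Inhibition >= 45 %.
#'
#' @return data.frame with columns `activity_type`, `direction`,
#'   `threshold_value`, `threshold_unit`.
#' @export
activity_rules <- function() {
  data.frame(
    activity_type = c("IC50", "Ki", "Kd", "EC50", "ED50", "Potency",
                      "Activity", "Inhibition"),
    direction = c("at_most", "less_than", "at_most", "at_most", "at_most",
                  "at_most", "at_least", "at_least"),
    threshold_value = c(50, 20, 10, 40, 10, 10, 40, 45),
    threshold_unit = c(rep("uM", 6), "percent", "percent"),
    stringsAsFactors = FALSE
  )
}

# Convert a concentration to nM; percent values pass through unchanged.
value_as_nM <- function(value, unit) {
  ifelse(unit == "percent", value, value * unname(CONC_UNITS[unit]))
}

#' Classify activity records as active, inactive or indeterminate
#'
#' Applies the rule table after normalizing concentrations to nM. A record's
#' relation and value define the feasible interval for the true measurement
#' (`=` a point, `<`/`<=` a left interval, `>`/`>=` a right interval;
#' `unspecified` is treated as `=`). The record is `active` only when the
#' whole interval lies in the rule's active region, `inactive` when it lies
#' wholly in the inactive region, and `indeterminate` otherwise — a censored
#' value compatible with both sides never promotes a compound. An
#' `explicit_label`, when present, overrides the numeric rule.
#'
#' @param records activity record data.frame (see [read_activity_table()]).
#' @param rules rule table; defaults to [activity_rules()].
#' @return character vector over `{active, inactive, indeterminate}`.
#' @export
classify_record <- function(records, rules = activity_rules()) {
  if (nrow(records) == 0) return(character(0))
  if (anyDuplicated(rules$activity_type)) {
    stopf("rule table must hold exactly one rule per activity type")
  }
  ridx <- match(records$activity_type, rules$activity_type)
  if (anyNA(ridx)) {
    stopf("no rule for activity_type: %s",
          paste(unique(records$activity_type[is.na(ridx)]), collapse = ", "))
  }
  bad_unit <- ifelse(rules$threshold_unit[ridx] == "percent",
                     records$unit != "percent",
                     !(records$unit %in% names(CONC_UNITS)))
  if (any(bad_unit)) {
    stopf("unit not convertible to the rule's unit for rows: %s",
          paste(which(bad_unit), collapse = ", "))
  }
  thr <- ifelse(rules$threshold_unit[ridx] == "percent",
                rules$threshold_value[ridx],
                rules$threshold_value[ridx] * unname(CONC_UNITS["uM"]))
  val <- value_as_nM(records$value, records$unit)
  rel <- records$relation
  # feasible interval [lo, hi] with open/closed endpoints
  lo <- ifelse(rel %in% c(">", ">="), val, ifelse(rel %in% c("<", "<="), 0, val))
  hi <- ifelse(rel %in% c("<", "<="), val, ifelse(rel %in% c(">", ">="), Inf, val))
  lo_open <- rel == ">"
  hi_open <- rel == "<"
  dir <- rules$direction[ridx]

  # active iff the entire interval satisfies the active condition,
  # inactive iff it entirely satisfies the complement.
  active <- ifelse(
    dir == "at_most",  hi <= thr,                          # T <= thr
    ifelse(dir == "less_than", hi < thr | (hi == thr & hi_open),  # T < thr
           lo >= thr))                                     # at_least: T >= thr
  inactive <- ifelse(
    dir == "at_most",  lo > thr | (lo == thr & lo_open),   # T > thr
    ifelse(dir == "less_than", lo >= thr,                  # T >= thr
           hi < thr | (hi == thr & hi_open)))              # at_least: T < thr

  out <- ifelse(active, "active", ifelse(inactive, "inactive", "indeterminate"))
  lab <- records$explicit_label
  out[!is.na(lab)] <- lab[!is.na(lab)]
  out
}

#' Build original families from activity records
#'
#' One `stage = "original"` family per `family_id`, containing every compound
#' with any record against that target — active, inactive or indeterminate —
#' mirroring database association semantics in which a compound-target link
#' need not imply activity.
#'
#' @param records activity record data.frame.
#' @return a `"family_set"` of original families.
#' @export
build_original_families <- function(records) {
  if (is.null(records) || nrow(records) == 0) stopf("no activity records")
  by_fam <- split(records, records$family_id)
  family_set(lapply(by_fam, function(df) {
    new_family(df$family_id[1], unique(df$compound_id), stage = "original",
               target_name = df$target_name[which(!is.na(df$target_name))[1]] %||%
                 NA_character_)
  }))
}

#' Build filtered families from activity records
#'
#' Classifies every record with [classify_record()] and keeps, per family,
#' exactly the compounds with at least one active record against that target
#' ("any-active" rule for conflicting duplicates). Families left with no
#' active compound are omitted.
#'
#' @param records activity record data.frame.
#' @param rules rule table; defaults to [activity_rules()].
#' @return a `"family_set"` of filtered families.
#' @export
build_filtered_families <- function(records, rules = activity_rules()) {
  if (is.null(records) || nrow(records) == 0) stopf("no activity records")
  lab <- classify_record(records, rules)
  act <- records[lab == "active", , drop = FALSE]
  if (nrow(act) == 0) {
    return(structure(list(), class = "family_set"))
  }
  by_fam <- split(act, act$family_id)
  family_set(lapply(by_fam, function(df) {
    new_family(df$family_id[1], unique(df$compound_id), stage = "filtered",
               target_name = df$target_name[which(!is.na(df$target_name))[1]] %||%
                 NA_character_)
  }))
}
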