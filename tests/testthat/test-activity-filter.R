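test_that("threshold values classify exactly per the rule table", {
  # at the threshold: Ki is strict (<), everything else non-strict
  at_threshold <- rbind(
    act_row("c1", "F", "IC50", 50, "uM"),
    act_row("c2", "F", "Ki", 20, "uM"),
    act_row("c3", "F", "Kd", 10, "uM"),
    act_row("c4", "F", "EC50", 40, "uM"),
    act_row("c5", "F", "ED50", 10, "uM"),
    act_row("c6", "F", "Potency", 10, "uM"),
    act_row("c7", "F", "Activity", 40, "percent"),
    act_row("c8", "F", "Inhibition", 45, "percent")
  )
  expect_equal(classify_record(at_threshold),
               c("active", "inactive", "active", "active", "active",
                 "active", "active", "active"))
})

test_that("classification flips exactly at each rule boundary", {
  eps <- 1e-6
  rules <- activity_rules()
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    unit <- if (r$threshold_unit == "percent") "percent" else "uM"
    below <- classify_record(act_row("c", "F", r$activity_type,
                                     r$threshold_value * (1 - eps), unit))
    above <- classify_record(act_row("c", "F", r$activity_type,
                                     r$threshold_value * (1 + eps), unit))
    if (r$direction %in% c("at_most", "less_than")) {
      expect_equal(below, "active")
      expect_equal(above, "inactive")
    } else {
      expect_equal(below, "inactive")
      expect_equal(above, "active")
    }
  }
})

test_that("units are normalized before comparison", {
  expect_equal(classify_record(act_row("c", "F", "IC50", 50000, "nM")),
               "active")
  expect_equal(classify_record(act_row("c", "F", "IC50", 0.05, "mM")),
               "active")
  expect_equal(classify_record(act_row("c", "F", "IC50", 0.051, "mM")),
               "inactive")
  expect_equal(classify_record(act_row("c", "F", "Kd", 1e-5, "M")),
               "active")
  expect_error(classify_record(act_row("c", "F", "IC50", 50, "percent")),
               "unit")
})

test_that("censored relations only classify when the comparison is decidable", {
  expect_equal(classify_record(act_row("c", "F", "IC50", 10, "uM",
                                       relation = ">")),
               "indeterminate")
  expect_equal(classify_record(act_row("c", "F", "IC50", 10, "uM",
                                       relation = "<")),
               "active")
  expect_equal(classify_record(act_row("c", "F", "IC50", 50, "uM",
                                       relation = "<=")),
               "active")
  expect_equal(classify_record(act_row("c", "F", "IC50", 50, "uM",
                                       relation = ">")),
               "inactive")
  expect_equal(classify_record(act_row("c", "F", "IC50", 60, "uM",
                                       relation = "<")),
               "indeterminate")
  # strict Ki rule: "<= 20" is compatible with Ki = 20 (inactive) -> undecided
  expect_equal(classify_record(act_row("c", "F", "Ki", 20, "uM",
                                       relation = "<=")),
               "indeterminate")
  expect_equal(classify_record(act_row("c", "F", "Ki", 20, "uM",
                                       relation = ">=")),
               "inactive")
  # percent rules are mirrored
  expect_equal(classify_record(act_row("c", "F", "Activity", 40, "percent",
                                       relation = ">=")),
               "active")
  expect_equal(classify_record(act_row("c", "F", "Activity", 40, "percent",
                                       relation = "<")),
               "inactive")
  expect_equal(classify_record(act_row("c", "F", "Activity", 50, "percent",
                                       relation = "<")),
               "indeterminate")
})

test_that("classification is total over types x relations x units", {
  rules <- activity_rules()
  combos <- expand.grid(type = rules$activity_type,
                        rel = c("=", "<", "<=", ">", ">=", "unspecified"),
                        stringsAsFactors = FALSE)
  for (k in seq_len(nrow(combos))) {
    unit <- if (combos$type[k] %in% c("Activity", "Inhibition")) "percent"
            else "uM"
    lab <- classify_record(act_row("c", "F", combos$type[k], 15, unit,
                                   relation = combos$rel[k]))
    expect_true(lab %in% c("active", "inactive", "indeterminate"))
  }
})

test_that("explicit labels override the numeric rule", {
  expect_equal(classify_record(act_row("c", "F", "IC50", 1, "uM",
                                       label = "inactive")),
               "inactive")
  expect_equal(classify_record(act_row("c", "F", "IC50", 500, "uM",
                                       label = "active")),
               "active")
})

test_that("original families keep every associated compound", {
  records <- rbind(
    act_row("a", "F1", "IC50", 1, "uM"),            # active
    act_row("b", "F1", "IC50", 500, "uM"),          # inactive
    act_row("c", "F1", "IC50", 10, "uM", relation = ">"),  # indeterminate
    act_row("a", "F2", "Ki", 1, "uM")               # second target
  )
  orig <- build_original_families(records)
  expect_equal(length(orig), 2)
  expect_setequal(orig[["F1"]]$member_ids, c("a", "b", "c"))
  expect_setequal(orig[["F2"]]$member_ids, "a")
  expect_true(all(vapply(orig, function(f) f$stage, "") == "original"))
  expect_error(build_original_families(act_row("a", "F", "IC50", 1, "uM")[0, ]),
               "no activity records")
})

test_that("filtered families keep only compounds with a qualifying active record", {
  records <- rbind(
    act_row("a", "F1", "IC50", 1, "uM"),
    act_row("b", "F1", "IC50", 500, "uM"),
    act_row("c", "F1", "IC50", 10, "uM", relation = ">"),
    # conflicting records: active by IC50 but inactive by Ki -> any-active
    act_row("d", "F1", "IC50", 5, "uM"),
    act_row("d", "F1", "Ki", 100, "uM"),
    # a family with no active member disappears
    act_row("e", "F2", "Ki", 100, "uM")
  )
  filt <- build_filtered_families(records)
  expect_equal(names(filt), "F1")
  expect_setequal(filt[["F1"]]$member_ids, c("a", "d"))
  expect_equal(filt[["F1"]]$stage, "filtered")
})

test_that("filtered families are subsets of original families", {
  set.seed(11)
  types <- activity_rules()$activity_type
  records <- do.call(rbind, lapply(1:120, function(i) {
    ty <- sample(types, 1)
    unit <- if (ty %in% c("Activity", "Inhibition")) "percent" else "uM"
    act_row(paste0("c", sample(1:40, 1)), paste0("F", sample(1:5, 1)),
            ty, stats::runif(1, 0, 100), unit,
            relation = sample(c("=", "<", ">", "<=", ">="), 1))
  }))
  orig <- build_original_families(records)
  filt <- build_filtered_families(records)
  for (id in names(filt)) {
    expect_true(all(filt[[id]]$member_ids %in% orig[[id]]$member_ids))
  }
})
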