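# Self-contained synthetic libraries with planted scaffold families and
# matching activity tables, so every pipeline stage is testable without any
# external compound database.
#
# Chemistry: each planted scaffold is a fixed ring-system core (12-16 heavy
# atoms) carrying an attachment amine; members are enumerated by appending
# small (1-4 heavy atom) N-substituents. Members of one scaffold therefore
# share most of their circular-fingerprint features (high within-scaffold
# Tanimoto) while different cores share almost none. Substituents are kept
# comparable in size so a scaffold series is homogeneous, like a congeneric
# medicinal-chemistry series.

# The core list is deliberately spread over distinct chemotypes (chosen once
# by maximizing the minimum cross-core fingerprint distance over a larger
# candidate pool) so planted scaffolds are mutually well separated: all
# cross-core Tanimoto values stay near or below ~0.33 while within-scaffold
# values stay above ~0.55.
SCAFFOLD_CORES <- c(
  "CC(C)Oc1ccc(Br)cc1CN",              # isopropoxy-bromophenyl-methylamine
  "O=C(c1ccc(F)cc1)c1ccc(CN)cc1C",     # fluoro-benzophenone-methylamine
  "CC1(C)CCC(=O)N1CCCN",               # gem-dimethyl-lactam-propylamine
  "CC1CCC2CCC(F)CC2C1CCN",             # methyl-fluoro-decalin-ethylamine
  "CCc1cnc(nc1)N1CCC(CC1)CN",          # ethylpyrimidine-piperidine
  "CSc1nc(C)cc(n1)OCC(C)N",            # thiomethyl-pyrimidine ether
  "FC(F)(F)c1ccc(nc1)OCCN",            # trifluoromethyl-pyridyl ether
  "Cc1[nH]c2ccc(F)cc2c1CCN",           # methyl-fluoro-indole-ethylamine
  "Cc1ccc(s1)C(=O)NC(C)CN",            # thiophene-carboxamide
  "O1CCN(CC1)Cc1cc(Cl)cc(c1)CN",       # morpholino-chlorobenzyl
  "CC(C)S(=O)(=O)C1CCC(C)(CC1)CN",     # isopropylsulfonyl-cyclohexane
  "C1CC1Cc1nnc(o1)CCCN"                # cyclopropyl-oxadiazole-propylamine
)

DECOY_CORES <- c(
  "Cc1ccc2cc(ccc2c1Cl)CCN",            # methyl-chloro-naphthalene-ethylamine
  "c1ccc(cc1)C1(CC1)C(=O)NCCN",        # phenyl-cyclopropane-carboxamide
  "CC(C)(C)c1ccc(cc1O)CCN",            # tert-butyl-phenol-ethylamine
  "N#Cc1cc(OC)ccc1CC(C)N",             # methoxy-benzonitrile amine
  "Clc1ccc2c(c1)cc(o2)CCN",            # chloro-benzofuran-ethylamine
  "Cc1ccc(cc1)S(=O)(=O)N1CCC(C1)CN"    # tosyl-pyrrolidine-methylamine
)

N_SUBSTITUENTS <- c("C", "CC", "CCO", "CCC", "C(C)C", "CCN", "CCF", "COC",
                    "CC(C)C", "CCCO", "CCCC", "CC(C)O", "CCCN", "CCOC",
                    "CC(C)N", "CCCF")

#' Synthetic-library configuration
#'
#' Defaults describe a compact separable benchmark: 3 target families, each
#' with 2 planted scaffolds of 8 members, no inactive noise, all eight
#' activity types in play, activity values placed at threshold times
#' `(1 +/- noise)` so both sides of every rule boundary are exercised.
#'
#' @param n_families number of target families.
#' @param scaffolds_per_family planted scaffolds per family (`> 1` plants the
#'   multi-scaffold structure that refinement must recover).
#' @param members_per_scaffold compounds per scaffold (max 16).
#' @param inactive_fraction fraction of each family's members that carry
#'   only inactive records (structurally unrelated decoys).
#' @param activity_types subset of the eight supported activity types.
#' @param noise relative spread of activity values around each threshold.
#' @param n_shared number of compounds per family additionally given an
#'   active record on the next family (cross-family polypharmacology).
#' @param seed integer seed; generation is fully deterministic per seed.
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(n_families = 3, scaffolds_per_family = 2,
                         members_per_scaffold = 8, inactive_fraction = 0,
                         activity_types = ACTIVITY_TYPES, noise = 0.5,
                         n_shared = 0, seed = 1) {
  if (!is_count(n_families) || !is_count(scaffolds_per_family) ||
      !is_count(members_per_scaffold)) {
    stopf("counts must be positive integers")
  }
  if (n_families * scaffolds_per_family > length(SCAFFOLD_CORES)) {
    stopf("at most %d planted scaffolds are available (%d requested)",
          length(SCAFFOLD_CORES), n_families * scaffolds_per_family)
  }
  if (members_per_scaffold > length(N_SUBSTITUENTS)) {
    stopf("at most %d members per scaffold are available",
          length(N_SUBSTITUENTS))
  }
  if (inactive_fraction < 0 || inactive_fraction >= 1) {
    stopf("inactive_fraction must lie in [0, 1)")
  }
  if (!all(activity_types %in% ACTIVITY_TYPES)) {
    stopf("unknown activity types: %s",
          paste(setdiff(activity_types, ACTIVITY_TYPES), collapse = ", "))
  }
  if (noise <= 0 || noise > 1) stopf("noise must lie in (0, 1]")
  if (!is.numeric(n_shared) || n_shared < 0) stopf("n_shared must be >= 0")
  structure(list(
    n_families = as.integer(n_families),
    scaffolds_per_family = as.integer(scaffolds_per_family),
    members_per_scaffold = as.integer(members_per_scaffold),
    inactive_fraction = inactive_fraction,
    activity_types = activity_types,
    noise = noise,
    n_shared = as.integer(n_shared),
    seed = as.integer(seed)
  ), class = "synth_config")
}

# One activity record for a compound against a family, on the requested side
# of the rule threshold.
synth_record <- function(compound_id, family_id, type, side, noise) {
  rules <- activity_rules()
  rule <- rules[rules$activity_type == type, ]
  u <- stats::runif(1, min = 0.2, max = 1)
  upper_rule <- rule$direction %in% c("at_most", "less_than")
  factor_ <- if ((side == "active") == upper_rule) 1 - noise * u else
    1 + noise * u
  value <- rule$threshold_value * factor_
  if (rule$threshold_unit == "percent") {
    unit <- "percent"
  } else if (stats::runif(1) < 0.5) {
    unit <- "uM"
  } else {
    unit <- "nM"
    value <- value * 1000
  }
  data.frame(
    compound_id = compound_id, family_id = family_id,
    target_name = paste0("target-", family_id),
    activity_type = type, relation = "=",
    value = signif(value, 6), unit = unit,
    explicit_label = NA_character_, stringsAsFactors = FALSE
  )
}

#' Generate a synthetic compound library with planted families
#'
#' Emits a SMILES library, an activity table and a ground-truth JSON into
#' `dir`. Active members are scaffold-series compounds with records on the
#' active side of the matching rule threshold; inactive noise members are
#' structurally unrelated decoys with inactive-side records, so original
#' families contain them but filtered families do not. Deterministic per
#' `config$seed`.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `molecules` (data.frame), `activities`
#'   (data.frame), `truth` (list) and the three file `paths`.
#' @export
generate_library <- function(config = synth_config(), dir = tempfile("synth")) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- with_seed(config$seed, generate_library_impl(config))
  paths <- list(
    molecules = file.path(dir, "lib.smi"),
    activities = file.path(dir, "activities.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_molecules(res$molecules, paths$molecules)
  write_activity_table(res$activities, paths$activities)
  jsonlite::write_json(res$truth, paths$truth, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(res, list(paths = paths)))
}

generate_library_impl <- function(config) {
  mols <- list(); acts <- list(); truth_cmp <- list()
  cid <- 0L
  type_cycle <- config$activity_types
  tix <- 0L
  decoy_ix <- 0L
  n_active_per_family <- config$scaffolds_per_family * config$members_per_scaffold
  n_inactive <- if (config$inactive_fraction > 0) {
    round(config$inactive_fraction / (1 - config$inactive_fraction) *
          n_active_per_family)
  } else 0L

  for (fam in seq_len(config$n_families)) {
    fam_id <- sprintf("FAM%02d", fam)
    fam_actives <- character(0)
    for (sc in seq_len(config$scaffolds_per_family)) {
      core <- SCAFFOLD_CORES[(fam - 1) * config$scaffolds_per_family + sc]
      for (m in seq_len(config$members_per_scaffold)) {
        cid <- cid + 1L
        id <- sprintf("CPD%04d", cid)
        smi <- paste0(core, N_SUBSTITUENTS[m])
        tix <- tix + 1L
        type <- type_cycle[(tix - 1L) %% length(type_cycle) + 1L]
        mols[[length(mols) + 1]] <- data.frame(
          id = id, smiles = smi, stringsAsFactors = FALSE)
        acts[[length(acts) + 1]] <- synth_record(id, fam_id, type, "active",
                                                 config$noise)
        truth_cmp[[length(truth_cmp) + 1]] <- list(
          id = id, family_id = fam_id, scaffold = sc, role = "active")
        fam_actives <- c(fam_actives, id)
      }
    }
    for (k in seq_len(n_inactive)) {
      cid <- cid + 1L
      decoy_ix <- decoy_ix + 1L
      id <- sprintf("CPD%04d", cid)
      core <- DECOY_CORES[(decoy_ix - 1L) %% length(DECOY_CORES) + 1L]
      sub <- N_SUBSTITUENTS[((decoy_ix - 1L) %/% length(DECOY_CORES)) %%
                              length(N_SUBSTITUENTS) + 1L]
      tix <- tix + 1L
      type <- type_cycle[(tix - 1L) %% length(type_cycle) + 1L]
      mols[[length(mols) + 1]] <- data.frame(
        id = id, smiles = paste0(core, sub), stringsAsFactors = FALSE)
      acts[[length(acts) + 1]] <- synth_record(id, fam_id, type, "inactive",
                                               config$noise)
      truth_cmp[[length(truth_cmp) + 1]] <- list(
        id = id, family_id = fam_id, scaffold = NA, role = "inactive")
    }
    if (config$n_shared > 0 && config$n_families > 1) {
      other <- sprintf("FAM%02d", fam %% config$n_families + 1L)
      for (id in utils::head(fam_actives, config$n_shared)) {
        tix <- tix + 1L
        type <- type_cycle[(tix - 1L) %% length(type_cycle) + 1L]
        acts[[length(acts) + 1]] <- synth_record(id, other, type, "active",
                                                 config$noise)
      }
    }
  }
  molecules <- do.call(rbind, mols)
  molecules$name <- NA_character_
  molecules$tags <- NA_character_
  activities <- do.call(rbind, acts)
  truth <- list(
    meta = list(tool = "targetfishR",
                version = as.character(utils::packageVersion("targetfishR")),
                seed = config$seed,
                config = unclass(config)),
    compounds = truth_cmp,
    expected = list(
      n_molecules = nrow(molecules),
      n_original_families = config$n_families,
      n_filtered_families = config$n_families,
      n_refined_families = config$n_families * config$scaffolds_per_family
    )
  )
  list(molecules = molecules, activities = activities, truth = truth)
}

#' Block-structured similarity fixture for clustering tests
#'
#' Builds a symmetric matrix with unit diagonal from planted blocks: within-
#' block entries centred on each block's `within` value, between-block
#' entries centred on the mean of the two blocks' `between` values, all
#' jittered uniformly by `+/- jitter` and clamped to `[0, 1]`.
#'
#' @param blocks list of `c(size, within, between)` triples.
#' @param seed integer seed for the jitter.
#' @param jitter half-width of the uniform jitter (default 0.02).
#' @return list with `sim` (the matrix) and `labels` (named planted block
#'   labels).
#' @export
generate_similarity_fixture <- function(blocks, seed = 1, jitter = 0.02) {
  blks <- lapply(blocks, function(b) {
    if (length(b) != 3) stopf("each block must be c(size, within, between)")
    if (b[1] < 1) stopf("block sizes must be >= 1")
    if (b[3] < 0 || b[3] >= b[2] || b[2] > 1) {
      stopf("blocks require 0 <= between < within <= 1")
    }
    b
  })
  sizes <- vapply(blks, `[`, numeric(1), 1)
  n <- sum(sizes)
  labels <- rep(seq_along(blks), sizes)
  ids <- sprintf("B%dI%d", labels, unlist(lapply(sizes, seq_len)))
  names(labels) <- ids
  with_seed(seed, {
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        base <- if (labels[i] == labels[j]) blks[[labels[i]]][2] else
          mean(c(blks[[labels[i]]][3], blks[[labels[j]]][3]))
        v <- base + stats::runif(1, -jitter, jitter)
        m[i, j] <- m[j, i] <- min(1, max(0, v))
      }
    }
    diag(m) <- 1
    list(sim = m, labels = labels)
  })
}
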