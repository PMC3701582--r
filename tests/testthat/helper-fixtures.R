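# Shared fixtures, built in code at test time.

# A fingerprint object from an explicit feature set (bypasses chemistry).
make_fp <- function(features, id = "x", radius = 2L) {
  structure(list(compound_id = id, features = sort(unique(as.numeric(features))),
                 radius = as.integer(radius)),
            class = "fingerprint")
}

# Random sparse fingerprints over a feature universe.
random_fps <- function(n, universe = 400, size_range = c(10, 60),
                       prefix = "R") {
  fps <- lapply(seq_len(n), function(i) {
    k <- sample(size_range[1]:size_range[2], 1)
    make_fp(sample.int(universe, k), id = paste0(prefix, i))
  })
  names(fps) <- vapply(fps, function(f) f$compound_id, "")
  fps
}

# Independent brute-force PR-score oracle: its own set algebra and kernel
# evaluation, sharing no code with the package path it checks.
oracle_pr_score <- function(query_features, member_feature_list, h) {
  ps <- numeric(length(member_feature_list))
  for (j in seq_along(member_feature_list)) {
    fb <- member_feature_list[[j]]
    inter <- 0
    for (v in query_features) if (v %in% fb) inter <- inter + 1
    uni <- length(query_features) + length(fb) - inter
    t_ab <- inter / uni
    ps[j] <- exp(-(t_ab * t_ab) / (2 * h * h))
  }
  sum(ps) / length(ps)
}

# Strip profile_matrix attributes for plain matrix comparison.
as_plain_matrix <- function(pm) {
  m <- unclass(pm)
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  m
}

# One activity record row.
act_row <- function(compound_id, family_id, type, value, unit,
                    relation = "=", label = NA_character_,
                    target_name = NA_character_) {
  data.frame(compound_id = compound_id, family_id = family_id,
             target_name = target_name, activity_type = type,
             relation = relation, value = value, unit = unit,
             explicit_label = label, stringsAsFactors = FALSE)
}

# Small fixed molecule table (parseable, diverse).
tiny_molecules <- function() {
  data.frame(
    id = c("aspirin", "ibuprofen", "caffeine", "ethanol"),
    smiles = c("CC(=O)Oc1ccccc1C(=O)O",
               "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
               "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
               "CCO"),
    name = NA_character_, tags = NA_character_,
    stringsAsFactors = FALSE
  )
}

# Adjusted Rand index between two label vectors aligned by name.
ari <- function(truth, labels) {
  common <- intersect(names(truth), names(labels))
  mclust::adjustedRandIndex(unlist(truth[common]), unlist(labels[common]))
}

# Planted two-scaffold library -> named list of everything downstream tests
# need. Cached per options string to keep the suite fast.
synth_env <- new.env()
synth_pipeline <- function(config = synth_config(), radius = 2) {
  key <- paste(unlist(unclass(config)), radius, collapse = "_")
  if (!is.null(synth_env[[key]])) return(synth_env[[key]])
  dir <- tempfile("synthlib")
  lib <- generate_library(config, dir)
  mols <- read_molecules(lib$paths$molecules)
  records <- read_activity_table(lib$paths$activities)
  fps <- compute_fingerprints(mols, radius = radius)
  out <- list(dir = dir, lib = lib, molecules = mols, records = records,
              fps = fps)
  synth_env[[key]] <- out
  out
}

# Planted truth as named label vectors.
truth_labels <- function(lib, what = c("scaffold", "family")) {
  what <- match.arg(what)
  cmp <- lib$truth$compounds
  labs <- vapply(cmp, function(x) {
    if (what == "scaffold") {
      if (is.null(x$scaffold) || is.na(x$scaffold)) "noise"
      else paste0(x$family_id, ".", x$scaffold)
    } else x$family_id
  }, "")
  names(labs) <- vapply(cmp, function(x) x$id, "")
  labs
}
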