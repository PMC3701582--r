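# On-disk artifacts: molecule libraries, activity tables, family definitions,
# score matrices.

ACTIVITY_TYPES <- c("IC50", "Ki", "Kd", "EC50", "ED50",
                    "Potency", "Activity", "Inhibition")
RELATIONS <- c("=", "<", "<=", ">", ">=", "unspecified")
CONC_UNITS <- c(nM = 1, uM = 1e3, mM = 1e6, M = 1e9)
ACTIVITY_COLUMNS <- c("compound_id", "family_id", "target_name",
                      "activity_type", "relation", "value", "unit",
                      "explicit_label")

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to its OpenBabel canonical form. Unparseable strings
#' yield `NA` rather than an error, so callers can report failures record by
#' record.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", source = trimws(s)),
      error = function(e) ""
    )
    out <- trimws(sub("[ \t].*$", "", out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Read a molecule library
#'
#' Reads a SMILES (`.smi`, one `SMILES<whitespace>id` record per line) or SDF
#' (V2000) file into a molecule table. Every record is canonicalized through
#' OpenBabel; records that fail to parse are collected in a parse report
#' (attribute `"parse_report"`) instead of being silently dropped.
#'
#' @param path file path.
#' @param format `"smiles"` or `"sdf"`; default guessed from the extension.
#' @return a `data.frame` with columns `id`, `smiles` (canonical), `name`,
#'   `tags`, carrying a `parse_report` attribute (data.frame with `record`,
#'   `input`, `reason`).
#' @export
read_molecules <- function(path, format = c("smiles", "sdf")) {
  if (!file.exists(path)) stopf("molecule file not found: %s", path)
  if (missing(format)) {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smiles"
  }
  format <- match.arg(format)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines))
    idx <- which(keep)
    toks <- strsplit(trimws(lines[keep]), "[ \t]+")
    raw_smiles <- vapply(toks, `[`, "", 1)
    ids <- vapply(seq_along(toks), function(i) {
      if (length(toks[[i]]) >= 2) toks[[i]][2] else sprintf("M%04d", i)
    }, "")
    names_ <- vapply(toks, function(tk) {
      if (length(tk) >= 3) paste(tk[-(1:2)], collapse = " ") else NA_character_
    }, "")
  } else {
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
    n <- length(sdfset)
    if (n == 0) stopf("no records in SDF file: %s", path)
    ok <- ChemmineR::validSDF(sdfset)
    ids <- ChemmineR::sdfid(sdfset)
    ids[!nzchar(ids) | is.na(ids)] <- sprintf("M%04d", which(!nzchar(ids) | is.na(ids)))
    raw_smiles <- rep(NA_character_, n)
    for (i in which(ok)) {
      smi <- tryCatch(
        trimws(sub("[ \t].*$", "", ChemmineOB::convertFormat(
          "SDF", "CAN",
          source = paste(c(ChemmineR::sdf2str(sdfset[[i]]), "$$$$"), collapse = "\n")))),
        error = function(e) NA_character_
      )
      raw_smiles[i] <- if (!is.na(smi) && nzchar(smi)) smi else NA_character_
    }
    idx <- seq_len(n)
    names_ <- rep(NA_character_, n)
  }
  canon <- if (format == "smiles") canonical_smiles(raw_smiles) else raw_smiles
  failed <- is.na(canon)
  report <- data.frame(
    record = idx[failed],
    input = ifelse(is.na(raw_smiles[failed]), "<unparseable record>",
                   raw_smiles[failed]),
    reason = rep("SMILES/SDF record failed to parse", sum(failed)),
    stringsAsFactors = FALSE
  )
  mols <- data.frame(
    id = ids[!failed],
    smiles = canon[!failed],
    name = names_[!failed],
    tags = rep(NA_character_, sum(!failed)),
    stringsAsFactors = FALSE
  )
  if (nrow(mols) == 0) stopf("no parseable molecule records in %s", path)
  if (anyDuplicated(mols$id)) {
    stopf("duplicate molecule ids: %s",
          paste(unique(mols$id[duplicated(mols$id)]), collapse = ", "))
  }
  rownames(mols) <- NULL
  attr(mols, "parse_report") <- report
  mols
}

#' Parse report of a molecule load
#'
#' @param molecules value returned by [read_molecules()].
#' @return data.frame of failed records (possibly empty).
#' @export
parse_report <- function(molecules) {
  attr(molecules, "parse_report") %||%
    data.frame(record = integer(), input = character(), reason = character())
}

#' Write a molecule table as a .smi file
#'
#' @param molecules data.frame with `id` and `smiles` columns.
#' @param path output path.
#' @export
write_molecules <- function(molecules, path) {
  writeLines(paste(molecules$smiles, molecules$id), path)
  invisible(path)
}

#' Read a bioactivity table
#'
#' Reads a CSV/TSV export in the ChEMBL-like schema (`compound_id`,
#' `family_id`, `activity_type`, `relation`, `value`, `unit`, optional
#' `target_name` and `explicit_label`). The delimiter is auto-detected
#' between comma and tab. Rows with an activity type outside the eight
#' supported categories, an unknown relation/unit, a non-numeric or negative
#' value, or a unit inconsistent with the activity type are excluded and
#' listed in the `"excluded"` attribute.
#'
#' @param path file path.
#' @return data.frame of typed activity records with attribute `"excluded"`.
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) stopf("activity table not found: %s", path)
  header <- readLines(path, n = 1)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  required <- c("compound_id", "family_id", "activity_type",
                "relation", "value", "unit")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stopf("activity table is missing required columns: %s",
          paste(missing_cols, collapse = ", "))
  }
  if (!"target_name" %in% names(raw)) raw$target_name <- NA_character_
  if (!"explicit_label" %in% names(raw)) raw$explicit_label <- NA_character_
  raw <- raw[ACTIVITY_COLUMNS]
  raw$relation[is.na(raw$relation) | !nzchar(trimws(raw$relation))] <- "unspecified"
  raw$relation <- trimws(raw$relation)
  raw$explicit_label[!nzchar(trimws(raw$explicit_label %||% ""))] <- NA_character_
  value_num <- suppressWarnings(as.numeric(raw$value))

  reasons <- character(nrow(raw))
  bad_type <- !(raw$activity_type %in% ACTIVITY_TYPES)
  reasons[bad_type] <- paste0("unsupported activity_type: ",
                              raw$activity_type[bad_type])
  bad_rel <- !(raw$relation %in% RELATIONS) & !nzchar(reasons)
  reasons[bad_rel] <- paste0("unknown relation: ", raw$relation[bad_rel])
  bad_val <- (is.na(value_num) | value_num < 0) & !nzchar(reasons)
  reasons[bad_val] <- paste0("unparseable or negative value: ",
                             raw$value[bad_val])
  bad_unit <- !(raw$unit %in% c(names(CONC_UNITS), "percent")) & !nzchar(reasons)
  reasons[bad_unit] <- paste0("unknown unit: ", raw$unit[bad_unit])
  percent_type <- raw$activity_type %in% c("Activity", "Inhibition")
  mismatch <- !nzchar(reasons) &
    ((percent_type & raw$unit != "percent") |
     (!percent_type & !(raw$unit %in% names(CONC_UNITS))))
  reasons[mismatch] <- "unit inconsistent with activity_type"
  bad_label <- !nzchar(reasons) & !is.na(raw$explicit_label) &
    !(raw$explicit_label %in% c("active", "inactive"))
  reasons[bad_label] <- paste0("unknown explicit_label: ",
                               raw$explicit_label[bad_label])

  ok <- !nzchar(reasons)
  records <- raw[ok, , drop = FALSE]
  records$value <- value_num[ok]
  rownames(records) <- NULL
  excluded <- data.frame(row = which(!ok), reason = reasons[!ok],
                         stringsAsFactors = FALSE)
  attr(records, "excluded") <- excluded
  records
}

#' Write an activity table
#'
#' @param records activity record data.frame.
#' @param path output path (CSV).
#' @export
write_activity_table <- function(records, path) {
  utils::write.csv(records[ACTIVITY_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

# --- families ---------------------------------------------------------------

#' Construct a compound family
#'
#' A family is a named set of compound ids at one of three curation stages:
#' `original` (all compounds with any record against the target), `filtered`
#' (compounds with at least one qualifying active record) or `refined`
#' (a scaffold-coherent subset of a filtered family).
#'
#' @param family_id family identifier.
#' @param member_ids non-empty character vector of compound ids.
#' @param stage one of `"original"`, `"filtered"`, `"refined"`.
#' @param target_name optional target description.
#' @param parent_id for refined families, the id of the parent filtered family.
#' @return an object of class `"family"`.
#' @export
new_family <- function(family_id, member_ids,
                       stage = c("original", "filtered", "refined"),
                       target_name = NA_character_, parent_id = NA_character_) {
  stage <- match.arg(stage)
  member_ids <- unique(as.character(member_ids))
  if (length(member_ids) == 0) stopf("family '%s' has no members", family_id)
  if (stage == "refined" && is.na(parent_id)) {
    stopf("refined family '%s' must name its parent filtered family", family_id)
  }
  structure(
    list(family_id = as.character(family_id),
         target_name = as.character(target_name),
         stage = stage, member_ids = member_ids,
         parent_id = as.character(parent_id)),
    class = "family"
  )
}

#' @export
print.family <- function(x, ...) {
  cat(sprintf("<family %s [%s]%s: %d members>\n", x$family_id, x$stage,
              if (!is.na(x$parent_id)) paste0(" parent=", x$parent_id) else "",
              length(x$member_ids)))
  invisible(x)
}

#' Bundle families into a family set
#'
#' @param families list of `"family"` objects.
#' @return named list of class `"family_set"` keyed by family id.
#' @export
family_set <- function(families) {
  if (is.null(families) || length(families) == 0) stopf("empty family set")
  ids <- vapply(families, function(f) f$family_id, "")
  if (anyDuplicated(ids)) {
    stopf("duplicate family ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(families) <- ids
  structure(families, class = "family_set")
}

#' @export
print.family_set <- function(x, ...) {
  stages <- table(vapply(x, function(f) f$stage, ""))
  cat(sprintf("<family_set: %d families (%s)>\n", length(x),
              paste(names(stages), stages, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
`[.family_set` <- function(x, i) {
  family_set(unclass(x)[i])
}

#' Write family definitions to JSON
#'
#' The JSON carries the three-stage lineage explicitly: every family stores
#' its stage and, for refined families, the id of the parent filtered family.
#'
#' @param families a `"family_set"` or list of families.
#' @param path output path.
#' @param meta optional named list stored under `meta` (e.g. seed, params).
#' @export
write_families <- function(families, path, meta = list()) {
  if (!inherits(families, "family_set")) families <- family_set(families)
  for (f in families) {
    if (length(f$member_ids) == 0) stopf("family '%s' has no members", f$family_id)
  }
  payload <- list(
    meta = c(list(tool = "targetfishR",
                  version = as.character(utils::packageVersion("targetfishR"))),
             meta),
    families = lapply(unname(families), function(f) {
      out <- list(family_id = f$family_id, stage = f$stage,
                  member_ids = as.list(sort(f$member_ids)))
      if (!is.na(f$target_name)) out$target_name <- f$target_name
      if (!is.na(f$parent_id)) out$parent_id <- f$parent_id
      out
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read family definitions from JSON
#'
#' @param path path written by [write_families()].
#' @return a `"family_set"`; the file's `meta` block is attached as an
#'   attribute.
#' @export
read_families <- function(path) {
  if (!file.exists(path)) stopf("family file not found: %s", path)
  payload <- jsonlite::read_json(path)
  fams <- payload$families %||% stopf("malformed family file: %s", path)
  if (length(fams) == 0) stopf("family file contains no families: %s", path)
  out <- family_set(lapply(fams, function(f) {
    new_family(f$family_id,
               unlist(f$member_ids, use.names = FALSE),
               stage = f$stage,
               target_name = f$target_name %||% NA_character_,
               parent_id = f$parent_id %||% NA_character_)
  }))
  attr(out, "meta") <- payload$meta
  out
}

# --- score matrices ---------------------------------------------------------

#' Write a PR-score matrix as CSV
#'
#' Rows are families, columns compounds, cells PR-scores.
#'
#' @param scores numeric matrix with family ids as rownames and compound ids
#'   as colnames.
#' @param path output path.
#' @export
write_score_matrix <- function(scores, path) {
  df <- data.frame(family_id = rownames(scores), scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a PR-score matrix written by [write_score_matrix()]
#'
#' @param path CSV path.
#' @return numeric matrix (families x compounds).
#' @export
read_score_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}
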