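# Circular fingerprints and Tanimoto similarity: the molecular representation
# under every downstream score.
#
# Feature sets are sparse hashed identifiers of atom-centred substructure
# environments (Morgan/ECFP scheme): at radius r every atom contributes the
# identifiers of its environments of radius 0..r. Radius 2 corresponds to
# ECFP4-style diameter-4 environments. Molecules are canonicalized before the
# graph is built, so the feature set is invariant to the atom order of the
# input SMILES.

DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                     P = 3, S = 2, Cl = 1, Br = 1, I = 1)
ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                   S = 16, Cl = 17, Br = 35, I = 53)

# MDL charge codes (atom block column 5): 1..7 -> +3,+2,+1,radical,-1,-2,-3
MDL_CHARGE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                `6` = -2, `7` = -3)

# Extract (elements, charges, bond table) from one ChemmineR SDF object.
sdf_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  elems <- sub("_.*$", "", rownames(ab))
  chg_code <- if ("C5" %in% colnames(ab)) as.character(ab[, "C5"]) else
    rep("0", nrow(ab))
  charges <- unname(MDL_CHARGE[chg_code])
  charges[is.na(charges)] <- 0
  bb <- ChemmineR::bondblock(sdf)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    matrix(numeric(0), ncol = 3)
  } else {
    unname(cbind(bb[, 1], bb[, 2], bb[, 3]))
  }
  list(elements = elems, charges = charges, bonds = bonds)
}

morgan_features <- function(graph, radius) {
  n <- length(graph$elements)
  if (n == 0) stopf("molecule has no atoms")
  bonds <- graph$bonds
  deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
  bond_sum <- numeric(n)
  nbrs <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds[k, 1]; b <- bonds[k, 2]; o <- bonds[k, 3]
      bond_sum[a] <- bond_sum[a] + o
      bond_sum[b] <- bond_sum[b] + o
      nbrs[[a]] <- rbind(nbrs[[a]], c(o, b))
      nbrs[[b]] <- rbind(nbrs[[b]], c(o, a))
    }
  }
  elems <- graph$elements
  zval <- unname(ATOMIC_NUMBER[elems])
  zval[is.na(zval)] <- 0
  defval <- unname(DEFAULT_VALENCE[elems])
  defval[is.na(defval)] <- 0
  hcount <- pmax(0, defval + graph$charges - bond_sum)
  ids <- vapply(seq_len(n), function(i) {
    hash_ints(c(zval[i], deg[i], bond_sum[i], graph$charges[i] + 8, hcount[i]))
  }, numeric(1))
  feats <- ids
  if (radius > 0) {
    for (level in seq_len(radius)) {
      new_ids <- vapply(seq_len(n), function(i) {
        nb <- nbrs[[i]]
        env <- if (is.null(nb)) numeric(0) else {
          pairs <- cbind(nb[, 1], ids[nb[, 2]])
          ord <- order(pairs[, 1], pairs[, 2])
          as.vector(t(pairs[ord, , drop = FALSE]))
        }
        hash_ints(c(level, ids[i], env))
      }, numeric(1))
      ids <- new_ids
      feats <- c(feats, new_ids)
    }
  }
  sort(unique(feats))
}

#' Compute a circular fingerprint
#'
#' @param smiles a single SMILES string (canonicalized internally).
#' @param radius neighbourhood radius; the default 2 matches ECFP4-style
#'   diameter-4 environments.
#' @param compound_id identifier stored with the fingerprint.
#' @return an object of class `"fingerprint"` with fields `compound_id`,
#'   `features` (sorted integer identifiers) and `radius`.
#' @examples
#' \dontrun{
#' fp <- compute_fingerprint("CCO", compound_id = "ethanol")
#' }
#' @export
compute_fingerprint <- function(smiles, radius = 2, compound_id = "query") {
  if (!is_count(radius + 1)) stopf("radius must be a non-negative integer")
  canon <- canonical_smiles(smiles)
  if (is.na(canon)) stopf("unparseable SMILES: %s", smiles)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(canon))[[1]]
  structure(
    list(compound_id = as.character(compound_id),
         features = morgan_features(sdf_graph(sdf), radius),
         radius = as.integer(radius)),
    class = "fingerprint"
  )
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s: %d features, radius %d%s>\n", x$compound_id,
              length(x$features), x$radius,
              if (!is.null(attr(x, "nbits")))
                sprintf(", folded to %d bits", attr(x, "nbits")) else ""))
  invisible(x)
}

#' Compute fingerprints for a molecule table
#'
#' @param molecules data.frame from [read_molecules()] (columns `id`,
#'   `smiles`), or a character vector of SMILES named by id.
#' @param radius neighbourhood radius.
#' @return named list of `"fingerprint"` objects keyed by compound id.
#' @export
compute_fingerprints <- function(molecules, radius = 2) {
  if (is.character(molecules)) {
    ids <- names(molecules) %||% sprintf("M%04d", seq_along(molecules))
    smiles <- unname(molecules)
  } else {
    ids <- molecules$id
    smiles <- molecules$smiles
  }
  if (length(smiles) == 0) stopf("no molecules supplied")
  canon <- canonical_smiles(smiles)
  bad <- which(is.na(canon))
  if (length(bad) > 0) {
    stopf("unparseable SMILES for: %s", paste(ids[bad], collapse = ", "))
  }
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(canon))
  fps <- lapply(seq_along(ids), function(i) {
    structure(
      list(compound_id = ids[i],
           features = morgan_features(sdf_graph(sdfset[[i]]), radius),
           radius = as.integer(radius)),
      class = "fingerprint"
    )
  })
  names(fps) <- ids
  fps
}

#' Fold a sparse fingerprint to a fixed bit length
#'
#' Maps every feature identifier to `id mod nbits`, for interoperability with
#' fixed-length bit-vector tools. Folding can merge distinct features
#' (collisions), so Tanimoto values on folded fingerprints may differ from the
#' sparse-set values.
#'
#' @param fp a `"fingerprint"`.
#' @param nbits number of bits (e.g. 1024 or 2048).
#' @return folded `"fingerprint"` whose features are bit positions.
#' @export
fold_fingerprint <- function(fp, nbits = 1024) {
  stopifnot(inherits(fp, "fingerprint"), is_count(nbits))
  out <- fp
  out$features <- sort(unique(fp$features %% nbits))
  attr(out, "nbits") <- as.integer(nbits)
  out
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over the feature sets; 1 for identical
#' sets, 0 for disjoint ones.
#'
#' @param a,b `"fingerprint"` objects computed at the same radius.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$radius != b$radius) {
    stopf("fingerprints computed at different radii (%d vs %d)",
          a$radius, b$radius)
  }
  tanimoto_sets(a$features, b$features)
}

tanimoto_sets <- function(fa, fb) {
  na <- length(fa); nb <- length(fb)
  if (na == 0 && nb == 0) stopf("both feature sets are empty")
  ni <- length(intersect(fa, fb))
  ni / (na + nb - ni)
}

#' All-against-all Tanimoto similarity matrix
#'
#' @param x a named list of `"fingerprint"` objects, or a molecule table
#'   (the fingerprints are then computed at `radius`).
#' @param radius neighbourhood radius used when `x` is a molecule table.
#' @return symmetric numeric matrix with unit diagonal, compound ids as
#'   dimnames.
#' @export
similarity_matrix <- function(x, radius = 2) {
  fps <- if (is.data.frame(x) || is.character(x)) {
    compute_fingerprints(x, radius)
  } else x
  if (length(fps) == 0) stopf("no fingerprints supplied")
  radii <- unique(vapply(fps, function(f) f$radius, integer(1)))
  if (length(radii) != 1) stopf("fingerprints computed at mixed radii")
  ids <- unname(vapply(fps, function(f) f$compound_id, ""))
  n <- length(fps)
  m <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- tanimoto_sets(fps[[i]]$features,
                                            fps[[j]]$features)
      }
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}
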