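## Structure-activity machinery: ECFP4-style hashed circular fingerprints
## (radius 2, i.e. diameter 4), Tanimoto similarity, average-linkage
## sub-cluster extraction, and nomination of non-BSA cluster members as new
## BSA candidates. SMILES parsing and desalting ride on ChemmineR/ChemmineOB;
## the circular-fingerprint construction itself is implemented here.

#' Circular fingerprint of a molecule
#'
#' Hashed extended-connectivity fingerprint of diameter 4 (radius 2): atom
#' environments are iteratively refined from an initial invariant (element,
#' heavy-atom degree, total bond order) by hashing the sorted
#' (bond-order, neighbor-identifier) list, and every identifier from radius 0
#' to `radius` is folded into `n_bits` bits. The construction is independent
#' of atom input order, so equivalent spellings of the same structure give the
#' same fingerprint. Salts are stripped first: only the largest covalent
#' fragment (most atoms, ties by bond count) is fingerprinted.
#'
#' @param smiles A single SMILES string.
#' @param drug_id Optional id carried on the fingerprint (used in error
#'   messages and by [similarity_provider()]).
#' @param n_bits Fingerprint width (default 2048).
#' @param radius Neighborhood radius (default 2, the "4" in ECFP4 being the
#'   diameter).
#' @return An object of class `fingerprint`: list with `drug_id`, `bits`
#'   (sorted 0-based bit indices), `n_bits`, `radius`.
#' @examples
#' \donttest{
#' fp <- fingerprint("CCO", "ethanol")
#' }
#' @export
fingerprint <- function(smiles, drug_id = NULL, n_bits = 2048L, radius = 2L) {
  stopifnot(is.character(smiles), length(smiles) == 1L, n_bits >= 2, radius >= 0)
  mol <- parse_smiles(smiles, drug_id)
  mol <- largest_fragment(mol)
  ids <- circular_identifiers(mol, radius)
  structure(
    list(drug_id = if (is.null(drug_id)) NA_character_ else normalize_id(drug_id),
         bits = sort(unique(ids %% n_bits)),
         n_bits = as.integer(n_bits), radius = as.integer(radius)),
    class = "fingerprint"
  )
}

#' Fingerprints for a set of structures
#'
#' @param smiles Named character vector of SMILES (names are drug ids) or the
#'   path to a `.smi` file with lines `SMILES<tab>drug_id`.
#' @param n_bits,radius See [fingerprint()].
#' @return Named list of `fingerprint` objects.
#' @export
fingerprint_set <- function(smiles, n_bits = 2048L, radius = 2L) {
  if (length(smiles) == 1L && is.null(names(smiles)) && file.exists(smiles)) {
    smiles <- read_smi(smiles)
  }
  if (is.null(names(smiles)) || any(!nzchar(names(smiles)))) {
    stop("fingerprint_set() needs SMILES named by drug id", call. = FALSE)
  }
  ids <- normalize_id(names(smiles))
  fps <- lapply(seq_along(smiles), function(i) fingerprint(smiles[[i]], ids[i], n_bits, radius))
  names(fps) <- ids
  fps
}

#' Read a SMILES file
#'
#' One record per line, `SMILES<tab>drug_id` (the `.smi` convention;
#' whitespace-separated also accepted).
#'
#' @param path Path to the file.
#' @return Named character vector of SMILES.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop(basename(path), ": line(s) without an id: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  out <- vapply(parts, `[[`, character(1), 1L)
  names(out) <- normalize_id(vapply(parts, `[[`, character(1), 2L))
  out
}

## --- molecule graph handling (ChemmineR/ChemmineOB backed) -----------------

## SMILES -> molecular graph through OpenBabel (ChemmineOB). The returned
## V2000 block is read directly: ChemmineR's SDF reader mishandles bond-less
## (single-heavy-atom) molecules, and the fixed-width block is unambiguous.
parse_smiles <- function(smiles, drug_id = NULL) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMILES parsing requires the ChemmineOB package", call. = FALSE)
  }
  who <- if (is.null(drug_id)) smiles else drug_id
  sdf <- tryCatch(
    suppressWarnings(suppressMessages(
      ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"))
    )),
    error = function(e) ""
  )
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stop("unparseable SMILES for ", who, call. = FALSE)
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1L) stop("unparseable SMILES for ", who, call. = FALSE)
  atom_lines <- lines[4L + seq_len(n_atoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  if (is.na(n_bonds) || n_bonds == 0L) {
    bonds <- matrix(numeric(0), ncol = 3)
  } else {
    bond_lines <- lines[4L + n_atoms + seq_len(n_bonds)]
    bonds <- cbind(
      as.numeric(substr(bond_lines, 1, 3)),
      as.numeric(substr(bond_lines, 4, 6)),
      as.numeric(substr(bond_lines, 7, 9))
    )
  }
  list(elements = elements, bonds = bonds)
}

## Keep the largest covalent fragment (desalting): most atoms, ties broken by
## bond count then by lowest original atom index (deterministic).
largest_fragment <- function(mol) {
  n <- length(mol$elements)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) {
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  nbonds <- vapply(as.numeric(names(sizes)), function(cc) {
    if (!nrow(mol$bonds)) 0 else sum(comp[mol$bonds[, 1]] == cc)
  }, numeric(1))
  best <- as.numeric(names(sizes))[order(-as.numeric(sizes), -nbonds,
                                         as.numeric(names(sizes)))][1]
  keep <- which(comp == best)
  remap <- match(seq_len(n), keep)
  bonds <- mol$bonds[mol$bonds[, 1] %in% keep & mol$bonds[, 2] %in% keep, , drop = FALSE]
  if (nrow(bonds)) {
    bonds[, 1] <- remap[bonds[, 1]]
    bonds[, 2] <- remap[bonds[, 2]]
  }
  list(elements = mol$elements[keep], bonds = bonds)
}

## Iteratively refined atom-environment identifiers, radius 0..r. Hashing uses
## only sorted neighbor lists, so identifiers are invariant to atom order.
circular_identifiers <- function(mol, radius) {
  n <- length(mol$elements)
  nb <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]; o <- mol$bonds[b, 3]
      nb[[i]] <- rbind(nb[[i]], c(j, o))
      nb[[j]] <- rbind(nb[[j]], c(i, o))
    }
  }
  degree <- vapply(nb, function(x) if (is.null(x)) 0 else nrow(x), numeric(1))
  valence <- vapply(nb, function(x) if (is.null(x)) 0 else sum(x[, 2]), numeric(1))
  ids <- vapply(seq_len(n), function(i) {
    hash_values(c(0, element_number(mol$elements[i]), degree[i], valence[i]))
  }, numeric(1))
  all_ids <- ids
  r <- 0L
  while (r < radius) {
    r <- r + 1L
    new_ids <- vapply(seq_len(n), function(i) {
      if (is.null(nb[[i]])) return(hash_values(c(r, ids[i])))
      env <- cbind(nb[[i]][, 2], ids[nb[[i]][, 1]])
      env <- env[order(env[, 1], env[, 2]), , drop = FALSE]
      hash_values(c(r, ids[i], t(env)))
    }, numeric(1))
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  all_ids
}

## 31-bit multiplicative hash over a numeric vector; double precision holds the
## intermediate products exactly because the modulus keeps values < 2^31.
hash_values <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

.element_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14, P = 15,
  S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26, Cu = 29, Zn = 30, As = 33,
  Se = 34, Br = 35, I = 53
)

element_number <- function(sym) {
  z <- .element_numbers[sym]
  if (is.na(z)) z <- 200 + sum(utf8ToInt(sym))  # rare elements: stable surrogate
  unname(z)
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("fingerprint %s: %d/%d bits set (radius %d)\n",
              x$drug_id, length(x$bits), x$n_bits, x$radius))
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' Intersection over union of the set bits, in `[0, 1]`.
#'
#' @param a,b `fingerprint` objects with equal `n_bits`.
#' @return Numeric similarity.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$n_bits != b$n_bits) {
    stop("fingerprints have different widths: ", a$n_bits, " vs ", b$n_bits,
         call. = FALSE)
  }
  u <- length(union(a$bits, b$bits))
  if (u == 0L) return(0)
  length(intersect(a$bits, b$bits)) / u
}

#' Cluster compounds by structural similarity
#'
#' Average-linkage agglomerative clustering on the Tanimoto distance
#' (1 - similarity), cut flat at `cutoff`. Compounds are processed in
#' drug-id order so the partition is deterministic.
#'
#' @param fingerprints List of `fingerprint` objects (named or carrying
#'   `drug_id`s).
#' @param cutoff Flat-cut distance in `[0, 1]` (default 0.6).
#' @return An object of class `cluster_set`: list with `members` (data frame
#'   `drug_id`, `cluster_id`), `cutoff`, `method`.
#' @export
cluster_compounds <- function(fingerprints, cutoff = 0.6) {
  stopifnot(length(fingerprints) >= 1L, cutoff >= 0, cutoff <= 1)
  ids <- fingerprint_ids(fingerprints)
  ord <- order(ids, method = "radix")
  fingerprints <- fingerprints[ord]
  ids <- ids[ord]
  n <- length(ids)
  if (n == 1L) {
    members <- data.frame(drug_id = ids, cluster_id = 1L, stringsAsFactors = FALSE)
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- 1 - tanimoto(fingerprints[[i]], fingerprints[[j]])
      }
    }
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    cl <- stats::cutree(hc, h = cutoff)
    members <- data.frame(drug_id = ids, cluster_id = as.integer(cl),
                          stringsAsFactors = FALSE)
  }
  structure(list(members = members, cutoff = cutoff, method = "average"),
            class = "cluster_set")
}

fingerprint_ids <- function(fingerprints) {
  ids <- names(fingerprints)
  if (is.null(ids)) ids <- vapply(fingerprints, function(f) f$drug_id, character(1))
  ids <- normalize_id(ids)
  if (any(is.na(ids) | !nzchar(ids)) || anyDuplicated(ids)) {
    stop("fingerprints must carry unique drug ids", call. = FALSE)
  }
  ids
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d compounds in %d clusters (average linkage, cutoff %g)\n",
              nrow(x$members), length(unique(x$members$cluster_id)), x$cutoff))
  invisible(x)
}

#' Nominate BSA candidates from structural sub-clusters
#'
#' Sub-clusters containing two or more known BSAs anchor the nomination: every
#' non-BSA member of such a cluster is proposed as a candidate, annotated with
#' its maximum Tanimoto similarity to an in-cluster BSA. Results are sorted by
#' that similarity, descending.
#'
#' @param clusters A `cluster_set` from [cluster_compounds()].
#' @param bsa_ids Character vector of known-BSA drug ids.
#' @param fingerprints The fingerprint list the clusters were built from
#'   (needed for the similarity annotation).
#' @return Data frame with columns `candidate_id`, `cluster_id`, `anchors`
#'   (semicolon-joined BSA ids), `max_tanimoto`.
#' @export
nominate_candidates <- function(clusters, bsa_ids, fingerprints) {
  stopifnot(inherits(clusters, "cluster_set"))
  bsa_ids <- normalize_id(bsa_ids)
  ids <- fingerprint_ids(fingerprints)
  fp_by_id <- fingerprints
  names(fp_by_id) <- ids
  m <- clusters$members
  out <- list()
  for (cl in sort(unique(m$cluster_id))) {
    members <- m$drug_id[m$cluster_id == cl]
    anchors <- intersect(members, bsa_ids)
    if (length(anchors) < 2L) next
    for (cand in sort(setdiff(members, bsa_ids), method = "radix")) {
      sims <- vapply(anchors, function(a) tanimoto(fp_by_id[[cand]], fp_by_id[[a]]),
                     numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        candidate_id = cand, cluster_id = cl,
        anchors = join_set(sort(anchors, method = "radix")),
        max_tanimoto = max(sims), stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(candidate_id = character(0), cluster_id = integer(0),
                      anchors = character(0), max_tanimoto = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$max_tanimoto, res$candidate_id, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build a structural-similarity provider
#'
#' The provider answers, for the C_SAR = 0.5 rule, whether a query drug is
#' structurally similar (Tanimoto at or above `threshold`, strict `>=`) to any
#' drug in a reference set. Two evidence sources can back it: a fingerprint
#' list, and/or an explicit table of declared similar pairs (used by packaged
#' fixtures where the similarity is asserted rather than computed). A query
#' whose structure is unknown returns not-similar with a warning.
#'
#' @param fingerprints Optional named list of `fingerprint` objects.
#' @param threshold Tanimoto threshold (default 0.4).
#' @param pairs Optional list of length-2 character vectors of drug ids
#'   declared similar (symmetric; similarity reported as 1).
#' @return A function `(query_id, set_ids)` returning a list with `similar`,
#'   `match`, `similarity`, `threshold`.
#' @export
similarity_provider <- function(fingerprints = NULL, threshold = 0.4, pairs = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  fp_ids <- if (!is.null(fingerprints)) fingerprint_ids(fingerprints) else character(0)
  if (!is.null(fingerprints)) names(fingerprints) <- fp_ids
  pair_key <- function(a, b) paste(sort(c(a, b), method = "radix"), collapse = "|")
  declared <- if (!is.null(pairs)) {
    vapply(pairs, function(p) pair_key(normalize_id(p[1]), normalize_id(p[2])), character(1))
  } else character(0)

  function(query_id, set_ids) {
    query_id <- normalize_id(query_id)
    set_ids <- setdiff(normalize_id(set_ids), query_id)
    miss <- list(similar = FALSE, match = NA_character_, similarity = 0,
                 threshold = threshold)
    if (!length(set_ids)) return(miss)
    for (s in sort(set_ids, method = "radix")) {
      if (pair_key(query_id, s) %in% declared) {
        return(list(similar = TRUE, match = s, similarity = 1, threshold = threshold))
      }
    }
    if (!query_id %in% fp_ids) {
      # only structure-backed providers warn: a declared-pair miss is an answer
      if (!is.null(fingerprints)) {
        warning("no structure for ", query_id, "; similarity treated as absent",
                call. = FALSE)
      }
      return(miss)
    }
    best <- miss
    for (s in sort(intersect(set_ids, fp_ids), method = "radix")) {
      sim <- tanimoto(fingerprints[[query_id]], fingerprints[[s]])
      if (sim > best$similarity) best <- list(similar = FALSE, match = s,
                                              similarity = sim, threshold = threshold)
    }
    best$similar <- best$similarity >= threshold
    if (!best$similar) best$match <- NA_character_
    best
  }
}
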