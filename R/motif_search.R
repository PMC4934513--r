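# Congruence search: precompile all candidate motifs of designated
# functional atoms in a target structure, then score them against a query
# motif by normalized pairwise-distance deviation plus thresholded
# potential-difference deviation (CScore; smaller is better, 0 = self).

#' Functional-atom table
#'
#' One designated side-chain atom per residue type used when precompiling
#' candidate motifs in a target.
#'
#' @return Named character vector: names are 3-letter residue codes,
#'   values are PDB atom names.
#' @export
functional_atoms <- function() {
  c(SER = "OG", THR = "OG1", ASP = "OD1", GLU = "OE1", TYR = "CZ",
    TRP = "CZ2", LYS = "NZ", ARG = "NH1", HIS = "NE2", ASN = "OD1",
    GLN = "OE1", CYS = "SG", PHE = "CZ")
}

#' Precompile a motif database from a target structure
#'
#' Collects the designated functional atom of every residue of the allowed
#' types, then enumerates every k-subset whose pairwise distances are all
#' at or below `cutoff`. The enumeration is complete (equal to brute-force
#' enumeration of all k-subsets followed by the distance test).
#'
#' @param target A `structure3d`.
#' @param allowed_types Residue types (3-letter codes) considered; default
#'   all types of [functional_atoms()].
#' @param k Motif size (>= 3; default 4).
#' @param cutoff Maximum pairwise distance within a motif, Angstrom
#'   (default 15).
#' @param atom_table Functional-atom table (default [functional_atoms()]).
#' @return A `motif_db`: list with `target_id`, `atoms` (functional-atom
#'   data frame), `combos` (k x M index matrix into `atoms`), `k`,
#'   `cutoff`.
#' @export
build_motif_db <- function(target, allowed_types = names(functional_atoms()),
                           k = 4, cutoff = 15,
                           atom_table = functional_atoms()) {
  stopifnot(inherits(target, "structure3d"), k >= 3)
  a <- target$atoms[!target$atoms$het, , drop = FALSE]
  sel <- a$resid %in% allowed_types &
         a$name == unname(atom_table[a$resid])
  fa <- a[which(sel), , drop = FALSE]
  rownames(fa) <- NULL
  if (nrow(fa) < k) {
    warning("only ", nrow(fa), " functional atoms of the allowed types in ",
            target$id, "; motif database is empty")
    combos <- matrix(integer(0), nrow = k)
  } else {
    D <- as.matrix(stats::dist(fa[, c("x", "y", "z")]))
    combos <- .enumerate_cliques(D <= cutoff + 1e-9, k)
  }
  structure(list(target_id = target$id, atoms = fa, combos = combos,
                 k = k, cutoff = cutoff),
            class = "motif_db")
}

# All k-cliques of an adjacency matrix, as a k x M index matrix with rows
# of each column ascending. Depth-first extension with neighbour pruning;
# complete by construction.
.enumerate_cliques <- function(adj, k) {
  n <- nrow(adj)
  diag(adj) <- TRUE
  out <- vector("list", 64); nout <- 0L
  grow <- function(clique, cand) {
    if (length(clique) == k) {
      nout <<- nout + 1L
      if (nout > length(out)) length(out) <<- 2L * length(out)
      out[[nout]] <<- clique
      return(invisible())
    }
    need <- k - length(clique)
    if (length(cand) < need) return(invisible())
    for (ii in seq_along(cand)) {
      v <- cand[ii]
      grow(c(clique, v), cand[-seq_len(ii)][adj[v, cand[-seq_len(ii)]]])
    }
  }
  grow(integer(0), seq_len(n))
  if (nout == 0L) return(matrix(integer(0), nrow = k))
  matrix(unlist(out[seq_len(nout)]), nrow = k)
}

#' @export
print.motif_db <- function(x, ...) {
  cat("<motif_db> ", x$target_id, ": ", ncol(x$combos), " candidate ",
      x$k, "-atom motifs over ", nrow(x$atoms),
      " functional atoms (cutoff ", x$cutoff, " A)\n", sep = "")
  invisible(x)
}

#' Congruence score (CScore) between two motifs
#'
#' `cscore = sum_{i<j} |d_q(i,j) - d_c(i,j)| / d_q(i,j)
#'          + lambda * sum_{i<j} g(dPD(i,j))`
#' where `dPD = ||PD_q| - |PD_c||` (absolute values on both levels),
#' `g(dPD) = 0` when `dPD < deadzone`, else
#' `(dPD - deadzone) / max(|PD_q|, deadzone)`. The distance term is
#' normalized by the query distance so the same deviation counts more on a
#' shorter reference distance; the potential term ignores deviations below
#' the dead-zone (default 100 kT/e) and constrains high potential
#' differences more loosely than low ones. Zero for a self-match; smaller
#' is better.
#'
#' @param query,candidate `motif` objects of equal size. When either PD
#'   matrix is missing the score is distance-only.
#' @param lambda Weight of the potential term (default 1).
#' @param deadzone PD deviation ignored below this value, kT/e
#'   (default 100).
#' @return List: `score`, `dist_term`, `pd_term`, and per-pair vectors
#'   `d_query`, `d_cand`, `d_dev`, `pd_dev` (upper-triangle order).
#' @export
cscore <- function(query, candidate, lambda = 1, deadzone = 100) {
  stopifnot(inherits(query, "motif"), inherits(candidate, "motif"))
  k <- nrow(query$atoms)
  if (nrow(candidate$atoms) != k) stop("motif sizes differ")
  ut <- upper.tri(query$distances)
  dq <- query$distances[ut]
  dc <- candidate$distances[ut]
  if (any(dq <= 0)) stop("degenerate query motif: zero pairwise distance")
  dist_dev <- abs(dq - dc) / dq
  dist_term <- sum(dist_dev)
  pd_term <- 0
  pd_dev <- rep(NA_real_, length(dq))
  if (!is.null(query$pds) && !is.null(candidate$pds)) {
    pq <- abs(query$pds[ut])
    pc <- abs(candidate$pds[ut])
    dpd <- abs(pq - pc)
    g <- ifelse(dpd < deadzone, 0, (dpd - deadzone) / pmax(pq, deadzone))
    pd_term <- sum(g)
    pd_dev <- dpd
  }
  list(score = dist_term + lambda * pd_term,
       dist_term = dist_term, pd_term = pd_term,
       d_query = dq, d_cand = dc, d_dev = abs(dq - dc), pd_dev = pd_dev)
}

#' Spatial congruence metrics: superposition RMSD and maximum pairwise
#' distance deviation
#'
#' `rmsd` is the coordinate RMSD after optimal least-squares (Kabsch)
#' superposition of the two ordered atom sets; `maxdev` is the largest
#' absolute difference between corresponding pairwise distances.
#'
#' @param query,candidate `motif` objects of equal size (>= 3 atoms).
#' @return List with `rmsd` and `maxdev`, both in Angstrom.
#' @export
congruence_metrics <- function(query, candidate) {
  stopifnot(inherits(query, "motif"), inherits(candidate, "motif"))
  k <- nrow(query$atoms)
  if (k < 3) stop("need at least 3 atoms")
  if (nrow(candidate$atoms) != k) stop("motif sizes differ")
  qx <- as.matrix(query$atoms[, c("x", "y", "z")])
  cx <- as.matrix(candidate$atoms[, c("x", "y", "z")])
  tr <- .kabsch_transform(qx, cx)
  r <- sqrt(mean(rowSums((apply_transform(tr, qx) - cx)^2)))
  ut <- upper.tri(query$distances)
  list(rmsd = r,
       maxdev = max(abs(query$distances[ut] - candidate$distances[ut])))
}

#' Search a motif database for congruent matches
#'
#' Every stored candidate combination is tested in every position order
#' compatible with the query's per-position residue groups
#' (order-preserving matching: candidate position p must be of a type in
#' the query's group p). Compatible candidates are scored with [cscore()];
#' matches with `cscore <= s_thresh` are returned sorted ascending by
#' score.
#'
#' @param db A `motif_db`.
#' @param query A `motif` with groups assigned ([assign_groups()]).
#' @param s_thresh Score threshold; matches scoring above it are discarded
#'   (default 5).
#' @param potentials Optional `potentials` for the target structure; when
#'   given (and the query has a PD matrix) the electrostatic term is
#'   scored, otherwise matching is distance-only.
#' @param lambda,deadzone Passed to [cscore()].
#' @param max_results Keep at most this many top matches (default 100).
#' @return A `match_list`: list of `match_result` objects, each with
#'   `motif` (the candidate as a `motif`), `cscore`, `rmsd`, `maxdev`,
#'   `breakdown` (per-pair deviations).
#' @export
search_motifs <- function(db, query, s_thresh = 5, potentials = NULL,
                          lambda = 1, deadzone = 100, max_results = 100) {
  stopifnot(inherits(db, "motif_db"), inherits(query, "motif"))
  k <- nrow(query$atoms)
  if (db$k != k) stop("database k (", db$k, ") != query size (", k, ")")
  if (is.null(query$groups)) stop("query motif has no groups; call ",
                                  "assign_groups() first")
  fa <- db$atoms
  use_pd <- !is.null(potentials) && !is.null(query$pds)
  pd_full <- if (use_pd) pairwise_pd(potentials, atom_keys(fa)) else NULL
  Dfull <- if (nrow(fa)) as.matrix(stats::dist(fa[, c("x", "y", "z")]))
           else matrix(0, 0, 0)
  perms <- .permutations(k)
  results <- list()

  if (ncol(db$combos)) {
    # position-compatibility of each functional atom with each query group
    compat <- vapply(query$groups, function(g) fa$resid %in% g,
                     logical(nrow(fa)))
    for (ci in seq_len(ncol(db$combos))) {
      combo <- db$combos[, ci]
      for (pi in seq_len(ncol(perms))) {
        ord <- combo[perms[, pi]]
        if (!all(compat[cbind(ord, seq_len(k))])) next
        cand <- structure(list(
          atoms = fa[ord, , drop = FALSE],
          keys = atom_keys(fa[ord, , drop = FALSE]),
          distances = Dfull[ord, ord, drop = FALSE],
          pds = if (use_pd) pd_full[ord, ord, drop = FALSE] else NULL,
          groups = NULL, source_id = db$target_id), class = "motif")
        sc <- cscore(query, cand, lambda = lambda, deadzone = deadzone)
        if (sc$score <= s_thresh) {
          met <- congruence_metrics(query, cand)
          results[[length(results) + 1L]] <- structure(
            list(motif = cand, cscore = sc$score, rmsd = met$rmsd,
                 maxdev = met$maxdev, breakdown = sc),
            class = "match_result")
        }
      }
    }
  }
  ord <- order(vapply(results, `[[`, numeric(1), "cscore"))
  results <- results[utils::head(ord, max_results)]
  structure(results, class = "match_list",
            query_id = query$source_id, target_id = db$target_id,
            s_thresh = s_thresh)
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1L))
  sub <- .permutations(k - 1)
  do.call(cbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    rbind(i, matrix(rest[sub], nrow = k - 1))
  }))
}

#' @export
print.match_list <- function(x, ...) {
  cat("<match_list> query ", attr(x, "query_id"), " vs target ",
      attr(x, "target_id"), ": ", length(x), " matches (s_thresh ",
      attr(x, "s_thresh"), ")\n", sep = "")
  for (i in seq_len(min(length(x), 5))) {
    m <- x[[i]]
    cat(sprintf("  %d. cscore %.3f rmsd %.2f max %.2f  [%s]\n", i,
                m$cscore, m$rmsd, m$maxdev,
                paste(paste0(.aa1(m$motif$atoms$resid),
                             m$motif$atoms$resno, m$motif$atoms$name),
                      collapse = ",")))
  }
  invisible(x)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> cscore %.3f rmsd %.2f A max %.2f A  [%s]\n",
              x$cscore, x$rmsd, x$maxdev,
              paste(paste0(.aa1(x$motif$atoms$resid), x$motif$atoms$resno,
                           x$motif$atoms$name), collapse = ",")))
  invisible(x)
}

#' Export search results as a TSV table
#'
#' One row per match: ranked score, metrics, matched atoms, and the
#' pairwise distance / PD rows of query and candidate.
#'
#' @param matches A `match_list`.
#' @param query The query `motif`.
#' @param path Output path.
#' @param header Optional comment lines.
#' @return Invisibly, `path`.
#' @export
write_matches <- function(matches, query, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  rows <- lapply(seq_along(matches), function(i) {
    m <- matches[[i]]
    data.frame(
      rank = i, cscore = round(m$cscore, 4), rmsd = round(m$rmsd, 2),
      maxdev = round(m$maxdev, 2),
      atoms = paste(paste0(.aa1(m$motif$atoms$resid), m$motif$atoms$resno,
                           m$motif$atoms$name), collapse = ","),
      d_query = paste(round(m$breakdown$d_query, 1), collapse = ","),
      d_match = paste(round(m$breakdown$d_cand, 1), collapse = ","),
      stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rank = integer(0), cscore = numeric(0), rmsd = numeric(0),
               maxdev = numeric(0), atoms = character(0),
               d_query = character(0), d_match = character(0))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Persist a motif database as JSON
#'
#' @param db A `motif_db`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
db_to_json <- function(db, path) {
  obj <- list(format = "motifdock/motif_db", version = 1L,
              target_id = db$target_id, k = db$k, cutoff = db$cutoff,
              atoms = db$atoms[, c("serial", "chain", "resno", "insert",
                                   "resid", "name", "elem",
                                   "x", "y", "z")],
              combos = if (ncol(db$combos)) t(db$combos) else
                matrix(integer(0), ncol = db$k))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load a motif database from JSON
#'
#' @param path Path written by [db_to_json()].
#' @return A `motif_db`.
#' @export
db_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "motifdock/motif_db")) {
    stop("not a motif database file")
  }
  atoms <- as.data.frame(obj$atoms, stringsAsFactors = FALSE)
  atoms$het <- FALSE
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  combos <- if (length(obj$combos)) {
    cm <- obj$combos
    if (is.null(dim(cm))) cm <- matrix(cm, ncol = obj$k)
    t(matrix(as.integer(cm), nrow = nrow(cm)))
  } else matrix(integer(0), nrow = obj$k)
  structure(list(target_id = obj$target_id, atoms = atoms,
                 combos = combos, k = obj$k, cutoff = obj$cutoff),
            class = "motif_db")
}
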