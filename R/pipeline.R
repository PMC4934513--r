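# End-to-end template docking: extract the contact motif from the
# holoenzyme, take its spatial/electrostatic features from the apo form
# when one is given (ligand binding perturbs the site), enumerate k-atom
# sub-motifs, search the target's precompiled motif database, and
# transplant the ligand through the best congruent match.

#' Dock a ligand into a target via a holoenzyme template
#'
#' Runs the full pipeline. The query features (pairwise distances, and PD
#' when potentials are supplied) are taken from `apo` when given --
#' binding perturbs the site, so the unbound form is the better query --
#' while the superposition anchors always use the holo coordinates, which
#' is where the ligand actually sits.
#'
#' @param holo Holoenzyme `structure3d`.
#' @param ligand A `ligand3d` from `holo` (or a het code string).
#' @param target Target `structure3d`.
#' @param apo Optional apo-form `structure3d` of the template protein
#'   (same residue numbering as `holo`).
#' @param n_contacts Contact atoms extracted from the holo site
#'   (default 5).
#' @param k Sub-motif size (default 4).
#' @param s_thresh CScore threshold (default 5).
#' @param scheme Residue group scheme (default `"default"`).
#' @param holo_potentials,target_potentials Optional `potentials` for the
#'   query-feature structure (apo if given, else holo) and for the target;
#'   both must be present for electrostatic scoring.
#' @param n_anchors Number of anchor atoms used for superposition: 3 uses
#'   the canonical-frame construction on the first three matched
#'   positions; larger values use least-squares over all `k` anchors.
#' @param frame Output frame passed to [dock_ligand()].
#' @param radius_cap,cutoff Caps for contact search and database motif
#'   diameter (defaults 8 and 15 Angstrom).
#' @return A `dock_run`: list with `contacts`, `submotifs`, `db`,
#'   `matches` (per sub-motif), `best` (list: `submotif`, `match`),
#'   `pose` (`docked_pose`), `n_candidates`. Errors with class
#'   `motifdock_no_match` when no match survives `s_thresh`.
#' @export
dock_from_template <- function(holo, ligand, target, apo = NULL,
                               n_contacts = 5, k = 4, s_thresh = 5,
                               scheme = "default",
                               holo_potentials = NULL,
                               target_potentials = NULL,
                               n_anchors = 3,
                               frame = "target",
                               radius_cap = 8.0, cutoff = 15) {
  if (is.character(ligand)) ligand <- select_ligand(holo, ligand)
  contacts <- get_motif(holo, ligand, n = n_contacts,
                        radius_cap = radius_cap)
  feature_struct <- if (is.null(apo)) holo else apo
  use_pd <- !is.null(holo_potentials) && !is.null(target_potentials)
  submotifs <- enumerate_submotifs(
    contacts, feature_struct, k = k,
    potentials = if (use_pd) holo_potentials else NULL)
  submotifs <- lapply(submotifs, assign_groups, scheme = scheme)

  allowed <- unique(unlist(lapply(submotifs, function(m) unlist(m$groups))))
  db <- build_motif_db(target, allowed_types = allowed, k = k,
                       cutoff = cutoff)
  matches <- lapply(submotifs, function(m)
    search_motifs(db, m, s_thresh = s_thresh,
                  potentials = if (use_pd) target_potentials else NULL))

  has <- which(vapply(matches, length, integer(1)) > 0)
  if (!length(has)) {
    stop(structure(class = c("motifdock_no_match", "error", "condition"),
                   list(message = paste0(
                     "no congruent site: no match in ", target$id,
                     " scored <= ", s_thresh, " for any of ",
                     length(submotifs), " sub-motifs"),
                     call = sys.call())))
  }
  best_scores <- vapply(has, function(i) matches[[i]][[1]]$cscore,
                        numeric(1))
  bi <- has[which.min(best_scores)]
  best_sub <- submotifs[[bi]]
  best_match <- matches[[bi]][[1]]

  # anchors: matched positions, holo coordinates on the template side
  na <- if (n_anchors >= k) k else 3
  hk <- .holo_anchor_keys(holo, best_sub, na)
  tk <- atom_keys(best_match$motif$atoms[seq_len(na), , drop = FALSE])
  pose <- dock_ligand(holo, ligand, hk, target, tk,
                      frame = frame,
                      method = if (na == 3) "frame" else "kabsch")
  structure(list(contacts = contacts, submotifs = submotifs, db = db,
                 matches = matches,
                 best = list(submotif = best_sub, match = best_match,
                             submotif_index = bi),
                 pose = pose,
                 n_candidates = ncol(db$combos)),
            class = "dock_run")
}

# Query features may come from the apo form; the superposition must use
# holo coordinates. Map the sub-motif's (chain, resno, name) onto holo.
.holo_anchor_keys <- function(holo, submotif, n) {
  a <- submotif$atoms[seq_len(n), , drop = FALSE]
  key <- paste(a$chain, a$resno, a$insert, a$resid, a$name, sep = "/")
  hk <- atom_keys(holo)
  idx <- match(key, hk)
  if (anyNA(idx)) stop("anchor atoms of the motif not found in the ",
                       "holo structure: ",
                       paste(key[is.na(idx)], collapse = ", "))
  hk[idx]
}

#' @export
print.dock_run <- function(x, ...) {
  cat("<dock_run> ", length(x$submotifs), " sub-motifs over ",
      x$n_candidates, " candidate motifs; best cscore ",
      format(x$best$match$cscore, digits = 4), " (sub-motif ",
      x$best$submotif_index, ")\n", sep = "")
  print(x$pose)
  invisible(x)
}
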