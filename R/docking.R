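# Rigid ligand transplantation. The canonical three-point frame puts
# anchor 1 at the origin, anchor 2 on the +Y axis and anchor 3 in the Z=0
# plane with positive X. Transforming holoenzyme and target each into this
# frame by their own anchors creates a unified coordinate framework; the
# ligand follows the holoenzyme's transform and can be mapped back into the
# target's original coordinates.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix (determinant +1).
#' @param translation Length-3 numeric; the transform maps `p` to
#'   `rotation %*% p + translation`.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be proper (det = +1); got det = ", det(rotation))
  }
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> det(R) =", format(det(x$R), digits = 10),
      " t = (", paste(format(x$t, digits = 6), collapse = ", "), ")\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param tr A `rigid_transform`.
#' @param xyz n x 3 matrix (or length-3 vector) of coordinates.
#' @return Transformed coordinates, same shape.
#' @export
apply_transform <- function(tr, xyz) {
  stopifnot(inherits(tr, "rigid_transform"))
  vec <- is.null(dim(xyz))
  if (vec) xyz <- matrix(xyz, ncol = 3)
  out <- sweep(as.matrix(xyz) %*% t(tr$R), 2, tr$t, "+")
  if (vec) as.numeric(out) else out
}

#' Invert a rigid transform
#' @param tr A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tr) {
  rigid_transform(t(tr$R), -as.numeric(t(tr$R) %*% tr$t))
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b `rigid_transform` objects.
#' @return The composition applying `b` first, then `a`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Canonical three-point frame transform
#'
#' Returns the proper rigid transform `T` with `T(a1) = (0,0,0)`,
#' `T(a2) = (0, |a2-a1|, 0)` on the +Y axis, and `T(a3)` in the Z=0 plane
#' with positive X (handedness convention: reflections are never
#' produced, so molecular chirality is preserved).
#'
#' @param a1,a2,a3 Length-3 coordinates of the three anchor points.
#' @return A `rigid_transform`.
#' @export
canonical_frame <- function(a1, a2, a3) {
  a1 <- as.numeric(a1); a2 <- as.numeric(a2); a3 <- as.numeric(a3)
  v2 <- a2 - a1; v3 <- a3 - a1
  n2 <- sqrt(sum(v2^2))
  if (n2 < 1e-8) stop("degenerate anchors: first two points coincide")
  ey <- v2 / n2
  vx <- v3 - sum(v3 * ey) * ey
  nx <- sqrt(sum(vx^2))
  if (nx < 1e-8) stop("degenerate anchors: the three points are collinear")
  ex <- vx / nx
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],   # ex x ey, right-handed
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- rbind(ex, ey, ez)
  dimnames(R) <- NULL
  rigid_transform(R, -as.numeric(R %*% a1))
}

# Least-squares (Kabsch) transform mapping `from` onto `to`; proper
# rotation enforced.
.kabsch_transform <- function(from, to) {
  from <- as.matrix(from); to <- as.matrix(to)
  cf <- colMeans(from); ct <- colMeans(to)
  H <- t(sweep(from, 2, cf)) %*% sweep(to, 2, ct)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.numeric(R %*% cf))
}

.coords_of <- function(s, keys) {
  a <- if (inherits(s, "structure3d")) s$atoms else s
  idx <- match(keys, atom_keys(a))
  if (anyNA(idx)) stop("anchor atoms not found: ",
                       paste(keys[is.na(idx)], collapse = ", "))
  as.matrix(a[idx, c("x", "y", "z")])
}

#' Transplant a ligand from a holoenzyme into a target structure
#'
#' Both structures are brought into the canonical frame of their own
#' anchor atoms ([canonical_frame()]); the ligand follows the holoenzyme.
#' With `frame = "target"` (default) the pose is additionally mapped back
#' by the inverse of the target's transform, so the ligand lands in the
#' target's original coordinates. Anchor correspondence is by position:
#' holo anchor i is matched to target anchor i (residue types may differ,
#' e.g. Glu onto Asp). With `method = "kabsch"` the superposition instead
#' uses least-squares over all k >= 3 anchors.
#'
#' @param holo The holoenzyme `structure3d`.
#' @param ligand A `ligand3d` from `holo`.
#' @param holo_anchor,target_anchor Atom keys (see [atom_keys()]) or atom
#'   data frames: 3 anchors for `method = "frame"`, >= 3 for `"kabsch"`.
#' @param target The target `structure3d`.
#' @param frame `"target"` (pose in the target's original coordinates) or
#'   `"canonical"` (pose in the shared canonical frame).
#' @param method `"frame"` (paper-style 3-point canonical frame) or
#'   `"kabsch"` (least-squares superposition of all anchors).
#' @return A `docked_pose`: list with `ligand` (atom data frame with
#'   transformed coordinates), `het_code`, `transform_holo`,
#'   `transform_target`, `transform_applied` (net map from holo frame to
#'   pose frame), `anchors` (holo/target data frames), `frame`,
#'   `anchor_rmsd` (least-squares RMSD of the anchor triplets; equals the
#'   congruence-metric RMSD), and `frame_rmsd` (residual of the alignment
#'   actually applied).
#' @export
dock_ligand <- function(holo, ligand, holo_anchor, target, target_anchor,
                        frame = c("target", "canonical"),
                        method = c("frame", "kabsch")) {
  frame <- match.arg(frame)
  method <- match.arg(method)
  stopifnot(inherits(holo, "structure3d"), inherits(ligand, "ligand3d"),
            inherits(target, "structure3d"))
  hk <- if (is.character(holo_anchor)) holo_anchor else atom_keys(holo_anchor)
  tk <- if (is.character(target_anchor)) target_anchor
        else atom_keys(target_anchor)
  if (length(hk) != length(tk)) stop("anchor counts differ")
  if (method == "frame" && length(hk) != 3) {
    stop("frame method needs exactly 3 anchors (got ", length(hk), ")")
  }
  if (length(hk) < 3) stop("need at least 3 anchors")
  hxyz <- .coords_of(holo, hk)
  txyz <- .coords_of(target, tk)

  if (method == "frame") {
    T_h <- canonical_frame(hxyz[1, ], hxyz[2, ], hxyz[3, ])
    T_t <- canonical_frame(txyz[1, ], txyz[2, ], txyz[3, ])
  } else {
    # shared frame = target's own coordinates; holo mapped by least squares
    T_h <- .kabsch_transform(hxyz, txyz)
    T_t <- rigid_transform()
  }
  applied <- if (frame == "canonical") T_h
             else compose_transforms(invert_transform(T_t), T_h)

  lig <- ligand$atoms
  lig[, c("x", "y", "z")] <- apply_transform(applied,
                                             as.matrix(lig[, c("x", "y", "z")]))
  # residuals of the anchor alignment actually applied
  hm <- apply_transform(applied, hxyz)
  tm <- if (frame == "canonical") apply_transform(T_t, txyz) else txyz
  frame_rmsd <- sqrt(mean(rowSums((hm - tm)^2)))
  ls_tr <- .kabsch_transform(hxyz, txyz)
  ls_rmsd <- sqrt(mean(rowSums((apply_transform(ls_tr, hxyz) - txyz)^2)))

  a_h <- as.data.frame(.anchor_frame(holo, hk), stringsAsFactors = FALSE)
  a_t <- as.data.frame(.anchor_frame(target, tk), stringsAsFactors = FALSE)
  structure(list(ligand = lig, het_code = ligand$het_code,
                 transform_holo = T_h, transform_target = T_t,
                 transform_applied = applied,
                 anchors = list(holo = a_h, target = a_t),
                 frame = frame, method = method,
                 anchor_rmsd = ls_rmsd, frame_rmsd = frame_rmsd),
            class = "docked_pose")
}

.anchor_frame <- function(s, keys) {
  a <- s$atoms
  a[match(keys, atom_keys(a)), c("chain", "resno", "insert", "resid",
                                 "name", "x", "y", "z"), drop = FALSE]
}

#' @export
print.docked_pose <- function(x, ...) {
  cat("<docked_pose> ", x$het_code, " (", nrow(x$ligand), " atoms) in ",
      x$frame, " frame via ", x$method,
      sprintf("; anchor rmsd %.3f A (frame residual %.3f A)\n",
              x$anchor_rmsd, x$frame_rmsd), sep = "")
  invisible(x)
}

#' Contacts of a docked pose with the target
#'
#' The `n` closest target residues to the posed ligand, using the
#' reporting contact rule (ligand atom N/O/S, any protein partner).
#'
#' @param pose A `docked_pose` in the target frame.
#' @param target The target `structure3d`.
#' @param n Number of contacts (default 10).
#' @param radius_cap Distance cap in Angstrom (default 8).
#' @return A `contact_set` (see [contact_table()]).
#' @export
pose_contacts <- function(pose, target, n = 10, radius_cap = 8.0) {
  stopifnot(inherits(pose, "docked_pose"))
  if (pose$frame != "target") {
    stop("pose is in the canonical frame; dock with frame = \"target\" ",
         "to compute contacts against the target")
  }
  lig <- structure(list(het_code = pose$het_code, chain = "Z", resno = 1L,
                        atoms = pose$ligand), class = "ligand3d")
  contact_table(target, lig, n = n, mode = "reporting",
                radius_cap = radius_cap)
}

#' Steric clash report for a docked pose
#'
#' Counts target heavy atoms lying within `cutoff` of any ligand heavy
#' atom (all target atoms are counted, including the anchor residues') and
#' reports the minimum observed distance.
#'
#' @param pose A `docked_pose` in the target frame.
#' @param target The target `structure3d`.
#' @param cutoff Clash distance in Angstrom (default 2.0).
#' @return List: `n_clashes`, `worst` (minimum pairwise distance, `Inf`
#'   when either set is empty), `pairs` (data frame of clashing pairs).
#' @export
clash_report <- function(pose, target, cutoff = 2.0) {
  stopifnot(inherits(pose, "docked_pose"), inherits(target, "structure3d"))
  if (pose$frame != "target") stop("pose must be in the target frame")
  prot <- target$atoms
  lig <- pose$ligand
  if (nrow(prot) == 0 || nrow(lig) == 0) {
    return(list(n_clashes = 0L, worst = Inf,
                pairs = data.frame()))
  }
  d <- .cross_dist(as.matrix(prot[, c("x", "y", "z")]),
                   as.matrix(lig[, c("x", "y", "z")]))
  hit <- which(d < cutoff, arr.ind = TRUE)
  pairs <- if (nrow(hit)) data.frame(
    target_atom = .atom_label(prot[hit[, 1], , drop = FALSE]),
    ligand_atom = lig$name[hit[, 2]],
    distance = d[hit], stringsAsFactors = FALSE) else data.frame()
  list(n_clashes = nrow(hit), worst = min(d), pairs = pairs)
}

#' Maximum intra-ligand atom distance
#'
#' The largest pairwise Euclidean distance within a ligand and the atom
#' names achieving it -- a simple conformational span metric for flexible
#' ligands.
#'
#' @param lig A `ligand3d` (or atom data frame with `name`, `x`, `y`, `z`).
#' @return List: `distance` (Angstrom), `atoms` (character pair).
#' @export
max_intraligand_distance <- function(lig) {
  a <- if (inherits(lig, "ligand3d")) lig$atoms else lig
  if (nrow(a) < 2) stop("need at least 2 ligand atoms")
  d <- as.matrix(stats::dist(a[, c("x", "y", "z")]))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  list(distance = max(d), atoms = c(a$name[ij[1]], a$name[ij[2]]))
}

#' Dump a rigid transform as JSON
#' @param tr A `rigid_transform`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written).
#' @export
transform_to_json <- function(tr, path = NULL) {
  js <- jsonlite::toJSON(list(rotation = tr$R, translation = tr$t),
                         digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
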