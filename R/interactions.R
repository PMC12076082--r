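# Intermolecular contact and molecular-valency analysis of coarse-grained
# slab trajectories. A "contact" is an unordered pair of beads belonging to
# different molecules at minimum-image distance strictly below the cutoff
# (default 7 A).

#' Intermolecular bead contacts in one frame
#'
#' Returns every unordered pair of beads on different molecules whose
#' minimum-image distance is strictly below `cutoff`, each pair exactly
#' once. Uses a periodic cell-list search (identical output to an all-pairs
#' scan).
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param mol Integer molecule id per bead.
#' @param box Box lengths (x, y, z).
#' @param cutoff Contact cutoff (Angstrom, default 7); must be below half
#'   the smallest box length for the minimum-image convention to be valid.
#' @return 2-column integer matrix of bead index pairs (i < j).
#' @export
#' @examples
#' xyz <- rbind(c(0, 0, 0), c(5, 0, 0))
#' contact_pairs(xyz, mol = c(1, 2), box = c(50, 50, 50))
contact_pairs <- function(xyz, mol, box, cutoff = 7) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3L, length(mol) == nrow(xyz),
            length(box) == 3L, cutoff > 0)
  if (cutoff >= min(box) / 2) {
    stop("cutoff must be smaller than half the smallest box length ",
         "(minimum-image convention)")
  }
  cpp_contact_pairs(xyz, as.integer(mol), as.numeric(box), cutoff)
}

#' Domain-resolved intermolecular contact percentages
#'
#' Classifies every intermolecular contact in every frame by the unordered
#' pair of domain labels of its two beads (repeats pooled into a single
#' `REPEAT` category), averages raw counts across frames, and normalises by
#' the total to percentages. The standard error across frames of the
#' per-frame percentages is reported alongside.
#'
#' @param traj A [slab_trajectory()] whose molecules all share one
#'   construct.
#' @param annotation A [annotate_regions()] result for that construct.
#' @param cutoff Contact cutoff (Angstrom, default 7).
#' @param discard_frac Fraction of initial frames discarded (default 0).
#' @param ordered Count each contact once per domain perspective (ordered
#'   pairs) instead of once per bead pair; off by default, which keeps the
#'   table symmetric.
#' @return A `contact_summary` data.frame: `domain_1`, `domain_2`,
#'   `mean_count`, `percentage`, `stderr` (percentage points), with
#'   attribute `n_frames`.
#' @export
domain_contact_fractions <- function(traj, annotation, cutoff = 7,
                                     discard_frac = 0, ordered = FALSE) {
  stopifnot(inherits(traj, "slab_trajectory"),
            inherits(annotation, "region_annotation"))
  labels <- pooled_labels(annotation)
  L <- length(labels)
  n_mol <- length(unique(traj$mol))
  if (nrow(traj$frames[[1L]]) != n_mol * L) {
    stop("bead count per molecule does not match the annotation length (",
         L, " residues expected)")
  }
  bead_lab <- rep(labels, times = n_mol)
  n_frames <- length(traj$frames)
  first <- min(n_frames, floor(discard_frac * n_frames) + 1L)
  keep <- seq.int(first, n_frames)
  cats <- character(0)
  counts <- list()
  for (fi in keep) {
    pr <- contact_pairs(traj$frames[[fi]], traj$mol, traj$box, cutoff)
    if (nrow(pr) == 0L) {
      counts[[length(counts) + 1L]] <- numeric(0)
      next
    }
    l1 <- bead_lab[pr[, 1L]]
    l2 <- bead_lab[pr[, 2L]]
    if (ordered) {
      key <- c(paste(l1, l2, sep = "|"), paste(l2, l1, sep = "|"))
    } else {
      key <- paste(pmin(l1, l2), pmax(l1, l2), sep = "|")
    }
    tb <- table(key)
    counts[[length(counts) + 1L]] <- tb
    cats <- union(cats, names(tb))
  }
  cats <- sort(cats)
  if (length(cats) == 0L) stop("no intermolecular contacts in trajectory")
  mat <- t(vapply(counts, function(tb) {
    v <- stats::setNames(numeric(length(cats)), cats)
    if (length(tb) > 0L) v[names(tb)] <- as.numeric(tb)
    v
  }, numeric(length(cats))))
  mean_counts <- colMeans(mat)
  pct <- 100 * mean_counts / sum(mean_counts)
  frame_pct <- 100 * mat / pmax(rowSums(mat), .Machine$double.eps)
  se <- apply(frame_pct, 2L, stats::sd) / sqrt(nrow(mat))
  parts <- strsplit(cats, "|", fixed = TRUE)
  out <- data.frame(
    domain_1 = vapply(parts, `[[`, character(1L), 1L),
    domain_2 = vapply(parts, `[[`, character(1L), 2L),
    mean_count = unname(mean_counts),
    percentage = unname(pct),
    stderr = unname(se)
  )
  attr(out, "n_frames") <- length(keep)
  class(out) <- c("contact_summary", "data.frame")
  out
}

#' Molecular valency in the protein bulk
#'
#' For each frame, every molecule whose centre of mass lies inside the
#' dense-phase ("bulk") z interval is assigned the number of distinct other
#' molecules it forms at least one contact with (cutoff 7 A by default,
#' matching the virtual-bond definition); partners themselves need not lie
#' in the bulk. The mean over molecules and frames is the molecular
#' valency.
#'
#' @param traj A [slab_trajectory()].
#' @param cutoff Contact cutoff (Angstrom).
#' @param bulk_region Length-2 z interval (Angstrom) defining the dense
#'   slab, e.g. the tanh-fitted slab half-width around the slab centre; must
#'   lie inside the box and be non-empty.
#' @param discard_frac Fraction of initial frames discarded (default 0).
#' @return A `valency_result`: `mean_valency`, `stderr` (across frames),
#'   `per_frame` (mean per frame), `per_molecule` (list of per-molecule
#'   counts per frame).
#' @export
molecular_valency <- function(traj, cutoff = 7, bulk_region,
                              discard_frac = 0) {
  stopifnot(inherits(traj, "slab_trajectory"), length(bulk_region) == 2L)
  Lz <- traj$box[3L]
  if (bulk_region[1L] >= bulk_region[2L] ||
      bulk_region[1L] < 0 || bulk_region[2L] > Lz) {
    stop("bulk region must be a non-empty z interval inside the box")
  }
  mols <- sort(unique(traj$mol))
  n_frames <- length(traj$frames)
  first <- min(n_frames, floor(discard_frac * n_frames) + 1L)
  keep <- seq.int(first, n_frames)
  per_frame_mean <- numeric(0)
  per_molecule <- list()
  for (fi in keep) {
    xyz <- traj$frames[[fi]]
    # molecule z centre of mass via circular mean (handles boundary
    # straddling)
    comz <- vapply(mols, function(m) {
      sel <- traj$mol == m
      circular_mean(xyz[sel, 3L] %% Lz, Lz, w = traj$mass[sel])
    }, numeric(1L))
    in_bulk <- comz >= bulk_region[1L] & comz <= bulk_region[2L]
    if (!any(in_bulk)) next
    pr <- contact_pairs(xyz, traj$mol, traj$box, cutoff)
    partner <- stats::setNames(vector("list", length(mols)),
                               as.character(mols))
    if (nrow(pr) > 0L) {
      m1 <- traj$mol[pr[, 1L]]
      m2 <- traj$mol[pr[, 2L]]
      edges <- unique(data.frame(a = pmin(m1, m2), b = pmax(m1, m2)))
      for (i in seq_len(nrow(edges))) {
        a <- as.character(edges$a[i]); b <- as.character(edges$b[i])
        partner[[a]] <- c(partner[[a]], edges$b[i])
        partner[[b]] <- c(partner[[b]], edges$a[i])
      }
    }
    val <- vapply(as.character(mols[in_bulk]),
                  function(m) length(unique(partner[[m]])), numeric(1L))
    per_frame_mean <- c(per_frame_mean, mean(val))
    per_molecule[[length(per_molecule) + 1L]] <- val
  }
  if (length(per_frame_mean) == 0L) {
    stop("no molecule centre of mass inside the bulk region in any frame")
  }
  se <- if (length(per_frame_mean) > 1L) {
    stats::sd(per_frame_mean) / sqrt(length(per_frame_mean))
  } else NA_real_
  structure(
    list(mean_valency = mean(per_frame_mean), stderr = se,
         per_frame = per_frame_mean, per_molecule = per_molecule),
    class = "valency_result"
  )
}

#' @export
print.valency_result <- function(x, ...) {
  cat(sprintf("molecular valency: %.3f +/- %.3g (SE over %d frames)\n",
              x$mean_valency, x$stderr, length(x$per_frame)))
  invisible(x)
}
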