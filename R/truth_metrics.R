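# Reference-based quality scores for a model of a protein-RNA complex:
# backbone lDDT, interface lDDT, ICS (contact F1), IPS (interface Jaccard),
# protein-RNA interface RMSD, and a single-superposition GDT approximation.
#
# Model and reference are matched by (chain, resno, atom name): chain
# mapping is assumed shared (CASP convention).  Metrics with an empty
# reference support are NA and flagged, never imputed.

BACKBONE_PROTEIN <- c("N", "CA", "C", "O")
BACKBONE_RNA <- c("P", "C3'", "C4'", "O3'", "O5'")

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of `moving` onto `fixed` with a proper
#' rotation (det = +1).
#'
#' @param moving,fixed n x 3 coordinate matrices with paired rows (n >= 3).
#' @return List: `rotation` (3x3, applied as x %*% t(R)), `translation`,
#'   `rmsd`, and `aligned` (the transformed moving set).
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("coordinate sets must be paired")
  if (nrow(moving) < 3) stop("kabsch_superpose(): need at least 3 points")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- sweep(P %*% t(R), 2, cf, `+`)
  rmsd <- sqrt(mean(rowSums((aligned - fixed)^2)))
  list(rotation = R, translation = cf - as.numeric(R %*% cm), rmsd = rmsd,
       aligned = aligned)
}

# atom tables matched by (chain, resno, atom); optionally restricted to a
# backbone atom set
matched_atoms <- function(model, reference, atom_set = NULL) {
  ma <- model$atoms; ra <- reference$atoms
  ma$nm <- normalize_atom_name(ma$atom); ra$nm <- normalize_atom_name(ra$atom)
  if (!is.null(atom_set)) {
    ma <- ma[ma$nm %in% atom_set, ]
    ra <- ra[ra$nm %in% atom_set, ]
  }
  mk <- paste(ma$chain, ma$resno, ma$nm)
  rk <- paste(ra$chain, ra$resno, ra$nm)
  hit <- match(rk, mk)
  ok <- !is.na(hit)
  list(
    ref = ra[ok, c("chain", "resno", "nm", "x", "y", "z", "polymer")],
    mod = ma[hit[ok], c("chain", "resno", "nm", "x", "y", "z", "polymer")]
  )
}

backbone_set <- function() c(BACKBONE_PROTEIN, BACKBONE_RNA)

flagged_na <- function(reason) {
  structure(NA_real_, flagged = reason)
}

#' Local distance difference test (lDDT)
#'
#' Superposition-free: the fraction of reference atom-pair distances (pairs
#' within the inclusion radius, atoms on different residues) reproduced by
#' the model within each threshold, averaged over thresholds.  The default
#' atom set is the backbone (N, CA, C, O for protein; P, C3', C4', O3',
#' O5' for RNA), i.e. bb-lDDT.
#'
#' @param model,reference `complex_structure`s with shared chain labeling.
#' @param inclusion_radius Reference distance cutoff for scored pairs, A.
#' @param thresholds Tolerances, A.
#' @param atom_set Atom names to score (default backbone).
#' @param inter_chain_only Score only atom pairs on different chains
#'   (interface lDDT).
#' @return Value in \[0, 1\], or flagged NA when the reference has no
#'   qualifying pairs.
#' @export
lddt <- function(model, reference, inclusion_radius = 15,
                 thresholds = c(0.5, 1, 2, 4), atom_set = backbone_set(),
                 inter_chain_only = FALSE) {
  m <- matched_atoms(model, reference, atom_set)
  if (nrow(m$ref) < 2) return(flagged_na("no matched atoms"))
  rxyz <- as.matrix(m$ref[, c("x", "y", "z")])
  mxyz <- as.matrix(m$mod[, c("x", "y", "z")])
  dr <- as.matrix(stats::dist(rxyz))
  dm <- as.matrix(stats::dist(mxyz))
  same_res <- outer(paste(m$ref$chain, m$ref$resno),
                    paste(m$ref$chain, m$ref$resno), `==`)
  sel <- upper.tri(dr) & !same_res & dr <= inclusion_radius
  if (inter_chain_only) {
    sel <- sel & outer(m$ref$chain, m$ref$chain, `!=`)
  }
  if (!any(sel)) {
    return(flagged_na(if (inter_chain_only) "no inter-chain reference contacts"
                      else "no reference contacts"))
  }
  diffs <- abs(dm[sel] - dr[sel])
  mean(vapply(thresholds, function(t) mean(diffs <= t), numeric(1)))
}

#' Interface lDDT
#'
#' [lddt()] restricted to atom pairs whose residues lie on different
#' chains.
#' @inheritParams lddt
#' @return Value in \[0, 1\] or flagged NA.
#' @export
ilddt <- function(model, reference, inclusion_radius = 15,
                  thresholds = c(0.5, 1, 2, 4), atom_set = backbone_set()) {
  lddt(model, reference, inclusion_radius, thresholds, atom_set,
       inter_chain_only = TRUE)
}

# inter-chain residue contact set of one structure as a character key vector;
# rd: optional precomputed residue_min_dist(x)
contact_set <- function(x, contact_cutoff, restrict = NULL, rd = NULL) {
  if (is.null(rd)) rd <- residue_min_dist(x)
  res <- rd$residues
  inter <- outer(res$chain, res$chain, `!=`)
  sel <- which(upper.tri(rd$dist) & inter & rd$dist <= contact_cutoff,
               arr.ind = TRUE)
  if (!is.null(restrict)) {
    keepers <- apply(sel, 1, function(ij) {
      chs <- c(res$chain[ij[1]], res$chain[ij[2]])
      setequal(chs, c(restrict$protein_chain, restrict$rna_chain))
    })
    sel <- sel[keepers, , drop = FALSE]
  }
  if (!nrow(sel)) return(character(0))
  a <- paste(res$chain[sel[, 1]], res$resno[sel[, 1]])
  b <- paste(res$chain[sel[, 2]], res$resno[sel[, 2]])
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Interface contact score (ICS)
#'
#' F1 score between the model's and the reference's inter-chain
#' residue-residue contact sets (heavy-atom minimum distance within the
#' cutoff), with residues matched by identity.
#'
#' @param model,reference `complex_structure`s.
#' @param contact_cutoff Contact distance, Angstrom.
#' @param restrict Optional one-row interface (list/tibble with
#'   `protein_chain`, `rna_chain`): restrict both contact sets to that
#'   chain pair.
#' @return F1 in \[0, 1\]; flagged NA when the reference set is empty.
#' @export
ics <- function(model, reference, contact_cutoff = 5, restrict = NULL,
                .rd = NULL) {
  ref_set <- contact_set(reference, contact_cutoff, restrict,
                         rd = .rd$reference)
  if (!length(ref_set)) return(flagged_na("empty reference contact set"))
  mod_set <- contact_set(model, contact_cutoff, restrict, rd = .rd$model)
  tp <- length(intersect(mod_set, ref_set))
  if (tp == 0) return(0)
  prec <- tp / length(mod_set)
  rec <- tp / length(ref_set)
  2 * prec * rec / (prec + rec)
}

interface_set <- function(x, atom_cutoff = 6, restrict = NULL, rd = NULL) {
  if (is.null(rd)) rd <- residue_min_dist(x)
  if (is.null(restrict)) {
    res <- rd$residues
    opp <- outer(res$polymer, res$polymer, `!=`)
    flag <- apply(rd$dist <= atom_cutoff & opp, 1, any)
    return(paste(res$chain, res$resno)[flag])
  }
  res <- rd$residues
  in_p <- res$chain == restrict$protein_chain
  in_r <- res$chain == restrict$rna_chain
  sub <- rd$dist[in_p, in_r, drop = FALSE] <= atom_cutoff
  keys <- c(paste(res$chain, res$resno)[in_p][apply(sub, 1, any)],
            paste(res$chain, res$resno)[in_r][apply(sub, 2, any)])
  keys
}

#' Interface patch similarity (IPS)
#'
#' Jaccard index between the model's and the reference's interface residue
#' sets (6 Angstrom opposite-polymer rule evaluated on each structure,
#' residues matched by identity).
#'
#' @inheritParams ics
#' @param atom_cutoff Interface residue distance cutoff, Angstrom.
#' @return Jaccard in \[0, 1\]; flagged NA when both sets are empty.
#' @export
ips <- function(model, reference, atom_cutoff = 6, restrict = NULL,
                .rd = NULL) {
  a <- interface_set(model, atom_cutoff, restrict, rd = .rd$model)
  b <- interface_set(reference, atom_cutoff, restrict, rd = .rd$reference)
  u <- union(a, b)
  if (!length(u)) return(flagged_na("both interface sets empty"))
  length(intersect(a, b)) / length(u)
}

#' Protein-RNA interface RMSD
#'
#' Interface residues are defined on the REFERENCE (any heavy atom within
#' `interface_cutoff` of a chain of the opposite polymer type); the
#' backbone atoms of those residues are optimally superposed (Kabsch) and
#' the RMSD reported.
#'
#' @param model,reference `complex_structure`s.
#' @param interface_cutoff Reference interface distance, Angstrom.
#' @return RMSD in Angstrom (>= 0).
#' @export
irmsd <- function(model, reference, interface_cutoff = 10, .rd_ref = NULL) {
  rd <- .rd_ref %||% residue_min_dist(reference)
  res <- rd$residues
  opp <- outer(res$polymer, res$polymer, `!=`)
  flag <- apply(rd$dist <= interface_cutoff & opp, 1, any)
  keys <- paste(res$chain, res$resno)[flag]
  if (!length(keys)) stop("irmsd(): reference has no interface residues")
  m <- matched_atoms(model, reference, backbone_set())
  sel <- paste(m$ref$chain, m$ref$resno) %in% keys
  if (sum(sel) < 3) stop("irmsd(): fewer than 3 matched interface backbone atoms")
  fit <- kabsch_superpose(as.matrix(m$mod[sel, c("x", "y", "z")]),
                          as.matrix(m$ref[sel, c("x", "y", "z")]))
  fit$rmsd
}

#' Approximate GDT-TS / GDT-HA
#'
#' Single global Kabsch superposition on all matched anchor atoms, then the
#' mean over thresholds of the fraction of anchors within each threshold.
#' This is a documented approximation: the full GDT search over many
#' superposition seeds is not performed, so values are a lower bound.
#'
#' @param model,reference `complex_structure`s.
#' @param thresholds_ts,thresholds_ha Distance thresholds, Angstrom.
#' @return Named list `gdt_ts`, `gdt_ha`, each in \[0, 1\], with attribute
#'   `approximate = TRUE`.
#' @export
gdt_approx <- function(model, reference, thresholds_ts = c(1, 2, 4, 8),
                       thresholds_ha = c(0.5, 1, 2, 4)) {
  am <- anchor_coords(model, warn = FALSE)
  ar <- anchor_coords(reference, warn = FALSE)
  key_m <- paste(am$chain, am$resno)
  key_r <- paste(ar$chain, ar$resno)
  hit <- match(key_r, key_m)
  ok <- !is.na(hit)
  if (sum(ok) < 3) stop("gdt_approx(): fewer than 3 matched anchors")
  fixed <- as.matrix(ar[ok, c("x", "y", "z")])
  moving <- as.matrix(am[hit[ok], c("x", "y", "z")])
  fit <- kabsch_superpose(moving, fixed)
  d <- sqrt(rowSums((fit$aligned - fixed)^2))
  out <- list(
    gdt_ts = mean(vapply(thresholds_ts, function(t) mean(d <= t), numeric(1))),
    gdt_ha = mean(vapply(thresholds_ha, function(t) mean(d <= t), numeric(1)))
  )
  attr(out, "approximate") <- TRUE
  out
}

#' Full ground-truth bundle for a model against a reference
#'
#' Three global fold scores (bb-lDDT and approximate GDT-TS/GDT-HA), three
#' global interface scores (iLDDT, IPS, ICS), the protein-RNA iRMSD, and
#' per-interface ICS/IPS for every reference interface.  Metrics whose
#' reference support is empty are NA with a `flagged` attribute and masked
#' downstream.
#'
#' @param model,reference `complex_structure`s with shared chain labels.
#' @return A `truth_bundle` list.
#' @export
truth_bundle <- function(model, reference) {
  gd <- gdt_approx(model, reference)
  rd <- list(model = residue_min_dist(model),
             reference = residue_min_dist(reference))
  ifaces <- enumerate_interfaces(reference)
  per <- if (nrow(ifaces)) {
    dplyr::bind_rows(lapply(seq_len(nrow(ifaces)), function(k) {
      r <- ifaces[k, ]
      tibble::tibble(protein_chain = r$protein_chain,
                     rna_chain = r$rna_chain,
                     ics = as.numeric(ics(model, reference, restrict = r,
                                          .rd = rd)),
                     ips = as.numeric(ips(model, reference, restrict = r,
                                          .rd = rd)))
    }))
  } else {
    tibble::tibble(protein_chain = character(), rna_chain = character(),
                   ics = numeric(), ips = numeric())
  }
  structure(list(
    bb_lddt = as.numeric(lddt(model, reference)),
    gdt_ts = gd$gdt_ts, gdt_ha = gd$gdt_ha,
    ilddt = as.numeric(ilddt(model, reference)),
    ips = as.numeric(ips(model, reference, .rd = rd)),
    ics = as.numeric(ics(model, reference, .rd = rd)),
    irmsd = irmsd(model, reference, .rd_ref = rd$reference),
    per_interface = per,
    gdt_approximate = TRUE
  ), class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("<truth_bundle>\n")
  cat(sprintf("  fold:      bb-lDDT %.3f  GDT-TS~ %.3f  GDT-HA~ %.3f\n",
              x$bb_lddt, x$gdt_ts, x$gdt_ha))
  cat(sprintf("  interface: iLDDT %.3f  IPS %.3f  ICS %.3f  iRMSD %.2f A\n",
              x$ilddt, x$ips, x$ics, x$irmsd))
  if (nrow(x$per_interface)) {
    cat("  per-interface:\n")
    for (k in seq_len(nrow(x$per_interface))) {
      r <- x$per_interface[k, ]
      cat(sprintf("    %s-%s: ICS %.3f  IPS %.3f\n", r$protein_chain,
                  r$rna_chain, r$ics, r$ips))
    }
  }
  invisible(x)
}

#' Tidy ground-truth table for a set of models
#'
#' @param models Named list of `complex_structure`s (or paths readable by
#'   [read_structure()]).
#' @param reference A `complex_structure` or path.
#' @return Tibble: one row per model with all global truth scores and
#'   per-interface scores in wide columns (`ics_<P>_<R>`, `ips_<P>_<R>`).
#' @export
truth_table <- function(models, reference) {
  if (is.character(reference)) reference <- read_structure(reference)
  if (is.null(names(models))) {
    names(models) <- paste0("model_", seq_along(models))
  }
  rows <- lapply(names(models), function(id) {
    m <- models[[id]]
    if (is.character(m)) m <- read_structure(m)
    b <- truth_bundle(m, reference)
    row <- tibble::tibble(model_id = id, bb_lddt = b$bb_lddt,
                          gdt_ts = b$gdt_ts, gdt_ha = b$gdt_ha,
                          ilddt = b$ilddt, ips = b$ips, ics = b$ics,
                          irmsd = b$irmsd)
    if (nrow(b$per_interface)) {
      for (k in seq_len(nrow(b$per_interface))) {
        r <- b$per_interface[k, ]
        row[[paste0("ics_", r$protein_chain, "_", r$rna_chain)]] <- r$ics
        row[[paste0("ips_", r$protein_chain, "_", r$rna_chain)]] <- r$ips
      }
    }
    row
  })
  dplyr::bind_rows(rows)
}
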