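# Synthetic complex and decoy generation.
#
# Idealized protein alpha-helices and A-form RNA strands are built from
# internal coordinates (NeRF), docked rigidly into contact, and degraded by
# rigid-body and torsion-space perturbations to emulate docking-style decoy
# ensembles whose interface and fold quality fall with a controlled
# magnitude.  These are geometric fixtures: no energetics, no clash
# minimization, planar idealized bases, fixed C3'-endo-like sugar.

PROTEIN_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.53,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.5,
  a_c_ca_cb = 110.6, omega = 180
)

RNA_GEOM <- list(
  # A-form backbone torsions (degrees) and standard bond geometry
  alpha = -68, beta = 178, gamma = 54, delta = 82, epsilon = -153, zeta = -71,
  b_p_o5 = 1.593, b_o5_c5 = 1.44, b_c5_c4 = 1.51, b_c4_c3 = 1.524,
  b_c3_o3 = 1.423, b_o3_p = 1.607,
  a_o3_p_o5 = 104, a_p_o5_c5 = 120, a_o5_c5_c4 = 111, a_c5_c4_c3 = 116,
  a_c4_c3_o3 = 110, a_c3_o3_p = 120
)

PURINES <- c("A", "G")

# ---- idealized planar base rings (local frame: glycosidic N at origin,
# ring extending toward +x, z = 0 plane) ------------------------------------

ring_polygon <- function(n, side, names) {
  R <- side / (2 * sin(pi / n))
  center <- c(R, 0, 0)
  ang <- pi - (seq_len(n) - 1) * 2 * pi / n
  xyz <- cbind(center[1] + R * cos(ang), center[2] + R * sin(ang), 0)
  rownames(xyz) <- names
  xyz
}

base_ring_template <- function(base) {
  if (!base %in% PURINES) {
    xyz <- ring_polygon(6, 1.39, c("N1", "C2", "N3", "C4", "C5", "C6"))
    return(xyz)
  }
  pent <- ring_polygon(5, 1.39, c("N9", "C8", "N7", "C5", "C4"))
  c4 <- pent["C4", ]; c5 <- pent["C5", ]
  p_center <- colMeans(pent)
  mid <- (c4 + c5) / 2
  u <- vunit(mid - p_center)
  hex_center <- mid + u * 1.39 * sqrt(3) / 2
  th5 <- atan2(c5[2] - hex_center[2], c5[1] - hex_center[1])
  th4 <- atan2(c4[2] - hex_center[2], c4[1] - hex_center[1])
  dd <- (th4 - th5) %% (2 * pi)
  step <- if (abs(dd - pi / 3) < 1e-6) -pi / 3 else pi / 3
  hexn <- c("C6", "N1", "C2", "N3")
  hx <- t(vapply(seq_along(hexn), function(k) {
    a <- th5 + k * step
    c(hex_center[1] + 1.39 * cos(a), hex_center[2] + 1.39 * sin(a), 0)
  }, numeric(3)))
  rownames(hx) <- hexn
  rbind(pent, hx)
}

glycosidic_atom <- function(base) if (base %in% PURINES) "N9" else "N1"

# attach a base template at C1', using the C1'->N direction and C2' to fix
# the ring plane; chi is implicit but identical for every residue
attach_base <- function(base, c1, c2) {
  tmpl <- base_ring_template(base)
  # glycosidic N placed 1.48 A from C1' in a reproducible off-backbone
  # direction
  e1 <- vunit(c1 - c2)
  aux <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e3 <- vunit(vcross(e1, aux))
  e2 <- vcross(e3, e1)
  dirn <- vunit(0.8 * e1 + 0.6 * e2)
  n_pos <- c1 + 1.48 * dirn
  f1 <- dirn                      # template +x
  f3 <- vunit(vcross(f1, e3))
  f2 <- vcross(f3, f1)
  basis <- cbind(f1, f2, f3)
  xyz <- t(basis %*% t(tmpl)) + matrix(n_pos, nrow(tmpl), 3, byrow = TRUE)
  rownames(xyz) <- rownames(tmpl)
  xyz
}

atoms_tibble <- function(chain, resno, resid, polymer, names, xyz) {
  tibble::tibble(
    chain = chain, resno = as.integer(resno), resid = resid,
    atom = names, element = element_from_name(names),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, polymer = polymer
  )
}

#' Build an idealized protein chain from backbone torsions
#'
#' Backbone (N, CA, C, O) plus CB (absent for glycine) from standard bond
#' geometry; defaults give an ideal alpha-helix.
#'
#' @param sequence Character vector of 3-letter residue codes.
#' @param phi,psi Backbone torsions in degrees (recycled along the chain).
#' @param chain_id Chain identifier.
#' @return A `complex_structure` with a single protein chain.
#' @export
make_protein_chain <- function(sequence, phi = -57, psi = -47, chain_id = "A") {
  n <- length(sequence)
  stopifnot(n >= 1)
  g <- PROTEIN_GEOM
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  C[1, ] <- nerf_place(c(0, 0, -1), N[1, ], CA[1, ], g$b_ca_c, g$a_n_ca_c, 60)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_c_n, g$a_ca_c_n, psi[i - 1])
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, g$omega)
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o,
                         psi[i] + 180)
  }
  rows <- lapply(seq_len(n), function(i) {
    nm <- c("N", "CA", "C", "O")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (sequence[i] != "GLY") {
      cb <- nerf_place(N[i, ], C[i, ], CA[i, ], PROTEIN_GEOM$b_ca_cb,
                       PROTEIN_GEOM$a_c_ca_cb, -122.6)
      nm <- c(nm, "CB"); xyz <- rbind(xyz, cb)
    }
    atoms_tibble(chain_id, i, sequence[i], "protein", nm, xyz)
  })
  new_complex_structure(dplyr::bind_rows(rows), source_path = "<synthetic>")
}

#' Build an idealized single-stranded A-form RNA chain
#'
#' Full backbone (P, O5', C5', C4', C3', O3'), sugar carbons C2'/C1', and
#' planar idealized base rings.  Default torsions are A-form; the helix is
#' regular, so pseudo-torsions are constant along the interior.
#'
#' @param sequence Character vector of 1-letter nucleotide codes (A/C/G/U).
#' @param chain_id Chain identifier.
#' @param torsions Optional named list overriding any of the six backbone
#'   torsions (alpha, beta, gamma, delta, epsilon, zeta), degrees.
#' @return A `complex_structure` with a single RNA chain.
#' @export
make_rna_chain <- function(sequence, chain_id = "B", torsions = list()) {
  n <- length(sequence)
  stopifnot(n >= 1, all(sequence %in% NT1))
  g <- utils::modifyList(RNA_GEOM, torsions)
  res <- vector("list", n)
  # per-residue backbone placement; prev holds last residue's C4', C3', O3'
  prev <- NULL
  for (i in seq_len(n)) {
    if (is.null(prev)) {
      P <- c(0, 0, 0)
      O5 <- c(g$b_p_o5, 0, 0)
      C5 <- nerf_place(c(0, 0, -1), P, O5, g$b_o5_c5, g$a_p_o5_c5, 45)
    } else {
      P <- nerf_place(prev$C4, prev$C3, prev$O3, g$b_o3_p, g$a_c3_o3_p,
                      g$epsilon)
      O5 <- nerf_place(prev$C3, prev$O3, P, g$b_p_o5, g$a_o3_p_o5, g$zeta)
      C5 <- nerf_place(prev$O3, P, O5, g$b_o5_c5, g$a_p_o5_c5, g$alpha)
    }
    C4 <- nerf_place(P, O5, C5, g$b_c5_c4, g$a_o5_c5_c4, g$beta)
    C3 <- nerf_place(O5, C5, C4, g$b_c4_c3, g$a_c5_c4_c3, g$gamma)
    O3 <- nerf_place(C5, C4, C3, g$b_c3_o3, g$a_c4_c3_o3, g$delta)
    C2 <- nerf_place(C5, C4, C3, 1.525, 102.6, -120)
    C1 <- nerf_place(C4, C3, C2, 1.53, 101.5, 35)
    ring <- attach_base(sequence[i], C1, C2)
    nm <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'", "C2'", "C1'",
            rownames(ring))
    xyz <- rbind(P, O5, C5, C4, C3, O3, C2, C1, ring)
    res[[i]] <- atoms_tibble(chain_id, i, sequence[i], "rna", nm, xyz)
    prev <- list(C4 = C4, C3 = C3, O3 = O3)
  }
  new_complex_structure(dplyr::bind_rows(res), source_path = "<synthetic>")
}

wc_partner <- c(A = "U", U = "A", G = "C", C = "G")

#' Build an idealized Watson-Crick paired RNA duplex
#'
#' Pair-centric construction: each base pair is laid out coplanar with the
#' purine N1 / pyrimidine N3 donor-acceptor distance at 2.9 Angstrom, then
#' stacked with A-form rise (2.81 A) and twist (32.7 deg).  Backbone atoms
#' (C1', C2', C3', C4', P) are attached approximately: the fixture is for
#' pairing/interface geometry, not for covalent realism.
#'
#' @param sequence Strand-1 nucleotides (1-letter); strand 2 is the reverse
#'   complement.
#' @param chain_ids Two chain identifiers.
#' @return A `complex_structure` with two RNA chains.
#' @export
make_rna_duplex <- function(sequence, chain_ids = c("B", "C")) {
  n <- length(sequence)
  stopifnot(n >= 1, all(sequence %in% NT1))
  rows <- list()
  for (k in seq_len(n)) {
    b1 <- sequence[k]; b2 <- unname(wc_partner[b1])
    pur <- if (b1 %in% PURINES) b1 else b2
    pyr <- if (b1 %in% PURINES) b2 else b1
    # pyrimidine at origin frame; purine across the WC edge
    pyr_xyz <- base_ring_template(pyr)
    pyr_center <- colMeans(pyr_xyz)
    n3 <- pyr_xyz["N3", ]
    d <- vunit(n3 - pyr_center)
    target_n1 <- n3 + 2.9 * d
    pur_t <- base_ring_template(pur)
    hex_center <- colMeans(pur_t[c("C6", "N1", "C2", "N3", "C4", "C5"), ])
    v <- vunit(hex_center - pur_t["N1", ])
    # rotate purine in-plane so its N1->center direction points along +d
    th <- atan2(d[2], d[1]) - atan2(v[2], v[1])
    R <- rotation_about_axis(c(0, 0, 1), rad2deg(th))
    pur_xyz <- t(R %*% t(pur_t))
    rownames(pur_xyz) <- rownames(pur_t)
    pur_xyz <- pur_xyz +
      matrix(target_n1 - pur_xyz["N1", ], nrow(pur_xyz), 3, byrow = TRUE)
    add_backbone <- function(ring, base) {
      ngly <- ring[glycosidic_atom(base), ]
      center <- colMeans(ring)
      out <- vunit(ngly - center)
      c1 <- ngly + 1.48 * out
      c2 <- c1 + 1.2 * out + c(0, 0, 0.9)
      c3 <- c1 + 2.2 * out + c(0, 0, 1.2)
      c4 <- c1 + 3.3 * out + c(0, 0, 0.8)
      p <- c1 + 4.3 * out + c(0, 0, 1.6)
      rbind(ring, `C1'` = c1, `C2'` = c2, `C3'` = c3, `C4'` = c4, P = p)
    }
    xyz1r <- add_backbone(if (b1 %in% PURINES) pur_xyz else pyr_xyz, b1)
    xyz2r <- add_backbone(if (b1 %in% PURINES) pyr_xyz else pur_xyz, b2)
    place <- function(xyz) {
      R <- rotation_about_axis(c(0, 0, 1), 32.7 * (k - 1))
      sweep(xyz %*% t(R), 2, c(0, 0, 2.81 * (k - 1)), `+`)
    }
    xyz1 <- place(xyz1r); xyz2 <- place(xyz2r)
    rows[[length(rows) + 1L]] <-
      atoms_tibble(chain_ids[1], k, b1, "rna", rownames(xyz1r), xyz1)
    rows[[length(rows) + 1L]] <-
      atoms_tibble(chain_ids[2], n + 1L - k, b2, "rna", rownames(xyz2r), xyz2)
  }
  at <- dplyr::bind_rows(rows)
  at <- dplyr::arrange(at, match(.data$chain, chain_ids), .data$resno)
  new_complex_structure(at, source_path = "<synthetic>")
}

#' Generate an idealized docked protein-RNA toy complex
#'
#' An ideal alpha-helical protein chain and an A-form single-stranded RNA
#' chain, rigidly placed so that at least three residue pairs are in
#' interface contact (heavy-atom distance <= 6 A) without steric collapse.
#'
#' @param n_protein_res,n_rna_res Chain lengths (>= 4 each).
#' @param seed Integer seed; the construction is fully reproducible.
#' @param min_contacts Required number of contacting residue pairs.
#' @param contact_dist Distance (A) defining a placement contact; the
#'   default 5 guarantees the interface also has contact-score support.
#' @return A `complex_structure` with chains A (protein) and B (RNA).
#' @export
make_toy_complex <- function(n_protein_res, n_rna_res, seed = 1,
                             min_contacts = 3, contact_dist = 5) {
  if (n_protein_res < 4 || n_rna_res < 4) {
    stop("make_toy_complex(): need at least 4 residues per chain")
  }
  withr::with_seed(seed, {
    prot_seq <- sample(setdiff(AA3, "GLY"), n_protein_res, replace = TRUE)
    # a couple of glycines exercise the anchor fallback
    if (n_protein_res >= 6) prot_seq[c(3, n_protein_res - 2)] <- "GLY"
    rna_seq <- sample(NT1, n_rna_res, replace = TRUE)
    prot <- make_protein_chain(prot_seq, chain_id = "A")
    rna0 <- make_rna_chain(rna_seq, chain_id = "B")
    p_xyz <- as.matrix(prot$atoms[, c("x", "y", "z")])
    p_com <- colMeans(p_xyz)
    for (attempt in seq_len(40)) {
      u <- random_unit_vector()
      Rr <- rotation_about_axis(random_unit_vector(), stats::runif(1, 0, 360))
      r_xyz0 <- as.matrix(rna0$atoms[, c("x", "y", "z")])
      r_xyz0 <- sweep(sweep(r_xyz0, 2, colMeans(r_xyz0)) %*% t(Rr), 2,
                      p_com, `+`)
      rad_p <- max(sqrt(rowSums(sweep(p_xyz, 2, p_com)^2)))
      rad_r <- max(sqrt(rowSums(sweep(r_xyz0, 2, p_com)^2)))
      # dock to the packing limit: the deepest approach that stays above
      # van-der-Waals contact, so the native is a packing optimum (as a
      # physical native would be) rather than a grazing contact
      placed <- NULL
      for (t_off in seq(rad_p + rad_r + 5, 0, by = -0.25)) {
        r_xyz <- sweep(r_xyz0, 2, t_off * u, `+`)
        dmat <- cross_min_residue_dist(prot$atoms, r_xyz, rna0$atoms)
        min_d <- min(dmat)
        if (min_d < 3.0) break
        if (sum(dmat <= contact_dist) >= min_contacts) placed <- r_xyz
      }
      if (!is.null(placed)) {
        rna <- rna0
        rna$atoms[, c("x", "y", "z")] <- as.data.frame(placed)
        return(new_complex_structure(
          dplyr::bind_rows(prot$atoms, rna$atoms), "<synthetic>"
        ))
      }
    }
  })
  stop("make_toy_complex(): could not place chains in contact; ",
       "try another seed")
}

# residue-pair min-distance matrix between protein atoms and (replaced) RNA
# coordinates; rows protein residues, cols RNA residues
cross_min_residue_dist <- function(prot_atoms, r_xyz, rna_atoms) {
  pi_res <- as.integer(factor(prot_atoms$resno,
                              levels = unique(prot_atoms$resno)))
  ri_res <- as.integer(factor(rna_atoms$resno,
                              levels = unique(rna_atoms$resno)))
  p_xyz <- as.matrix(prot_atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(p_xyz^2), rowSums(r_xyz^2), `+`) -
    2 * p_xyz %*% t(r_xyz)
  d2[d2 < 0] <- 0
  dmin <- matrix(Inf, max(pi_res), max(ri_res))
  for (i in seq_len(nrow(d2))) {
    row <- sqrt(d2[i, ])
    agg <- tapply(row, ri_res, min)
    dmin[pi_res[i], ] <- pmin(dmin[pi_res[i], ], agg)
  }
  dmin
}

#' Rigid-body perturbation of one chain
#'
#' Rotates the named chain about its center of mass by a random axis and an
#' angle drawn uniformly in \[0, rot_mag\], then translates it by a random
#' direction with norm uniform in \[0, trans_mag\].  Internal geometry is
#' untouched.
#'
#' @param x A `complex_structure`.
#' @param chain_id Chain to perturb.
#' @param rot_mag Maximum rotation, degrees.
#' @param trans_mag Maximum translation, Angstrom.
#' @param seed Integer seed.
#' @param exact Use the magnitudes exactly rather than drawing uniformly
#'   below them (used by the graded decoy schedule, where the level should
#'   pin the displacement).
#' @return Perturbed `complex_structure`.
#' @export
perturb_rigid <- function(x, chain_id, rot_mag, trans_mag, seed = 1,
                          exact = FALSE) {
  stopifnot(inherits(x, "complex_structure"), rot_mag >= 0, trans_mag >= 0)
  if (!chain_id %in% x$chains$chain_id) stop("unknown chain: ", chain_id)
  if (rot_mag == 0 && trans_mag == 0) return(x)
  withr::with_seed(seed, {
    sel <- x$atoms$chain == chain_id
    xyz <- as.matrix(x$atoms[sel, c("x", "y", "z")])
    com <- center_of_mass(x$atoms[sel, ])
    axis <- random_unit_vector()
    ang <- if (exact) rot_mag else stats::runif(1, 0, rot_mag)
    xyz <- rotate_points(xyz, com, axis, ang)
    shift <- random_unit_vector() *
      (if (exact) trans_mag else stats::runif(1, 0, trans_mag))
    xyz <- sweep(xyz, 2, shift, `+`)
    x$atoms[sel, c("x", "y", "z")] <- as.data.frame(xyz)
    x
  })
}

#' Torsion-space perturbation of backbone dihedrals
#'
#' Adds N(0, jitter^2) noise to protein phi/psi and to RNA backbone torsions
#' (about the P-O5' and C4'-C3' bonds), rotating all downstream atoms of the
#' chain about the bond axis.  Bond lengths are preserved exactly
#' (rotations about axes through bonded atoms).
#'
#' @param x A `complex_structure`.
#' @param torsion_jitter Standard deviation of the torsion noise, degrees.
#' @param seed Integer seed.
#' @return Perturbed `complex_structure`.
#' @export
perturb_internal <- function(x, torsion_jitter, seed = 1) {
  stopifnot(inherits(x, "complex_structure"), torsion_jitter >= 0)
  if (torsion_jitter == 0) return(x)
  withr::with_seed(seed, {
    at <- x$atoms
    for (ch in x$chains$chain_id) {
      idx <- which(at$chain == ch)
      sub <- at[idx, ]
      polymer <- sub$polymer[1]
      bonds <- if (polymer == "protein") list(c("N", "CA"), c("CA", "C"))
               else list(c("P", "O5'"), c("C4'", "C3'"))
      xyz <- as.matrix(sub[, c("x", "y", "z")])
      nm <- normalize_atom_name(sub$atom)
      for (rn in unique(sub$resno)) {
        for (bd in bonds) {
          i1 <- which(sub$resno == rn & nm == bd[1])
          i2 <- which(sub$resno == rn & nm == bd[2])
          if (length(i1) != 1L || length(i2) != 1L) next
          down <- seq_len(nrow(sub)) > i2
          if (!any(down)) next
          delta <- stats::rnorm(1, 0, torsion_jitter)
          axis <- xyz[i2, ] - xyz[i1, ]
          if (vnorm(axis) < 1e-9) next
          xyz[down, ] <- rotate_points(xyz[down, , drop = FALSE],
                                       xyz[i2, ], axis, delta)
        }
      }
      at[idx, c("x", "y", "z")] <- as.data.frame(xyz)
    }
    x$atoms <- at
    x
  })
}

# rotate a chain about a random axis through its COM, then translate it so
# the realized RMS displacement of the chain equals d_target exactly; the
# magnitude level thus pins the displacement rung (decoys graded by
# closeness), with only the direction left random
rigid_displace_to <- function(x, chain_id, d_target, rot_mag, seed) {
  if (d_target <= 0) return(x)
  withr::with_seed(seed, {
    sel <- x$atoms$chain == chain_id
    xyz0 <- as.matrix(x$atoms[sel, c("x", "y", "z")])
    com <- center_of_mass(x$atoms[sel, ])
    axis <- random_unit_vector()
    ang <- rot_mag
    xyz <- rotate_points(xyz0, com, axis, ang)
    # keep rotational displacement below the rung so translation can top up
    for (k in 1:3) {
      rms_rot <- sqrt(mean(rowSums((xyz - xyz0)^2)))
      if (rms_rot <= 0.9 * d_target) break
      ang <- ang * 0.9 * d_target / rms_rot
      xyz <- rotate_points(xyz0, com, axis, ang)
    }
    delta <- xyz - xyz0
    rms2 <- mean(rowSums(delta^2))
    u <- random_unit_vector()
    b <- sum(colMeans(delta) * u)
    disc <- b^2 + d_target^2 - rms2
    t_norm <- if (disc <= 0) 0 else -b + sqrt(disc)
    xyz <- sweep(xyz, 2, t_norm * u, `+`)
    x$atoms[sel, c("x", "y", "z")] <- as.data.frame(xyz)
    x
  })
}

#' Decoy schedule specification
#'
#' Defaults describe a docking-style degradation ladder of five rungs up to
#' a realized rigid displacement of 8 Angstrom of the RNA chain (rotation up
#' to 30 degrees, topped up by translation so each rung's chain RMS
#' displacement is exact), plus up to 10 degrees of backbone torsion noise
#' emulating small-mover refinement decoys.
#'
#' @param n_decoys Number of decoys (native excluded).
#' @param rot_max Rigid rotation at magnitude 1, degrees.
#' @param trans_max Realized chain RMS displacement at magnitude 1, A.
#' @param jitter_max Torsion jitter at magnitude 1 (deg).
#' @param n_levels Number of evenly spaced magnitude levels.
#' @param seed Integer seed.
#' @return A `decoy_spec` list.
#' @export
decoy_spec <- function(n_decoys = 50, rot_max = 30, trans_max = 8,
                       jitter_max = 10, n_levels = 5, seed = 1) {
  stopifnot(n_decoys >= 1, rot_max >= 0, trans_max >= 0, jitter_max >= 0,
            n_levels >= 1)
  structure(list(n_decoys = n_decoys, rot_max = rot_max,
                 trans_max = trans_max, jitter_max = jitter_max,
                 n_levels = n_levels, seed = seed),
            class = "decoy_spec")
}

#' Generate a graded decoy ensemble with ground-truth labels
#'
#' Decoys are dealt across the magnitude schedule (level k maps to
#' magnitude k / n_levels); every decoy is labeled by [truth_bundle()]
#' against the native.  The native itself (magnitude 0) is always row 1.
#'
#' @param native A `complex_structure` (the reference).
#' @param spec A [decoy_spec()].
#' @return Tibble: `id`, `magnitude`, list-column `decoy`, the global truth
#'   scores as columns, and a list-column `bundle` of full
#'   [truth_bundle()] results.
#' @export
decoy_set <- function(native, spec = decoy_spec()) {
  stopifnot(inherits(native, "complex_structure"), inherits(spec, "decoy_spec"))
  rna_chains <- native$chains$chain_id[native$chains$polymer_type == "rna"]
  levels <- rep_len(seq_len(spec$n_levels), spec$n_decoys)
  mags <- c(0, levels / spec$n_levels)
  decoys <- vector("list", length(mags))
  decoys[[1]] <- native
  for (j in seq_along(levels)) {
    f <- levels[j] / spec$n_levels
    d <- native
    for (ch in rna_chains) {
      d <- rigid_displace_to(d, ch, f * spec$trans_max, f * spec$rot_max,
                             seed = spec$seed + 7919L * j)
    }
    d <- perturb_internal(d, f * spec$jitter_max,
                          seed = spec$seed + 104729L * j)
    decoys[[j + 1]] <- d
  }
  bundles <- lapply(decoys, truth_bundle, reference = native)
  glob <- dplyr::bind_rows(lapply(bundles, function(b) {
    tibble::tibble(bb_lddt = b$bb_lddt, gdt_ts = b$gdt_ts, gdt_ha = b$gdt_ha,
                   ilddt = b$ilddt, ips = b$ips, ics = b$ics, irmsd = b$irmsd)
  }))
  tibble::tibble(
    id = sprintf("decoy_%03d", seq_along(mags) - 1L),
    magnitude = mags, decoy = decoys
  ) |>
    dplyr::bind_cols(glob) |>
    dplyr::mutate(bundle = bundles)
}

#' Write a decoy ensemble to PDB files with a manifest
#'
#' @param decoys Result of [decoy_set()].
#' @param native The native `complex_structure`.
#' @param dir Output directory (created if needed).
#' @param complex_id Identifier used in filenames and the manifest.
#' @return Path of the manifest TSV, invisibly.
#' @export
write_decoy_set <- function(decoys, native, dir, complex_id = "toy") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref_path <- file.path(dir, paste0(complex_id, "_native.pdb"))
  write_pdb(native, ref_path)
  paths <- vapply(seq_len(nrow(decoys)), function(i) {
    p <- file.path(dir, paste0(complex_id, "_", decoys$id[i], ".pdb"))
    write_pdb(decoys$decoy[[i]], p)
    p
  }, character(1))
  manifest <- tibble::tibble(
    complex_id = complex_id, decoy_path = paths, reference_path = ref_path,
    magnitude = decoys$magnitude
  )
  mp <- file.path(dir, paste0(complex_id, "_manifest.tsv"))
  utils::write.table(manifest, mp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(mp)
}
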