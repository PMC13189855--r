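# Featurization: 66 node channels and 12 edge channels.
#
# Annotated channels come from internal annotators (torsions, a simplified
# DSSP-style secondary-structure assigner, Shrake-Rupley solvent
# accessibility, geometric RNA base-pair detection, secondary-structure
# element decomposition, center-of-mass geometry).  Predicted channels come
# from optional provider tables and are zero-filled when absent.

#' Default feature layout
#'
#' Named channel blocks with offsets and widths for the 66-channel node and
#' 12-channel edge feature vectors.  The layout is versioned so an
#' alternative channel composition can be swapped in; block widths are
#' asserted to sum to 66 / 12 at construction.
#'
#' @return A `feature_layout` object with `node` and `edge` block tables.
#' @export
feature_layout <- function() {
  node <- tibble::tibble(
    block = c("aa_onehot", "nt_onehot", "unknown_res", "polymer_flag",
              "interface_flag", "com_geometry", "ss8", "rsa",
              "phipsi_sincos", "pred_ss3", "pred_rsa", "pred_phipsi_sincos",
              "etatheta_sincos", "rna_pair_flags", "rna_element", "valid_mask"),
    width = c(20L, 4L, 1L, 1L, 1L, 4L, 8L, 1L, 4L, 3L, 1L, 4L, 4L, 3L, 5L, 2L)
  )
  edge <- tibble::tibble(
    block = c("min_atom_dist", "anchor_dist", "orient_angles",
              "pred_protein_dist", "pred_protein_angles", "rna_pair_annot",
              "rna_pair_prob", "inter_chain", "protein_rna", "spare"),
    width = c(1L, 1L, 2L, 1L, 2L, 1L, 1L, 1L, 1L, 1L)
  )
  node$offset <- cumsum(c(0L, node$width[-nrow(node)]))
  edge$offset <- cumsum(c(0L, edge$width[-nrow(edge)]))
  stopifnot(sum(node$width) == 66L, sum(edge$width) == 12L)
  structure(list(node = node, edge = edge, version = "carpqa-layout-1"),
            class = "feature_layout")
}

layout_slice <- function(layout_tbl, block) {
  r <- layout_tbl[layout_tbl$block == block, ]
  if (nrow(r) != 1L) stop("unknown feature block: ", block)
  seq.int(r$offset + 1L, r$offset + r$width)
}

#' Channel indices of a named block
#' @param layout A [feature_layout()].
#' @param block Block name.
#' @param which `"node"` or `"edge"`.
#' @return Integer channel indices (1-based).
#' @export
feature_block <- function(layout, block, which = c("node", "edge")) {
  which <- match.arg(which)
  layout_slice(layout[[which]], block)
}

# distances mapped smoothly into [0,1); d_half is the half-saturation point
scale_dist <- function(d, d_half) d / (d + d_half)
scale_angle <- function(a) ifelse(is.na(a), 0, a / 180)

sincos <- function(deg) {
  bad <- is.na(deg)
  s <- sin(deg2rad(deg)); cs <- cos(deg2rad(deg))
  s[bad] <- 0; cs[bad] <- 0
  cbind(s, cs)
}

# ---- torsions --------------------------------------------------------------

#' Protein backbone torsions
#'
#' @param x A `complex_structure`.
#' @return Tibble: chain, resno, phi, psi (degrees, `(-180, 180]`), NA where
#'   undefined (termini or missing backbone atoms).
#' @export
backbone_torsions <- function(x) {
  res <- residues(x) |> dplyr::filter(.data$polymer == "protein")
  out <- res |> dplyr::mutate(phi = NA_real_, psi = NA_real_)
  for (ch in unique(res$chain)) {
    idx <- which(res$chain == ch)
    coords <- lapply(idx, function(i) {
      at <- res$atoms[[i]]
      list(N = atom_coord(at, "N"), CA = atom_coord(at, "CA"),
           C = atom_coord(at, "C"))
    })
    for (k in seq_along(idx)) {
      cc <- coords[[k]]
      if (k > 1) {
        pc <- coords[[k - 1]]
        if (!is.null(pc$C) && !is.null(cc$N) && !is.null(cc$CA) &&
            !is.null(cc$C) &&
            res$resno[idx[k]] == res$resno[idx[k - 1]] + 1L) {
          out$phi[idx[k]] <- dihedral(pc$C, cc$N, cc$CA, cc$C)
        }
      }
      if (k < length(idx)) {
        nc <- coords[[k + 1]]
        if (!is.null(cc$N) && !is.null(cc$CA) && !is.null(cc$C) &&
            !is.null(nc$N) &&
            res$resno[idx[k + 1]] == res$resno[idx[k]] + 1L) {
          out$psi[idx[k]] <- dihedral(cc$N, cc$CA, cc$C, nc$N)
        }
      }
    }
  }
  out |> dplyr::select("chain", "resno", "phi", "psi")
}

#' RNA pseudo-torsions eta and theta
#'
#' eta(i) = dihedral(C4'(i-1), P(i), C4'(i), P(i+1));
#' theta(i) = dihedral(P(i), C4'(i), P(i+1), C4'(i+1)).  Termini and
#' residues with missing P/C4' atoms are NA.
#'
#' @param x A `complex_structure`.
#' @return Tibble: chain, resno, eta, theta (degrees).
#' @export
rna_pseudotorsions <- function(x) {
  res <- residues(x) |> dplyr::filter(.data$polymer == "rna")
  out <- res |> dplyr::mutate(eta = NA_real_, theta = NA_real_)
  for (ch in unique(res$chain)) {
    idx <- which(res$chain == ch)
    P <- lapply(idx, function(i) atom_coord(res$atoms[[i]], "P"))
    C4 <- lapply(idx, function(i) atom_coord(res$atoms[[i]], "C4'"))
    consec <- function(a, b) res$resno[idx[b]] == res$resno[idx[a]] + 1L
    for (k in seq_along(idx)) {
      if (k > 1 && k < length(idx) && consec(k - 1, k) && consec(k, k + 1)) {
        if (!is.null(C4[[k - 1]]) && !is.null(P[[k]]) && !is.null(C4[[k]]) &&
            !is.null(P[[k + 1]])) {
          out$eta[idx[k]] <- dihedral(C4[[k - 1]], P[[k]], C4[[k]],
                                      P[[k + 1]])
        }
        if (!is.null(P[[k]]) && !is.null(C4[[k]]) && !is.null(P[[k + 1]]) &&
            !is.null(C4[[k + 1]])) {
          out$theta[idx[k]] <- dihedral(P[[k]], C4[[k]], P[[k + 1]],
                                        C4[[k + 1]])
        }
      }
    }
  }
  out |> dplyr::select("chain", "resno", "eta", "theta")
}

# ---- secondary structure ---------------------------------------------------

# Kabsch-Sander style H-bond energy between donor NH(i) and acceptor CO(j),
# kcal/mol; hydrogen rebuilt from backbone geometry
dssp_hbond_matrix <- function(N, CA, C, O, resno) {
  n <- nrow(N)
  H <- matrix(NA_real_, n, 3)
  for (i in 2:max(2, n)) {
    if (i > n) break
    if (anyNA(N[i, ]) || anyNA(C[i - 1, ]) || anyNA(CA[i, ])) next
    if (resno[i] != resno[i - 1] + 1L) next
    d <- vunit(vunit(N[i, ] - C[i - 1, ]) + vunit(N[i, ] - CA[i, ]))
    H[i, ] <- N[i, ] + 1.0 * d
  }
  hb <- matrix(FALSE, n, n)
  q <- 0.084 * 332
  for (i in seq_len(n)) {
    if (anyNA(H[i, ]) || anyNA(N[i, ])) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2) next
      if (anyNA(C[j, ]) || anyNA(O[j, ])) next
      rON <- vnorm(O[j, ] - N[i, ]); rCH <- vnorm(C[j, ] - H[i, ])
      rOH <- vnorm(O[j, ] - H[i, ]); rCN <- vnorm(C[j, ] - N[i, ])
      if (min(rON, rCH, rOH, rCN) < 0.5) next # clash: not a bond
      E <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[i, j] <- E < -0.5
    }
  }
  hb
}

#' Assign 8-state protein secondary structure
#'
#' Simplified DSSP-style assignment from backbone hydrogen bonds
#' (Kabsch-Sander electrostatic energy, bond when E < -0.5 kcal/mol):
#' helices H/G/I from consecutive 4/3/5-turns, strands E and isolated
#' bridges B from ladder bridges, turns T, bends S, otherwise '-'.
#' Chains shorter than 4 residues are all '-'.
#'
#' @param x A `complex_structure`.
#' @return Tibble: chain, resno, ss8 (one of H,G,I,E,B,T,S,-).
#' @export
assign_secondary_structure <- function(x) {
  res <- residues(x) |> dplyr::filter(.data$polymer == "protein")
  out <- res |> dplyr::mutate(ss8 = "-") |>
    dplyr::select("chain", "resno", "ss8")
  for (ch in unique(res$chain)) {
    idx <- which(res$chain == ch)
    n <- length(idx)
    if (n < 4) next
    getm <- function(nm) t(vapply(idx, function(i) {
      v <- atom_coord(res$atoms[[i]], nm)
      if (is.null(v)) rep(NA_real_, 3) else v
    }, numeric(3)))
    N <- getm("N"); CA <- getm("CA"); C <- getm("C"); O <- getm("O")
    hb <- dssp_hbond_matrix(N, CA, C, O, res$resno[idx])
    # hb[d, a]: NH of d donates to CO of a; n-turn at i <=> hb[i+n, i]
    turn <- function(i, k) i + k <= n && hb[i + k, i]
    ss <- rep("-", n)
    # helices: two consecutive n-turns
    mark_helix <- function(ss, k, code) {
      for (i in 2:n) {
        if (i + k <= n && turn(i, k) && turn(i - 1, k)) {
          ss[i:(i + k - 1)] <- ifelse(ss[i:(i + k - 1)] == "-", code,
                                      ss[i:(i + k - 1)])
        }
      }
      ss
    }
    # bridges (Kabsch-Sander definitions, Hbond(i,j) = hb[j, i])
    bridge <- matrix(FALSE, n, n)
    for (i in 2:(n - 1)) {
      for (j in 2:(n - 1)) {
        if (abs(i - j) < 3) next
        par <- (hb[j, i - 1] && hb[i + 1, j]) ||
               (hb[i, j - 1] && hb[j + 1, i])
        anti <- (hb[j, i] && hb[i, j]) ||
                (hb[j + 1, i - 1] && hb[i + 1, j - 1])
        bridge[i, j] <- par || anti
      }
    }
    in_bridge <- apply(bridge, 1, any)
    # E: bridge with an adjacent bridge residue (ladder); B: isolated
    for (i in which(in_bridge)) {
      nb <- (i > 1 && in_bridge[i - 1]) || (i < n && in_bridge[i + 1])
      ss[i] <- if (nb) "E" else "B"
    }
    ss <- mark_helix(ss, 4, "H")
    ss <- mark_helix(ss, 3, "G")
    ss <- mark_helix(ss, 5, "I")
    # turns: inside any unmarked n-turn
    for (k in 3:5) {
      for (i in seq_len(n - k)) {
        if (turn(i, k)) {
          span <- (i + 1):(i + k - 1)
          ss[span] <- ifelse(ss[span] == "-", "T", ss[span])
        }
      }
    }
    # bends: CA(i-2)-CA(i)-CA(i+2) kink > 70 degrees
    for (i in 3:(n - 2)) {
      if (ss[i] != "-") next
      if (anyNA(CA[i - 2, ]) || anyNA(CA[i, ]) || anyNA(CA[i + 2, ])) next
      kink <- vangle(CA[i - 2, ] - CA[i, ], CA[i + 2, ] - CA[i, ])
      if (kink < 110) ss[i] <- "S" # i.e. direction change > 70 deg
    }
    out$ss8[idx] <- ss
  }
  out
}

# ---- solvent accessibility -------------------------------------------------

VDW_RADIUS <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, SE = 1.90)

# Tien et al. (2013) theoretical maximum ASA, Angstrom^2
MAX_ASA_PROTEIN <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
  GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174
)

.carpqa_cache <- new.env(parent = emptyenv())

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area per atom
#'
#' @param atoms Atom tibble (element, x, y, z).
#' @param probe Probe radius, Angstrom.
#' @param n_points Sphere sample points per atom.
#' @return Numeric vector of per-atom SASA (A^2).
#' @export
shrake_rupley <- function(atoms, probe = 1.4, n_points = 144) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- VDW_RADIUS[atoms$element]
  rad[is.na(rad)] <- 1.7
  rr <- rad + probe
  sp <- fibonacci_sphere(n_points)
  n <- nrow(xyz)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * xyz %*% t(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rr[i] + rr)^2 & seq_len(n) != i)
    pts <- sweep(sp * rr[i], 2, xyz[i, ], `+`)
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
        acc <- acc & dj2 > rr[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    out[i] <- 4 * pi * rr[i]^2 * frac
  }
  out
}

max_asa_nucleotide <- function(base) {
  key <- paste0("maxasa_", base)
  if (!is.null(.carpqa_cache[[key]])) return(.carpqa_cache[[key]])
  # middle residue of an extended (unstacked) trinucleotide, computed once
  tri <- make_rna_chain(rep(base, 3),
                        torsions = list(alpha = 180, zeta = 180, beta = 180))
  sasa <- shrake_rupley(tri$atoms)
  mid <- tri$atoms$resno == 2L
  val <- sum(sasa[mid])
  .carpqa_cache[[key]] <- val
  val
}

#' Relative solvent accessibility per residue
#'
#' Shrake-Rupley SASA divided by a residue-type maximum (Tien et al.
#' theoretical values for amino acids; per-nucleotide maxima computed once
#' from an extended trinucleotide and cached), clipped to \[0, 1\].
#'
#' @param x A `complex_structure`.
#' @param probe Probe radius, Angstrom.
#' @param n_points Sphere points per atom (144 by default; the estimate is
#'   converged to well under 0.05 RSA at that sampling).
#' @return Tibble: chain, resno, rsa.
#' @export
relative_solvent_accessibility <- function(x, probe = 1.4, n_points = 144) {
  sasa <- shrake_rupley(x$atoms, probe = probe, n_points = n_points)
  per_res <- tibble::tibble(chain = x$atoms$chain, resno = x$atoms$resno,
                            resid = x$atoms$resid, polymer = x$atoms$polymer,
                            sasa = sasa) |>
    dplyr::group_by(.data$chain, .data$resno, .data$resid, .data$polymer) |>
    dplyr::summarise(sasa = sum(.data$sasa), .groups = "drop")
  mx <- numeric(nrow(per_res))
  isp <- per_res$polymer == "protein"
  mx[isp] <- MAX_ASA_PROTEIN[per_res$resid[isp]]
  if (any(!isp)) {
    mx[!isp] <- vapply(per_res$resid[!isp], max_asa_nucleotide, numeric(1))
  }
  mx[is.na(mx) | mx <= 0] <- 200
  per_res |>
    dplyr::mutate(rsa = pmin(1, .data$sasa / mx)) |>
    dplyr::select("chain", "resno", "rsa")
}

# ---- RNA base pairs and elements -------------------------------------------

RING_ATOMS <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
COMPLEMENT_PAIRS <- c("A:U", "U:A", "G:C", "C:G", "G:U", "U:G")

#' Detect RNA base pairs geometrically
#'
#' Complementary bases (A-U, G-C, G-U) whose purine-N1 / pyrimidine-N3
#' distance is <= 3.5 A with base-plane normals within 30 degrees are
#' canonical; any other base-base ring-atom contact <= 3.5 A is
#' non-canonical.  Sequence-adjacent residues of the same chain (stacking
#' neighbors) are never reported as pairs.
#'
#' @param x A `complex_structure`.
#' @return Tibble: chain_i, resno_i, chain_j, resno_j, canonical (logical),
#'   one row per unordered pair.
#' @export
annotate_rna_pairs <- function(x) {
  res <- residues(x) |> dplyr::filter(.data$polymer == "rna")
  empty <- tibble::tibble(chain_i = character(), resno_i = integer(),
                          chain_j = character(), resno_j = integer(),
                          canonical = logical())
  if (nrow(res) < 2) return(empty)
  rings <- lapply(res$atoms, function(at) {
    nm <- normalize_atom_name(at$atom)
    as.matrix(at[nm %in% RING_ATOMS, c("x", "y", "z")])
  })
  keyat <- function(at, nm0) {
    nm <- normalize_atom_name(at$atom)
    i <- which(nm == nm0)
    if (length(i)) c(at$x[i[1]], at$y[i[1]], at$z[i[1]]) else NULL
  }
  out <- list()
  for (i in seq_len(nrow(res) - 1)) {
    for (j in (i + 1):nrow(res)) {
      same_chain <- res$chain[i] == res$chain[j]
      if (same_chain && abs(res$resno[i] - res$resno[j]) <= 1L) next
      ri <- rings[[i]]; rj <- rings[[j]]
      if (nrow(ri) < 3 || nrow(rj) < 3) next
      d2 <- outer(rowSums(ri^2), rowSums(rj^2), `+`) - 2 * ri %*% t(rj)
      mind <- sqrt(max(0, min(d2)))
      if (mind > 3.5) next
      canonical <- FALSE
      combo <- paste0(res$resid[i], ":", res$resid[j])
      if (combo %in% COMPLEMENT_PAIRS) {
        pur <- if (res$resid[i] %in% PURINES) i else j
        pyr <- if (pur == i) j else i
        n1 <- keyat(res$atoms[[pur]], "N1")
        n3 <- keyat(res$atoms[[pyr]], "N3")
        if (!is.null(n1) && !is.null(n3) && vnorm(n1 - n3) <= 3.5) {
          a <- vangle(plane_normal(ri), plane_normal(rj))
          if (min(a, 180 - a) <= 30) canonical <- TRUE
        }
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        chain_i = res$chain[i], resno_i = res$resno[i],
        chain_j = res$chain[j], resno_j = res$resno[j], canonical = canonical
      )
    }
  }
  if (!length(out)) empty else dplyr::bind_rows(out)
}

# maximum non-crossing, non-conflicting subset of candidate pairs
# (Nussinov-style DP over positions 1..n with an allowed-pair matrix)
max_noncrossing_pairs <- function(pairs_ij, n) {
  if (nrow(pairs_ij) == 0) return(pairs_ij)
  allowed <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(pairs_ij))) {
    allowed[pairs_ij$i[r], pairs_ij$j[r]] <- TRUE
    allowed[pairs_ij$j[r], pairs_ij$i[r]] <- TRUE
  }
  M <- matrix(0L, n + 1, n + 1) # M[i, j+1] over interval [i, j]
  for (len in 2:n) {
    for (i in seq_len(n - len + 1)) {
      j <- i + len - 1
      best <- M[i, j] # j unpaired (interval [i, j-1])
      for (k in i:(j - 1)) {
        if (allowed[k, j]) {
          left <- if (k > i) M[i, k] else 0L
          inner <- if (j - k > 1) M[k + 1, j] else 0L
          best <- max(best, left + inner + 1L)
        }
      }
      M[i, j + 1] <- best
    }
  }
  res <- list()
  trace <- function(i, j) {
    while (i < j) {
      if (M[i, j + 1] == M[i, j]) { j <- j - 1; next }
      for (k in i:(j - 1)) {
        if (allowed[k, j]) {
          left <- if (k > i) M[i, k] else 0L
          inner <- if (j - k > 1) M[k + 1, j] else 0L
          if (left + inner + 1L == M[i, j + 1]) {
            res[[length(res) + 1L]] <<- c(k, j)
            if (j - k > 1) trace(k + 1, j - 1)
            j <- k - 1
            break
          }
        }
      }
      if (j <= i) break
      i <- i # continue with [i, j]
    }
  }
  trace(1, n)
  if (!length(res)) return(pairs_ij[0, ])
  m <- do.call(rbind, res)
  tibble::tibble(i = pmin(m[, 1], m[, 2]), j = pmax(m[, 1], m[, 2]))
}

#' RNA secondary-structure element labels
#'
#' Reduces the pair list of one chain to its maximum non-crossing nested
#' subset, then labels each residue: paired residues are `stem`; unpaired
#' residues are `hairpin`, `interior`, or `multiloop` by the number of
#' helix branches directly inside their closing pair, and `exterior` when
#' not enclosed by any pair.
#'
#' @param pairs Pair tibble as from [annotate_rna_pairs()] (intra-chain rows
#'   for `chain` are used).
#' @param x A `complex_structure` (for the chain's residue list), or an
#'   integer chain length.
#' @param chain Chain id.
#' @return Tibble: chain, resno, element.
#' @export
rna_elements <- function(pairs, x, chain) {
  if (inherits(x, "complex_structure")) {
    res <- residues(x) |>
      dplyr::filter(.data$polymer == "rna", .data$chain == !!chain)
    resno <- res$resno
  } else {
    resno <- seq_len(x)
  }
  n <- length(resno)
  pos <- stats::setNames(seq_len(n), resno)
  pp <- pairs |>
    dplyr::filter(.data$chain_i == !!chain, .data$chain_j == !!chain)
  pij <- tibble::tibble(i = unname(pos[as.character(pp$resno_i)]),
                        j = unname(pos[as.character(pp$resno_j)])) |>
    dplyr::filter(!is.na(.data$i), !is.na(.data$j))
  nested <- if (nrow(pij)) max_noncrossing_pairs(pij, n) else pij
  pt <- rep(NA_integer_, n)
  if (nrow(nested)) {
    pt[nested$i] <- nested$j
    pt[nested$j] <- nested$i
  }
  element <- rep("exterior", n)
  element[!is.na(pt)] <- "stem"
  for (k in which(is.na(pt))) {
    # innermost enclosing pair
    enc <- which(!is.na(pt) & seq_len(n) < k & pt > k)
    if (!length(enc)) next
    i0 <- max(enc); j0 <- pt[i0]
    # count helix branches strictly inside (i0, j0)
    inside <- (i0 + 1):(j0 - 1)
    branches <- 0L
    m <- i0 + 1L
    while (m < j0) {
      if (!is.na(pt[m]) && pt[m] > m && pt[m] < j0) {
        branches <- branches + 1L
        m <- pt[m] + 1L
      } else m <- m + 1L
    }
    element[k] <- if (branches == 0L) "hairpin"
                  else if (branches == 1L) "interior"
                  else "multiloop"
  }
  tibble::tibble(chain = chain, resno = resno, element = element)
}

# ---- center-of-mass geometry ----------------------------------------------

residue_orientation <- function(at, polymer, resid) {
  if (polymer == "protein") {
    a <- atom_coord(at, "CA")
    b <- if (identical(resid, "GLY")) atom_coord(at, "C")
         else atom_coord(at, "CB") %||% atom_coord(at, "C")
  } else {
    a <- atom_coord(at, "C3'")
    b <- atom_coord(at, "C1'")
  }
  if (is.null(a) || is.null(b)) return(NULL)
  b - a
}

#' Residue geometry relative to complex and chain centers of mass
#'
#' Distance from each residue's anchor atom to the center of mass of the
#' whole complex and of its own chain, plus the angle at the anchor between
#' the residue orientation vector (CA->CB for protein, CA->C for glycine;
#' C3'->C1' for RNA) and the anchor->COM direction.
#'
#' @param x A `complex_structure`.
#' @return Tibble: chain, resno, d_complex, a_complex, d_chain, a_chain
#'   (Angstrom / degrees); degenerate angles are 0.
#' @export
geometry_features <- function(x) {
  com_all <- center_of_mass(x$atoms)
  coms <- lapply(split(x$atoms, x$atoms$chain), center_of_mass)
  res <- residues(x)
  anch <- anchor_coords(x, warn = FALSE)
  res <- dplyr::inner_join(res, anch, by = c("chain", "resno"),
                           suffix = c("", ".anchor"))
  n <- nrow(res)
  out <- tibble::tibble(chain = res$chain, resno = res$resno,
                        d_complex = NA_real_, a_complex = NA_real_,
                        d_chain = NA_real_, a_chain = NA_real_)
  for (k in seq_len(n)) {
    a <- c(res$x[k], res$y[k], res$z[k])
    ov <- residue_orientation(res$atoms[[k]], res$polymer[k], res$resid[k])
    cc <- coms[[res$chain[k]]]
    out$d_complex[k] <- vnorm(com_all - a)
    out$d_chain[k] <- vnorm(cc - a)
    if (is.null(ov)) {
      out$a_complex[k] <- 0; out$a_chain[k] <- 0
    } else {
      out$a_complex[k] <- vangle(ov, com_all - a)
      out$a_chain[k] <- vangle(ov, cc - a)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- annotation bundle -----------------------------------------------------

#' Run all internal annotators over a structure
#'
#' @param x A `complex_structure`.
#' @param sasa_points Sphere points for SASA.
#' @return List of annotation tables used by [node_features()] /
#'   [edge_features()]: torsions, pseudotorsions, ss8, rsa, pairs,
#'   elements, geometry, interface.
#' @export
annotate_structure <- function(x, sasa_points = 144) {
  pairs <- annotate_rna_pairs(x)
  rna_chains <- x$chains$chain_id[x$chains$polymer_type == "rna"]
  elements <- dplyr::bind_rows(lapply(rna_chains, function(ch) {
    rna_elements(pairs, x, ch)
  }))
  list(
    torsions = backbone_torsions(x),
    pseudotorsions = rna_pseudotorsions(x),
    ss8 = assign_secondary_structure(x),
    rsa = relative_solvent_accessibility(x, n_points = sasa_points),
    pairs = pairs,
    elements = elements,
    geometry = geometry_features(x),
    interface = interface_residues(x)
  )
}

SS8_STATES <- c("H", "G", "I", "E", "B", "T", "S", "-")
RNA_ELEMENTS <- c("stem", "hairpin", "interior", "multiloop", "exterior")

#' Assemble the 66-channel node feature matrix
#'
#' @param x A `complex_structure`.
#' @param annotations Result of [annotate_structure()] (computed if NULL).
#' @param providers Optional list of provider tables (see
#'   [feature_providers()]); absent providers zero-fill their channels.
#' @param layout A [feature_layout()].
#' @return Numeric matrix N_residues x 66 with a `residues` attribute
#'   (tibble: chain, resno, resid, polymer).
#' @export
node_features <- function(x, annotations = NULL, providers = NULL,
                          layout = feature_layout()) {
  if (is.null(annotations)) annotations <- annotate_structure(x)
  res <- residues(x) |> dplyr::select("chain", "resno", "resid", "polymer")
  n <- nrow(res)
  F <- matrix(0, n, sum(layout$node$width))
  put <- function(block, vals) {
    idx <- layout_slice(layout$node, block)
    stopifnot(ncol(as.matrix(vals)) == length(idx))
    F[, idx] <<- as.matrix(vals)
  }
  is_prot <- res$polymer == "protein"
  aa <- matrix(0, n, 20); nt <- matrix(0, n, 4); unk <- numeric(n)
  ai <- match(res$resid, AA3); ni <- match(res$resid, NT1)
  for (k in seq_len(n)) {
    if (is_prot[k] && !is.na(ai[k])) aa[k, ai[k]] <- 1
    else if (!is_prot[k] && !is.na(ni[k])) nt[k, ni[k]] <- 1
    else unk[k] <- 1
  }
  put("aa_onehot", aa); put("nt_onehot", nt); put("unknown_res", unk)
  put("polymer_flag", as.numeric(is_prot))
  ifres <- dplyr::left_join(res, annotations$interface,
                            by = c("chain", "resno"))
  put("interface_flag", as.numeric(ifres$interface %||% FALSE) |>
        (\(v) ifelse(is.na(v), 0, v))())
  geom <- dplyr::left_join(res, annotations$geometry, by = c("chain", "resno"))
  put("com_geometry", cbind(scale_dist(geom$d_complex, 20),
                            scale_angle(geom$a_complex),
                            scale_dist(geom$d_chain, 20),
                            scale_angle(geom$a_chain)))
  ss <- dplyr::left_join(res, annotations$ss8, by = c("chain", "resno"))
  ssm <- matrix(0, n, 8)
  si <- match(ss$ss8, SS8_STATES)
  for (k in seq_len(n)) if (!is.na(si[k])) ssm[k, si[k]] <- 1
  put("ss8", ssm)
  rsa <- dplyr::left_join(res, annotations$rsa, by = c("chain", "resno"))
  put("rsa", ifelse(is.na(rsa$rsa), 0, rsa$rsa))
  tor <- dplyr::left_join(res, annotations$torsions, by = c("chain", "resno"))
  put("phipsi_sincos", cbind(sincos(tor$phi), sincos(tor$psi)))
  pst <- dplyr::left_join(res, annotations$pseudotorsions,
                          by = c("chain", "resno"))
  put("etatheta_sincos", cbind(sincos(pst$eta), sincos(pst$theta)))
  # RNA pair flags: canonical, non-canonical, paired-at-all
  pr <- annotations$pairs
  canon <- noncanon <- rep(FALSE, n)
  if (nrow(pr)) {
    key <- paste(res$chain, res$resno)
    for (r in seq_len(nrow(pr))) {
      ki <- match(paste(pr$chain_i[r], pr$resno_i[r]), key)
      kj <- match(paste(pr$chain_j[r], pr$resno_j[r]), key)
      for (kk in c(ki, kj)) {
        if (is.na(kk)) next
        if (pr$canonical[r]) canon[kk] <- TRUE else noncanon[kk] <- TRUE
      }
    }
  }
  put("rna_pair_flags", cbind(canon, noncanon, canon | noncanon) * 1)
  el <- dplyr::left_join(res, annotations$elements, by = c("chain", "resno"))
  elm <- matrix(0, n, 5)
  ei <- match(el$element, RNA_ELEMENTS)
  for (k in seq_len(n)) if (!is.na(ei[k])) elm[k, ei[k]] <- 1
  put("rna_element", elm)
  # predicted blocks from providers (zero when absent)
  if (!is.null(providers$protein_residue)) {
    pv <- dplyr::left_join(res, providers$protein_residue,
                           by = c("chain", "resno"))
    z <- function(v) ifelse(is.na(v), 0, v)
    put("pred_ss3", cbind(z(pv$ss3_h), z(pv$ss3_e), z(pv$ss3_c)))
    put("pred_rsa", z(pv$rsa))
    put("pred_phipsi_sincos",
        cbind(z(pv$phi_sin), z(pv$phi_cos), z(pv$psi_sin), z(pv$psi_cos)))
  }
  tor_valid <- !(is.na(tor$phi) & is.na(tor$psi) & is.na(pst$eta) &
                   is.na(pst$theta))
  put("valid_mask", cbind(as.numeric(tor_valid), 0))
  stopifnot(!anyNA(F), all(is.finite(F)))
  attr(F, "residues") <- res
  attr(F, "layout_version") <- layout$version
  F
}

#' Assemble 12-channel edge features for a set of residue pairs
#'
#' Channels: min heavy-atom distance, anchor-anchor distance, two
#' orientation-vector angles (one per endpoint, against the anchor-anchor
#' axis), predicted intra-protein distance and two angles (provider),
#' annotated RNA pair flag, predicted RNA pairing probability (provider),
#' inter-chain indicator, protein-RNA indicator, spare.
#'
#' @param x A `complex_structure`.
#' @param pairs Tibble with chain_i, resno_i, chain_j, resno_j (plus
#'   optional precomputed min_dist, anchor_dist columns).
#' @param annotations Result of [annotate_structure()] (computed if NULL).
#' @param providers Optional provider list.
#' @param layout A [feature_layout()].
#' @return Numeric matrix nrow(pairs) x 12.
#' @export
edge_features <- function(x, pairs, annotations = NULL, providers = NULL,
                          layout = feature_layout()) {
  if (is.null(annotations)) annotations <- annotate_structure(x)
  res <- residues(x)
  key <- paste(res$chain, res$resno)
  ki <- match(paste(pairs$chain_i, pairs$resno_i), key)
  kj <- match(paste(pairs$chain_j, pairs$resno_j), key)
  stopifnot(!anyNA(ki), !anyNA(kj))
  m <- nrow(pairs)
  E <- matrix(0, m, sum(layout$edge$width))
  put <- function(block, vals) {
    idx <- layout_slice(layout$edge, block)
    E[, idx] <<- as.matrix(vals)
  }
  anch <- anchor_coords(x, warn = FALSE)
  akey <- paste(anch$chain, anch$resno)
  ai <- match(paste(pairs$chain_i, pairs$resno_i), akey)
  aj <- match(paste(pairs$chain_j, pairs$resno_j), akey)
  axyz <- as.matrix(anch[, c("x", "y", "z")])
  min_dist <- if ("min_dist" %in% names(pairs)) pairs$min_dist else NULL
  if (is.null(min_dist)) {
    min_dist <- vapply(seq_len(m), function(r) {
      a <- as.matrix(res$atoms[[ki[r]]][, c("x", "y", "z")])
      b <- as.matrix(res$atoms[[kj[r]]][, c("x", "y", "z")])
      sqrt(max(0, min(outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b))))
    }, numeric(1))
  }
  anchor_dist <- if ("anchor_dist" %in% names(pairs)) pairs$anchor_dist
                 else NULL
  if (is.null(anchor_dist)) {
    anchor_dist <- sqrt(rowSums((axyz[ai, , drop = FALSE] -
                                   axyz[aj, , drop = FALSE])^2))
  }
  put("min_atom_dist", scale_dist(min_dist, 8))
  put("anchor_dist", scale_dist(anchor_dist, 14))
  ang <- matrix(0, m, 2)
  for (r in seq_len(m)) {
    if (is.na(ai[r]) || is.na(aj[r])) next
    axis <- axyz[aj[r], ] - axyz[ai[r], ]
    ovi <- residue_orientation(res$atoms[[ki[r]]], res$polymer[ki[r]],
                               res$resid[ki[r]])
    ovj <- residue_orientation(res$atoms[[kj[r]]], res$polymer[kj[r]],
                               res$resid[kj[r]])
    ang[r, 1] <- if (is.null(ovi)) 0 else vangle(ovi, axis) / 180
    ang[r, 2] <- if (is.null(ovj)) 0 else vangle(ovj, -axis) / 180
  }
  put("orient_angles", ang)
  pr <- annotations$pairs
  if (nrow(pr)) {
    pk1 <- paste(pr$chain_i, pr$resno_i, pr$chain_j, pr$resno_j)
    pk2 <- paste(pr$chain_j, pr$resno_j, pr$chain_i, pr$resno_i)
    ek <- paste(pairs$chain_i, pairs$resno_i, pairs$chain_j, pairs$resno_j)
    put("rna_pair_annot", as.numeric(ek %in% c(pk1, pk2)))
  }
  inter <- pairs$chain_i != pairs$chain_j
  put("inter_chain", as.numeric(inter))
  put("protein_rna", as.numeric(res$polymer[ki] != res$polymer[kj]))
  if (!is.null(providers$protein_pair)) {
    pp <- providers$protein_pair
    pk <- paste(pp$chain_i, pp$resno_i, pp$chain_j, pp$resno_j)
    ek1 <- paste(pairs$chain_i, pairs$resno_i, pairs$chain_j, pairs$resno_j)
    ek2 <- paste(pairs$chain_j, pairs$resno_j, pairs$chain_i, pairs$resno_i)
    hit <- match(ek1, pk); hit2 <- match(ek2, pk)
    hit[is.na(hit)] <- hit2[is.na(hit)]
    ok <- !is.na(hit)
    pd <- matrix(0, m, 1); pa <- matrix(0, m, 2)
    pd[ok, 1] <- scale_dist(pp$dist[hit[ok]], 14)
    pa[ok, 1] <- scale_angle(pp$angle1[hit[ok]])
    pa[ok, 2] <- scale_angle(pp$angle2[hit[ok]])
    put("pred_protein_dist", pd)
    put("pred_protein_angles", pa)
  }
  if (!is.null(providers$rna_pair)) {
    rp <- providers$rna_pair
    pk <- paste(rp$chain_i, rp$resno_i, rp$chain_j, rp$resno_j)
    ek1 <- paste(pairs$chain_i, pairs$resno_i, pairs$chain_j, pairs$resno_j)
    ek2 <- paste(pairs$chain_j, pairs$resno_j, pairs$chain_i, pairs$resno_i)
    hit <- match(ek1, pk); hit2 <- match(ek2, pk)
    hit[is.na(hit)] <- hit2[is.na(hit)]
    ok <- !is.na(hit)
    pv <- numeric(m)
    pv[ok] <- rp$prob[hit[ok]]
    put("rna_pair_prob", pv)
  }
  stopifnot(!anyNA(E), all(is.finite(E)))
  E
}

#' Bundle predicted-feature provider tables
#'
#' Providers stand in for external sequence-based predictors.  Each table is
#' keyed by (chain, resno) or by residue pairs; missing entries zero-fill.
#'
#' @param protein_residue Tibble: chain, resno, ss3_h, ss3_e, ss3_c, rsa,
#'   phi_sin, phi_cos, psi_sin, psi_cos.
#' @param protein_pair Tibble: chain_i, resno_i, chain_j, resno_j, dist,
#'   angle1, angle2.
#' @param rna_pair Tibble: chain_i, resno_i, chain_j, resno_j, prob.
#' @return A provider list for [node_features()] / [edge_features()].
#' @export
feature_providers <- function(protein_residue = NULL, protein_pair = NULL,
                              rna_pair = NULL) {
  chk <- function(tb) {
    if (!is.null(tb)) {
      stopifnot(all(vapply(tb[vapply(tb, is.numeric, logical(1))],
                           function(v) all(is.finite(v) | is.na(v)),
                           logical(1))))
    }
    tb
  }
  list(protein_residue = chk(protein_residue),
       protein_pair = chk(protein_pair), rna_pair = chk(rna_pair))
}

#' Read a provider table from TSV
#' @param path TSV file with a header row.
#' @return Tibble.
#' @export
read_provider_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}
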