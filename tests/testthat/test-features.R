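test_that("backbone torsions are recovered from a chain built with known phi/psi", {
  x <- make_protein_chain(rep("ALA", 10), phi = -57, psi = -47)
  tor <- backbone_torsions(x)
  expect_true(is.na(tor$phi[1]))
  expect_true(is.na(tor$psi[10]))
  expect_equal(tor$phi[2:10], rep(-57, 9), tolerance = 1e-6)
  expect_equal(tor$psi[1:9], rep(-47, 9), tolerance = 1e-6)
  # a different torsion pair round-trips too
  y <- make_protein_chain(rep("LEU", 8), phi = -120, psi = 130)
  tory <- backbone_torsions(y)
  expect_equal(tory$phi[3], -120, tolerance = 1e-6)
  expect_equal(tory$psi[3], 130, tolerance = 1e-6)
})

test_that("torsions flag undefined at chain breaks and single residues", {
  x1 <- make_protein_chain("ALA")
  t1 <- backbone_torsions(x1)
  expect_true(all(is.na(c(t1$phi, t1$psi))))
  x <- make_protein_chain(rep("ALA", 8))
  x$atoms <- x$atoms[!(x$atoms$resno == 4 & x$atoms$atom == "N"), ]
  tor <- backbone_torsions(x)
  expect_true(is.na(tor$phi[4]))   # needs its own N
  expect_false(is.na(tor$phi[3]))
  expect_false(is.na(tor$phi[6]))
})

test_that("RNA pseudo-torsions are constant on a regular helix and rotation-invariant", {
  x <- make_rna_chain(c("A", "U", "G", "C", "A", "U", "G", "C"))
  pt <- rna_pseudotorsions(x)
  inner <- 2:7
  expect_true(all(!is.na(pt$eta[inner])))
  expect_lt(diff(range(pt$eta[inner])), 1e-6)
  expect_lt(diff(range(pt$theta[inner])), 1e-6)
  expect_true(is.na(pt$eta[1]) && is.na(pt$eta[8]))
  withr::with_seed(7, {
    R <- random_rotation_matrix()
    xr <- transform_structure(x, R, c(3, -2, 9))
    ptr <- rna_pseudotorsions(xr)
    expect_equal(ptr$eta, pt$eta, tolerance = 1e-6)
    expect_equal(ptr$theta, pt$theta, tolerance = 1e-6)
  })
  x2 <- make_rna_chain(c("A", "U"))
  expect_true(all(is.na(rna_pseudotorsions(x2)$eta)))
})

test_that("secondary structure: helix interiors H, sparse chains dash", {
  helix <- make_protein_chain(rep("ALA", 12))
  ss <- assign_secondary_structure(helix)
  expect_true(all(ss$ss8[4:9] == "H"))
  ext <- make_protein_chain(rep("ALA", 10), phi = -139, psi = 135)
  sse <- assign_secondary_structure(ext)
  # a lone extended strand has no hydrogen-bond partners
  expect_true(all(sse$ss8 %in% c("-", "S")))
  tri <- make_protein_chain(rep("ALA", 3))
  expect_true(all(assign_secondary_structure(tri)$ss8 == "-"))
})

test_that("relative solvent accessibility: exposure, burial, convergence", {
  free <- make_protein_chain("ALA")
  expect_gt(relative_solvent_accessibility(free)$rsa, 0.9)
  # residue enclosed in a synthetic cage of atoms is buried
  ala <- micro_protein_res("A", 1, c(0, 0, 0))
  withr::with_seed(3, {
    pts <- matrix(stats::rnorm(3 * 400), ncol = 3)
    pts <- 5.5 * pts / sqrt(rowSums(pts^2))
  })
  cage <- dplyr::bind_rows(lapply(1:4, function(k) {
    idx <- ((k - 1) * 100 + 1):(k * 100)
    tibble::tibble(chain = "B", resno = k, resid = "ALA",
                   atom = paste0("CA", seq_along(idx)), element = "C",
                   x = pts[idx, 1], y = pts[idx, 2], z = pts[idx, 3],
                   occ = 1, polymer = "protein")
  }))
  caged <- micro_structure(ala, cage)
  rsa <- relative_solvent_accessibility(caged)
  expect_lt(rsa$rsa[rsa$chain == "A"], 0.05)
  # doubling the sphere sampling moves values by less than 0.05
  x <- toy_complex(1)
  r1 <- relative_solvent_accessibility(x)
  r2 <- relative_solvent_accessibility(x, n_points = 288)
  expect_lt(max(abs(r1$rsa - r2$rsa)), 0.05)
})

test_that("base-pair detection recovers a Watson-Crick duplex and ignores strands", {
  d <- make_rna_duplex(c("G", "A", "U", "C", "G", "G"))
  pairs <- annotate_rna_pairs(d)
  canon <- pairs[pairs$canonical, ]
  expect_gte(nrow(canon), 6)
  # every constructed WC pair (B:k with C:n+1-k) is recovered as canonical
  found <- paste(canon$chain_i, canon$resno_i, canon$chain_j, canon$resno_j)
  for (k in 1:6) {
    expect_true(paste("B", k, "C", 7 - k) %in% found ||
                  paste("C", 7 - k, "B", k) %in% found)
  }
  ss <- make_rna_chain(c("A", "C", "G", "U", "A", "C"))
  expect_equal(nrow(annotate_rna_pairs(ss)), 0L)
  # atom order within residues does not matter
  withr::with_seed(5, {
    d2 <- d
    d2$atoms <- d2$atoms[sample(nrow(d2$atoms)), ]
    d2$atoms <- dplyr::arrange(d2$atoms, match(.data$chain, c("B", "C")),
                               .data$resno)
    p2 <- annotate_rna_pairs(d2)
    key <- function(p) sort(paste(p$chain_i, p$resno_i, p$chain_j,
                                  p$resno_j, p$canonical))
    expect_equal(key(p2), key(pairs))
  })
})

test_that("element decomposition labels hairpins, tails and bulges", {
  # stem of 4 bp + 4-nt loop + 2-nt tails: positions 3..6 pair 15..12
  pairs <- tibble::tibble(chain_i = "B", resno_i = 3:6,
                          chain_j = "B", resno_j = 16:13,
                          canonical = TRUE)
  el <- rna_elements(pairs, 18L, "B")
  expect_equal(el$element[3:6], rep("stem", 4))
  expect_equal(el$element[13:16], rep("stem", 4))
  expect_equal(el$element[7:12], rep("hairpin", 6))
  expect_equal(el$element[c(1, 2, 17, 18)], rep("exterior", 4))
  # unpaired strand: everything exterior
  none <- pairs[0, ]
  expect_true(all(rna_elements(none, 8L, "B")$element == "exterior"))
  # two stems with unpaired positions between them: interior loop
  p2 <- tibble::tibble(chain_i = "B", resno_i = c(1, 2, 3, 6, 7, 8),
                       chain_j = "B", resno_j = c(20, 19, 18, 15, 14, 13),
                       canonical = TRUE)
  el2 <- rna_elements(p2, 20L, "B")
  expect_equal(el2$element[c(4, 5, 16, 17)], rep("interior", 4))
  expect_equal(el2$element[9:12], rep("hairpin", 4))
})

test_that("conflicting pairs reduce to the maximum non-crossing subset", {
  # crossing pair (2,10) vs nested pairs (1,12),(2,11),(3,9): DP keeps the
  # larger nested set
  p <- tibble::tibble(chain_i = "B", resno_i = c(1, 2, 3, 2),
                      chain_j = "B", resno_j = c(12, 11, 9, 10),
                      canonical = TRUE)
  el <- rna_elements(p, 12L, "B")
  expect_equal(sum(el$element == "stem"), 6)
})

test_that("center-of-mass geometry: hand-built right angle and rigid invariance", {
  r1 <- tibble::tibble(chain = "A", resno = 1L, resid = "ALA",
                       atom = c("CA", "CB"), element = "C",
                       x = c(0, 2), y = 0, z = 0, occ = 1,
                       polymer = "protein")
  r2 <- tibble::tibble(chain = "A", resno = 2L, resid = "ALA",
                       atom = c("CA", "CB"), element = "C",
                       x = 3, y = 10, z = 0, occ = 1, polymer = "protein")
  x <- micro_structure(r1, r2)
  # complex COM = (2, 5, 0); residue-1 anchor = CB at (2, 0, 0);
  # orientation CA->CB = +x, anchor->COM = +y: right angle, distance 5
  g <- geometry_features(x)
  expect_equal(g$d_complex[1], 5, tolerance = 1e-9)
  expect_equal(g$a_complex[1], 90, tolerance = 1e-9)
  y <- toy_complex(1)
  gy <- geometry_features(y)
  withr::with_seed(13, {
    R <- random_rotation_matrix()
    yt <- transform_structure(y, R, c(-4, 8, 1))
    gt <- geometry_features(yt)
    for (cc in c("d_complex", "a_complex", "d_chain", "a_chain")) {
      expect_equal(gt[[cc]], gy[[cc]], tolerance = 1e-6)
    }
  })
})

test_that("node features: 66 channels, clean one-hots, no NaN, zero predicted blocks", {
  x <- toy_complex(1)
  layout <- feature_layout()
  nf <- node_features(x, layout = layout)
  expect_equal(ncol(nf), 66L)
  expect_false(anyNA(nf))
  expect_true(all(is.finite(nf)))
  res <- attr(nf, "residues")
  aa <- nf[, feature_block(layout, "aa_onehot"), drop = FALSE]
  nt <- nf[, feature_block(layout, "nt_onehot"), drop = FALSE]
  expect_true(all(rowSums(aa) <= 1 & rowSums(nt) <= 1))
  expect_true(all(rowSums(aa)[res$polymer == "protein"] == 1))
  expect_true(all(rowSums(nt)[res$polymer == "rna"] == 1))
  gly <- which(res$resid == "GLY")
  expect_true(all(rowSums(aa[gly, , drop = FALSE]) == 1))
  for (blk in c("pred_ss3", "pred_rsa", "pred_phipsi_sincos")) {
    expect_true(all(nf[, feature_block(layout, blk)] == 0))
  }
  expect_equal(nf[, feature_block(layout, "polymer_flag")],
               as.numeric(res$polymer == "protein"))
})

test_that("edge features: 12 channels with correct pair indicators", {
  x <- toy_complex(1)
  layout <- feature_layout()
  res <- residues(x)
  prot <- res[res$polymer == "protein", ]
  rna <- res[res$polymer == "rna", ]
  pairs <- tibble::tibble(
    chain_i = c(prot$chain[1], prot$chain[1]),
    resno_i = c(prot$resno[1], prot$resno[1]),
    chain_j = c(prot$chain[2], rna$chain[1]),
    resno_j = c(prot$resno[2], rna$resno[1])
  )
  ef <- edge_features(x, pairs, layout = layout)
  expect_equal(ncol(ef), 12L)
  expect_false(anyNA(ef))
  ic <- feature_block(layout, "inter_chain", "edge")
  pr <- feature_block(layout, "protein_rna", "edge")
  expect_equal(ef[1, ic], 0)
  expect_equal(ef[1, pr], 0)
  expect_equal(ef[2, ic], 1)
  expect_equal(ef[2, pr], 1)
})

test_that("provider tables fill the predicted channels and zero-fill gaps", {
  x <- toy_complex(1)
  layout <- feature_layout()
  res <- residues(x)
  prot <- res[res$polymer == "protein", ]
  prov <- feature_providers(
    protein_residue = tibble::tibble(
      chain = prot$chain[1], resno = prot$resno[1],
      ss3_h = 0.8, ss3_e = 0.1, ss3_c = 0.1, rsa = 0.5,
      phi_sin = -0.8, phi_cos = 0.5, psi_sin = -0.7, psi_cos = 0.7
    )
  )
  nf <- node_features(x, providers = prov, layout = layout)
  rid <- which(attr(nf, "residues")$resno == prot$resno[1] &
                 attr(nf, "residues")$chain == prot$chain[1])
  ss3 <- feature_block(layout, "pred_ss3")
  expect_equal(nf[rid, ss3], c(0.8, 0.1, 0.1))
  expect_true(all(nf[-rid, ss3] == 0))
})

test_that("feature layout invariants hold and default widths sum correctly", {
  layout <- feature_layout()
  expect_equal(sum(layout$node$width), 66L)
  expect_equal(sum(layout$edge$width), 12L)
  # blocks contiguous and non-overlapping
  expect_equal(layout$node$offset,
               cumsum(c(0L, layout$node$width[-nrow(layout$node)])))
  expect_error(feature_block(layout, "no_such_block"), "unknown")
})

test_that("geometric node features are invariant to atom order within residues", {
  x <- toy_complex(2)
  withr::with_seed(21, {
    y <- x
    y$atoms <- y$atoms[sample(nrow(y$atoms)), ]
    y$atoms <- dplyr::arrange(y$atoms, match(.data$chain, c("A", "B")),
                              .data$resno)
  })
  gx <- geometry_features(x); gy <- geometry_features(y)
  expect_equal(gx$d_complex, gy$d_complex, tolerance = 1e-9)
  tx <- backbone_torsions(x); ty <- backbone_torsions(y)
  expect_equal(tx$phi, ty$phi, tolerance = 1e-9)
})
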