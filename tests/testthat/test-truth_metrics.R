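test_that("Kabsch superposition: identity, rotation recovery, optimality", {
  withr::with_seed(1, {
    X <- matrix(stats::rnorm(30), 10, 3)
    f0 <- kabsch_superpose(X, X)
    expect_equal(f0$rmsd, 0, tolerance = 1e-10)
    expect_equal(f0$rotation, diag(3), tolerance = 1e-8)
    R <- random_rotation_matrix()
    Y <- sweep(X %*% t(R), 2, c(4, -2, 7), `+`)
    f1 <- kabsch_superpose(Y, X)
    expect_equal(f1$rmsd, 0, tolerance = 1e-8)
    expect_equal(f1$rotation %*% R, diag(3), tolerance = 1e-6)
    expect_equal(det(f1$rotation), 1, tolerance = 1e-8)
    # noisy pair: matches the independent Euler-angle optimiser
    Z <- Y + matrix(stats::rnorm(30, 0, 0.8), 10, 3)
    expect_equal(kabsch_superpose(Z, X)$rmsd, bf_superpose_rmsd(Z, X),
                 tolerance = 1e-3)
  })
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3")
})

ca_chain <- function(xs, chain = "A", resid = "ALA") {
  rows <- lapply(seq_along(xs), function(i) tibble::tibble(
    chain = chain, resno = i, resid = resid, atom = "CA", element = "C",
    x = xs[[i]][1], y = xs[[i]][2], z = xs[[i]][3], occ = 1,
    polymer = "protein"))
  do.call(micro_structure, rows)
}

test_that("lDDT: identity, rigid invariance, and a hand-enumerated toy", {
  ref <- ca_chain(list(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)))
  expect_equal(lddt(ref, ref), 1)
  withr::with_seed(2, {
    R <- random_rotation_matrix()
    moved <- transform_structure(ref, R, c(10, -3, 2))
    expect_equal(lddt(moved, ref), 1)
  })
  # third atom moved by 3 A: pairs (1,2) exact, (1,3) and (2,3) off by 3,
  # preserved only at the 4 A threshold:
  # fractions (1/3, 1/3, 1/3, 1) -> mean 0.5
  mod <- ca_chain(list(c(0, 0, 0), c(4, 0, 0), c(11, 0, 0)))
  expect_equal(lddt(mod, ref), 0.5, tolerance = 1e-12)
})

test_that("iLDDT ignores intra-chain pairs and flags single chains", {
  x <- toy_complex(1)
  moved <- transform_structure(x, diag(3), c(20, 0, 0), chain = "B")
  il <- ilddt(moved, x)
  bl <- lddt(moved, x)
  expect_lt(il, 0.3)
  expect_lt(il, bl - 0.3)
  single <- carpqa:::new_complex_structure(
    x$atoms[x$atoms$chain == "A", ])
  v <- ilddt(single, single)
  expect_true(is.na(v))
  expect_match(attr(v, "flagged"), "inter-chain")
})

test_that("ICS is the contact-set F1: identity, zero, and 2-of-3 recovery", {
  mk <- function(b3_center) {
    p <- lapply(1:3, function(i) micro_protein_res("A", i, c(12 * i, 0, 0)))
    r <- list(micro_rna_res("B", 1, c(12, 3.5, 0)),
              micro_rna_res("B", 2, c(24, 3.5, 0)),
              micro_rna_res("B", 3, b3_center))
    do.call(micro_structure, c(p, r))
  }
  # reference contacts: A1-B1, A2-B2, A3-B3
  ref <- mk(c(36, 3.5, 0))
  expect_equal(length(bf_contacts(ref)), 3L)
  expect_equal(ics(ref, ref), 1)
  far <- transform_structure(ref, diag(3), c(0, 100, 0), "B")
  expect_equal(ics(far, ref), 0)
  # model keeps A1-B1 and A2-B2, breaks A3-B3, gains spurious A1-B3:
  # TP = 2, |model| = 3, |ref| = 3 -> precision = recall = F1 = 2/3
  mod <- mk(c(12, -3.5, 0))
  expect_equal(length(bf_contacts(mod)), 3L)
  expect_equal(ics(mod, ref), 2 / 3, tolerance = 1e-12)
})

test_that("IPS is the interface-set Jaccard: identity, disjoint, 3-of-6", {
  # four protein residues on a line; RNA residues placed either in contact
  # (4 A on y) or far away; positions chosen per scenario
  build <- function(p_pos, r_pos) {
    p <- lapply(seq_along(p_pos), function(i) {
      micro_protein_res("A", i, p_pos[[i]])
    })
    r <- lapply(seq_along(r_pos), function(i) micro_rna_res("B", i, r_pos[[i]]))
    do.call(micro_structure, c(p, r))
  }
  # reference: A1-B1 and A2-B2 in contact -> interface {A1, A2, B1, B2}
  ref <- build(list(c(0, 0, 0), c(15, 0, 0), c(30, 0, 0), c(45, 0, 0)),
               list(c(0, 4, 0), c(15, 4, 0)))
  expect_setequal(bf_iface_set(ref),
                  c("A 000001", "A 000002", "B 000001", "B 000002"))
  expect_equal(ips(ref, ref), 1)
  far <- transform_structure(ref, diag(3), c(0, 300, 0), chain = "B")
  expect_equal(ips(far, ref), 0)
  # model: A1-B1 kept; A2 pulled away; B2 now contacts A3 and A4
  # -> model interface {A1, B1, B2, A3, A4}
  # intersection with ref = {A1, B1, B2} (3); union = 6 -> Jaccard 0.5
  mod <- build(list(c(0, 0, 0), c(15, 40, 0), c(30, 0, 0), c(36, 0, 0)),
               list(c(0, 4, 0), c(33, 4, 0)))
  expect_setequal(bf_iface_set(mod),
                  c("A 000001", "B 000001", "B 000002", "A 000003",
                    "A 000004"))
  expect_equal(ips(mod, ref), 0.5, tolerance = 1e-12)
})

test_that("iRMSD: zero at identity and under rigid motion, matches optimiser", {
  x <- toy_complex(2)
  expect_equal(irmsd(x, x), 0, tolerance = 1e-9)
  withr::with_seed(3, {
    R <- random_rotation_matrix()
    moved <- transform_structure(x, R, c(5, 5, -9))
    expect_equal(irmsd(moved, x), 0, tolerance = 1e-8)
    pert <- perturb_rigid(x, "B", 15, 2, seed = 4)
    expect_equal(irmsd(pert, x), bf_irmsd(pert, x), tolerance = 1e-3)
    expect_gt(irmsd(pert, x), 0)
  })
})

test_that("approximate GDT: identity and agreement with the optimiser oracle", {
  x <- toy_complex(1)
  g0 <- gdt_approx(x, x)
  expect_equal(g0$gdt_ts, 1)
  expect_equal(g0$gdt_ha, 1)
  withr::with_seed(4, {
    R <- random_rotation_matrix()
    moved <- transform_structure(x, R, c(1, 2, 3))
    g1 <- gdt_approx(moved, x)
    expect_equal(g1$gdt_ts, 1)
    expect_equal(g1$gdt_ha, 1)
    # perturbed model: recompute fractions with the independent optimiser
    pert <- perturb_internal(x, 12, seed = 5)
    am <- anchor_coords(pert, warn = FALSE)
    ar <- anchor_coords(x, warn = FALSE)
    stopifnot(identical(paste(am$chain, am$resno), paste(ar$chain, ar$resno)))
    P <- as.matrix(am[, c("x", "y", "z")])
    Q <- as.matrix(ar[, c("x", "y", "z")])
    # independent superposition: optimise, then count threshold fractions
    cm <- colMeans(P); cf <- colMeans(Q)
    Pc <- sweep(P, 2, cm); Qc <- sweep(Q, 2, cf)
    obj <- function(ang) {
      ca <- cos(ang); sa <- sin(ang)
      Rx <- matrix(c(1, 0, 0, 0, ca[1], -sa[1], 0, sa[1], ca[1]), 3, byrow = TRUE)
      Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, byrow = TRUE)
      Rz <- matrix(c(ca[3], -sa[3], 0, sa[3], ca[3], 0, 0, 0, 1), 3, byrow = TRUE)
      sqrt(mean(rowSums((Pc %*% t(Rz %*% Ry %*% Rx) - Qc)^2)))
    }
    o <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
    ca <- cos(o$par); sa <- sin(o$par)
    Rx <- matrix(c(1, 0, 0, 0, ca[1], -sa[1], 0, sa[1], ca[1]), 3, byrow = TRUE)
    Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, byrow = TRUE)
    Rz <- matrix(c(ca[3], -sa[3], 0, sa[3], ca[3], 0, 0, 0, 1), 3, byrow = TRUE)
    d <- sqrt(rowSums((Pc %*% t(Rz %*% Ry %*% Rx) - Qc)^2))
    ts_bf <- mean(vapply(c(1, 2, 4, 8), function(t) mean(d <= t), numeric(1)))
    g2 <- gdt_approx(pert, x)
    expect_equal(g2$gdt_ts, ts_bf, tolerance = 0.02)
  })
})

test_that("truth metrics match brute-force oracles on random fixtures", {
  n_checked <- 0
  for (s in 1:12) {
    ref <- random_micro_complex(3000 + s, max_res = 4)
    mod <- perturb_rigid(ref, "B", 20, 3, seed = s)
    v <- lddt(mod, ref)
    bf <- bf_lddt(mod, ref)
    if (!is.na(bf)) expect_equal(as.numeric(v), bf, tolerance = 1e-9)
    vi <- ilddt(mod, ref)
    bfi <- bf_lddt(mod, ref, inter_only = TRUE)
    if (!is.na(bfi)) expect_equal(as.numeric(vi), bfi, tolerance = 1e-9)
    vc <- ics(mod, ref)
    bfc <- bf_ics(mod, ref)
    if (!is.na(bfc)) expect_equal(as.numeric(vc), bfc, tolerance = 1e-9)
    vp <- ips(mod, ref)
    bfp <- bf_ips(mod, ref)
    if (!is.na(bfp)) expect_equal(as.numeric(vp), bfp, tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 12)
})

test_that("self-comparison bundle is perfect and rigidly invariant", {
  x <- toy_complex(5)
  b <- truth_bundle(x, x)
  expect_equal(b$bb_lddt, 1)
  expect_equal(b$gdt_ts, 1)
  expect_equal(b$gdt_ha, 1)
  expect_equal(b$ilddt, 1)
  expect_equal(b$ips, 1)
  expect_equal(b$ics, 1)
  expect_equal(b$irmsd, 0, tolerance = 1e-9)
  expect_true(all(b$per_interface$ics == 1))
  expect_true(all(b$per_interface$ips == 1))
  withr::with_seed(6, {
    R <- random_rotation_matrix()
    pert <- perturb_rigid(x, "B", 25, 5, seed = 7)
    b1 <- truth_bundle(pert, x)
    pert_rigid <- transform_structure(pert, R, c(-3, 12, 4))
    b2 <- truth_bundle(pert_rigid, x)
    for (f in c("bb_lddt", "gdt_ts", "gdt_ha", "ilddt", "ips", "ics")) {
      expect_equal(b2[[f]], b1[[f]], tolerance = 1e-9)
    }
    expect_equal(b2$irmsd, b1$irmsd, tolerance = 1e-7)
  })
})

test_that("one-chain displacement degrades interface scores monotonically", {
  x <- toy_complex(4)
  shifts <- c(0.5, 1.5, 3, 6, 12)
  ir <- vapply(shifts, function(d) {
    irmsd(transform_structure(x, diag(3), c(d, 0, 0), chain = "B"), x)
  }, numeric(1))
  il <- vapply(shifts, function(d) {
    ilddt(transform_structure(x, diag(3), c(d, 0, 0), chain = "B"), x)
  }, numeric(1))
  expect_true(all(diff(ir) >= -1e-9))
  expect_true(all(diff(il) <= 1e-9))
})

test_that("truth_table emits one tidy row per model with per-interface columns", {
  x <- toy_complex(1)
  pert <- perturb_rigid(x, "B", 10, 2, seed = 9)
  tb <- truth_table(list(native = x, decoy = pert), x)
  expect_equal(nrow(tb), 2L)
  expect_equal(tb$bb_lddt[1], 1)
  expect_true("ics_A_B" %in% names(tb))
  expect_lt(tb$ilddt[2], 1)
})
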