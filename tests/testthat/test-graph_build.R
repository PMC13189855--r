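two_res_structure <- function(anchor_gap, extra_atom_gap = NULL) {
  # two alanines whose CB anchors are anchor_gap apart on the x axis; an
  # optional extra pair of side atoms at a controlled separate distance
  r1 <- tibble::tibble(chain = "A", resno = 1L, resid = "ALA",
                       atom = c("CA", "CB"), element = "C",
                       x = c(-1.5, 0), y = 0, z = 0, occ = 1,
                       polymer = "protein")
  r2 <- tibble::tibble(chain = "A", resno = 2L, resid = "ALA",
                       atom = c("CA", "CB"), element = "C",
                       x = anchor_gap + c(1.5, 0), y = 0, z = 0, occ = 1,
                       polymer = "protein")
  if (!is.null(extra_atom_gap)) {
    # hang one atom off each residue, extra_atom_gap apart, well below the
    # anchors on y so the anchor distance is unaffected
    r1 <- dplyr::bind_rows(r1, tibble::tibble(
      chain = "A", resno = 1L, resid = "ALA", atom = "CG1", element = "C",
      x = anchor_gap / 2 - extra_atom_gap / 2, y = -30, z = 0, occ = 1,
      polymer = "protein"))
    r2 <- dplyr::bind_rows(r2, tibble::tibble(
      chain = "A", resno = 2L, resid = "ALA", atom = "CG1", element = "C",
      x = anchor_gap / 2 + extra_atom_gap / 2, y = -30, z = 0, occ = 1,
      polymer = "protein"))
  }
  micro_structure(r1, r2)
}

adj_npairs <- function(x, ...) nrow(carpqa:::residue_adjacency(x, ...)$pairs)

test_that("edge rule: anchor distance OR any heavy-atom distance", {
  # anchors 10 A apart, every atom pair > 6 A -> edge via the anchor rule
  expect_equal(adj_npairs(two_res_structure(10)), 1L)
  # anchors 20 A apart, but one atom pair at 5 A -> edge via the atom rule
  expect_equal(adj_npairs(two_res_structure(20, extra_atom_gap = 5)), 1L)
  # anchors 20 A apart, closest atoms 8 A -> no edge
  expect_equal(adj_npairs(two_res_structure(20, extra_atom_gap = 8)), 0L)
  # boundary: exactly at the cutoffs still joins
  expect_equal(adj_npairs(two_res_structure(14)), 1L)
  expect_equal(adj_npairs(two_res_structure(14.01)), 0L)
})

test_that("edge construction equals the brute-force oracle on random fixtures", {
  for (s in 1:50) {
    x <- random_micro_complex(1000 + s)
    ra <- carpqa:::residue_adjacency(x, warn = FALSE)
    keys <- paste(ra$residues$chain, sprintf("%06d", ra$residues$resno))
    got <- sort(paste(keys[ra$pairs[, 1]], keys[ra$pairs[, 2]], sep = "|"))
    expect_identical(got, bf_edges(x))
  }
})

test_that("interface residues follow the 6 A opposite-polymer rule", {
  x <- toy_complex(1)
  ir <- interface_residues(x)
  keys <- paste(ir$chain, sprintf("%06d", ir$resno))[ir$interface]
  expect_setequal(keys, bf_iface_set(x))
  expect_gt(length(keys), 0)
  # separated chains: no interface anywhere
  far <- transform_structure(x, diag(3), c(100, 0, 0), chain = "B")
  expect_false(any(interface_residues(far)$interface))
  # flags do not depend on chain file order
  swapped <- x
  swapped$atoms <- dplyr::arrange(x$atoms, match(.data$chain, c("B", "A")))
  swapped <- carpqa:::new_complex_structure(swapped$atoms)
  ir2 <- interface_residues(swapped)
  expect_setequal(paste(ir2$chain, ir2$resno)[ir2$interface],
                  paste(ir$chain, ir$resno)[ir$interface])
})

test_that("a single contacting residue pair flags exactly those residues", {
  p <- lapply(1:3, function(i) micro_protein_res("A", i, c(14 * i, 0, 0)))
  r <- lapply(1:3, function(i) micro_rna_res("B", i, c(14 * i, 40, 0)))
  r[[2]] <- micro_rna_res("B", 2, c(28, 4.2, 0)) # near protein residue 2
  x <- do.call(micro_structure, c(p, r))
  ir <- interface_residues(x)
  flagged <- paste(ir$chain, ir$resno)[ir$interface]
  expect_setequal(flagged, c("A 2", "B 2"))
})

test_that("interface enumeration is contact-driven and deterministically ordered", {
  x <- toy_complex(1)
  expect_equal(enumerate_interfaces(x),
               tibble::tibble(protein_chain = "A", rna_chain = "B"))
  far <- transform_structure(x, diag(3), c(200, 0, 0), chain = "B")
  expect_equal(nrow(enumerate_interfaces(far)), 0L)
  # two protein chains touching one RNA
  p1 <- lapply(1:2, function(i) micro_protein_res("A", i, c(4 * i, 0, 0)))
  p2 <- lapply(1:2, function(i) micro_protein_res("C", i, c(4 * i, 12, 0)))
  r <- lapply(1:2, function(i) micro_rna_res("B", i, c(4 * i, 6, 0)))
  x2 <- do.call(micro_structure, c(p1, p2, r))
  ifs <- enumerate_interfaces(x2)
  expect_equal(ifs$protein_chain, c("A", "C"))
  expect_equal(ifs$rna_chain, c("B", "B"))
})

test_that("graph arcs are symmetric with shared features and no self-loops", {
  g <- toy_graph(1)
  expect_false(any(g$edges$from == g$edges$to))
  key <- paste(g$edges$from, g$edges$to)
  rev_key <- paste(g$edges$to, g$edges$from)
  expect_setequal(key, rev_key)
  # distance channels identical on both arc directions
  m <- match(rev_key, key)
  layout <- feature_layout()
  for (blk in c("min_atom_dist", "anchor_dist", "inter_chain",
                "protein_rna")) {
    j <- feature_block(layout, blk, "edge")
    expect_equal(g$edge_feat[m, j], g$edge_feat[, j])
  }
})

test_that("interface mask equals the union of per-interface memberships", {
  x <- toy_complex(3)
  g <- build_graph(x, sasa_points = 40)
  union_keys <- character(0)
  for (k in seq_len(nrow(g$interfaces))) {
    union_keys <- union(union_keys,
                        carpqa:::interface_set(x, 6, g$interfaces[k, ]))
  }
  mask_keys <- paste(g$nodes$chain, g$nodes$resno)[g$interface_mask]
  expect_setequal(mask_keys, union_keys)
})

test_that("connected components do not increase with a larger anchor cutoff", {
  components <- function(x, anchor_cutoff) {
    ra <- carpqa:::residue_adjacency(x, anchor_cutoff = anchor_cutoff,
                                     warn = FALSE)
    n <- nrow(ra$residues)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (nrow(ra$pairs)) {
      for (r in seq_len(nrow(ra$pairs))) {
        a <- find(ra$pairs[r, 1]); b <- find(ra$pairs[r, 2])
        if (a != b) parent[a] <- b
      }
    }
    length(unique(vapply(seq_len(n), find, integer(1))))
  }
  for (s in 1:5) {
    x <- random_micro_complex(2000 + s, max_res = 5)
    cc <- vapply(c(4, 8, 14, 25), function(ac) components(x, ac), numeric(1))
    expect_true(all(diff(cc) <= 0))
  }
})

test_that("graph dump writes inspectable node and edge tables", {
  g <- toy_graph(1)
  d <- withr::local_tempdir()
  write_graph_tables(g, d)
  nodes <- utils::read.delim(file.path(d, "nodes.tsv"))
  edges <- utils::read.delim(file.path(d, "edges.tsv"))
  expect_equal(nrow(nodes), nrow(g$nodes))
  expect_equal(nrow(edges), nrow(g$edges))
})
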