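# Residue interaction graph: nodes are residues, edges join residue pairs
# whose anchor atoms are within 14 A or whose closest heavy atoms are within
# 6 A.  Undirected edges are stored as two directed arcs sharing features,
# matching message-passing convention.

# residue-by-residue minimum heavy-atom distance matrix, with the residue
# table it indexes
residue_min_dist <- function(x) {
  at <- x$atoms
  rkey <- paste(at$chain, at$resno)
  rids <- unique(rkey)
  ridx <- match(rkey, rids)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * xyz %*% t(xyz)
  d2[d2 < 0] <- 0
  n <- length(rids)
  groups <- split(seq_along(ridx), ridx)
  # aggregate atom-level min over residue blocks (row pass then column pass)
  m1 <- matrix(NA_real_, n, nrow(d2))
  for (g in seq_len(n)) {
    m1[g, ] <- do.call(pmin, lapply(groups[[g]], function(r) d2[r, ]))
  }
  dmin <- matrix(NA_real_, n, n)
  for (g in seq_len(n)) {
    dmin[, g] <- do.call(pmin, lapply(groups[[g]], function(cc) m1[, cc]))
  }
  dmin <- sqrt(dmin)
  res_tbl <- at[!duplicated(rkey), c("chain", "resno", "resid", "polymer")]
  list(dist = dmin, residues = tibble::as_tibble(res_tbl))
}

#' Interface residues of a protein-RNA complex
#'
#' A residue is an interface residue when any of its heavy atoms lies
#' within `atom_cutoff` of any heavy atom of a chain of the opposite
#' polymer type.
#'
#' @param x A `complex_structure`.
#' @param atom_cutoff Heavy-atom distance cutoff, Angstrom.
#' @return Tibble: chain, resno, interface (logical).
#' @export
interface_residues <- function(x, atom_cutoff = 6) {
  rd <- residue_min_dist(x)
  res <- rd$residues
  opp <- outer(res$polymer, res$polymer, `!=`)
  flag <- apply(rd$dist <= atom_cutoff & opp, 1, any)
  tibble::tibble(chain = res$chain, resno = res$resno, interface = flag)
}

#' Enumerate protein-RNA interfaces
#'
#' A (protein chain, RNA chain) pair is an interface when at least one
#' residue-residue heavy-atom contact is within the cutoff.  Order is
#' deterministic: protein chain id, then RNA chain id, lexicographic.
#'
#' @param x A `complex_structure`.
#' @param atom_cutoff Heavy-atom distance cutoff, Angstrom.
#' @return Tibble: protein_chain, rna_chain.
#' @export
enumerate_interfaces <- function(x, atom_cutoff = 6) {
  rd <- residue_min_dist(x)
  res <- rd$residues
  pch <- sort(unique(res$chain[res$polymer == "protein"]))
  rch <- sort(unique(res$chain[res$polymer == "rna"]))
  out <- list()
  for (p in pch) {
    for (r in rch) {
      sub <- rd$dist[res$chain == p, res$chain == r, drop = FALSE]
      if (length(sub) && min(sub) <= atom_cutoff) {
        out[[length(out) + 1L]] <- tibble::tibble(protein_chain = p,
                                                  rna_chain = r)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(protein_chain = character(), rna_chain = character()))
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$protein_chain, .data$rna_chain)
}

# undirected edge list under the interaction rule (anchor distance OR any
# heavy-atom distance), with residues lacking anchors dropped
residue_adjacency <- function(x, anchor_cutoff = 14, atom_cutoff = 6,
                              warn = TRUE) {
  rd <- residue_min_dist(x)
  res <- rd$residues
  anch <- anchor_coords(x, warn = warn)
  akey <- paste(anch$chain, anch$resno)
  rkey <- paste(res$chain, res$resno)
  keep <- rkey %in% akey
  res <- res[keep, , drop = FALSE]
  dmin <- rd$dist[keep, keep, drop = FALSE]
  axyz <- as.matrix(anch[match(paste(res$chain, res$resno), akey),
                         c("x", "y", "z")])
  ad2 <- outer(rowSums(axyz^2), rowSums(axyz^2), `+`) - 2 * axyz %*% t(axyz)
  ad2[ad2 < 0] <- 0
  adist <- sqrt(ad2)
  adj <- (adist <= anchor_cutoff | dmin <= atom_cutoff)
  diag(adj) <- FALSE
  und <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  list(residues = res, pairs = und, dmin = dmin, adist = adist)
}

#' Build the residue interaction graph of a complex
#'
#' An edge joins residues i and j when their anchor atoms are within
#' `anchor_cutoff` or any heavy-atom pair is within `atom_cutoff`.
#' Residues without a resolvable anchor are excluded with a warning.
#'
#' @param x A `complex_structure`.
#' @param providers Optional predicted-feature providers.
#' @param layout A [feature_layout()].
#' @param anchor_cutoff Anchor-anchor distance cutoff, Angstrom.
#' @param atom_cutoff Heavy-atom distance cutoff, Angstrom (also used for
#'   the interface definition).
#' @param annotations Optional precomputed [annotate_structure()] result.
#' @param sasa_points Sphere points for the SASA annotator.
#' @return A `complex_graph`: nodes (tibble), node_feat (N x 66),
#'   edges (tibble of directed arcs i -> j), edge_feat (arcs x 12),
#'   interface_mask, interfaces, node_to_interface, layout version.
#' @export
build_graph <- function(x, providers = NULL, layout = feature_layout(),
                        anchor_cutoff = 14, atom_cutoff = 6,
                        annotations = NULL, sasa_points = 144) {
  if (nrow(dplyr::distinct(x$atoms, .data$chain, .data$resno)) < 2) {
    stop("build_graph(): need at least 2 residues")
  }
  ra <- residue_adjacency(x, anchor_cutoff, atom_cutoff)
  res <- ra$residues
  dmin <- ra$dmin
  adist <- ra$adist
  und <- ra$pairs
  n <- nrow(res)
  if (is.null(annotations)) {
    annotations <- annotate_structure(x, sasa_points = sasa_points)
  }
  nf <- node_features(x, annotations = annotations, providers = providers,
                      layout = layout)
  nf_res <- attr(nf, "residues")
  nf <- nf[match(paste(res$chain, res$resno),
                 paste(nf_res$chain, nf_res$resno)), , drop = FALSE]
  pairs <- tibble::tibble(
    chain_i = res$chain[und[, 1]], resno_i = res$resno[und[, 1]],
    chain_j = res$chain[und[, 2]], resno_j = res$resno[und[, 2]],
    min_dist = dmin[und], anchor_dist = adist[und]
  )
  ef_und <- edge_features(x, pairs, annotations = annotations,
                          providers = providers, layout = layout)
  # orientation angle channels are endpoint-specific: swap them for the
  # reverse arc
  idx_ang <- layout_slice(layout$edge, "orient_angles")
  ef_rev <- ef_und
  ef_rev[, idx_ang] <- ef_und[, rev(idx_ang)]
  edges <- tibble::tibble(
    from = c(und[, 1], und[, 2]),
    to = c(und[, 2], und[, 1])
  )
  edge_feat <- rbind(ef_und, ef_rev)
  iface_tbl <- dplyr::left_join(res, annotations$interface,
                                by = c("chain", "resno"))
  interface_mask <- ifelse(is.na(iface_tbl$interface), FALSE,
                           iface_tbl$interface)
  interfaces <- enumerate_interfaces(x, atom_cutoff = atom_cutoff)
  node_to_interface <- lapply(seq_len(nrow(interfaces)), function(k) {
    which(res$chain %in% c(interfaces$protein_chain[k],
                           interfaces$rna_chain[k]))
  })
  structure(
    list(nodes = res, node_feat = nf, edges = edges, edge_feat = edge_feat,
         interface_mask = interface_mask, interfaces = interfaces,
         node_to_interface = node_to_interface,
         layout_version = layout$version),
    class = "complex_graph"
  )
}

#' @export
print.complex_graph <- function(x, ...) {
  cat("<complex_graph> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges) / 2, " undirected edges, ",
      sum(x$interface_mask), " interface residues, ",
      nrow(x$interfaces), " protein-RNA interface(s)\n", sep = "")
  invisible(x)
}

#' Dump a graph as plain tabular files
#'
#' Writes `nodes.tsv` (residue table + features) and `edges.tsv` (arcs +
#' features) into `dir` for inspection.
#'
#' @param g A `complex_graph`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_graph_tables <- function(g, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- dplyr::bind_cols(
    g$nodes, tibble::as_tibble(as.data.frame(unclass(g$node_feat)))
  )
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  edges <- dplyr::bind_cols(
    g$edges, tibble::as_tibble(as.data.frame(g$edge_feat))
  )
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
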