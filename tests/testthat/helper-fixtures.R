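# Shared fixtures and independent brute-force oracles.
#
# Oracles deliberately use naive nested loops and their own linear algebra,
# so they share no code path with the implementation they check.

.fixture_cache <- new.env(parent = emptyenv())

toy_complex <- function(seed = 1, np = 12, nr = 8) {
  key <- paste0("toy_", seed, "_", np, "_", nr)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_toy_complex(np, nr, seed = seed)
  }
  .fixture_cache[[key]]
}

toy_graph <- function(seed = 1) {
  key <- paste0("graph_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- build_graph(toy_complex(seed), sasa_points = 60)
  }
  .fixture_cache[[key]]
}

toy_model <- function(seed = 3, hidden = 16, heads = 2) {
  key <- paste0("model_", seed, "_", hidden, "_", heads)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- init_carp(
      carp_config(hidden_dim = hidden, attention_heads = heads, seed = seed))
  }
  .fixture_cache[[key]]
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}

# minimal hand-built residues at controlled positions ("micro" structures)
micro_protein_res <- function(chain, resno, center, resid = "ALA") {
  off <- rbind(N = c(-1.2, 0.6, 0), CA = c(0, 0, 0), C = c(1.3, 0.5, 0),
               O = c(1.5, 1.7, 0), CB = c(-0.3, -1.4, 0.4))
  tibble::tibble(
    chain = chain, resno = as.integer(resno), resid = resid,
    atom = rownames(off), element = c("N", "C", "C", "O", "C"),
    x = center[1] + off[, 1], y = center[2] + off[, 2],
    z = center[3] + off[, 3], occ = 1, polymer = "protein"
  )
}

micro_rna_res <- function(chain, resno, center, resid = "A") {
  off <- rbind(P = c(-2, 1, 0.5), `O5'` = c(-1.5, 0.2, 0),
               `C4'` = c(-0.7, -0.5, 0), `C3'` = c(0, 0, 0),
               `O3'` = c(0.4, 1.3, 0), `C1'` = c(1.2, -0.8, 0.3),
               N9 = c(2.4, -0.6, 0.3), C8 = c(3.2, 0.4, 0.4),
               N7 = c(4.4, 0, 0.3), C5 = c(4.4, -1.4, 0.2),
               C4 = c(3.2, -1.8, 0.2))
  tibble::tibble(
    chain = chain, resno = as.integer(resno), resid = resid,
    atom = rownames(off),
    element = ifelse(grepl("^P", rownames(off)), "P",
                     ifelse(grepl("^O", rownames(off)), "O",
                            ifelse(grepl("^N", rownames(off)), "N", "C"))),
    x = center[1] + off[, 1], y = center[2] + off[, 2],
    z = center[3] + off[, 3], occ = 1, polymer = "rna"
  )
}

micro_structure <- function(...) {
  carpqa:::new_complex_structure(dplyr::bind_rows(...),
                                 source_path = "<micro>")
}

# ---- brute-force oracles ---------------------------------------------------

res_split <- function(x) {
  at <- x$atoms
  split(at, paste(at$chain, sprintf("%06d", at$resno)))
}

bf_min_dist <- function(ra, rb) {
  best <- Inf
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(rb))) {
      d <- sqrt((ra$x[i] - rb$x[j])^2 + (ra$y[i] - rb$y[j])^2 +
                  (ra$z[i] - rb$z[j])^2)
      if (d < best) best <- d
    }
  }
  best
}

bf_anchor <- function(r) {
  nm <- gsub("\\*", "'", toupper(r$atom))
  if (r$polymer[1] == "rna") {
    i <- which(nm == "C3'")
  } else if (r$resid[1] == "GLY" || !any(nm == "CB")) {
    i <- which(nm == "CA")
  } else {
    i <- which(nm == "CB")
  }
  if (!length(i)) return(NULL)
  c(r$x[i[1]], r$y[i[1]], r$z[i[1]])
}

# O(N^2) brute-force edge set as a sorted key vector "i|j" over residue keys
bf_edges <- function(x, anchor_cutoff = 14, atom_cutoff = 6) {
  rs <- res_split(x)
  keys <- names(rs)
  out <- character(0)
  for (i in seq_along(rs)) {
    ai <- bf_anchor(rs[[i]])
    if (is.null(ai)) next
    for (j in seq_along(rs)) {
      if (j <= i) next
      aj <- bf_anchor(rs[[j]])
      if (is.null(aj)) next
      ok <- sqrt(sum((ai - aj)^2)) <= anchor_cutoff ||
        bf_min_dist(rs[[i]], rs[[j]]) <= atom_cutoff
      if (ok) out <- c(out, paste(keys[i], keys[j], sep = "|"))
    }
  }
  sort(out)
}

bf_backbone <- function(x) {
  at <- x$atoms
  nm <- gsub("\\*", "'", toupper(at$atom))
  keep <- (at$polymer == "protein" & nm %in% c("N", "CA", "C", "O")) |
    (at$polymer == "rna" & nm %in% c("P", "C3'", "C4'", "O3'", "O5'"))
  at <- at[keep, ]
  at$nm <- nm[keep]
  at
}

bf_lddt <- function(model, reference, inter_only = FALSE,
                    radius = 15, thresholds = c(0.5, 1, 2, 4)) {
  rb <- bf_backbone(reference); mb <- bf_backbone(model)
  mkey <- paste(mb$chain, mb$resno, mb$nm)
  hits <- match(paste(rb$chain, rb$resno, rb$nm), mkey)
  ok <- !is.na(hits)
  rb <- rb[ok, ]; mb <- mb[hits[ok], ]
  total <- 0; kept <- numeric(length(thresholds))
  for (i in seq_len(nrow(rb))) {
    for (j in seq_len(nrow(rb))) {
      if (j <= i) next
      if (rb$chain[i] == rb$chain[j] && rb$resno[i] == rb$resno[j]) next
      if (inter_only && rb$chain[i] == rb$chain[j]) next
      dr <- sqrt((rb$x[i] - rb$x[j])^2 + (rb$y[i] - rb$y[j])^2 +
                   (rb$z[i] - rb$z[j])^2)
      if (dr > radius) next
      dm <- sqrt((mb$x[i] - mb$x[j])^2 + (mb$y[i] - mb$y[j])^2 +
                   (mb$z[i] - mb$z[j])^2)
      total <- total + 1
      for (t in seq_along(thresholds)) {
        if (abs(dm - dr) <= thresholds[t]) kept[t] <- kept[t] + 1
      }
    }
  }
  if (total == 0) return(NA_real_)
  mean(kept / total)
}

bf_contacts <- function(x, cutoff = 5) {
  rs <- res_split(x)
  keys <- names(rs)
  out <- character(0)
  for (i in seq_along(rs)) {
    for (j in seq_along(rs)) {
      if (j <= i) next
      if (rs[[i]]$chain[1] == rs[[j]]$chain[1]) next
      if (bf_min_dist(rs[[i]], rs[[j]]) <= cutoff) {
        out <- c(out, paste(keys[i], keys[j], sep = "|"))
      }
    }
  }
  out
}

bf_ics <- function(model, reference, cutoff = 5) {
  rc <- bf_contacts(reference, cutoff)
  if (!length(rc)) return(NA_real_)
  mc <- bf_contacts(model, cutoff)
  tp <- length(intersect(mc, rc))
  if (tp == 0) return(0)
  p <- tp / length(mc); r <- tp / length(rc)
  2 * p * r / (p + r)
}

bf_iface_set <- function(x, cutoff = 6) {
  rs <- res_split(x)
  keys <- names(rs)
  out <- character(0)
  for (i in seq_along(rs)) {
    for (j in seq_along(rs)) {
      if (i == j) next
      if (rs[[i]]$polymer[1] == rs[[j]]$polymer[1]) next
      if (bf_min_dist(rs[[i]], rs[[j]]) <= cutoff) {
        out <- c(out, keys[i])
        break
      }
    }
  }
  unique(out)
}

bf_ips <- function(model, reference, cutoff = 6) {
  a <- bf_iface_set(model, cutoff); b <- bf_iface_set(reference, cutoff)
  u <- union(a, b)
  if (!length(u)) return(NA_real_)
  length(intersect(a, b)) / length(u)
}

# superposition by direct optimisation over Euler angles (independent of
# the SVD route)
bf_superpose_rmsd <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(as.matrix(moving), 2, cm); Q <- sweep(as.matrix(fixed), 2, cf)
  obj <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rx <- matrix(c(1, 0, 0, 0, ca[1], -sa[1], 0, sa[1], ca[1]), 3, byrow = TRUE)
    Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, byrow = TRUE)
    Rz <- matrix(c(ca[3], -sa[3], 0, sa[3], ca[3], 0, 0, 0, 1), 3, byrow = TRUE)
    R <- Rz %*% Ry %*% Rx
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  best <- Inf
  for (st in list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0),
                  c(0, 0, pi / 2), c(pi, 0, 0), c(0.5, 1.2, -0.7))) {
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

bf_irmsd <- function(model, reference, cutoff = 10) {
  rs <- res_split(reference)
  ifres <- character(0)
  for (i in seq_along(rs)) {
    for (j in seq_along(rs)) {
      if (i == j) next
      if (rs[[i]]$polymer[1] == rs[[j]]$polymer[1]) next
      if (bf_min_dist(rs[[i]], rs[[j]]) <= cutoff) {
        ifres <- c(ifres, names(rs)[i])
        break
      }
    }
  }
  rb <- bf_backbone(reference)
  rb <- rb[paste(rb$chain, sprintf("%06d", rb$resno)) %in% ifres, ]
  mb <- bf_backbone(model)
  hits <- match(paste(rb$chain, rb$resno, rb$nm),
                paste(mb$chain, mb$resno, mb$nm))
  ok <- !is.na(hits)
  bf_superpose_rmsd(mb[hits[ok], c("x", "y", "z")],
                    rb[ok, c("x", "y", "z")])
}

# random small structures with a protein and an RNA chain for oracle sweeps
random_micro_complex <- function(seed, max_res = 6) {
  withr::with_seed(seed, {
    np <- sample(2:max_res, 1)
    nr <- sample(2:max_res, 1)
    spread <- stats::runif(1, 4, 14)
    rows <- list()
    for (i in seq_len(np)) {
      rows[[length(rows) + 1L]] <-
        micro_protein_res("A", i, stats::rnorm(3, 0, spread))
    }
    for (i in seq_len(nr)) {
      rows[[length(rows) + 1L]] <-
        micro_rna_res("B", i, stats::rnorm(3, 0, spread))
    }
    do.call(micro_structure, rows)
  })
}
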