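# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape records matrix-valued nodes and their backward closures; the model
# builds its forward pass on a tape, and ag_backward() accumulates
# gradients in reverse topological (= creation) order.  Only the operations
# the graph-transformer needs are implemented; every backward rule is
# checked against finite differences in the test suite.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$vals <- list()
  t$parents <- list()
  t$backfns <- list()
  t$n <- 0L
  t
}

ag_push <- function(tape, val, parents = integer(0), backfn = NULL) {
  tape$n <- tape$n + 1L
  tape$vals[[tape$n]] <- val
  tape$parents[[tape$n]] <- parents
  tape$backfns[[tape$n]] <- backfn
  structure(list(t = tape, i = tape$n), class = "ag")
}

ag_val <- function(x) x$t$vals[[x$i]]

as_mat <- function(v) {
  if (is.matrix(v)) v else matrix(v, ncol = 1)
}

#' @noRd
ag_const <- function(tape, v) ag_push(tape, as_mat(v))

# leaf with gradient tracking (parameters)
ag_param <- function(tape, v) ag_push(tape, as_mat(v), parents = NA_integer_)

ag_mm <- function(a, b) {
  A <- ag_val(a); B <- ag_val(b)
  ag_push(a$t, A %*% B, c(a$i, b$i), function(G) {
    list(G %*% t(B), t(A) %*% G)
  })
}

ag_t <- function(a) {
  A <- ag_val(a)
  ag_push(a$t, t(A), a$i, function(G) list(t(G)))
}

# elementwise binary with row-vector / scalar / column-vector broadcasting
# on the second argument; plain numerics are wrapped as constants
ag_ew <- function(a, b, fw, bwa, bwb) {
  if (!inherits(b, "ag")) b <- ag_const(a$t, b)
  A <- ag_val(a); B <- ag_val(b)
  bc <- if (identical(dim(A), dim(B))) "none"
        else if (nrow(B) == 1L && ncol(B) == ncol(A)) "row"
        else if (ncol(B) == 1L && nrow(B) == nrow(A)) "col"
        else if (all(dim(B) == c(1L, 1L))) "scalar"
        else stop("ag: incompatible shapes")
  Bx <- switch(bc,
    none = B,
    row = matrix(B, nrow(A), ncol(A), byrow = TRUE),
    col = matrix(B, nrow(A), ncol(A)),
    scalar = matrix(B[1, 1], nrow(A), ncol(A))
  )
  unbc <- function(G) switch(bc,
    none = G,
    row = matrix(colSums(G), 1),
    col = matrix(rowSums(G), ncol = 1),
    scalar = matrix(sum(G), 1, 1)
  )
  ag_push(a$t, fw(A, Bx), c(a$i, b$i), function(G) {
    list(bwa(G, A, Bx), unbc(bwb(G, A, Bx)))
  })
}

ag_add <- function(a, b) ag_ew(a, b, `+`, function(G, A, B) G,
                               function(G, A, B) G)
ag_sub <- function(a, b) ag_ew(a, b, `-`, function(G, A, B) G,
                               function(G, A, B) -G)
ag_mul <- function(a, b) ag_ew(a, b, `*`, function(G, A, B) G * B,
                               function(G, A, B) G * A)
ag_div <- function(a, b) ag_ew(a, b, `/`, function(G, A, B) G / B,
                               function(G, A, B) -G * A / B^2)

ag_scale <- function(a, k) {
  A <- ag_val(a)
  ag_push(a$t, A * k, a$i, function(G) list(G * k))
}

ag_addc <- function(a, k) {
  A <- ag_val(a)
  ag_push(a$t, A + k, a$i, function(G) list(G))
}

ag_relu <- function(a) {
  A <- ag_val(a)
  ag_push(a$t, pmax(A, 0), a$i, function(G) list(G * (A > 0)))
}

ag_sigmoid <- function(a) {
  A <- ag_val(a)
  S <- 1 / (1 + exp(-A))
  ag_push(a$t, S, a$i, function(G) list(G * S * (1 - S)))
}

ag_tanh <- function(a) {
  A <- ag_val(a)
  Th <- tanh(A)
  ag_push(a$t, Th, a$i, function(G) list(G * (1 - Th^2)))
}

ag_sqrt <- function(a) {
  A <- ag_val(a)
  S <- sqrt(A)
  ag_push(a$t, S, a$i, function(G) list(G / (2 * S)))
}

ag_abs <- function(a) {
  A <- ag_val(a)
  ag_push(a$t, abs(A), a$i, function(G) list(G * sign(A)))
}

ag_gather <- function(a, idx) {
  A <- ag_val(a)
  ag_push(a$t, A[idx, , drop = FALSE], a$i, function(G) {
    D <- matrix(0, nrow(A), ncol(A))
    rs <- rowsum(G, group = idx) # idx may repeat
    D[as.integer(rownames(rs)), ] <- rs
    list(D)
  })
}

# scatter-add rows of a into n bins given by idx (length nrow(a))
ag_scatter <- function(a, idx, n) {
  A <- ag_val(a)
  S <- matrix(0, n, ncol(A))
  rs <- rowsum(A, group = idx)
  S[as.integer(rownames(rs)), ] <- rs
  ag_push(a$t, S, a$i, function(G) list(G[idx, , drop = FALSE]))
}

ag_rowsum <- function(a) {
  A <- ag_val(a)
  ag_push(a$t, matrix(rowSums(A), ncol = 1), a$i, function(G) {
    list(matrix(G, nrow(A), ncol(A)))
  })
}

ag_colmean <- function(a) {
  A <- ag_val(a)
  ag_push(a$t, matrix(colMeans(A), 1), a$i, function(G) {
    list(matrix(G, nrow(A), ncol(A), byrow = TRUE) / nrow(A))
  })
}

ag_sum <- function(a) {
  A <- ag_val(a)
  ag_push(a$t, matrix(sum(A), 1, 1), a$i, function(G) {
    list(matrix(G[1, 1], nrow(A), ncol(A)))
  })
}

ag_mean <- function(a) {
  A <- ag_val(a)
  ag_push(a$t, matrix(mean(A), 1, 1), a$i, function(G) {
    list(matrix(G[1, 1] / length(A), nrow(A), ncol(A)))
  })
}

ag_concat <- function(a, b) {
  A <- ag_val(a); B <- ag_val(b)
  ag_push(a$t, cbind(A, B), c(a$i, b$i), function(G) {
    list(G[, seq_len(ncol(A)), drop = FALSE],
         G[, ncol(A) + seq_len(ncol(B)), drop = FALSE])
  })
}

# row-wise softmax (square or rectangular matrix)
ag_softmax_rows <- function(a) {
  A <- ag_val(a)
  M <- A - apply(A, 1, max)
  E <- exp(M)
  S <- E / rowSums(E)
  ag_push(a$t, S, a$i, function(G) {
    list(S * (G - rowSums(S * G)))
  })
}

# softmax of a column vector within segments
ag_softmax_seg <- function(a, seg) {
  A <- ag_val(a)
  v <- A[, 1]
  mx <- tapply(v, seg, max)[as.character(seg)]
  e <- exp(v - mx)
  tot <- tapply(e, seg, sum)[as.character(seg)]
  S <- matrix(e / tot, ncol = 1)
  ag_push(a$t, S, a$i, function(G) {
    g <- G[, 1]
    dot <- tapply(S[, 1] * g, seg, sum)[as.character(seg)]
    list(matrix(S[, 1] * (g - dot), ncol = 1))
  })
}

# backward pass from a scalar node; returns list of gradients indexed by
# node id (NULL where not reached)
ag_backward <- function(tape, loss) {
  stopifnot(all(dim(ag_val(loss)) == c(1L, 1L)))
  grads <- vector("list", tape$n)
  grads[[loss$i]] <- matrix(1, 1, 1)
  for (k in seq(loss$i, 1L)) {
    G <- grads[[k]]
    if (is.null(G)) next
    bf <- tape$backfns[[k]]
    if (is.null(bf)) next
    ps <- tape$parents[[k]]
    pg <- bf(G)
    for (m in seq_along(ps)) {
      p <- ps[m]
      if (is.na(p)) next
      if (is.null(grads[[p]])) grads[[p]] <- pg[[m]]
      else grads[[p]] <- grads[[p]] + pg[[m]]
    }
  }
  grads
}
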