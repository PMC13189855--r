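# The graph-transformer quality-assessment network.
#
# Three components, each followed by learned top-k pooling: (1) a GPS-style
# block mixing a full multi-head self-attention over node features with an
# edge-conditioned neighborhood aggregation (GINE-style), (2) an attention-
# weighted message-passing layer along edges (TransformerConv-style),
# (3) the same after pruning every arc that does not connect a protein node
# to an RNA node.  Three global-attention-pooling heads read the final node
# embeddings concatenated with the raw interface and polymer indicators:
# fold (3 outputs), interface (3 outputs) and per-interface (2 outputs per
# protein-RNA interface, attention masked to that interface's chain pair).
# GraphNorm and ReLU throughout; sigmoid on every output.

#' Model configuration
#'
#' @param hidden_dim Node embedding width (divisible by `attention_heads`).
#' @param attention_heads Number of attention heads.
#' @param topk_ratio Top-k pooling keep-ratio per component, in (0, 1];
#'   recycled to length 3.
#' @param dropout Dropout probability on node embeddings (training only).
#' @param head_hidden Hidden width of the readout MLPs.
#' @param seed Seed for parameter initialization.
#' @return A `carp_config` list.
#' @export
carp_config <- function(hidden_dim = 64, attention_heads = 4,
                        topk_ratio = 0.8, dropout = 0.1,
                        head_hidden = NULL, seed = 1) {
  if (hidden_dim <= 0 || attention_heads <= 0) {
    stop("carp_config(): dimensions must be positive")
  }
  if (hidden_dim %% attention_heads != 0) {
    stop("carp_config(): hidden_dim must be divisible by attention_heads")
  }
  topk_ratio <- rep_len(topk_ratio, 3)
  if (any(topk_ratio <= 0 | topk_ratio > 1)) {
    stop("carp_config(): topk_ratio must lie in (0, 1]")
  }
  if (is.null(head_hidden)) head_hidden <- hidden_dim
  structure(list(hidden_dim = hidden_dim,
                 attention_heads = attention_heads,
                 topk_ratio = topk_ratio, dropout = dropout,
                 head_hidden = head_hidden, seed = seed),
            class = "carp_config")
}

xavier <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

#' Initialize model parameters
#'
#' Deterministic given `config$seed` (and `seed` when supplied).
#'
#' @param config A [carp_config()].
#' @param layout A [feature_layout()] the model is bound to.
#' @param seed Optional override of `config$seed`.
#' @return A `carp_model`: list with `params` (named matrices), `config`,
#'   `layout_version`, `n_params`.
#' @export
init_carp <- function(config = carp_config(), layout = feature_layout(),
                      seed = NULL) {
  stopifnot(inherits(config, "carp_config"))
  h <- config$hidden_dim
  nh <- config$attention_heads
  dh <- h %/% nh
  d_node <- sum(layout$node$width)
  d_edge <- sum(layout$edge$width)
  hh <- config$head_hidden
  params <- list()
  withr::with_seed(seed %||% config$seed, {
    params[["embed.W"]] <- xavier(d_node, h)
    params[["embed.b"]] <- matrix(0, 1, h)
    for (k in seq_len(nh)) {
      for (nm in c("Wq", "Wk", "Wv")) {
        params[[paste0("c1.attn", k, ".", nm)]] <- xavier(h, dh)
      }
    }
    params[["c1.attn.Wo"]] <- xavier(h, h)
    params[["c1.gine.We"]] <- xavier(d_edge, h)
    params[["c1.gine.Wn"]] <- xavier(h, h)
    params[["c1.gine.b"]] <- matrix(0, 1, h)
    for (comp in c("c2", "c3")) {
      for (k in seq_len(nh)) {
        for (nm in c("Wq", "Wk", "Wv")) {
          params[[paste0(comp, ".h", k, ".", nm)]] <- xavier(h, dh)
        }
        params[[paste0(comp, ".h", k, ".Wek")]] <- xavier(d_edge, dh)
        params[[paste0(comp, ".h", k, ".Wev")]] <- xavier(d_edge, dh)
      }
      params[[paste0(comp, ".Wroot")]] <- xavier(h, h)
    }
    for (comp in c("c1", "c2", "c3")) {
      params[[paste0(comp, ".norm.gamma")]] <- matrix(1, 1, h)
      params[[paste0(comp, ".norm.beta")]] <- matrix(0, 1, h)
      params[[paste0(comp, ".pool.p")]] <- matrix(stats::rnorm(h) / sqrt(h),
                                                  h, 1)
    }
    for (head in c("fold", "iface", "perif")) {
      nout <- if (head == "perif") 2L else 3L
      din <- h + 2L
      params[[paste0(head, ".gate.W")]] <- xavier(din, 1)
      params[[paste0(head, ".gate.b")]] <- matrix(0, 1, 1)
      params[[paste0(head, ".val.W")]] <- xavier(din, hh)
      params[[paste0(head, ".mlp.W1")]] <- xavier(hh, hh)
      params[[paste0(head, ".mlp.b1")]] <- matrix(0, 1, hh)
      params[[paste0(head, ".mlp.W2")]] <- xavier(hh, nout)
      params[[paste0(head, ".mlp.b2")]] <- matrix(0, 1, nout)
    }
  })
  structure(list(params = params, config = config,
                 layout_version = layout$version,
                 n_params = sum(vapply(params, length, numeric(1)))),
            class = "carp_model")
}

#' @export
print.carp_model <- function(x, ...) {
  cat("<carp_model> hidden", x$config$hidden_dim, "| heads",
      x$config$attention_heads, "| pool ratios",
      paste(x$config$topk_ratio, collapse = "/"), "|",
      x$n_params, "parameters | layout", x$layout_version, "\n")
  invisible(x)
}

# ---- forward pass ----------------------------------------------------------

# multi-head full attention over node features (GPS global branch)
fw_global_attention <- function(X, P, nh, dh) {
  heads <- vector("list", nh)
  for (k in seq_len(nh)) {
    Q <- ag_mm(X, P[[paste0("c1.attn", k, ".Wq")]])
    K <- ag_mm(X, P[[paste0("c1.attn", k, ".Wk")]])
    V <- ag_mm(X, P[[paste0("c1.attn", k, ".Wv")]])
    A <- ag_softmax_rows(ag_scale(ag_mm(Q, ag_t(K)), 1 / sqrt(dh)))
    heads[[k]] <- ag_mm(A, V)
  }
  Hcat <- Reduce(ag_concat, heads)
  ag_mm(Hcat, P[["c1.attn.Wo"]])
}

# GINE-style neighborhood aggregation with edge features
fw_gine <- function(X, Ef, src, dst, n, P) {
  if (length(src) == 0) {
    return(ag_add(ag_mm(X, P[["c1.gine.Wn"]]), P[["c1.gine.b"]]))
  }
  Xe <- ag_relu(ag_add(ag_gather(X, src), ag_mm(Ef, P[["c1.gine.We"]])))
  M <- ag_scatter(Xe, dst, n)
  ag_add(ag_mm(ag_add(X, M), P[["c1.gine.Wn"]]), P[["c1.gine.b"]])
}

# TransformerConv-style attention message passing along arcs
fw_transformer_conv <- function(X, Ef, src, dst, n, P, comp, nh, dh) {
  root <- ag_mm(X, P[[paste0(comp, ".Wroot")]])
  if (length(src) == 0) return(root)
  heads <- vector("list", nh)
  for (k in seq_len(nh)) {
    pre <- paste0(comp, ".h", k, ".")
    Q <- ag_mm(X, P[[paste0(pre, "Wq")]])
    K <- ag_mm(X, P[[paste0(pre, "Wk")]])
    V <- ag_mm(X, P[[paste0(pre, "Wv")]])
    Ke <- ag_add(ag_gather(K, src), ag_mm(Ef, P[[paste0(pre, "Wek")]]))
    Ve <- ag_add(ag_gather(V, src), ag_mm(Ef, P[[paste0(pre, "Wev")]]))
    s <- ag_scale(ag_rowsum(ag_mul(ag_gather(Q, dst), Ke)), 1 / sqrt(dh))
    alpha <- ag_softmax_seg(s, dst)
    heads[[k]] <- ag_scatter(ag_mul(Ve, alpha), dst, n)
  }
  ag_add(root, Reduce(ag_concat, heads))
}

# GraphNorm (mean/variance over the graph's nodes per channel, learned
# scale and shift), then ReLU
fw_norm_relu <- function(X, P, comp) {
  mu <- ag_colmean(X)
  xc <- ag_sub(X, mu)
  v <- ag_colmean(ag_mul(xc, xc))
  Xn <- ag_div(xc, ag_sqrt(ag_addc(v, 1e-5)))
  ag_relu(ag_add(ag_mul(Xn, P[[paste0(comp, ".norm.gamma")]]),
                 P[[paste0(comp, ".norm.beta")]]))
}

# learned top-k pooling: keep ceiling(ratio * n) nodes by score X p, gate
# survivors by tanh(score); ties broken by original node index
fw_topk <- function(X, P, comp, ratio, prov) {
  p <- P[[paste0(comp, ".pool.p")]]
  y <- ag_mm(X, p)
  yv <- ag_val(y)[, 1]
  n <- length(yv)
  k <- max(1L, ceiling(ratio * n))
  keep <- order(-yv, seq_len(n))[seq_len(k)]
  keep <- sort(keep)
  Xp <- ag_mul(ag_gather(X, keep), ag_tanh(ag_gather(y, keep)))
  list(X = Xp, keep = keep, prov = prov[keep])
}

subset_arcs <- function(src, dst, keep) {
  pos <- match(seq_along(keep), keep) # not used; remap below
  remap <- rep(NA_integer_, max(c(src, dst, keep)))
  remap[keep] <- seq_along(keep)
  ok <- src %in% keep & dst %in% keep
  list(src = remap[src[ok]], dst = remap[dst[ok]], sel = which(ok))
}

fw_dropout <- function(X, p) {
  if (p <= 0) return(X)
  A <- ag_val(X)
  mask <- matrix(stats::rbinom(length(A), 1, 1 - p), nrow(A)) / (1 - p)
  ag_mul(X, mask)
}

# global attention pooling readout over a node subset
fw_gap_head <- function(Hfeat, rows, P, head) {
  Hs <- ag_gather(Hfeat, rows)
  gl <- ag_add(ag_mm(Hs, P[[paste0(head, ".gate.W")]]),
               P[[paste0(head, ".gate.b")]])
  alpha <- ag_softmax_seg(gl, rep(1L, length(rows)))
  HV <- ag_mm(Hs, P[[paste0(head, ".val.W")]])
  r <- ag_mm(ag_t(alpha), HV)
  z <- ag_relu(ag_add(ag_mm(r, P[[paste0(head, ".mlp.W1")]]),
                      P[[paste0(head, ".mlp.b1")]]))
  ag_sigmoid(ag_add(ag_mm(z, P[[paste0(head, ".mlp.W2")]]),
                    P[[paste0(head, ".mlp.b2")]]))
}

# full forward pass on a tape; returns output nodes and parameter ids so a
# loss can be built on the same tape
carp_forward_tape <- function(graph, model, training = FALSE) {
  stopifnot(inherits(graph, "complex_graph"), inherits(model, "carp_model"))
  if (!identical(graph$layout_version, model$layout_version)) {
    stop("feature layout version mismatch: graph ", graph$layout_version,
         " vs model ", model$layout_version)
  }
  n <- nrow(graph$nodes)
  if (n < 1) stop("carp_forward(): empty graph")
  cfg <- model$config
  nh <- cfg$attention_heads
  dh <- cfg$hidden_dim %/% nh
  tape <- ag_tape()
  P <- lapply(model$params, function(m) ag_param(tape, m))
  param_ids <- vapply(P, function(x) x$i, integer(1))
  X0 <- ag_const(tape, graph$node_feat)
  src <- graph$edges$from
  dst <- graph$edges$to
  Ef <- ag_const(tape, graph$edge_feat)
  drop_p <- if (training) cfg$dropout else 0
  # component 1: GPS block (global attention + GINE) + pool
  X <- ag_add(ag_mm(X0, P[["embed.W"]]), P[["embed.b"]])
  a1 <- fw_global_attention(X, P, nh, dh)
  g1 <- fw_gine(X, Ef, src, dst, n, P)
  X1 <- fw_norm_relu(ag_add(ag_add(X, a1), g1), P, "c1")
  X1 <- fw_dropout(X1, drop_p)
  pool1 <- fw_topk(X1, P, "c1", cfg$topk_ratio[1], seq_len(n))
  s1 <- subset_arcs(src, dst, pool1$keep)
  Ef1 <- if (length(s1$sel)) ag_gather(Ef, s1$sel) else Ef
  # component 2: TransformerConv + pool
  n1 <- length(pool1$keep)
  X2 <- fw_transformer_conv(pool1$X, Ef1, s1$src, s1$dst, n1, P, "c2", nh, dh)
  X2 <- fw_norm_relu(X2, P, "c2")
  X2 <- fw_dropout(X2, drop_p)
  pool2 <- fw_topk(X2, P, "c2", cfg$topk_ratio[2], pool1$prov)
  s2 <- subset_arcs(s1$src, s1$dst, pool2$keep)
  # prune arcs that do not connect a protein node to an RNA node
  polymer <- graph$nodes$polymer
  pr <- polymer[pool2$prov[s2$src]] != polymer[pool2$prov[s2$dst]]
  s2p <- list(src = s2$src[pr], dst = s2$dst[pr],
              sel = s1$sel[s2$sel][pr])
  Ef2 <- if (length(s2p$sel)) ag_gather(Ef, s2p$sel) else Ef
  # component 3: TransformerConv on the pruned graph + pool
  n2 <- length(pool2$keep)
  X3pre <- fw_transformer_conv(pool2$X, Ef2, s2p$src, s2p$dst, n2, P, "c3",
                               nh, dh)
  X3pre <- fw_norm_relu(X3pre, P, "c3")
  X3pre <- fw_dropout(X3pre, drop_p)
  pool3 <- fw_topk(X3pre, P, "c3", cfg$topk_ratio[3], pool2$prov)
  # heads read the pooled embeddings concatenated with the raw interface and
  # polymer indicator channels of the surviving residues
  indicators <- cbind(as.numeric(graph$interface_mask),
                      as.numeric(polymer == "protein"))
  feat_for <- function(Xnode, prov) {
    ag_concat(Xnode, ag_const(tape, indicators[prov, , drop = FALSE]))
  }
  H3 <- feat_for(pool3$X, pool3$prov)
  fold <- fw_gap_head(H3, seq_along(pool3$prov), P, "fold")
  iface <- fw_gap_head(H3, seq_along(pool3$prov), P, "iface")
  per_if <- vector("list", nrow(graph$interfaces))
  fallbacks <- character(0)
  for (k in seq_len(nrow(graph$interfaces))) {
    members <- graph$node_to_interface[[k]]
    rows <- which(pool3$prov %in% members)
    if (length(rows)) {
      per_if[[k]] <- fw_gap_head(H3, rows, P, "perif")
    } else {
      # pooling removed every node of this interface: fall back to the
      # component's pre-pooling embeddings, then to the embedded input
      rows_pre <- which(pool2$prov %in% members)
      if (length(rows_pre)) {
        per_if[[k]] <- fw_gap_head(feat_for(X3pre, pool2$prov), rows_pre,
                                   P, "perif")
        fallbacks <- c(fallbacks, "pre-pool")
      } else {
        per_if[[k]] <- fw_gap_head(feat_for(X1, seq_len(n)), members,
                                   P, "perif")
        fallbacks <- c(fallbacks, "input")
      }
    }
  }
  list(tape = tape, param_ids = param_ids, fold = fold, iface = iface,
       per_if = per_if, pools = list(pool1$prov, pool2$prov, pool3$prov),
       fallbacks = fallbacks)
}

#' Score a complex graph
#'
#' Runs the forward pass and returns the predicted quality scores: three
#' global fold scores (predicted bb-lDDT, GDT-TS, GDT-HA), three global
#' interface scores (predicted iLDDT, IPS, ICS), and two scores per
#' protein-RNA interface (predicted interface IPS and ICS).  All outputs
#' are sigmoid-valued, strictly inside (0, 1).
#'
#' @param graph A `complex_graph`.
#' @param model A `carp_model`.
#' @return A `qa_output`: list with `fold` (F0, F1, F2), `iface` (I0, I1,
#'   I2) and `per_interface` tibble (protein_chain, rna_chain, p0, p1).
#' @export
carp_forward <- function(graph, model) {
  fw <- carp_forward_tape(graph, model, training = FALSE)
  if (length(fw$fallbacks)) {
    message("per-interface head fallback used for ", length(fw$fallbacks),
            " interface(s): ", paste(fw$fallbacks, collapse = ", "))
  }
  per <- graph$interfaces
  if (nrow(per)) {
    pv <- t(vapply(fw$per_if, function(o) ag_val(o)[1, ], numeric(2)))
    per$p0 <- pv[, 1]
    per$p1 <- pv[, 2]
  } else {
    per$p0 <- numeric(0)
    per$p1 <- numeric(0)
  }
  structure(list(
    fold = stats::setNames(ag_val(fw$fold)[1, ], c("F0", "F1", "F2")),
    iface = stats::setNames(ag_val(fw$iface)[1, ], c("I0", "I1", "I2")),
    per_interface = per
  ), class = "qa_output")
}

#' @export
print.qa_output <- function(x, ...) {
  cat("<qa_output>\n  fold  F0..2:", sprintf("%.4f", x$fold), "\n")
  cat("  iface I0..2:", sprintf("%.4f", x$iface), "\n")
  if (nrow(x$per_interface)) {
    for (k in seq_len(nrow(x$per_interface))) {
      r <- x$per_interface[k, ]
      cat(sprintf("  interface %s-%s: P0 %.4f  P1 %.4f\n", r$protein_chain,
                  r$rna_chain, r$p0, r$p1))
    }
  }
  invisible(x)
}

#' Ensemble prediction by output averaging
#'
#' Arithmetic mean of every output channel across ensemble members;
#' per-interface rows are aligned by interface identity.
#'
#' @param graph A `complex_graph`.
#' @param models List of `carp_model`s (e.g. one per cross-validation fold).
#' @return A `qa_output`.
#' @export
ensemble_predict <- function(graph, models) {
  if (inherits(models, "carp_model")) models <- list(models)
  stopifnot(length(models) >= 1)
  outs <- lapply(models, function(m) carp_forward(graph, m))
  key <- function(o) paste(o$per_interface$protein_chain,
                           o$per_interface$rna_chain)
  k0 <- key(outs[[1]])
  for (o in outs[-1]) {
    if (!identical(key(o), k0)) stop("ensemble members disagree on interfaces")
  }
  avg <- outs[[1]]
  avg$fold <- rowMeans(vapply(outs, `[[`, numeric(3), "fold"))
  avg$iface <- rowMeans(vapply(outs, `[[`, numeric(3), "iface"))
  names(avg$fold) <- c("F0", "F1", "F2")
  names(avg$iface) <- c("I0", "I1", "I2")
  if (nrow(avg$per_interface)) {
    nif <- nrow(avg$per_interface)
    avg$per_interface$p0 <- rowMeans(
      matrix(vapply(outs, function(o) o$per_interface$p0, numeric(nif)),
             nrow = nif))
    avg$per_interface$p1 <- rowMeans(
      matrix(vapply(outs, function(o) o$per_interface$p1, numeric(nif)),
             nrow = nif))
  }
  avg
}

#' Save / load model checkpoints as portable JSON
#'
#' Parameters, configuration and the feature-layout version are stored in a
#' plain-text container; loading refuses to score graphs built with a
#' different layout version.
#'
#' @param model A `carp_model`.
#' @param path Output path (.json).
#' @return `path` invisibly (`save_carp`); a `carp_model` (`load_carp`).
#' @export
save_carp <- function(model, path) {
  stopifnot(inherits(model, "carp_model"))
  obj <- list(
    layout_version = model$layout_version,
    config = unclass(model$config),
    params = lapply(model$params, function(m) {
      list(dim = dim(m), data = as.numeric(m))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_carp
#' @export
load_carp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgl <- obj$config
  config <- carp_config(hidden_dim = cfgl$hidden_dim,
                        attention_heads = cfgl$attention_heads,
                        topk_ratio = cfgl$topk_ratio,
                        dropout = cfgl$dropout,
                        head_hidden = cfgl$head_hidden, seed = cfgl$seed)
  params <- lapply(obj$params, function(p) {
    matrix(p$data, p$dim[1], p$dim[2])
  })
  structure(list(params = params, config = config,
                 layout_version = obj$layout_version,
                 n_params = sum(vapply(params, length, numeric(1)))),
            class = "carp_model")
}
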