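# Training: masked multi-task L1 loss over the eight score types,
# stratified 5-fold assignment over cluster labels, and a desk-scale
# gradient training loop with per-fold validation checkpoints.

TRUTH_FOLD_FIELDS <- c("bb_lddt", "gdt_ts", "gdt_ha")
TRUTH_IFACE_FIELDS <- c("ilddt", "ips", "ics")

#' Multi-task L1 loss between predictions and ground truth
#'
#' Eight score types: three global fold (bb-lDDT, GDT-TS, GDT-HA), three
#' global interface (iLDDT, IPS, ICS) and two per-interface (IPS, ICS; each
#' averaged over its interfaces first).  The loss is the mean absolute
#' error per type, averaged over the types that have at least one valid
#' (unmasked) entry.  iRMSD is never a training target.
#'
#' @param pred A `qa_output`.
#' @param truth A `truth_bundle`.
#' @param masks Optional named logical vector over
#'   `c("bb_lddt","gdt_ts","gdt_ha","ilddt","ips","ics","perif_ips","perif_ics")`;
#'   by default a type is valid when its truth value is not NA.
#' @return Scalar loss >= 0.
#' @export
multitask_l1_loss <- function(pred, truth, masks = NULL) {
  stopifnot(inherits(pred, "qa_output"), inherits(truth, "truth_bundle"))
  terms <- c(
    abs(pred$fold - unlist(truth[TRUTH_FOLD_FIELDS])),
    abs(pred$iface - unlist(truth[TRUTH_IFACE_FIELDS]))
  )
  names(terms) <- c(TRUTH_FOLD_FIELDS, TRUTH_IFACE_FIELDS)
  mt <- match_interfaces(pred$per_interface, truth$per_interface)
  perif_ips <- if (nrow(mt)) mean(abs(mt$p0 - mt$ips)) else NA_real_
  perif_ics <- if (nrow(mt)) mean(abs(mt$p1 - mt$ics)) else NA_real_
  terms <- c(terms, perif_ips = perif_ips, perif_ics = perif_ics)
  if (!is.null(masks)) terms[names(masks)[!masks]] <- NA_real_
  if (all(is.na(terms))) stop("multitask_l1_loss(): all score types masked")
  mean(terms, na.rm = TRUE)
}

# align predicted and true per-interface rows by chain-pair identity
match_interfaces <- function(pred_if, truth_if) {
  if (!nrow(pred_if) || !nrow(truth_if)) {
    return(tibble::tibble(p0 = numeric(), p1 = numeric(), ips = numeric(),
                          ics = numeric()))
  }
  m <- dplyr::inner_join(pred_if, truth_if,
                         by = c("protein_chain", "rna_chain"))
  m <- m[!is.na(m$ips) | !is.na(m$ics), , drop = FALSE]
  m
}

#' Stratified k-fold assignment over cluster labels
#'
#' Complexes with an RNA clan label are dealt first, one clan stratum at a
#' time; clanless complexes follow, stratified by protein-sequence
#' cluster.  Within a stratum the members are shuffled (seeded) and dealt
#' to the folds in ascending current-size order, so per-stratum fold counts
#' differ by at most one.  Note this distributes cluster members ACROSS
#' folds (stratified representation, not group-disjoint cross-validation).
#'
#' @param labels Tibble/data frame: `complex_id`, `seq_cluster_id`, and
#'   optional `clan_id` (NA = no clan).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Tibble: complex_id, fold (1..k), provenance (stratum label).
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  labels <- tibble::as_tibble(labels)
  if (k < 2) stop("stratified_folds(): k must be >= 2")
  stopifnot(all(c("complex_id", "seq_cluster_id") %in% names(labels)),
            !anyDuplicated(labels$complex_id))
  if (!"clan_id" %in% names(labels)) labels$clan_id <- NA_character_
  fold_sizes <- integer(k)
  out <- list()
  withr::with_seed(seed, {
    deal <- function(ids, provenance) {
      ids <- sample(ids)
      # round-robin over folds ordered by current size: per-stratum counts
      # differ by at most one, and small folds catch up first
      ord <- order(fold_sizes, seq_len(k))
      for (m in seq_along(ids)) {
        f <- ord[((m - 1L) %% k) + 1L]
        fold_sizes[f] <<- fold_sizes[f] + 1L
        out[[length(out) + 1L]] <<- tibble::tibble(
          complex_id = ids[m], fold = f, provenance = provenance)
      }
    }
    with_clan <- labels[!is.na(labels$clan_id), ]
    for (cl in sort(unique(with_clan$clan_id))) {
      deal(with_clan$complex_id[with_clan$clan_id == cl],
           paste0("clan:", cl))
    }
    clanless <- labels[is.na(labels$clan_id), ]
    for (sc in sort(unique(clanless$seq_cluster_id))) {
      deal(clanless$complex_id[clanless$seq_cluster_id == sc],
           paste0("seq_cluster:", sc))
    }
  })
  dplyr::arrange(dplyr::bind_rows(out),
                 match(.data$complex_id, labels$complex_id))
}

# loss as a tape node, sharing the forward tape (training path)
loss_on_tape <- function(fw, graph, truth) {
  terms <- list()
  ft <- unlist(truth[TRUTH_FOLD_FIELDS])
  it <- unlist(truth[TRUTH_IFACE_FIELDS])
  add_masked <- function(node, target) {
    ok <- !is.na(target)
    if (!any(ok)) return(NULL)
    tgt <- matrix(ifelse(ok, target, 0), 1)
    msk <- matrix(as.numeric(ok), 1)
    ag_scale(ag_sum(ag_mul(ag_abs(ag_sub(node, tgt)), msk)), 1 / sum(ok))
  }
  # fold / iface types enter per-type (each is its own mean over 1 entry);
  # build per-type terms so the final mean weights types equally
  for (j in seq_along(ft)) {
    if (is.na(ft[j])) next
    sub <- ag_gathercol(fw$fold, j)
    terms[[length(terms) + 1L]] <- ag_abs(ag_sub(sub, ft[j]))
  }
  for (j in seq_along(it)) {
    if (is.na(it[j])) next
    sub <- ag_gathercol(fw$iface, j)
    terms[[length(terms) + 1L]] <- ag_abs(ag_sub(sub, it[j]))
  }
  if (length(fw$per_if) && nrow(truth$per_interface)) {
    gkey <- paste(graph$interfaces$protein_chain, graph$interfaces$rna_chain)
    tkey <- paste(truth$per_interface$protein_chain,
                  truth$per_interface$rna_chain)
    hit <- match(gkey, tkey)
    for (ch in 1:2) {
      tvals <- truth$per_interface[[c("ips", "ics")[ch]]][hit]
      ok <- which(!is.na(tvals))
      if (!length(ok)) next
      s <- NULL
      for (kk in ok) {
        d <- ag_abs(ag_sub(ag_gathercol(fw$per_if[[kk]], ch), tvals[kk]))
        s <- if (is.null(s)) d else ag_add(s, d)
      }
      terms[[length(terms) + 1L]] <- ag_scale(s, 1 / length(ok))
    }
  }
  if (!length(terms)) stop("loss_on_tape(): all score types masked")
  tot <- terms[[1]]
  if (length(terms) > 1) for (tm in terms[-1]) tot <- ag_add(tot, tm)
  ag_scale(tot, 1 / length(terms))
}

# column slice of a 1 x C node
ag_gathercol <- function(a, j) {
  A <- ag_val(a)
  ag_push(a$t, A[, j, drop = FALSE], a$i, function(G) {
    D <- matrix(0, nrow(A), ncol(A))
    D[, j] <- G
    list(D)
  })
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

dataset_loss <- function(model, dataset, idx) {
  mean(vapply(idx, function(i) {
    multitask_l1_loss(carp_forward(dataset$graph[[i]], model),
                      dataset$truth[[i]])
  }, numeric(1)))
}

#' Train the quality-assessment network with per-fold validation
#'
#' Gradient training (Adam, batch size 1) of one model per validation
#' fold: the fold is held out, the rest is the training split, and the
#' checkpoint with the minimum validation loss is kept.  Learning rate
#' halves when the validation loss plateaus; early stop after `patience`
#' epochs without improvement.
#'
#' @param dataset Tibble with columns `complex_id`, `graph` (list of
#'   `complex_graph`), `truth` (list of `truth_bundle`).
#' @param folds A [stratified_folds()] assignment for `complex_id`s.
#' @param config A [carp_config()].
#' @param seed Integer seed (parameter init, shuffling, dropout).
#' @param epochs Maximum epochs.
#' @param lr Initial learning rate.
#' @param patience Early-stopping patience (epochs).
#' @param plateau Epochs without improvement before the learning rate halves.
#' @param validation_folds Which folds to use as validation (default: all).
#' @param verbose Print per-epoch losses.
#' @return A `carp_fit`: `models` (one per validation fold), `curves`
#'   (fold, epoch, train_loss, val_loss), `best` (per-fold summary),
#'   `config`.
#' @export
train_carp <- function(dataset, folds, config = carp_config(), seed = 1,
                       epochs = 30, lr = 1e-3, patience = 10, plateau = 5,
                       validation_folds = NULL, verbose = FALSE) {
  stopifnot(all(c("complex_id", "graph", "truth") %in% names(dataset)))
  fmap <- folds$fold[match(dataset$complex_id, folds$complex_id)]
  if (anyNA(fmap)) stop("train_carp(): dataset has complexes missing from folds")
  used_folds <- sort(unique(fmap))
  if (length(used_folds) < 2) stop("train_carp(): need >= 2 populated folds")
  if (is.null(validation_folds)) validation_folds <- used_folds
  curves <- list()
  models <- list()
  best_rows <- list()
  for (vf in validation_folds) {
    tr_idx <- which(fmap != vf)
    va_idx <- which(fmap == vf)
    if (!length(tr_idx)) stop("train_carp(): empty training split")
    model <- init_carp(config, seed = seed + 1000L * vf)
    st <- adam_init(model$params)
    best_val <- Inf; best_params <- model$params; best_epoch <- 0L
    since_best <- 0L
    cur_lr <- lr
    withr::with_seed(seed + vf, {
      for (ep in seq_len(epochs)) {
        ord <- sample(tr_idx)
        tl <- 0
        for (i in ord) {
          fw <- carp_forward_tape(dataset$graph[[i]], model, training = TRUE)
          ls <- loss_on_tape(fw, dataset$graph[[i]], dataset$truth[[i]])
          gr <- ag_backward(fw$tape, ls)
          grads <- lapply(fw$param_ids, function(id) gr[[id]])
          upd <- adam_step(model$params, grads, st, cur_lr)
          model$params <- upd$params; st <- upd$state
          tl <- tl + ag_val(ls)[1, 1]
        }
        vl <- dataset_loss(model, dataset, va_idx)
        curves[[length(curves) + 1L]] <- tibble::tibble(
          fold = vf, epoch = ep, train_loss = tl / length(ord),
          val_loss = vl, lr = cur_lr)
        if (verbose) {
          message(sprintf("fold %d epoch %d train %.4f val %.4f", vf, ep,
                          tl / length(ord), vl))
        }
        if (vl < best_val - 1e-6) {
          best_val <- vl; best_params <- model$params; best_epoch <- ep
          since_best <- 0L
        } else {
          since_best <- since_best + 1L
          if (since_best %% plateau == 0L) cur_lr <- cur_lr / 2
          if (since_best >= patience) break
        }
      }
    })
    model$params <- best_params
    models[[as.character(vf)]] <- model
    best_rows[[length(best_rows) + 1L]] <- tibble::tibble(
      fold = vf, best_epoch = best_epoch, best_val_loss = best_val,
      n_train = length(tr_idx), n_val = length(va_idx))
  }
  structure(list(models = models, curves = dplyr::bind_rows(curves),
                 best = dplyr::bind_rows(best_rows), config = config),
            class = "carp_fit")
}

#' @export
print.carp_fit <- function(x, ...) {
  cat("<carp_fit>", length(x$models), "fold model(s)\n")
  print(x$best)
  invisible(x)
}

#' Tidy per-epoch learning curves of a fit
#' @param x A `carp_fit`.
#' @param ... Unused.
#' @return Tibble: fold, epoch, train_loss, val_loss, lr.
#' @method tidy carp_fit
#' @export
tidy.carp_fit <- function(x, ...) x$curves

#' One-row-per-fold fit summary
#' @param x A `carp_fit`.
#' @param ... Unused.
#' @return Tibble: fold, best_epoch, best_val_loss, n_train, n_val.
#' @method glance carp_fit
#' @export
glance.carp_fit <- function(x, ...) x$best

#' Learning-curve plot for a fit
#' @param object A `carp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot carp_fit
#' @export
autoplot.carp_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$curves, c("train_loss", "val_loss"),
                           names_to = "split", values_to = "loss")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~fold, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "epoch", y = "multi-task L1 loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' Build a labeled training dataset from decoy ensembles
#'
#' Featurizes every decoy of every complex into a graph and pairs it with
#' its truth bundle.
#'
#' @param complexes Named list of `complex_structure` natives.
#' @param spec A [decoy_spec()] applied to each complex (its seed is offset
#'   per complex).
#' @param sasa_points SASA sphere points (reduced for speed in toy runs).
#' @param progress Print progress.
#' @return List with `dataset` (tibble: complex_id, magnitude, graph,
#'   truth) and `labels` (tibble: complex_id, seq_cluster_id) where every
#'   complex is its own singleton cluster.
#' @export
build_decoy_dataset <- function(complexes, spec = decoy_spec(n_decoys = 20),
                                sasa_points = 60, progress = FALSE) {
  stopifnot(length(names(complexes)) == length(complexes))
  rows <- list()
  for (ci in seq_along(complexes)) {
    id <- names(complexes)[ci]
    native <- complexes[[ci]]
    sp <- spec
    sp$seed <- spec$seed + 131L * ci
    ds <- decoy_set(native, sp)
    for (j in seq_len(nrow(ds))) {
      g <- build_graph(ds$decoy[[j]], sasa_points = sasa_points)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        complex_id = id, decoy_id = ds$id[j], magnitude = ds$magnitude[j],
        graph = list(g), truth = list(ds$bundle[[j]]))
    }
    if (progress) message("featurized ", id, " (", nrow(ds), " decoys)")
  }
  dataset <- dplyr::bind_rows(rows)
  labels <- tibble::tibble(complex_id = names(complexes),
                           seq_cluster_id = names(complexes))
  list(dataset = dataset, labels = labels)
}
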