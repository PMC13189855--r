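# Evaluation statistics for model-ranking experiments: ranking loss,
# outlier-robust Z-scores and their CASP16-weighted combination, top-k
# summed Z, iRMSD quantile selection metrics, per-interface weighted
# correlations and feature sensitivity.

#' Ranking loss
#'
#' The gap between the best true quality in an ensemble and the true
#' quality of the predictor's top-ranked model:
#' `RL = |max(M) - M[argmax(Mhat)]|`.  Argmax ties break to the first
#' index.
#'
#' @param m True quality scores.
#' @param mhat Predicted quality scores (same length).
#' @return Scalar >= 0.
#' @export
ranking_loss <- function(m, mhat) {
  stopifnot(length(m) == length(mhat), length(m) >= 1)
  abs(max(m) - m[which.max(mhat)])
}

#' Outlier-excluding Z-scores
#'
#' Two-pass convention: Z-scores from the mean/sd of all values, then the
#' mean/sd are recomputed excluding values whose first-pass Z is below
#' `outlier_cut`, and final Z-scores come from the second-pass statistics.
#' Zero variance (either pass) gives all-zero Z.
#'
#' @param values Per-model metric values (length >= 2).
#' @param outlier_cut First-pass Z threshold below which a value is
#'   excluded from the second-pass statistics.
#' @return Numeric vector of Z-scores.
#' @export
zscores <- function(values, outlier_cut = -2) {
  stopifnot(length(values) >= 2)
  s1 <- stats::sd(values)
  if (!is.finite(s1) || s1 == 0) return(rep(0, length(values)))
  z1 <- (values - mean(values)) / s1
  keep <- z1 >= outlier_cut
  if (sum(keep) < 2) return(z1)
  s2 <- stats::sd(values[keep])
  if (!is.finite(s2) || s2 == 0) return(rep(0, length(values)))
  (values - mean(values[keep])) / s2
}

#' CASP16 combined Z-score
#'
#' `0.3 (0.3 Z_TM + 0.3 Z_GDT_TS + 0.4 Z_LDDT) +
#'  0.7 (Z_ICS + Z_IPS + Z_iLDDT) / 3`.
#'
#' @param panel Data frame / tibble with columns z_tm, z_gdt_ts, z_lddt,
#'   z_ics, z_ips, z_ilddt (per model).
#' @return Numeric vector of combined Z-scores.
#' @export
z_casp16 <- function(panel) {
  need <- c("z_tm", "z_gdt_ts", "z_lddt", "z_ics", "z_ips", "z_ilddt")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("z_casp16(): missing components: ",
                         paste(miss, collapse = ", "))
  if (any(vapply(panel[need], function(v) any(!is.finite(v)), logical(1)))) {
    stop("z_casp16(): non-finite Z components")
  }
  0.3 * (0.3 * panel$z_tm + 0.3 * panel$z_gdt_ts + 0.4 * panel$z_lddt) +
    0.7 * (panel$z_ics + panel$z_ips + panel$z_ilddt) / 3
}

#' Summed Z of the predictor's top-k models
#'
#' Selects the k models ranked highest by the predicted score (ties broken
#' by model id order) and sums their combined Z-scores with negative
#' values clipped to zero.
#'
#' @param mhat Predicted quality scores.
#' @param z Per-model combined Z-scores (e.g. [z_casp16()]).
#' @param k Number of top models.
#' @param ids Optional model ids for tie-breaking (default: input order).
#' @return Scalar sum of clipped Z over the selected models.
#' @export
topk_sum_z <- function(mhat, z, k = 3, ids = seq_along(mhat)) {
  stopifnot(length(mhat) == length(z))
  if (k > length(mhat)) stop("topk_sum_z(): k exceeds the number of models")
  sel <- order(-mhat, ids)[seq_len(k)]
  sum(pmax(z[sel], 0))
}

#' iRMSD quantile scores
#'
#' `Q(x) = 100 * count(iRMSD >= x) / N`, evaluated at each model's own
#' iRMSD (the model itself included), so the best (smallest-iRMSD) model
#' scores 100.
#'
#' @param irmsd Per-model iRMSD values, Angstrom.
#' @return Numeric vector of quantiles in (0, 100].
#' @export
quantile_scores <- function(irmsd) {
  stopifnot(length(irmsd) >= 1)
  vapply(irmsd, function(x) 100 * sum(irmsd >= x) / length(irmsd), numeric(1))
}

#' Top-k selection metrics against iRMSD quantiles
#'
#' True top models are those at or above the 99th quantile (Q >= 99).
#' Success indicates at least one top-k-ranked model is a true top model;
#' recall is the percentage of true top models retrieved in the top k;
#' the average and best quantiles summarize the top-k selection.
#'
#' @param mhat Predicted quality scores (higher = better).
#' @param irmsd Per-model iRMSD values.
#' @param k Number of selected models.
#' @param ids Optional ids for deterministic tie-breaks.
#' @param true_top_quantile Quantile bound defining true top models.
#' @return One-row tibble: success (0/1), recall (%), avg_quantile,
#'   best_quantile, n_true_top.
#' @export
selection_metrics <- function(mhat, irmsd, k = 5, ids = seq_along(mhat),
                              true_top_quantile = 99) {
  stopifnot(length(mhat) == length(irmsd))
  if (k > length(mhat)) stop("selection_metrics(): k exceeds ensemble size")
  q <- quantile_scores(irmsd)
  true_top <- which(q >= true_top_quantile)
  sel <- order(-mhat, ids)[seq_len(k)]
  tibble::tibble(
    success = as.numeric(length(intersect(sel, true_top)) > 0),
    recall = if (length(true_top)) {
      100 * length(intersect(sel, true_top)) / length(true_top)
    } else NA_real_,
    avg_quantile = mean(q[sel]),
    best_quantile = max(q[sel]),
    n_true_top = length(true_top)
  )
}

clip0 <- function(v) ifelse(is.na(v), NA_real_, pmax(v, 0))

#' Per-interface evaluation with equal target representation
#'
#' Each (target, interface) pair is an independent entry.  Entries whose
#' prediction coverage is below `coverage_min` are dropped.  Per entry the
#' Spearman and Pearson correlations (negatives clipped to zero) and the
#' ranking loss are computed, then aggregated with weight
#' 1 / (number of interfaces in the entry's target), so every target
#' contributes equal total weight; `weighting = "direct"` instead weights
#' by the interface count.
#'
#' @param entries Tibble with columns `target`, `interface`, and
#'   list-columns or long columns `pred`, `truth` (per-model vectors), or
#'   long format with one row per (target, interface, model): columns
#'   target, interface, model_id, pred, truth.
#' @param coverage_min Minimum fraction of models with predictions.
#' @param weighting `"inverse"` (equal target representation) or
#'   `"direct"`.
#' @return One-row tibble: spearman, pearson, ranking_loss, n_entries.
#' @export
per_interface_eval <- function(entries, coverage_min = 0.6,
                               weighting = c("inverse", "direct")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("target", "interface", "pred", "truth") %in% names(entries)))
  per_entry <- entries |>
    dplyr::group_by(.data$target, .data$interface) |>
    dplyr::summarise(
      coverage = mean(!is.na(.data$pred)),
      spearman = if (sum(!is.na(.data$pred)) >= 2) {
        suppressWarnings(stats::cor(.data$pred, .data$truth,
                                    method = "spearman",
                                    use = "complete.obs"))
      } else NA_real_,
      pearson = if (sum(!is.na(.data$pred)) >= 2) {
        suppressWarnings(stats::cor(.data$pred, .data$truth,
                                    use = "complete.obs"))
      } else NA_real_,
      rl = {
        ok <- !is.na(.data$pred) & !is.na(.data$truth)
        if (any(ok)) ranking_loss(.data$truth[ok], .data$pred[ok])
        else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::filter(.data$coverage >= coverage_min)
  if (!nrow(per_entry)) {
    stop("per_interface_eval(): no entries pass the coverage filter")
  }
  # zero-variance entries give NA correlations: treated as 0 after clipping
  per_entry$spearman <- clip0(ifelse(is.na(per_entry$spearman), 0,
                                     per_entry$spearman))
  per_entry$pearson <- clip0(ifelse(is.na(per_entry$pearson), 0,
                                    per_entry$pearson))
  n_if <- per_entry |>
    dplyr::count(.data$target, name = "n_interfaces")
  per_entry <- dplyr::left_join(per_entry, n_if, by = "target")
  w <- if (weighting == "inverse") 1 / per_entry$n_interfaces
       else per_entry$n_interfaces
  tibble::tibble(
    spearman = stats::weighted.mean(per_entry$spearman, w),
    pearson = stats::weighted.mean(per_entry$pearson, w),
    ranking_loss = stats::weighted.mean(per_entry$rl, w, na.rm = TRUE),
    n_entries = nrow(per_entry)
  )
}

#' Sensitivity of the combined scores to one feature channel
#'
#' Mean absolute change of each combined score when the channel is zeroed
#' across all nodes (or edges) of every graph, averaged over graphs.
#'
#' @param model A `carp_model` or list (ensemble).
#' @param graphs List of `complex_graph`s.
#' @param channel Channel index (1-based) within the node or edge feature
#'   matrix.
#' @param which `"node"` or `"edge"`.
#' @return One-row tibble with the mean absolute change of fold, iface,
#'   merged and rp, plus `sensitivity` (their mean).
#' @export
feature_sensitivity <- function(model, graphs, channel,
                                which = c("node", "edge")) {
  which <- match.arg(which)
  nch <- if (which == "node") ncol(graphs[[1]]$node_feat)
         else ncol(graphs[[1]]$edge_feat)
  if (!(channel %in% seq_len(nch))) {
    stop("feature_sensitivity(): unknown channel ", channel)
  }
  deltas <- vapply(graphs, function(g) {
    base <- carp_scores(ensemble_predict(g, model))
    gz <- g
    if (which == "node") gz$node_feat[, channel] <- 0
    else gz$edge_feat[, channel] <- 0
    pert <- carp_scores(ensemble_predict(gz, model))
    c(abs(pert$fold - base$fold), abs(pert$iface - base$iface),
      abs(pert$merged - base$merged),
      if (is.na(base$rp) || is.na(pert$rp)) NA_real_
      else abs(pert$rp - base$rp))
  }, numeric(4))
  m <- rowMeans(deltas, na.rm = TRUE)
  tibble::tibble(channel = channel, which = which,
                 d_fold = m[1], d_iface = m[2], d_merged = m[3],
                 d_rp = m[4], sensitivity = mean(m, na.rm = TRUE))
}

#' Scatter plot of predicted vs true quality
#'
#' @param data Tibble with columns `truth`, `pred` and optionally
#'   `complex_id` for faceting.
#' @param truth,pred Column names (strings).
#' @return A ggplot object.
#' @export
plot_prediction_quality <- function(data, truth = "truth", pred = "pred") {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data[[truth]],
                                          y = .data[[pred]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(linetype = 2, color = "grey50") +
    ggplot2::labs(x = "true quality", y = "predicted quality") +
    ggplot2::theme_minimal()
  if ("complex_id" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(~complex_id)
  }
  p
}
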