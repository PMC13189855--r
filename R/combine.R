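# Combined quality scores from the raw network outputs.

#' Combined CARP scores from a prediction
#'
#' * `fold` (CARP-Fold): mean of the three global fold predictions.
#' * `iface` (CARP-Iface): mean of the three global interface predictions.
#' * `merged` (CARP-Merged): mean of `fold` and `iface`.
#' * `perif[i]` (CARP-PerIF): mean of the two per-interface predictions.
#' * `perif_g[i]` (CARP-PerIF-G): mean of `perif[i]` and `iface`.
#' * `rp` (CARP-RP): grand mean of all per-interface predictions.
#'
#' With zero interfaces, `rp` is NA (flagged) and `per_if` is empty while
#' the global scores are still emitted.
#'
#' @param out A `qa_output`.
#' @return A `carp_scores` list: fold, iface, merged, rp, per_if (tibble:
#'   protein_chain, rna_chain, perif, perif_g).
#' @export
carp_scores <- function(out) {
  stopifnot(inherits(out, "qa_output"))
  fold <- mean(out$fold)
  iface <- mean(out$iface)
  per <- out$per_interface
  if (nrow(per)) {
    per_if <- tibble::tibble(
      protein_chain = per$protein_chain, rna_chain = per$rna_chain,
      perif = (per$p0 + per$p1) / 2
    )
    per_if$perif_g <- (per_if$perif + iface) / 2
    rp <- mean(c(per$p0, per$p1))
  } else {
    per_if <- tibble::tibble(protein_chain = character(),
                             rna_chain = character(), perif = numeric(),
                             perif_g = numeric())
    rp <- flagged_na("no protein-RNA interfaces")
  }
  structure(list(fold = fold, iface = iface, merged = (fold + iface) / 2,
                 rp = as.numeric(rp), per_if = per_if),
            class = "carp_scores")
}

#' @export
print.carp_scores <- function(x, ...) {
  cat(sprintf("<carp_scores> fold %.4f | iface %.4f | merged %.4f | rp %s\n",
              x$fold, x$iface, x$merged,
              if (is.na(x$rp)) "NA" else sprintf("%.4f", x$rp)))
  if (nrow(x$per_if)) print(x$per_if)
  invisible(x)
}

#' Tidy one-row table of combined scores
#' @param x A `carp_scores`.
#' @param ... Unused.
#' @return Tibble with fold, iface, merged, rp and wide per-interface
#'   columns.
#' @method tidy carp_scores
#' @export
tidy.carp_scores <- function(x, ...) {
  row <- tibble::tibble(fold = x$fold, iface = x$iface, merged = x$merged,
                        rp = x$rp)
  if (nrow(x$per_if)) {
    for (k in seq_len(nrow(x$per_if))) {
      r <- x$per_if[k, ]
      row[[paste0("perif_", r$protein_chain, "_", r$rna_chain)]] <- r$perif
      row[[paste0("perif_g_", r$protein_chain, "_", r$rna_chain)]] <- r$perif_g
    }
  }
  row
}

#' Score one or more structures end to end
#'
#' Parses (if needed), featurizes, runs the model (or ensemble) and
#' returns one tidy row per model with the six combined scores plus the
#' raw outputs.
#'
#' @param structures Named list of `complex_structure`s or file paths.
#' @param model A `carp_model` or list of them (ensemble).
#' @param sasa_points SASA sphere points.
#' @return Tibble, one row per input.
#' @export
score_structures <- function(structures, model, sasa_points = 144) {
  if (is.null(names(structures))) {
    names(structures) <- paste0("model_", seq_along(structures))
  }
  rows <- lapply(names(structures), function(id) {
    s <- structures[[id]]
    if (is.character(s)) s <- read_structure(s)
    g <- build_graph(s, sasa_points = sasa_points)
    out <- ensemble_predict(g, model)
    sc <- carp_scores(out)
    raw <- tibble::tibble(
      F0 = out$fold[1], F1 = out$fold[2], F2 = out$fold[3],
      I0 = out$iface[1], I1 = out$iface[2], I2 = out$iface[3]
    )
    dplyr::bind_cols(tibble::tibble(model_id = id), tidy(sc), raw)
  })
  dplyr::bind_rows(rows)
}
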