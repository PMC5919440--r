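#' Construct a scored edge set
#'
#' A scored edge set is a data frame of canonical unordered pairs with an
#' optional numeric `score` and an optional logical `label` (gold-standard
#' positive/negative). Pairs are canonicalized (endpoints bytewise sorted)
#' and duplicates collapsed keeping the maximum score.
#'
#' @param edges Two-column pair representation (see [build_instance()]).
#' @param score Optional numeric scores, one per row of `edges` (or a
#'   `score` column in `edges` itself).
#' @param label Optional logical labels (`TRUE` = positive).
#' @return Data frame with columns `protein_a`, `protein_b`, and where
#'   given, `score` and `label`.
#' @export
scored_edges <- function(edges, score = NULL, label = NULL) {
  if (is.null(label) && is.data.frame(edges)) label <- edges[["label"]]
  ef <- as_edge_frame(edges)
  if (!is.null(score)) ef$score <- as.numeric(score)
  if (!is.null(label)) ef$label <- as.logical(label)
  if (!is.null(ef$score) && any(!is.finite(ef$score)))
    stop("scores must be finite")
  has_label <- !is.null(ef[["label"]])
  labels <- ef[["label"]]
  ef$label <- NULL
  out <- canonicalize_edges(ef)
  if (has_label && nrow(out)) {
    rowkey <- canonicalize_edges_key(ef)
    out$label <- vapply(out$key, function(k) any(labels[rowkey == k]), TRUE)
  }
  out$key <- NULL
  rownames(out) <- NULL
  out
}

# canonical key per row without dedup/sort (helper for scored_edges)
canonicalize_edges_key <- function(ef) {
  swap <- str_gt(ef$protein_a, ef$protein_b)
  a <- ifelse(swap, ef$protein_b, ef$protein_a)
  b <- ifelse(swap, ef$protein_a, ef$protein_b)
  paste(a, b, sep = "\t")
}

edge_keys <- function(edges) {
  ef <- canonicalize_edges(edges)
  ef$key
}

#' Overlap between predicted and gold-standard edge sets
#'
#' Summarizes how a prediction agrees with a gold-standard scored set: the
#' number of common edges, the mean gold score over all common edges, and
#' the mean gold score over the `top_k` highest-ranked common edges
#' (predicted edges ranked by predicted score, descending, ties broken by
#' bytewise pair order). When fewer than `top_k` common edges exist the mean
#' is over those present and the shortfall is reported.
#'
#' @param predicted Scored edge set of predictions (data frame with
#'   `protein_a`, `protein_b`, optional `score`; unscored predictions are
#'   ranked by pair order).
#' @param gold Gold-standard scored edge set (must carry `score`).
#' @param top_k Number of top predictions to average over (default 100).
#' @param average `"gold"` (default) averages the gold scores of the
#'   selected common edges; `"predicted"` averages their predicted scores.
#' @return A list with `n_predicted`, `n_gold`, `n_common`,
#'   `mean_common` (NA when no common edges), `mean_top` (NA likewise),
#'   `top_k`, and `top_shortfall`.
#' @export
overlap_summary <- function(predicted, gold, top_k = 100L,
                            average = c("gold", "predicted")) {
  average <- match.arg(average)
  top_k <- as.integer(top_k)
  stopifnot(top_k >= 1L)
  pe <- canonicalize_edges(predicted, "predicted")
  ge <- canonicalize_edges(gold, "gold")
  if (is.null(ge$score) && nrow(ge)) stop("gold set must carry scores")
  common <- pe[pe$key %in% ge$key, , drop = FALSE]
  gs <- ge$score[match(common$key, ge$key)]
  ps <- common$score %||% rep(NA_real_, nrow(common))
  if (all(is.na(ps))) ps <- rep(0, nrow(common))
  ord <- order(-xtfrm(ps), common$protein_a, common$protein_b,
               method = "radix")
  sel <- utils::head(ord, top_k)
  pick <- if (average == "gold") gs else ps
  list(
    n_predicted = nrow(pe),
    n_gold = nrow(ge),
    n_common = nrow(common),
    mean_common = if (nrow(common)) mean(gs) else NA_real_,
    mean_top = if (length(sel)) mean(pick[sel]) else NA_real_,
    top_k = top_k,
    top_shortfall = max(0L, top_k - nrow(common))
  )
}

#' Combine a connectivity-based score with an external method score
#'
#' Linear combination `S_c = SPE * S_g + S_e`, where `S_g` is the
#' rank-based confidence from the greedy augmentation, `S_e` the external
#' method's confidence, and `SPE` the weight given to the augmentation
#' evidence. With `spe = 0` the external score is returned unchanged.
#'
#' @param s_g,s_e Numeric score vectors (recycled to a common length).
#' @param spe Numeric weight.
#' @return Numeric vector of combined scores.
#' @examples
#' combine_scores(2, 3, 0.5)  # 4
#' @export
combine_scores <- function(s_g, s_e, spe) {
  stopifnot(is.numeric(s_g), is.numeric(s_e), is.numeric(spe),
            all(is.finite(s_g)), all(is.finite(s_e)), all(is.finite(spe)))
  spe * s_g + s_e
}

#' Combine two scored edge sets
#'
#' Union-of-edges combination: every edge present in either set is scored
#' `SPE * S_g + S_e`, with a missing `S_g` or `S_e` contributing 0 (an edge
#' only the augmentation found carries no external evidence, and vice
#' versa). Labels, when present on either input, are carried through
#' (positive if positive in either).
#'
#' @param greedy_set Scored edge set of augmentation confidences (`S_g`).
#' @param external_set Scored edge set of an external method (`S_e`).
#' @param spe Weight for the augmentation score.
#' @return Scored edge set with the combined `score`.
#' @export
combine_scored_sets <- function(greedy_set, external_set, spe) {
  g <- canonicalize_edges(greedy_set, "greedy_set")
  e <- canonicalize_edges(external_set, "external_set")
  keys <- str_sort(unique(c(g$key, e$key)))
  sg <- ifelse(is.na(m <- match(keys, g$key)), 0,
               (g$score %||% rep(0, nrow(g)))[m])
  se <- ifelse(is.na(m2 <- match(keys, e$key)), 0,
               (e$score %||% rep(0, nrow(e)))[m2])
  parts <- strsplit(keys, "\t", fixed = TRUE)
  out <- data.frame(
    protein_a = vapply(parts, `[[`, "", 1L),
    protein_b = vapply(parts, `[[`, "", 2L),
    score = combine_scores(sg, se, spe),
    stringsAsFactors = FALSE)
  gl <- g[["label"]]; el <- e[["label"]]
  if (!is.null(gl) || !is.null(el)) {
    lg <- if (is.null(gl)) rep(NA, nrow(g)) else gl
    le <- if (is.null(el)) rep(NA, nrow(e)) else el
    out$label <- (!is.na(m) & lg[m] %in% TRUE) | (!is.na(m2) & le[m2] %in% TRUE)
  }
  out
}

#' Confusion-matrix criteria for edge prediction
#'
#' Computes the six standard binary-classification criteria over an explicit
#' pair universe: recall `TP/(TP+FN)`, precision `TP/(TP+FP)`, specificity
#' `TN/(TN+FP)`, accuracy `(TP+TN)/|universe|`, F-measure (harmonic mean of
#' precision and recall), and Matthews correlation coefficient. The universe
#' must be stated explicitly (e.g. all pairs over the proteins under study)
#' because the negative class is defined by it; see [pair_universe()].
#' Criteria whose denominator is zero are reported as `NA` ("undefined"),
#' never silently 0.
#'
#' @param predicted,gold Edge sets (pairs; any representation accepted by
#'   [build_instance()]). Both must be subsets of `universe`.
#' @param universe The declared pair universe (edge set).
#' @return An object of class `min_ppi_metrics`: list with `counts` (TP,
#'   FP, TN, FN) and the six criteria.
#' @export
confusion_metrics <- function(predicted, gold, universe) {
  uk <- edge_keys(universe)
  pk <- edge_keys(predicted)
  gk <- edge_keys(gold)
  if (!all(pk %in% uk)) stop("predicted edges outside the declared universe")
  if (!all(gk %in% uk)) stop("gold edges outside the declared universe")
  tp <- sum(pk %in% gk)
  fp <- length(pk) - tp
  fn <- length(gk) - tp
  tn <- length(uk) - tp - fp - fn
  div <- function(num, den) if (den > 0) num / den else NA_real_
  recall <- div(tp, tp + fn)
  precision <- div(tp, tp + fp)
  specificity <- div(tn, tn + fp)
  acc <- div(tp + tn, length(uk))
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  mcc_den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den > 0)
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den else NA_real_
  structure(list(
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    recall = recall, precision = precision, specificity = specificity,
    accuracy = acc, f_measure = f1, mcc = mcc
  ), class = "min_ppi_metrics")
}

#' @export
print.min_ppi_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$counts["TP"], x$counts["FP"],
              x$counts["TN"], x$counts["FN"]))
  for (nm in c("recall", "precision", "specificity", "accuracy",
               "f_measure", "mcc"))
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else sprintf("%.4f", x[[nm]])))
  invisible(x)
}

#' All unordered pairs over a protein set
#'
#' Convenience constructor for the explicit pair universe required by
#' [confusion_metrics()].
#'
#' @param proteins Character vector of protein identifiers.
#' @return Data frame of all `choose(n, 2)` canonical pairs.
#' @export
pair_universe <- function(proteins) {
  proteins <- str_sort(unique(as.character(proteins)))
  n <- length(proteins)
  if (n < 2L)
    return(data.frame(protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE))
  iu <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  iv <- sequence((n - 1L):1L) + iu
  data.frame(protein_a = proteins[iu], protein_b = proteins[iv],
             stringsAsFactors = FALSE)
}

#' Area under the ROC curve
#'
#' AUC computed as the Mann-Whitney rank statistic with midrank tie
#' correction, which equals the trapezoidal area under the ROC curve over
#' all score thresholds. Invariant under strictly monotone transformations
#' of the scores; 0.5 when every edge carries the same score.
#'
#' @param scored A scored edge set with logical `label` column (or a data
#'   frame with `score` and `label`).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scored) {
  score <- scored[["score"]]
  label <- scored[["label"]]
  if (is.null(score) || is.null(label))
    stop("scored must carry 'score' and 'label' columns")
  label <- as.logical(label)
  stopifnot(all(is.finite(score)), !anyNA(label))
  npos <- sum(label)
  nneg <- sum(!label)
  if (npos == 0L || nneg == 0L)
    stop("AUC undefined: need at least one positive and one negative label")
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - npos * (npos + 1) / 2) / (npos * nneg)
}
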