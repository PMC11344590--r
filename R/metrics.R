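#' Area under the ROC curve of a ranked candidate list
#'
#' Computed by the Mann-Whitney identity: the probability that a uniformly
#' chosen positive candidate outscores a uniformly chosen negative one, with
#' exact score ties credited 1/2 (midrank convention). This equals the
#' trapezoidal area under the ROC curve swept over score thresholds, with the
#' standard direction (scores at or above the threshold predicted positive).
#'
#' @param ranked A `RankedList` (or data frame with `score` and `label`).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(ranked) {
  lab <- ranked$label
  n_pos <- sum(lab == 1L); n_neg <- sum(lab == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stopf("AUROC undefined without both positives and negatives")
  }
  r <- rank(ranked$score, ties.method = "average")
  (sum(r[lab == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Uses the average-precision convention: the mean over positive candidates of
#' precision at the rank where each positive is retrieved, under the list's
#' deterministic tie-break. Equals 1 iff every positive precedes every
#' negative in the ranked order.
#'
#' @param ranked A `RankedList`.
#' @return AUPRC in (0, 1\].
#' @export
auprc <- function(ranked) {
  lab <- ranked$label
  n_pos <- sum(lab == 1L)
  if (n_pos == 0L) stopf("AUPRC undefined without positives")
  hits <- which(lab == 1L)
  mean(seq_along(hits) / hits)
}

#' Hit\@k of a ranked candidate list
#'
#' 1 iff any of the top `min(k, length)` candidates is a positive; Hit\@1 is
#' the `k = 1` case.
#'
#' @param ranked A `RankedList`.
#' @param k Positive integer cut-off.
#' @return 0 or 1.
#' @export
hit_at_k <- function(ranked, k) {
  stopifnot(k >= 1L)
  top <- ranked$label[seq_len(min(k, nrow(ranked)))]
  as.integer(any(top == 1L))
}

#' Score one ranked list with all per-query metrics
#'
#' @param ranked A `RankedList`.
#' @param query_id,superfamily_id,fold_id Grouping keys carried into the
#'   record for aggregation.
#' @return A one-row `QueryMetricRecord` data frame with columns `query_id`,
#'   `superfamily_id`, `fold_id`, `auroc`, `auprc`, `hit1`, `hit10`, `n_pos`,
#'   `n_neg`.
#' @export
score_ranked_list <- function(ranked, query_id, superfamily_id, fold_id) {
  data.frame(
    query_id = query_id, superfamily_id = superfamily_id, fold_id = fold_id,
    auroc = auroc(ranked), auprc = auprc(ranked),
    hit1 = hit_at_k(ranked, 1L), hit10 = hit_at_k(ranked, 10L),
    n_pos = sum(ranked$label == 1L), n_neg = sum(ranked$label == 0L),
    stringsAsFactors = FALSE
  )
}

#' Evaluate one model over a set of query tasks
#'
#' Ranks every task with [rank_candidates()] (embedding store) or
#' [rank_candidates_from_matrix()] (precomputed score matrix) and scores it.
#' Queries left without negatives (possible in tiny databases once
#' same-family or same-superfamily candidates are excluded) and queries whose
#' representation is degenerate are dropped; counts by reason are attached as
#' `attr(, "drop_log")`.
#'
#' @param tasks A list of `QueryTask` objects from [build_query_tasks()].
#' @param store A pooled `RepresentationStore` (or `NULL`).
#' @param score_matrix A pairwise score matrix (or `NULL`); exactly one of
#'   `store` and `score_matrix` must be supplied.
#' @return A `QueryMetricRecord` data frame, one row per scored query.
#' @export
evaluate_model <- function(tasks, store = NULL, score_matrix = NULL) {
  if (is.null(store) == is.null(score_matrix)) {
    stopf("supply exactly one of `store` and `score_matrix`")
  }
  rows <- vector("list", length(tasks))
  dropped_no_neg <- character(0)
  dropped_degenerate <- character(0)
  for (i in seq_along(tasks)) {
    task <- tasks[[i]]
    ranked <- tryCatch(
      if (!is.null(store)) rank_candidates(task, store)
      else rank_candidates_from_matrix(task, score_matrix),
      error = function(e) {
        if (grepl("zero-norm", conditionMessage(e))) NULL else stop(e)
      })
    if (is.null(ranked)) {
      dropped_degenerate <- c(dropped_degenerate, task$query_id)
      next
    }
    if (sum(ranked$label == 0L) == 0L || sum(ranked$label == 1L) == 0L) {
      dropped_no_neg <- c(dropped_no_neg, task$query_id)
      next
    }
    rows[[i]] <- score_ranked_list(ranked, task$query_id,
                                   task$superfamily_id, task$fold_id)
  }
  records <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(records)) {
    records <- data.frame(query_id = character(), superfamily_id = character(),
                          fold_id = character(), auroc = numeric(),
                          auprc = numeric(), hit1 = integer(),
                          hit10 = integer(), n_pos = integer(),
                          n_neg = integer(), stringsAsFactors = FALSE)
  }
  rownames(records) <- NULL
  attr(records, "drop_log") <- list(no_negatives = dropped_no_neg,
                                    degenerate = dropped_degenerate)
  records
}

metric_cols <- c("auroc", "auprc", "hit1", "hit10")

#' Aggregate per-query metrics
#'
#' Two schemes: `"weighted"` first averages each metric within every
#' Superfamily (or Fold, at fold level) and then averages the group means, so
#' that small groups count as much as large ones; `"unweighted"` is the plain
#' mean over all queries.
#'
#' @param records A `QueryMetricRecord` data frame.
#' @param scheme `"weighted"` or `"unweighted"`.
#' @param level `"superfamily"` or `"fold"`: the grouping key for the
#'   weighted scheme.
#' @return An `AggregateResult` list with `scheme`, `level`, `per_group` (a
#'   data frame of group means and query counts) and `overall` (named numeric
#'   vector over auroc/auprc/hit1/hit10).
#' @export
aggregate_metrics <- function(records, scheme = c("weighted", "unweighted"),
                              level = c("superfamily", "fold")) {
  scheme <- match.arg(scheme); level <- match.arg(level)
  if (nrow(records) == 0L) stopf("no records to aggregate")
  key <- if (level == "superfamily") records$superfamily_id else records$fold_id
  per_group <- do.call(rbind, lapply(split(seq_len(nrow(records)), key),
    function(idx) {
      data.frame(group_id = key[idx[1]],
                 as.list(colMeans(records[idx, metric_cols, drop = FALSE])),
                 n_queries = length(idx),
                 mean_n_pos = mean(records$n_pos[idx]),
                 stringsAsFactors = FALSE)
    }))
  per_group <- per_group[order(per_group$group_id), , drop = FALSE]
  rownames(per_group) <- NULL
  overall <- if (scheme == "weighted") {
    colMeans(per_group[, metric_cols, drop = FALSE])
  } else {
    colMeans(records[, metric_cols, drop = FALSE])
  }
  structure(list(scheme = scheme, level = level, per_group = per_group,
                 overall = overall),
            class = "AggregateResult")
}

#' @export
print.AggregateResult <- function(x, ...) {
  cat(sprintf("<AggregateResult %s, %s level> %d group(s)\n",
              x$scheme, x$level, nrow(x$per_group)))
  print(round(x$overall, 4))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Ranks are assigned with midranks for ties. For tie-free inputs this equals
#' the classical closed form `1 - 6 * sum(d_k^2) / (n (n^2 - 1))` over the
#' rank differences `d_k`; with ties it is the Pearson correlation of the
#' rank vectors (the standard generalisation).
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @return Spearman's rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stopf("length mismatch: %d vs %d", n, length(y))
  if (n < 2L) stopf("Spearman correlation requires n >= 2")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stopf("Spearman correlation undefined for zero rank variance")
  }
  if (!anyDuplicated(rx) && !anyDuplicated(ry)) {
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  } else {
    stats::cor(rx, ry)
  }
}

#' Pairwise model-agreement matrix of Spearman correlations
#'
#' Quantifies whether models find the same groups easy or hard: for every
#' model pair, the lower triangle holds Spearman's rho between per-group
#' (Superfamily or Fold) mean-AUROC lists and the upper triangle rho between
#' per-query AUROC lists, each computed on the intersection of groups/queries
#' the two models share. The diagonal is 1 by convention.
#'
#' @param per_model_records Named list (>= 2 models) of `QueryMetricRecord`
#'   data frames over the same task set.
#' @param level Grouping level for the per-group lists.
#' @return An `AgreementMatrix`: a square numeric matrix with model dimnames,
#'   plus `attr(, "n_group")` / `attr(, "n_query")` matrices of intersection
#'   sizes.
#' @export
agreement_matrix <- function(per_model_records,
                             level = c("superfamily", "fold")) {
  level <- match.arg(level)
  models <- names(per_model_records)
  if (length(models) < 2L) stopf("need at least two models")
  group_lists <- lapply(per_model_records, function(r) {
    agg <- aggregate_metrics(r, "weighted", level)
    stats::setNames(agg$per_group$auroc, agg$per_group$group_id)
  })
  query_lists <- lapply(per_model_records, function(r) {
    stats::setNames(r$auroc, r$query_id)
  })
  k <- length(models)
  rho <- diag(1, k); dimnames(rho) <- list(models, models)
  n_group <- n_query <- matrix(0L, k, k, dimnames = list(models, models))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    if (i > j) { # lower triangle: per-group agreement
      shared <- intersect(names(group_lists[[i]]), names(group_lists[[j]]))
      if (!length(shared)) stopf("models '%s' and '%s' share no groups",
                                 models[i], models[j])
      rho[i, j] <- spearman_rho(group_lists[[i]][shared],
                                group_lists[[j]][shared])
      n_group[i, j] <- length(shared)
    } else {     # upper triangle: per-query agreement
      shared <- intersect(names(query_lists[[i]]), names(query_lists[[j]]))
      if (!length(shared)) stopf("models '%s' and '%s' share no queries",
                                 models[i], models[j])
      rho[i, j] <- spearman_rho(query_lists[[i]][shared],
                                query_lists[[j]][shared])
      n_query[i, j] <- length(shared)
    }
  }
  structure(rho, class = c("AgreementMatrix", class(rho)),
            n_group = n_group, n_query = n_query, level = level)
}
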