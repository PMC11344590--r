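#' Label a pair of classifications for a retrieval level
#'
#' At the superfamily level a candidate is a remote homolog of the query iff
#' both share a Superfamily but belong to different Families; candidates in
#' the query's own Family are excluded from the candidate set altogether, so
#' the task is remote homology versus non-homology rather than versus "all
#' others". At the fold level the rule shifts one tier up: positives share the
#' Fold but not the Superfamily, and same-Superfamily candidates are excluded.
#'
#' @param a,b `ClassificationPath` objects of depth 4.
#' @param level `"superfamily"` or `"fold"`.
#' @return One of `"positive"`, `"negative"`, `"excluded"`. Symmetric in `a`
#'   and `b`.
#' @export
label_pair <- function(a, b, level = c("superfamily", "fold")) {
  level <- match.arg(level)
  stopifnot(inherits(a, "ClassificationPath"), inherits(b, "ClassificationPath"))
  if (a$depth != 4L || b$depth != 4L) {
    stopf("label_pair requires depth-4 classifications")
  }
  if (level == "superfamily") {
    if (identical(a$family_id, b$family_id)) return("excluded")
    if (identical(a$superfamily_id, b$superfamily_id)) return("positive")
    "negative"
  } else {
    if (identical(a$superfamily_id, b$superfamily_id)) return("excluded")
    if (identical(a$fold_id, b$fold_id)) return("positive")
    "negative"
  }
}

#' Build per-query retrieval tasks from a domain database
#'
#' Every domain in the database becomes an independent query against the rest
#' of the database. For each query, every other domain is labelled by
#' [label_pair()]; excluded domains are removed from the candidate set, and
#' queries with zero positive candidates are dropped from the task list (they
#' have no remote homolog to find). The dropped ids are recorded in
#' `attr(, "dropped")`.
#'
#' @param db A `DomainDatabase`.
#' @param level `"superfamily"` or `"fold"`.
#' @return A list of `QueryTask` objects, each a list with `query_id`,
#'   `superfamily_id`, `fold_id`, `candidate_ids` (database order), `labels`
#'   (named 0/1 integer vector), `n_excluded` and `threshold_label`.
#' @export
build_query_tasks <- function(db, level = c("superfamily", "fold")) {
  level <- match.arg(level)
  stopifnot(inherits(db, "DomainDatabase"))
  if (nrow(db) == 0L) stopf("empty database")
  ids <- db$domain_id
  th <- attr(db, "identity_threshold_label")
  if (level == "superfamily") {
    excl_key <- db$family_id
    pos_key <- db$superfamily_id
  } else {
    excl_key <- db$superfamily_id
    pos_key <- db$fold_id
  }
  tasks <- vector("list", nrow(db))
  dropped <- character(0)
  for (i in seq_len(nrow(db))) {
    same_excl <- excl_key == excl_key[i]
    same_pos <- pos_key == pos_key[i]
    keep <- !same_excl
    labels <- as.integer(same_pos[keep])
    if (sum(labels) == 0L) {
      dropped <- c(dropped, ids[i])
      next
    }
    names(labels) <- ids[keep]
    tasks[[i]] <- structure(list(
      query_id = ids[i],
      superfamily_id = db$superfamily_id[i],
      fold_id = db$fold_id[i],
      candidate_ids = ids[keep],
      labels = labels,
      n_excluded = sum(same_excl) - 1L,
      threshold_label = th
    ), class = "QueryTask")
  }
  tasks <- tasks[!vapply(tasks, is.null, TRUE)]
  if (!length(tasks)) warnf("no queries retained at %s level", level)
  attr(tasks, "dropped") <- dropped
  attr(tasks, "level") <- level
  tasks
}

# Assemble a RankedList from parallel score/label vectors: descending score,
# exact ties broken by ascending candidate id.
make_ranked_list <- function(candidate_ids, scores, labels) {
  ord <- order(-scores, candidate_ids)
  structure(data.frame(
    candidate_id = candidate_ids[ord],
    score = scores[ord],
    label = as.integer(labels[ord]),
    stringsAsFactors = FALSE
  ), class = c("RankedList", "data.frame"), tie_policy = "ascending_candidate_id")
}

#' Rank a query's candidates by cosine similarity of representations
#'
#' Scores every candidate by cosine similarity between the query's and the
#' candidate's pooled representation and sorts descending; exact score ties
#' are broken by ascending candidate id so rankings are reproducible.
#' Candidates with a zero-norm (degenerate) representation are removed from
#' the ranking and listed in `attr(, "degenerate")`; a degenerate query is an
#' error.
#'
#' @param task A `QueryTask`.
#' @param store A pooled `RepresentationStore` covering the query and all
#'   candidates.
#' @return A `RankedList` data frame with columns `candidate_id`, `score`,
#'   `label`.
#' @export
rank_candidates <- function(task, store) {
  stopifnot(inherits(task, "QueryTask"), inherits(store, "RepresentationStore"))
  if (store$layout != "pooled") {
    stopf("rank_candidates requires a pooled store; call pool_store() first")
  }
  need <- c(task$query_id, task$candidate_ids)
  missing <- setdiff(need, store_ids(store))
  if (length(missing)) {
    stopf("store '%s' lacks representations for: %s", store$model_name,
          paste(missing, collapse = ", "))
  }
  q <- store$vectors[task$query_id, ]
  cand <- store$vectors[task$candidate_ids, , drop = FALSE]
  s <- cosine_scores(q, cand)
  degen <- task$candidate_ids[is.na(s)]
  keep <- !is.na(s)
  out <- make_ranked_list(task$candidate_ids[keep], s[keep], task$labels[keep])
  attr(out, "degenerate") <- degen
  out
}

#' Rank a query's candidates from a precomputed score matrix
#'
#' The same contract as [rank_candidates()], but scores come from a supplied
#' pairwise match-score matrix (rows = queries, columns = candidates, higher =
#' more similar). This is the route by which external baselines such as
#' profile-HMM alignment scorers enter the identical metric pipeline.
#'
#' @param task A `QueryTask`.
#' @param scores A numeric matrix with domain ids as dimnames, covering every
#'   (query, candidate) pair of the task.
#' @return A `RankedList` data frame.
#' @export
rank_candidates_from_matrix <- function(task, scores) {
  stopifnot(inherits(task, "QueryTask"), is.matrix(scores))
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stopf("score matrix requires domain-id dimnames")
  }
  if (!task$query_id %in% rownames(scores)) {
    stopf("score matrix lacks query '%s'", task$query_id)
  }
  missing <- setdiff(task$candidate_ids, colnames(scores))
  if (length(missing)) {
    stopf("score matrix lacks candidates: %s", paste(missing, collapse = ", "))
  }
  s <- scores[task$query_id, task$candidate_ids]
  if (any(!is.finite(s))) {
    bad <- task$candidate_ids[!is.finite(s)]
    stopf("non-finite score for pair(s) (%s, %s)", task$query_id,
          paste(bad, collapse = ", "))
  }
  make_ranked_list(task$candidate_ids, as.numeric(s), task$labels)
}
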