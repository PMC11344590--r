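# Independent oracles and tiny fixture builders shared across the suite.

# Brute-force AUROC: fraction of (positive, negative) pairs where the positive
# outscores the negative, ties credited 1/2. Independent of the package's
# rank-based implementation.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Direct average-precision summation over the ranked label sequence:
# sum over positive ranks k of precision@k, divided by the positive count.
oracle_ap <- function(ranked_labels) {
  ranks <- which(ranked_labels == 1L)
  sum(cumsum(ranked_labels)[ranks] / ranks) / length(ranks)
}

# Build a DomainDatabase from sccs tokens alone; sequences are irrelevant
# placeholders of distinct lengths.
toy_db <- function(sccs, ids = sprintf("dtoy%03d", seq_along(sccs)),
                   seqs = NULL) {
  if (is.null(seqs)) {
    seqs <- vapply(seq_along(sccs), function(i) {
      paste(rep(c("M", "K", "V", "L")[(i %% 4) + 1], 8 + (i %% 3)),
            collapse = "")
    }, "")
  }
  domain_database(domain_id = ids, sccs = sccs, sequence = seqs)
}

# A pooled store from an explicit id -> vector list.
toy_store <- function(vectors, model_name = "toy") {
  representation_store(do.call(rbind, vectors), model_name = model_name)
}

# A RankedList straight from scores/labels (bypassing task machinery) for
# metric tests; uses the package's deterministic tie-break.
ranked_from_scores <- function(scores, labels,
                               ids = sprintf("c%03d", seq_along(scores))) {
  ord <- order(-scores, ids)
  structure(data.frame(candidate_id = ids[ord], score = scores[ord],
                       label = as.integer(labels[ord]),
                       stringsAsFactors = FALSE),
            class = c("RankedList", "data.frame"))
}

# Random metric instance with optional score ties (small discrete support).
random_instance <- function(max_n = 12L, tie_prone = FALSE) {
  n <- sample(2:max_n, 1L)
  n_pos <- sample(seq_len(n - 1L), 1L)
  labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  scores <- if (tie_prone) sample(seq(0, 1, by = 0.25), n, replace = TRUE)
            else stats::runif(n)
  list(scores = scores, labels = labels)
}

# Direct per-query positive counts from database columns, used as the
# independent check on task construction and the query-dropping rule.
direct_positive_counts <- function(db, level) {
  if (level == "superfamily") {
    vapply(seq_len(nrow(db)), function(i) {
      sum(db$superfamily_id == db$superfamily_id[i] &
            db$family_id != db$family_id[i])
    }, 1L)
  } else {
    vapply(seq_len(nrow(db)), function(i) {
      sum(db$fold_id == db$fold_id[i] &
            db$superfamily_id != db$superfamily_id[i])
    }, 1L)
  }
}
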