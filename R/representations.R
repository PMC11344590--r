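#' Construct a representation store
#'
#' A `RepresentationStore` holds one representation per domain id for a single
#' model: either pooled (layout `"pooled"`, a numeric matrix with one row per
#' domain) or per-residue (layout `"per_residue"`, a named list of `l_i x D`
#' matrices). All representations must share the dimension D and contain only
#' finite values.
#'
#' @param vectors A numeric matrix with unique rownames (pooled layout), or a
#'   named list of numeric matrices (per-residue layout).
#' @param model_name Model label, e.g. `"prottrans_t5"`.
#' @param layout `"pooled"` or `"per_residue"`.
#' @return A `RepresentationStore` list with fields `model_name`, `layout`,
#'   `dim`, `vectors`.
#' @export
representation_store <- function(vectors, model_name,
                                 layout = c("pooled", "per_residue")) {
  layout <- match.arg(layout)
  if (layout == "pooled") {
    if (is.list(vectors) && !is.data.frame(vectors)) {
      dims <- vapply(vectors, length, 1L)
      if (length(unique(dims)) > 1L) {
        bad <- names(vectors)[dims != dims[1]]
        stopf("inconsistent dimensions in store '%s': %s", model_name,
              paste(bad, collapse = ", "))
      }
      vectors <- do.call(rbind, vectors)
    }
    stopifnot(is.matrix(vectors), is.numeric(vectors))
    if (is.null(rownames(vectors)) || anyDuplicated(rownames(vectors))) {
      stopf("pooled store requires unique domain-id rownames")
    }
    if (!all(is.finite(vectors))) {
      bad <- rownames(vectors)[!apply(is.finite(vectors), 1, all)]
      stopf("non-finite entries for: %s", paste(bad, collapse = ", "))
    }
    dim_d <- ncol(vectors)
  } else {
    stopifnot(is.list(vectors), !is.null(names(vectors)),
              !anyDuplicated(names(vectors)))
    dims <- vapply(vectors, ncol, 1L)
    if (length(unique(dims)) > 1L) {
      stopf("inconsistent dimensions in store '%s': %s", model_name,
            paste(names(vectors)[dims != dims[1]], collapse = ", "))
    }
    ok <- vapply(vectors, function(m) is.matrix(m) && all(is.finite(m)) &&
                   nrow(m) >= 1L, TRUE)
    if (!all(ok)) {
      stopf("invalid or non-finite matrices for: %s",
            paste(names(vectors)[!ok], collapse = ", "))
    }
    dim_d <- dims[1]
  }
  structure(list(model_name = model_name, layout = layout,
                 dim = as.integer(dim_d), vectors = vectors),
            class = "RepresentationStore")
}

#' @export
print.RepresentationStore <- function(x, ...) {
  n <- if (x$layout == "pooled") nrow(x$vectors) else length(x$vectors)
  cat(sprintf("<RepresentationStore '%s'> %d ids, dim %d, layout %s\n",
              x$model_name, n, x$dim, x$layout))
  invisible(x)
}

store_ids <- function(store) {
  if (store$layout == "pooled") rownames(store$vectors) else names(store$vectors)
}

#' Mean-pool a per-residue embedding matrix
#'
#' Collapses an `l_i x D` residue-level matrix to the protein-level vector by
#' averaging over the sequence length: `p_j = mean_k s[k, j]`. Accumulation is
#' in double precision.
#'
#' @param matrix A numeric matrix with `l_i >= 1` rows.
#' @param domain_id Optional id used in error messages.
#' @return A length-D numeric vector.
#' @export
pool_mean <- function(matrix, domain_id = NULL) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 1L)
  if (!all(is.finite(matrix))) {
    stopf("non-finite embedding entries%s",
          if (is.null(domain_id)) "" else sprintf(" for domain '%s'", domain_id))
  }
  colMeans(matrix)
}

#' Pool a per-residue store to a pooled store
#'
#' Applies [pool_mean()] to every matrix in a per-residue store; pooled stores
#' pass through unchanged.
#'
#' @param store A `RepresentationStore`.
#' @return A pooled `RepresentationStore`.
#' @export
pool_store <- function(store) {
  stopifnot(inherits(store, "RepresentationStore"))
  if (store$layout == "pooled") return(store)
  pooled <- t(vapply(names(store$vectors),
                     function(id) pool_mean(store$vectors[[id]], id),
                     numeric(store$dim)))
  if (store$dim == 1L) pooled <- matrix(pooled, ncol = 1L,
                                        dimnames = list(names(store$vectors), NULL))
  representation_store(pooled, model_name = store$model_name)
}

#' Cosine similarity of two representations
#'
#' `cos(u, v) = (u . v) / (||u|| ||v||)`; symmetric and invariant to positive
#' rescaling of either argument. Zero-norm vectors are degenerate
#' representations and raise an error rather than being silently scored.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A number in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stopf("dimension mismatch: %d vs %d", length(u), length(v))
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stopf("zero-norm (degenerate) representation")
  s <- sum(u * v) / (nu * nv)
  max(-1, min(1, s))
}

# Cosine of one query vector against a candidate matrix; NA for zero-norm
# candidates (handled by the caller), error for a zero-norm query.
cosine_scores <- function(query_vec, cand_mat) {
  nq <- sqrt(sum(query_vec^2))
  if (nq == 0) stopf("zero-norm (degenerate) query representation")
  nc <- sqrt(rowSums(cand_mat^2))
  s <- as.vector(cand_mat %*% query_vec) / (nc * nq)
  s[nc == 0] <- NA_real_
  pmax(-1, pmin(1, s))
}

#' Write a representation store to a plain-text file
#'
#' The on-disk format is a TSV with `#key=value` comment lines declaring
#' `model_name`, `layout` and `dim`, a header row `domain_id e1 ... eD`, and
#' one row per vector (pooled) or per residue, grouped by domain in order
#' (per-residue). Values are written with 17 significant digits so the
#' round-trip is exact to double precision.
#'
#' @param store A `RepresentationStore`.
#' @param path Output path.
#' @export
write_representation_store <- function(store, path) {
  stopifnot(inherits(store, "RepresentationStore"))
  if (store$layout == "pooled") {
    ids <- rownames(store$vectors)
    m <- store$vectors
  } else {
    ids <- rep(names(store$vectors), vapply(store$vectors, nrow, 1L))
    m <- do.call(rbind, store$vectors)
  }
  header <- c(sprintf("#model_name=%s", store$model_name),
              sprintf("#layout=%s", store$layout),
              sprintf("#dim=%d", store$dim),
              paste(c("domain_id", sprintf("e%d", seq_len(store$dim))),
                    collapse = "\t"))
  body <- paste(ids, apply(m, 1, function(r) {
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t")
  }), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Load a representation store from a plain-text file
#'
#' Reads the format written by [write_representation_store()]. Per-residue
#' stores can be pooled on load.
#'
#' @param path Path to the store file.
#' @param pool_if_needed If `TRUE`, a per-residue store is mean-pooled to a
#'   pooled store on load.
#' @return A `RepresentationStore`.
#' @export
load_representation_store <- function(path, pool_if_needed = FALSE) {
  lines <- readLines(path, n = 5L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#", "", ml), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  for (key in c("model_name", "layout", "dim")) {
    if (is.null(meta[[key]])) stopf("store '%s' lacks #%s metadata", path, key)
  }
  if (!meta$layout %in% c("pooled", "per_residue")) {
    stopf("unknown store layout '%s'", meta$layout)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  d <- as.integer(meta$dim)
  if (ncol(tab) != d + 1L) {
    stopf("store '%s': %d value columns but dim=%d", path, ncol(tab) - 1L, d)
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (meta$layout == "pooled") {
    rownames(m) <- tab$domain_id
    store <- representation_store(m, model_name = meta$model_name)
  } else {
    mats <- lapply(split(seq_len(nrow(m)), factor(tab$domain_id,
                                                  levels = unique(tab$domain_id))),
                   function(idx) m[idx, , drop = FALSE])
    store <- representation_store(mats, model_name = meta$model_name,
                                  layout = "per_residue")
    if (pool_if_needed) store <- pool_store(store)
  }
  store
}
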