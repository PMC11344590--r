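#' Specify a synthetic SCOP-like hierarchy
#'
#' Defines a balanced Class -> Fold -> Superfamily -> Family -> domain tree.
#' The total number of domains is the product of the four counts. All folds
#' are placed under a single synthetic class (`"a"`); tests that need
#' cross-class contrasts construct sccs tokens directly.
#'
#' @param n_folds,superfamilies_per_fold,families_per_superfamily,domains_per_family
#'   Positive integers.
#' @param seed Integer seed controlling sequence generation.
#' @param length_range Length-2 integer vector: sequence lengths are drawn
#'   uniformly from this range (default 50-200).
#' @return A `HierarchySpec` list.
#' @export
hierarchy_spec <- function(n_folds, superfamilies_per_fold,
                           families_per_superfamily, domains_per_family,
                           seed = 1L, length_range = c(50L, 200L)) {
  counts <- c(n_folds, superfamilies_per_fold, families_per_superfamily,
              domains_per_family)
  if (any(counts < 1L) || any(counts != as.integer(counts))) {
    stopf("all hierarchy counts must be positive integers")
  }
  stopifnot(length(length_range) == 2L, length_range[1] >= 1L,
            length_range[2] >= length_range[1])
  structure(list(n_folds = as.integer(n_folds),
                 superfamilies_per_fold = as.integer(superfamilies_per_fold),
                 families_per_superfamily = as.integer(families_per_superfamily),
                 domains_per_family = as.integer(domains_per_family),
                 seed = as.integer(seed),
                 length_range = as.integer(length_range)),
            class = "HierarchySpec")
}

#' Specify the hierarchical signal of synthetic embeddings
#'
#' Synthetic embeddings are sums of fold-, superfamily- and family-level
#' centroids plus isotropic Gaussian noise. Each centroid is an independent
#' standard-normal vector of dimension `dim`, drawn once per group from the
#' seeded stream, so the weight of each level controls how tightly that level
#' clusters in cosine space — the controllable analogue of the assumption that
#' representations of homologous domains are nearer than those of
#' non-homologs.
#'
#' @param dim Embedding dimension D (>= 2).
#' @param fold_weight,superfamily_weight,family_weight Non-negative weights of
#'   the level centroids.
#' @param noise_sd Standard deviation of per-domain Gaussian noise.
#' @param seed Integer seed.
#' @return A `SignalSpec` list.
#' @export
signal_spec <- function(dim = 16L, fold_weight = 0, superfamily_weight = 0,
                        family_weight = 0, noise_sd = 0, seed = 1L) {
  stopifnot(dim >= 2L, fold_weight >= 0, superfamily_weight >= 0,
            family_weight >= 0, noise_sd >= 0)
  if (fold_weight + superfamily_weight + family_weight + noise_sd == 0) {
    stopf("at least one weight or noise_sd must be positive")
  }
  structure(list(dim = as.integer(dim), fold_weight = fold_weight,
                 superfamily_weight = superfamily_weight,
                 family_weight = family_weight, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "SignalSpec")
}

#' Generate a synthetic classified domain database
#'
#' Enumerates the balanced hierarchy of a [hierarchy_spec()] with systematic
#' sccs paths (`a.<fold>.<superfamily>.<family>`) and sequential zero-padded
#' domain ids, and draws random amino-acid sequences over the 20 standard
#' letters. Sequence content is uncorrelated with the hierarchy: embeddings,
#' not sequences, carry the structural signal in this generator.
#'
#' @param spec A `HierarchySpec`.
#' @return A `DomainDatabase`. Deterministic for a fixed spec.
#' @export
generate_hierarchy <- function(spec) {
  stopifnot(inherits(spec, "HierarchySpec"))
  grid <- expand.grid(
    dom = seq_len(spec$domains_per_family),
    fam = seq_len(spec$families_per_superfamily),
    sf  = seq_len(spec$superfamilies_per_fold),
    fold = seq_len(spec$n_folds)
  )
  grid <- grid[order(grid$fold, grid$sf, grid$fam, grid$dom), , drop = FALSE]
  n <- nrow(grid)
  sccs <- sprintf("a.%d.%d.%d", grid$fold, grid$sf, grid$fam)
  ids <- sprintf("dsyn%05d", seq_len(n))
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  seqs <- with_seed(spec$seed, {
    lens <- sample(spec$length_range[1]:spec$length_range[2], n, replace = TRUE)
    vapply(lens, function(l) paste(sample(aa, l, replace = TRUE), collapse = ""), "")
  })
  domain_database(domain_id = ids, sccs = sccs, sequence = seqs,
                  description = "synthetic domain")
}

# Draw one standard-normal centroid per unique group id, in sorted id order so
# the assignment is independent of database row order.
draw_centroids <- function(group_ids, dim) {
  groups <- sort(unique(group_ids))
  m <- matrix(stats::rnorm(length(groups) * dim), nrow = length(groups))
  rownames(m) <- groups
  m
}

#' Generate pooled synthetic embeddings with hierarchical signal
#'
#' Each domain's vector is
#' `fold_weight * c_fold + superfamily_weight * c_SF + family_weight * c_F + eps`,
#' with centroids `c` drawn once per group and `eps ~ N(0, noise_sd^2 I)` per
#' domain. With a single positive level weight and no noise, all domains of a
#' group share one exact vector (within-group cosine 1); with all weights zero
#' and positive noise the embeddings carry no homology signal (null model).
#'
#' @param db A depth-4 classified `DomainDatabase`.
#' @param signal A `SignalSpec`.
#' @param model_name Name recorded in the returned store.
#' @return A pooled [representation_store()] with one vector per domain.
#' @export
generate_embeddings <- function(db, signal, model_name = "synthetic_signal") {
  stopifnot(inherits(db, "DomainDatabase"), inherits(signal, "SignalSpec"))
  n <- nrow(db)
  vec <- with_seed(signal$seed, {
    c_fold <- draw_centroids(db$fold_id, signal$dim)
    c_sf   <- draw_centroids(db$superfamily_id, signal$dim)
    c_fam  <- draw_centroids(db$family_id, signal$dim)
    eps <- matrix(stats::rnorm(n * signal$dim, sd = signal$noise_sd), nrow = n)
    signal$fold_weight        * c_fold[db$fold_id, , drop = FALSE] +
      signal$superfamily_weight * c_sf[db$superfamily_id, , drop = FALSE] +
      signal$family_weight      * c_fam[db$family_id, , drop = FALSE] +
      eps
  })
  rownames(vec) <- db$domain_id
  representation_store(vec, model_name = model_name)
}

#' Generate uniform-random baseline representations
#'
#' The no-information baseline: each domain receives a vector of independent
#' uniform-\[0,1) numbers of the given length (default 150), unrelated to the
#' classification. Ranking with these representations while keeping the true
#' homology labels calibrates every metric at chance level.
#'
#' @param ids Non-empty character vector of domain ids.
#' @param length Vector length (default 150).
#' @param seed Integer seed.
#' @param model_name Name recorded in the store.
#' @return A pooled [representation_store()].
#' @export
generate_random_representations <- function(ids, length = 150L, seed = 1L,
                                            model_name = "random_baseline") {
  if (!length(ids)) stopf("ids must be non-empty")
  if (anyDuplicated(ids)) stopf("ids must be unique")
  vec <- with_seed(seed, {
    matrix(stats::runif(length(ids) * length), nrow = base::length(ids))
  })
  rownames(vec) <- ids
  representation_store(vec, model_name = model_name)
}

#' Generate per-residue synthetic embedding matrices
#'
#' For each domain, an `l_i x D` matrix whose rows are the domain's pooled
#' target vector (exactly the [generate_embeddings()] output for the same
#' spec) plus independent per-residue Gaussian noise, so mean pooling recovers
#' the pooled vector up to noise of order `residue_noise_sd / sqrt(l_i)`.
#'
#' @param db A `DomainDatabase`.
#' @param signal A `SignalSpec` (drives the pooled targets).
#' @param residue_noise_sd Standard deviation of the per-residue noise.
#' @param model_name Name recorded in the store.
#' @return A per-residue [representation_store()]: a keyed list of matrices.
#' @export
generate_per_residue_embeddings <- function(db, signal, residue_noise_sd = 0,
                                            model_name = "synthetic_residue") {
  stopifnot(inherits(db, "DomainDatabase"), residue_noise_sd >= 0)
  pooled <- generate_embeddings(db, signal)
  lens <- nchar(db$sequence)
  mats <- with_seed(derive_seed(signal$seed, 104729L), {
    lapply(seq_len(nrow(db)), function(i) {
      l <- lens[i]
      target <- matrix(pooled$vectors[db$domain_id[i], ], nrow = l,
                       ncol = signal$dim, byrow = TRUE)
      target + matrix(stats::rnorm(l * signal$dim, sd = residue_noise_sd),
                      nrow = l)
    })
  })
  names(mats) <- db$domain_id
  representation_store(mats, model_name = model_name, layout = "per_residue")
}
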