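#!/usr/bin/env Rscript

# Stage 1: build the synthetic study set.
#
# Generates a SCOP-like classified domain database (4 folds x 2 superfamilies
# x 2 families x 5 domains = 80 domains, labelled as a 30%-identity subset)
# and four representation sources over it:
#   plm_strong   pooled embeddings with strong superfamily-level signal
#   plm_weak     pooled embeddings with weak signal in heavier noise
#   plm_residue  per-residue embeddings (mean-pooled downstream) whose pooled
#                targets match a mid-strength signal
#   random       the uniform-[0,1) length-150 baseline
# Everything is written as plain text under results/data/.

suppressMessages(library(remhombench))

RUN_SEED <- 2026L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

db <- generate_hierarchy(hierarchy_spec(4, 2, 2, 5, seed = RUN_SEED))
write_annotation_table(db, file.path(out_dir, "domains.tsv"))
cat(sprintf("database: %d domains, %d families, %d superfamilies, %d folds\n",
            nrow(db), length(unique(db$family_id)),
            length(unique(db$superfamily_id)), length(unique(db$fold_id))))

specs <- list(
  plm_strong = signal_spec(dim = 32, superfamily_weight = 2, noise_sd = 0.5,
                           seed = RUN_SEED + 1L),
  plm_weak   = signal_spec(dim = 32, superfamily_weight = 0.6, noise_sd = 1,
                           seed = RUN_SEED + 2L)
)
for (name in names(specs)) {
  st <- generate_embeddings(db, specs[[name]], model_name = name)
  write_representation_store(st, file.path(out_dir, paste0(name, ".tsv")))
  cat(sprintf("wrote %s: %d pooled vectors, dim %d\n", name, nrow(st$vectors),
              st$dim))
}

# shares the centroid draws of plm_weak (same seed and dimension) with a
# stronger superfamily weight: a stand-in for two related models trained on
# similar data, whose agreement stage 3 quantifies
resid <- generate_per_residue_embeddings(
  db, signal_spec(dim = 32, superfamily_weight = 1, noise_sd = 0.8,
                  seed = RUN_SEED + 2L),
  residue_noise_sd = 0.5, model_name = "plm_residue")
write_representation_store(resid, file.path(out_dir, "plm_residue.tsv"))
cat(sprintf("wrote plm_residue: %d per-residue matrices, dim %d\n",
            length(resid$vectors), resid$dim))

rnd <- generate_random_representations(db$domain_id, length = 150,
                                       seed = RUN_SEED + 4L,
                                       model_name = "random")
write_representation_store(rnd, file.path(out_dir, "random.tsv"))
cat("wrote random: uniform-[0,1) baseline, length 150\n")
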