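#!/usr/bin/env Rscript
# Stage 4: habitat and spatial predictors of association.
# Regresses the pairwise simple-ratio association matrix on habitat
# similarity (depth, distance to shore, distance to the shelf break) and
# geographic proximity, with significance from 1,000 QAP permutations of
# the response. Positive habitat-similarity coefficients indicate that
# whales using similar habitat associate more.
# Outputs (results/): mrqap.json

suppressPackageStartupMessages(library(podscape))
seed <- as.integer(Sys.getenv("PODSCAPE_SEED", "1"))

cov <- read.csv("results/covariates.csv")
assoc_wide <- as.matrix(read.csv("results/association.csv", row.names = 1,
                                 check.names = FALSE))
ids <- rownames(assoc_wide)

mean_by_id <- function(v) tapply(v, cov$id, mean)[ids]
preds <- list(
  build_predictor(mean_by_id(cov$depth_m), name = "depth_similarity"),
  build_predictor(mean_by_id(cov$dist_shore_km), name = "shore_similarity"),
  build_predictor(mean_by_id(cov$dist_shelf_km), name = "shelf_similarity"),
  geo_proximity_predictor(mean_by_id(cov$x), mean_by_id(cov$y), planar = TRUE)
)
fit <- fit_mrqap(assoc_wide, preds, n_perm = 1000, seed = seed)
print(fit)

jsonlite::write_json(
  list(beta = as.list(fit$beta), p_perm = as.list(fit$p_perm),
       adj_r2 = fit$adj_r2, f_stat = fit$f_stat, n = fit$n,
       n_perm = fit$n_perm, seed = fit$seed),
  "results/mrqap.json", auto_unbox = TRUE, digits = NA)
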