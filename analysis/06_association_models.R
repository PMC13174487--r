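#!/usr/bin/env Rscript
# Stage 6: association models.
#
# Kendall correlation and zero-inflated negative binomial regression of
# CXCL13 counts on the transition score (the model-based validation of
# the expression/state association), the quadratic-versus-linear model
# comparison, and a rank-based differential expression of Lymphoid-
# aggregate immune cells against the surrounding immune cells.

suppressPackageStartupMessages(library(stemniche))

counts <- as.matrix(read_expression("results/data/expression"))
scores <- read.csv("results/state_scores.csv")
expr <- lognorm(counts)

kt <- kendall_tau(expr["CXCL13", ], scores$transition)
cat(sprintf("Kendall tau (CXCL13 vs transition): %.3f (p = %.3g)\n",
            kt$tau, kt$p_value))

zb <- zinb_lrt(counts["CXCL13", ], cbind(transition = scores$transition))
cat(sprintf("ZINB: pi = %.3f, theta = %.2f, slope = %.2f, LRT = %.1f (p = %.3g)\n",
            zb$fit_full$pi, zb$fit_full$theta,
            zb$fit_full$beta[["transition"]], zb$lrt, zb$p_value))

qv <- quadratic_vs_linear(scores$transition, expr["CXCL13", ])
cat(sprintf("quadratic vs linear: R^2 %.3f vs %.3f, LRT %.1f (p = %.3g)\n",
            qv$r2_quadratic, qv$r2_linear, qv$lrt, qv$p_value))

# Lymphoid members vs surrounding immune cells, on the tissue panel
map <- read_cell_map("results/data/cell_map.csv")
texpr <- as.matrix(read_expression("results/data/tissue_expression"))
aggs <- read.csv("results/aggregates.csv")
mem <- read.csv("results/aggregate_membership.csv")
lymph_id <- aggs$aggregate_id[aggs$class_label == "Lymphoid"]
in_l <- mem$cell_id[mem$aggregate_id %in% lymph_id]
other <- setdiff(map$cell_id[map$cell_type != "tumor"], in_l)
de <- rank_de(texpr[, in_l, drop = FALSE], texpr[, other, drop = FALSE])
write.csv(de, "results/lymphoid_rank_de.csv", row.names = FALSE)
cat("rank DE, Lymphoid aggregate vs surrounding immune cells:\n")
print(de[order(de$p), ], row.names = FALSE)
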