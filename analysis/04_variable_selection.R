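#!/usr/bin/env Rscript

# Stage 4: data-driven variable selection on the extended variable set.
#
# Ranks all variables (completeness, within-variable logrank, permutation
# importance of a fitted model), then chooses how many top-ranked variables
# to keep by 3-fold cross-validated C-index. Writes rankings and the CV
# curve under results/selection/.

suppressPackageStartupMessages(library(survmiss))
seed <- 20180831 %% 2147483647
dir.create("results/selection", showWarnings = FALSE, recursive = TRUE)

cohort <- if (file.exists("results/cohort.csv")) {
  read_cohort("results/cohort.csv")
} else {
  generate_cohort(caliber_like_spec(10000, 200, seed = seed))$cohort
}
sp <- split_train_test(cohort, 2 / 3, seed = seed)

rk_miss <- rank_variables(sp$train, "missingness")
rk_lr <- rank_variables(sp$train, "logrank")
write_ranking(rk_miss, "results/selection/ranking_missingness.csv")
write_ranking(rk_lr, "results/selection/ranking_logrank.csv")
cat("top 10 by within-variable logrank:\n")
print(head(rk_lr$ranking, 10), digits = 3)

factory <- function(train, variables) {
  enc <- fit_encoder(train, "indicator")
  fit <- fit_cox(encode(enc, train), train$time, train$event)
  bl <- breslow_baseline(fit)
  function(new) predict_risk(fit, encode(enc, cohort_subset(
    new, variables = variables)), 5, baseline = bl)
}
sel <- select_count(rk_lr, c(100, 50, 25, 12, 6), factory, sp$train,
                    k = 3, seed = seed)
write.csv(sel$cv_curve, "results/selection/cv_curve.csv", row.names = FALSE)
cat(sprintf("chosen count: %d variables (CV C-index %.3f)\n", sel$count,
            max(sel$cv_curve$mean_c)))

risk <- sel$model(sp$test)
cat(sprintf("held-out C-index of the selected model: %.3f\n",
            c_index(risk, sp$test$time, sp$test$event)))

# permutation importance of the final model on held-out data
rk_perm <- rank_variables(cohort_subset(sp$test, variables = sel$variables),
                          "permutation", risk_fun = sel$model,
                          n_shuffles = 10, seed = seed)
write_ranking(rk_perm, "results/selection/ranking_permutation.csv")
cat("top 10 by permutation importance (held-out):\n")
print(head(rk_perm$ranking, 10), digits = 3)
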