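#!/usr/bin/env Rscript
# Recurrent composition modules: correlation structure, group discovery and
# naming, SVM validation of the groups, and log-rank survival stratification
# of the fibroblast-dominated group against the rest.

suppressMessages(library(lunghet))

comp_df <- read.delim("results/compositions.tsv", check.names = FALSE)
W <- as.matrix(comp_df[, setdiff(names(comp_df), c("sample", "residual"))])
rownames(W) <- comp_df$sample
samples <- read.delim("results/bulk_samples.tsv")

R <- composition_correlation(W)
write.table(data.frame(sample = rownames(R), R, check.names = FALSE),
            "results/composition_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ga <- discover_groups(W, k = "auto")
message(sprintf("discovered %d groups: %s", ga$k,
                paste(ga$group_names, collapse = ", ")))
write.table(ga$groups, "results/groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

svm_rep <- classify_subtypes(W, samples$group[match(rownames(W),
                                                    samples$sample)],
                             seed = 4)
message(sprintf("SVM on compositions vs true archetypes: mean AUC %.3f (SD %.3f)",
                svm_rep$mean_auc, svm_rep$sd_auc))

grp <- ga$groups$group_name[match(samples$sample, ga$groups$sample)]
contrast <- ifelse(grp == "Fib-high", "Fib-high", "rest")
lr <- logrank_test(samples$time, samples$event, contrast)
message(sprintf("log-rank Fib-high vs rest: chisq = %.2f, p = %.4g",
                lr$chisq, lr$p_value))
jsonlite::write_json(list(k = ga$k, group_names = ga$group_names,
                          svm_mean_auc = svm_rep$mean_auc,
                          svm_sd_auc = svm_rep$sd_auc,
                          logrank_chisq = lr$chisq,
                          logrank_p = lr$p_value),
                     "results/modules_survival.json",
                     auto_unbox = TRUE, digits = NA)
for (g in names(lr$curves))
  write.table(lr$curves[[g]],
              sprintf("results/km_curve_%s.tsv", gsub("[^A-Za-z0-9]", "_", g)),
              sep = "\t", quote = FALSE, row.names = FALSE)
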