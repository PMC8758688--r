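#!/usr/bin/env Rscript
# Simulate the study cohort: a desk-scale single-cell atlas (12 cell types,
# ~3000 cells, 2000 genes on 5 chromosomes) with malignant AT2/basal
# subclones carrying contiguous dosage events, plus 120 bulk samples drawn
# from four composition archetypes (Fib-high, AT2-high, NE-high, hybrid)
# with group-dependent survival. Everything downstream reads results/.

suppressMessages(library(lunghet))

dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)

catalog <- generate_gene_catalog(5, 400, seed = 1)
design <- cohort_design(seed = 1)
sim <- simulate_single_cells(catalog, design)
message(sprintf("simulated %d cells x %d genes (%d malignant: %s)",
                ncol(sim$cells$counts), nrow(sim$cells$counts),
                sum(sim$cells$meta$malignant),
                paste(names(table(sim$cells$meta$cell_type[sim$cells$meta$malignant])),
                      collapse = ", ")))

write_cohort(sim$cells, catalog, "results/cohort",
             truth = list(markers = sim$truth$markers,
                          events = sim$truth$events))

profiles <- cell_type_profiles(sim$cells)
bulk <- simulate_bulk(catalog, profiles, design, seed = 2)
write_bulk(bulk$bulk, "results/bulk_expression.tsv")

surv <- simulate_survival(bulk$truth$group, design$hazards,
                          design$censoring_rate, seed = 3)
samples <- data.frame(sample = colnames(bulk$bulk),
                      group = bulk$truth$group,
                      time = surv$time, event = surv$event)
write.table(samples, "results/bulk_samples.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample = rownames(bulk$truth$composition),
                       bulk$truth$composition, check.names = FALSE),
            "results/true_compositions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("simulated %d bulk samples from %d archetypes; %d deaths observed",
                nrow(samples), length(design$archetypes), sum(samples$event)))
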