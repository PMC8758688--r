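#!/usr/bin/env Rscript
# Build the cell-type signature matrix from the single cells and deconvolve
# the bulk cohort into cell-type compositions; check recovery against the
# simulated truth.

suppressMessages(library(lunghet))

cells <- read_cohort("results/cohort")
bulk <- read_bulk("results/bulk_expression.tsv")
truth <- read.delim("results/true_compositions.tsv", check.names = FALSE)
truth_w <- as.matrix(truth[, -1]); rownames(truth_w) <- truth$sample

signature <- build_signature_matrix(cells)
message(sprintf("signature: %d marker genes x %d cell types",
                nrow(signature$matrix), ncol(signature$matrix)))
write.table(data.frame(gene_id = rownames(signature$matrix),
                       signature$matrix, check.names = FALSE),
            "results/signature_matrix.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(signature$provenance, "results/signature_provenance.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

comp <- deconvolve(signature, bulk)
write.table(data.frame(sample = rownames(comp$weights), comp$weights,
                       residual = comp$residual, check.names = FALSE),
            "results/compositions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cons <- evaluate_consistency(comp$weights, truth_w[, colnames(comp$weights)])
message(sprintf("deconvolution vs truth: overall Pearson r = %.3f over %d samples",
                cons$overall, cons$n_pairs))
message("per-type r: ",
        paste(sprintf("%s %.2f", names(cons$per_type), cons$per_type),
              collapse = ", "))
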