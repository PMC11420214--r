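#!/usr/bin/env Rscript
# Secondary-structure fold grouping along a mutational path.
#
# Takes the bridged parent->winner path from analysis/04_neutral_path.R,
# predicts a baseline maximum-base-pairing structure for every intermediate
# and groups consecutive structures into folds by base-pair distance to each
# fold's first member. Abrupt fold changes along an otherwise single-mutation
# path are the structural signature of punctuated transitions between
# catalytic folds. (Structures from a thermodynamic predictor can be
# substituted via read_dotbracket_file(); fold counts are predictor-dependent.)

library(ribolandscape)
dir.create("results", showWarnings = FALSE)

report <- jsonlite::read_json("results/neutral_path_report.json",
                              simplifyVector = TRUE)
path <- report$sequences
cat(sprintf("Folding %d path intermediates (baseline max-pairing predictor)\n",
            length(path)))

structures <- lapply(path, nussinov_fold)
folds <- group_folds(structures, threshold = 8)
cat(sprintf("%d distinct folds along the path; new folds first appear at steps: %s\n",
            folds$n_folds,
            paste(folds$jump_indices, collapse = ", ")))

write_fold_tsv(folds, "results/path_folds.tsv")
jsonlite::write_json(list(n_folds = folds$n_folds,
                          jump_indices = folds$jump_indices),
                     "results/path_folds_summary.json", auto_unbox = TRUE)

# dot-bracket dump of the representative structure of each fold
lines <- unlist(lapply(folds$representatives, function(i) {
  c(sprintf(">fold%d_step%d", folds$fold_labels[i], i),
    structures[[i]]$sequence, structures[[i]]$dotbracket)
}))
writeLines(lines, "results/fold_representatives.db")
cat("Wrote results/path_folds.tsv, path_folds_summary.json, fold_representatives.db\n")
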