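#!/usr/bin/env Rscript
# Stage 4 — subcortical-weighted gradients.
#
# Weights each subject's first three aligned gradients by that subject's
# subcortical-cortical connectivity profiles (volume-scaled with the same
# rule as cortical edges), averages to per-structure degree values, and
# compares groups multivariately and per gradient (FDR across the 16
# structures). Outputs under results/subcortical/.

library(conngrad)

cohort_dir <- "results/cohort"
grad_dir <- "results/gradients"
out <- "results/subcortical"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rt <- read_region_table(file.path(cohort_dir, "regions.tsv"))
mf <- read_manifest(file.path(cohort_dir, "manifest.tsv"))
vols <- rt$volume[rt$is_cortical]
vol_sub <- rt$volume[!rt$is_cortical]
sub_names <- rt$name[!rt$is_cortical]

aligned <- lapply(mf$subject_id, function(id)
  read_matrix(file.path(grad_dir, paste0(id, "_gradients.tsv"))))
subc <- lapply(file.path(cohort_dir, mf$subcortical_path), read_matrix)
subc <- lapply(subc, function(s) s / outer(vol_sub, vols, `+`))
names(aligned) <- names(subc) <- mf$subject_id

degrees <- cohort_subcortical_degrees(aligned, subc, k = 3L)
dimnames(degrees)[[2]] <- sub_names
res <- compare_subcortical(degrees, design_matrix(mf))

write_stat_map(res$multivariate, file.path(out, "subcortical_multivariate.tsv"))
for (g in names(res$univariate)) {
  write_stat_map(res$univariate[[g]],
                 file.path(out, sprintf("subcortical_univariate_%s.tsv", g)))
}
# per-subject degree tables
deg_flat <- do.call(rbind, lapply(seq_len(dim(degrees)[1]), function(i)
  data.frame(subject_id = mf$subject_id[i], structure = sub_names,
             degrees[i, , ], row.names = NULL)))
write.table(deg_flat, file.path(out, "degrees.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

sm <- res$multivariate
cat("subcortical multivariate comparison (Hotelling's T2 across g1-g3):\n")
print(sm[order(-sm$statistic), ], row.names = FALSE, digits = 3)
cat(sprintf("maximal statistic: %s (T2 = %.2f)\n",
            sm$unit[which.max(sm$statistic)], max(sm$statistic)))
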