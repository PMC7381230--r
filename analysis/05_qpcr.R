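#!/usr/bin/env Rscript
# Step 5: qPCR confirmation — relative quantity of the planted genus
# against total-bacteria amplicons via 2^-dCt, compared between sorted
# and unsorted fractions with Student's t-test.

library(seroglycan)

fx <- "scratch/fixtures"
if (!file.exists(file.path(fx, "qpcr_ct.tsv"))) {
  source("analysis/01_simulate_cohort.R")
}
dir.create("results", showWarnings = FALSE)

ct <- read_ct_table(file.path(fx, "qpcr_ct.tsv"))
rq <- delta_ct_quantities(ct)
sheet <- read.delim(file.path(fx, "sample_sheet.tsv"),
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
rq$fraction <- sheet$fraction[match(rq$sample_id, sheet$sample_id)]
write.table(rq, "results/qpcr_relative_quantities.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("median relative quantity (target / total bacteria) by fraction:\n")
print(tapply(rq$relative_quantity, rq$fraction, median), digits = 3)

rq$serum_group <- sheet$serum_group[match(rq$sample_id, sheet$sample_id)]

compare <- function(sel, label) {
  res <- compare_fractions(rq$relative_quantity[sel], rq$fraction[sel])
  cat(sprintf("%s: t = %.2f, p = %.3g (n = %d vs %d)\n",
              label, res$statistic, res$p_value, res$n_a, res$n_b))
}
compare(rq$fraction %in% c("AAL_pos", "unsorted") &
          rq$serum_group %in% c("none"),
        "AAL_pos vs matched unsorted")
# only CD sera carry the planted IgG binding, so the informative contrast
# is the CD-captured fraction against its matched unsorted samples
compare(rq$fraction %in% c("IgG_pos", "unsorted") & rq$serum_group == "CD",
        "IgG_pos (CD sera) vs matched unsorted")
compare(rq$fraction %in% c("IgG_pos", "unsorted") & rq$serum_group == "ctrl",
        "IgG_pos (ctrl sera) vs matched unsorted")
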