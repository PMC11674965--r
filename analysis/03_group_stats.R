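#!/usr/bin/env Rscript

# Stage 3: group comparisons and brain-behavior correlation.
# Wilcoxon rank-sum per connection (FC: 12 tests; directed TGC: 24 tests),
# Holm-corrected within each subsystem family (DVS/VVS/VS; both directions
# of a connection share the directed family), and Spearman correlation of
# the designated connection's FC and TGC with response time over the
# brain-behavior subset.

library(dvsconn)

if (!file.exists("results/connectivity.csv"))
  stop("run analysis/02_connectivity.R first")

config <- cohort_config(seed = 1L)
cohort <- generate_cohort(config)
subj <- cohort$subjects
conn_tbl <- utils::read.csv("results/connectivity.csv",
                            stringsAsFactors = FALSE)

groups <- setNames(subj$group, subj$subject_id)
fc_tests <- compare_groups(conn_tbl, groups, "fc")
tgc_tests <- compare_groups(conn_tbl, groups, "tgc")
utils::write.csv(fc_tests, "results/fc_tests.csv", row.names = FALSE)
utils::write.csv(tgc_tests, "results/tgc_tests.csv", row.names = FALSE)

report_sig <- function(tests, label) {
  sig <- tests[tests$p_holm < 0.05, ]
  if (nrow(sig) == 0) {
    cat("no", label, "connection survives Holm correction;",
        "smallest raw p:", format(min(tests$p_raw), digits = 3), "at",
        tests$connection[which.min(tests$p_raw)], "\n")
  } else {
    for (i in seq_len(nrow(sig)))
      cat(sprintf("%s %s (%s): p_raw %.4f, Holm p* %.4f\n", label,
                  sig$connection[i], sig$direction[i], sig$p_raw[i],
                  sig$p_holm[i]))
  }
}
report_sig(fc_tests, "FC")
report_sig(tgc_tests, "TGC")

# brain-behavior over the 44-subject subset with fMRI and RT
rts <- setNames(subj$response_time_ms, subj$subject_id)
rts[!(subj$fmri_complete & subj$rt_complete)] <- NA
bb_fc <- brain_behavior(conn_tbl, rts, "L SOG--L SPL", "fc", "undirected")
bb_tgc <- brain_behavior(conn_tbl, rts, "L SOG--L SPL", "tgc", "a->b")
cat(sprintf("FC  vs RT: rho = %.3f, p = %.4f, n = %d\n",
            bb_fc$rho, bb_fc$p, bb_fc$n))
cat(sprintf("TGC vs RT: rho = %.3f, p = %.4f, n = %d\n",
            bb_tgc$rho, bb_tgc$p, bb_tgc$n))
bb_path <- "results/brain_behavior.csv"
utils::write.csv(rbind(as.data.frame(bb_fc), as.data.frame(bb_tgc)),
                 bb_path, row.names = FALSE)
cat("group statistics written to results/\n")
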