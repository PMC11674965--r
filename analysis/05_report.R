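#!/usr/bin/env Rscript

# Stage 5: report and figures.
# Writes the markdown summary of Holm-significant connections and, when
# ggplot2 is available, plain violin and scatter analogues of the group
# difference and brain-behavior plots for the designated connections.

library(dvsconn)

needed <- c("results/connectivity.csv", "results/fc_tests.csv",
            "results/tgc_tests.csv", "results/structural_tests.csv")
if (!all(file.exists(needed)))
  stop("run analysis stages 1-4 first")

config <- cohort_config(seed = 1L)
cohort <- generate_cohort(config)
subj <- cohort$subjects
conn_tbl <- utils::read.csv("results/connectivity.csv",
                            stringsAsFactors = FALSE)

results <- list(
  connectivity = conn_tbl,
  fc_tests = utils::read.csv("results/fc_tests.csv"),
  tgc_tests = utils::read.csv("results/tgc_tests.csv"),
  structural_tests = utils::read.csv("results/structural_tests.csv"),
  brain_behavior = {
    rts <- setNames(subj$response_time_ms, subj$subject_id)
    rts[!(subj$fmri_complete & subj$rt_complete)] <- NA
    list(fc = brain_behavior(conn_tbl, rts, "L SOG--L SPL", "fc"),
         tgc = brain_behavior(conn_tbl, rts, "L SOG--L SPL", "tgc",
                              "a->b"))
  })

path <- run_report(results, "results")
cat("report written to", path, "\n")
cat(readLines(path), sep = "\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE)

  des <- conn_tbl[conn_tbl$connection == "L SOG--L SPL" &
                    conn_tbl$metric == "fc", ]
  des$group <- subj$group[match(des$subject_id, subj$subject_id)]
  p1 <- ggplot(des, aes(group, value, fill = group)) +
    geom_violin(alpha = 0.6) + geom_jitter(width = 0.08, size = 1) +
    labs(y = "FC (Pearson r)", x = NULL,
         title = "L SOG -- L SPL undirected connectivity") +
    theme_minimal() + theme(legend.position = "none")
  ggsave("results/figures/fc_violin.png", p1, width = 4, height = 4,
         dpi = 150)

  tgc <- conn_tbl[conn_tbl$connection == "L SOG--L SPL" &
                    conn_tbl$direction == "a->b", ]
  tgc$rt <- subj$response_time_ms[match(tgc$subject_id, subj$subject_id)]
  tgc$group <- subj$group[match(tgc$subject_id, subj$subject_id)]
  p2 <- ggplot(tgc[!is.na(tgc$rt), ], aes(value, rt, colour = group)) +
    geom_point() + geom_smooth(method = "lm", se = FALSE,
                               colour = "grey30", linewidth = 0.5) +
    labs(x = "TGC (L SOG → L SPL)", y = "response time (ms)",
         title = "Brain-behavior relation") +
    theme_minimal()
  ggsave("results/figures/tgc_vs_rt.png", p2, width = 5, height = 4,
         dpi = 150)
  cat("figures written to results/figures/\n")
}
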