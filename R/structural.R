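#' Load a per-subject, per-connection structural metric table
#'
#' Reads and validates a CSV of fractional anisotropy (FA) and quantitative
#' anisotropy (QA) scalars, one row per (subject, connection), as exported by
#' tractography software or produced by [generate_structural_table()].
#' Fiber tracking itself is out of scope; the table interface consumes its
#' scalar summaries.
#'
#' @param path CSV path with columns `subject_id`, `connection`, `fa`, `qa`
#'   (an optional `subsystem` column is preserved).
#' @return Validated data frame (possibly empty).
#' @export
load_structural_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "connection", "fa", "qa")
  missing <- setdiff(required, names(tbl))
  if (length(missing))
    stop("structural table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(tbl) == 0) return(tbl)
  bad_fa <- which(!is.finite(tbl$fa) | tbl$fa <= 0 | tbl$fa >= 1)
  if (length(bad_fa))
    stop("FA outside (0, 1) at row(s): ", paste(bad_fa, collapse = ", "))
  bad_qa <- which(!is.finite(tbl$qa) | tbl$qa <= 0)
  if (length(bad_qa))
    stop("QA must be positive; offending row(s): ",
         paste(bad_qa, collapse = ", "))
  if (anyDuplicated(tbl[, c("subject_id", "connection")]))
    stop("duplicate (subject, connection) rows in structural table")
  tbl
}

#' Reference tractography parameters per connection
#'
#' The packaged per-connection deterministic-tracking parameter set
#' (minimum/maximum fiber length, angular threshold, QA threshold) shipped
#' as reference metadata for validating external exports; it plays no role
#' in computation.
#'
#' @return Data frame with one row per connection.
#' @export
tracking_parameters <- function() {
  path <- system.file("extdata", "tracking_parameters.csv",
                      package = "dvsconn", mustWork = TRUE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(tbl$min_length_mm < tbl$max_length_mm),
            all(tbl$angular_threshold_deg > 0 &
                  tbl$angular_threshold_deg < 90))
  tbl$connection <- connection_label(tbl$roi_a, tbl$roi_b)
  tbl
}

#' Group comparison of structural anisotropy metrics
#'
#' Routes FA and QA through the same statistical engine as the functional
#' comparisons ([compare_groups()]): one Wilcoxon rank-sum test per
#' connection per metric, Holm-corrected within each subsystem family.
#'
#' @param records Structural table (`subject_id`, `connection`, `fa`, `qa`,
#'   optionally `subsystem`; subsystems are filled in from the atlas
#'   connections when absent).
#' @param groups Named character vector mapping subject id to group.
#' @param alternative Test sidedness, default two-sided.
#' @return Row-bound [compare_groups()] results for `fa` and `qa`.
#' @export
structural_group_comparison <- function(records, groups,
                                        alternative = "two.sided") {
  if (!"subsystem" %in% names(records)) {
    conns <- stream_connections(visual_stream_atlas())
    records$subsystem <- conns$subsystem[match(records$connection,
                                               conns$connection)]
  }
  long <- rbind(
    data.frame(subject_id = records$subject_id,
               connection = records$connection,
               subsystem = records$subsystem,
               metric = "fa", direction = "undirected",
               value = records$fa, stringsAsFactors = FALSE),
    data.frame(subject_id = records$subject_id,
               connection = records$connection,
               subsystem = records$subsystem,
               metric = "qa", direction = "undirected",
               value = records$qa, stringsAsFactors = FALSE))
  rbind(compare_groups(long, groups, "fa", alternative),
        compare_groups(long, groups, "qa", alternative))
}
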