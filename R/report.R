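# Table-style reporting: per-subunit and per-case accuracy tables plus
# the packaged clinical reference table.

ROMAN_SUBUNITS <- c("I", "II", "III", "IV", "V")

#' Reference per-case accuracy of unilateral clinical reconstructions
#'
#' The published per-case reference table for the 15 unilateral clinical
#' defect cases of the original clinical evaluation of this reconstruction
#' approach: cause of defect, cosine similarity and mean surface error
#' (mm) per case. Shipped as a plain-text input for report aggregation and
#' as the canonical example of the per-case report schema.
#'
#' @return data.frame with columns `case`, `cause`, `cosine`,
#'   `mean_error_mm` (15 rows).
#' @export
clinical_cases <- function() {
  path <- system.file("extdata", "clinical_cases.csv", package = "midfacer",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))

#' Render per-subunit and per-case accuracy tables
#'
#' Produces the two standard report tables: per-subunit mean +- SD of
#' cosine similarity and mean error over subunits I-V plus an overall row,
#' and a per-case listing with an average row. Ordering is deterministic
#' (subunits I-V; cases in input order); display values are rounded
#' half-up to 2 decimals.
#'
#' @param subunit_results data.frame with columns `subunit` (1..5),
#'   `cosine`, `mean_error_mm`, one row per artificial-defect case; may be
#'   NULL to skip table 1.
#' @param case_results data.frame with columns `case`, `cause`, `cosine`,
#'   `mean_error_mm`, one row per clinical case; may be NULL to skip
#'   table 2.
#' @param dir optional output directory; writes `table1.csv` /
#'   `table2.csv` there.
#' @return List with data.frames `table1`, `table2` and markdown strings
#'   `table1_md`, `table2_md` (NULL where the input was NULL).
#' @export
render_tables <- function(subunit_results = NULL, case_results = NULL,
                          dir = NULL) {
  out <- list(table1 = NULL, table2 = NULL, table1_md = NULL,
              table2_md = NULL)
  if (!is.null(subunit_results)) {
    stopifnot(all(c("subunit", "cosine", "mean_error_mm") %in%
                    names(subunit_results)))
    rows <- lapply(1:5, function(su) {
      sel <- subunit_results$subunit == su
      if (!any(sel))
        return(data.frame(subunit = ROMAN_SUBUNITS[su],
                          cosine_similarity = "-",
                          mean_error_mm = "-"))
      cs <- summarize_group(subunit_results$cosine[sel])
      er <- summarize_group(subunit_results$mean_error_mm[sel])
      data.frame(
        subunit = ROMAN_SUBUNITS[su],
        cosine_similarity = paste0(fmt2(cs$mean), " +- ", fmt2(cs$sd)),
        mean_error_mm = paste0(fmt2(er$mean), " +- ", fmt2(er$sd)))
    })
    cs <- summarize_group(subunit_results$cosine)
    er <- summarize_group(subunit_results$mean_error_mm)
    t1 <- rbind(do.call(rbind, rows), data.frame(
      subunit = "overall",
      cosine_similarity = paste0(fmt2(cs$mean), " +- ", fmt2(cs$sd)),
      mean_error_mm = paste0(fmt2(er$mean), " +- ", fmt2(er$sd))))
    out$table1 <- t1
    out$table1_md <- df_to_markdown(t1)
  }
  if (!is.null(case_results)) {
    stopifnot(all(c("case", "cause", "cosine", "mean_error_mm") %in%
                    names(case_results)))
    t2 <- data.frame(
      case = as.character(case_results$case),
      cause = case_results$cause,
      cosine_similarity = fmt2(case_results$cosine),
      mean_error_mm = fmt2(case_results$mean_error_mm))
    t2 <- rbind(t2, data.frame(
      case = "average", cause = "-",
      cosine_similarity = fmt2(mean(case_results$cosine)),
      mean_error_mm = fmt2(mean(case_results$mean_error_mm))))
    out$table2 <- t2
    out$table2_md <- df_to_markdown(t2)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    if (!is.null(out$table1))
      utils::write.csv(out$table1, file.path(dir, "table1.csv"),
                       row.names = FALSE)
    if (!is.null(out$table2))
      utils::write.csv(out$table2, file.path(dir, "table2.csv"),
                       row.names = FALSE)
  }
  out
}

df_to_markdown <- function(df) {
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(hdr, sep, rows), collapse = "\n")
}
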