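# Packaged 25-cell-line screen tables. Values are fixture data: they are
# loaded, checksum-verified and summarized, never recomputed from curves
# (the AUC convention behind them is not recoverable from dose data alone).

.fixture_md5 <- c(
  hnscc_table1.tsv = "47d788d0f8e3090c012cd33fe8ebd4e0",
  hnscc_table2.tsv = "bdad0561200e1112eef690490be915a5"
)

read_fixture <- function(file) {
  path <- system.file("extdata", file, package = "basalscreen", mustWork = TRUE)
  got <- unname(tools::md5sum(path))
  if (!identical(got, unname(.fixture_md5[[file]]))) {
    abort(paste0("fixture checksum mismatch for ", file,
                 ": expected ", .fixture_md5[[file]], ", got ", got))
  }
  readr::read_tsv(path, show_col_types = FALSE, na = "NA")
}

#' Packaged single-agent screen table (25 HNSCC cell lines)
#'
#' Dose-response AUC values for 25 HNSCC cell lines (10 basal, 15 non-basal
#' by consensus transcriptomic call) under six drugs: the EGFR-directed
#' Afatinib, Erlotinib and Cetuximab, plus Gedatolisib (PI3K/mTOR),
#' Cobimetinib (MEK) and Trastuzumab (HER2). Lower AUC means greater
#' sensitivity.
#'
#' @return Tibble `cell_line`, `subtype`, one AUC column per drug.
#' @export
hnscc_table1 <- function() read_fixture("hnscc_table1.tsv")

#' Packaged drug-combination Bliss score table (25 HNSCC cell lines)
#'
#' Bliss synergy scores for the nine pairwise combinations of the three
#' EGFR-directed drugs with Cobimetinib, Gedatolisib and Trastuzumab, per
#' cell line; some entries are missing (NA).
#'
#' @return Tibble `cell_line`, `subtype`, one score column per combination.
#' @export
hnscc_table2 <- function() read_fixture("hnscc_table2.tsv")

#' Summarize a packaged screen table
#'
#' For the single-agent table: per-drug mean AUC over all lines, basal and
#' non-basal group means, and a Welch t-test of the group difference. For
#' the combination table: the same per combination on Bliss scores, with
#' missing values dropped and counted.
#'
#' @param which `"table1"` (single-agent AUC) or `"table2"` (Bliss scores).
#' @param variant t-test variant passed to [two_sample_t()].
#' @return A tibble with one row per drug or combination: `measure`,
#'   `mean_all`, `mean_basal`, `mean_nonbasal`, `direction` (sign of basal
#'   minus non-basal), `statistic`, `p_value`, `n_missing`.
#' @examples
#' analyze_fixture("table1")
#' @export
analyze_fixture <- function(which = c("table1", "table2"),
                            variant = "welch") {
  which <- match.arg(which)
  tab <- if (which == "table1") hnscc_table1() else hnscc_table2()
  long <- tab |>
    tidyr::pivot_longer(-c("cell_line", "subtype"),
                        names_to = "measure", values_to = "value")
  long |>
    dplyr::group_by(.data$measure) |>
    dplyr::group_modify(function(d, key) {
      basal <- d$value[d$subtype == "Basal" & !is.na(d$value)]
      nonbasal <- d$value[d$subtype == "Non-Basal" & !is.na(d$value)]
      ht <- two_sample_t(basal, nonbasal, variant = variant)
      tibble(
        mean_all = mean(d$value, na.rm = TRUE),
        mean_basal = mean(basal),
        mean_nonbasal = mean(nonbasal),
        direction = sign(mean(basal) - mean(nonbasal)),
        statistic = ht$statistic,
        p_value = ht$p_value,
        n_missing = sum(is.na(d$value))
      )
    }) |>
    dplyr::ungroup()
}
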