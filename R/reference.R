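#' Published reference medians for hypocotyl secondary growth
#'
#' Median per-section cell counts and total transverse areas reported for
#' the Arabidopsis accessions Col-0 and Ler at the start (15 dag) and end
#' (35 dag) of the secondary-growth time course. Shipped as a small
#' plain-text table for comparisons such as proliferation fold changes.
#'
#' @return data.frame with columns `genotype`, `timepoint_dag`,
#'   `median_cell_count`, `median_total_area_um2`.
#' @export
reference_counts <- function() {
  utils::read.csv(
    system.file("extdata", "reference_counts.csv", package = "quanthisto"),
    stringsAsFactors = FALSE
  )
}

#' Cell-proliferation fold change between two time points
#'
#' Ratio of median cell counts at the last and first time point per
#' genotype — e.g. from 15 to 35 dag the reference medians give a ~21-fold
#' increase for Col-0 (18124/883) and a ~42-fold increase for Ler
#' (11026/260): lower overall but higher relative secondary growth in Ler.
#'
#' @param counts data.frame as returned by [reference_counts()] (or any
#'   table with `genotype`, `timepoint_dag`, `median_cell_count`).
#' @return data.frame with `genotype`, `from_dag`, `to_dag`, `fold_change`.
#' @export
proliferation_fold_change <- function(counts = reference_counts()) {
  out <- lapply(split(counts, counts$genotype), function(d) {
    d <- d[order(d$timepoint_dag), ]
    first <- d[1, ]
    last <- d[nrow(d), ]
    data.frame(
      genotype = first$genotype,
      from_dag = first$timepoint_dag, to_dag = last$timepoint_dag,
      fold_change = last$median_cell_count / first$median_cell_count
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
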