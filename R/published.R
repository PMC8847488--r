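#' Tag composition of the clinical development cohort
#'
#' The published per-split embryo counts of the multi-centre clinical
#' cohort the method was developed on, by implantation/genetic tag. These
#' counts are reference inputs for sanity arithmetic — e.g. the fully
#' supervised stage A trains on the KID-labeled training embryos only, so
#' its training-set size is the train KIDp + KIDn total.
#'
#' @return `data.frame` with one row per split (`train_val`, `test`) and
#'   columns `KIDp`, `KIDn`, `KIDu`, `Discarded`, `Hard_discarded`,
#'   `Not_KID`, `Euploid`, `Aneuploid`.
#' @export
clinical_tag_counts <- function() {
  data.frame(
    split = c("train_val", "test"),
    KIDp = c(1314L, 380L),
    KIDn = c(6485L, 637L),
    KIDu = c(2106L, 404L),
    Discarded = c(36507L, 2289L),
    Hard_discarded = c(11504L, 687L),
    Not_KID = c(14934L, 2333L),
    Euploid = c(3427L, 592L),
    Aneuploid = c(13L, 58L)
  )
}

#' Size of the fully supervised training set
#'
#' The number of embryos available to the fully supervised cascade stage:
#' the KID-labeled (KIDp + KIDn) embryos of the training split.
#'
#' @param counts a tag-count table as returned by [clinical_tag_counts()].
#' @param split which split row to use.
#' @return integer count.
#' @export
n_supervised_embryos <- function(counts = clinical_tag_counts(),
                                 split = "train_val") {
  row <- counts[counts$split == split, ]
  as.integer(row$KIDp + row$KIDn)
}
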