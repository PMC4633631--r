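#' Published estimates bundled with the package
#'
#' Three small reference tables from a large single-centre case-control
#' study of nine pediatric autoimmune diseases (plus pediatric epilepsy as
#' a non-immune comparator), used for worked examples and for checking the
#' package's report arithmetic against printed values:
#'
#' * `"cohorts"` — per-disease case/control counts, genomic-inflation
#'   factor, and the observed population prevalence used for the
#'   liability-scale transform.
#' * `"h2"` — SNP-heritability estimates (all autosomes, autosomes
#'   excluding the extended MHC, chromosome X) with SEs, LRT p-values and
#'   the MHC percentage contribution. P-values printed as "<1e-4" are
#'   stored as 1e-4.
#' * `"rg"` — genetic-correlation estimates for the disease pairs reaching
#'   nominal significance, with and without the extended MHC, and the
#'   Bonferroni-adjusted (9 tests per disease) column.
#'
#' @param which One of "cohorts", "h2", "rg".
#' @return A data frame.
#' @export
published_estimates <- function(which = c("cohorts", "h2", "rg")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("published_", which, ".tsv"),
                   package = "coherit", mustWork = TRUE)
  utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "")
}
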