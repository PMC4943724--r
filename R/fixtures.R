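#' Published trait-correlation summaries for Nellore bulls
#'
#' Loads the bundled cross-trait correlation matrices among nine growth and
#' carcass traits (birth weight; weaning and post-weaning gain; conformation,
#' carcass finishing precocity and muscling at weaning and yearling)
#' reported for a Nellore bull reference population: correlations among
#' deregressed EBVs, and among genome-wide association t-values. Their
#' upper-triangle off-diagonal means (0.442 and 0.423) are the two summary
#' statistics used to motivate pleiotropy mapping in this population, and
#' serve as a worked example for \code{\link{meanOffdiagonal}}.
#'
#' @param which \code{"debv"} or \code{"tvalues"}.
#' @return 9 x 9 numeric matrix with trait dimnames.
#' @export
nelloreTraitCorrelations <- function(which = c("debv", "tvalues")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("nellore_", sub("values", "value", which),
                          "_correlations.tsv"),
                   package = "pleioscan", mustWork = TRUE)
  df <- read.table(f, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  as.matrix(df)
}
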