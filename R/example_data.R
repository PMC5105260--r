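#' Published diversity summaries of ten example compound collections
#'
#' Whole-library scaffold metrics (chemotype count N, library size M,
#' singleton count N_sing, CSR AUC, F50), median intra-library
#' MACCS/Tanimoto similarity and mean intra-set property distance for ten
#' well-known compound collections: two commercial natural-product
#' screening sets (MEGx, NATx), flavor compounds generally recognized as
#' safe (GRAS) and its cyclic subset, carcinogenic compounds and their
#' cyclic subset, approved anticancer and non-anticancer drugs, clinical
#' candidates, and an epigenetic-focused screening set. The table serves as
#' the worked example for threshold resolution and quadrant
#' classification when the underlying structures are not at hand.
#'
#' @return data.frame with columns `set_name`, `N`, `M`, `N_sing`, `auc`,
#'   `f50`, `median_maccs`, `property_distance` (NA where not published
#'   for a subset).
#' @examples
#' ex <- exampleLibrarySummaries()
#' stats::median(ex$f50)
#' @export
exampleLibrarySummaries <- function() {
  f <- system.file("extdata", "example_library_summaries.tsv",
                   package = "ConsensusDiversity", mustWork = TRUE)
  utils::read.delim(f, check.names = FALSE, stringsAsFactors = FALSE)
}
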