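#' Published four-target benchmark probability matrices
#'
#' The assignment probability matrices P(nu = i) reported for the
#' four-target benchmark (ESR, VDR, COX2, CTSD) at mixture sizes
#' K = 1, 3 and 7, together with the published feasibility-index column.
#' Shipped as package data so that the feasibility computation can be
#' checked against the published values: applying
#' `feasibility_index(diag, "table4")` to each block's diagonal
#' reproduces `F_printed` to the precision of the rounded inputs.
#'
#' @return Data frame with columns `K`, `class`, one probability column
#'   per predicted class (`ESR`, `VDR`, `COX2`, `CTSD`) and `F_printed`.
#' @examples
#' b <- benchmark_prob_matrix()
#' p_self <- b[b$K == 1 & b$class == "CTSD", "CTSD"]
#' feasibility_index(p_self)   # about 3.972
#' @export
benchmark_prob_matrix <- function() {
  utils::read.table(
    system.file("extdata", "benchmark_prob_matrix.tsv",
                package = "klscreen", mustWork = TRUE),
    sep = "\t", header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE)
}
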