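# Protein local-alignment scoring in bits, BLOSUM62 with affine gaps
# (open 11, extend 1) and the standard gapped Karlin-Altschul constants for
# that matrix (lambda = 0.267, K = 0.041), so scores and E-values are on the
# familiar blastp scale.

ka_lambda <- 0.267
ka_K <- 0.041

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

raw_to_bits <- function(raw) (ka_lambda * raw - log(ka_K)) / log(2)

#' Local alignment bitscores of protein queries against one subject
#'
#' Smith-Waterman local alignment (via Biostrings) of each query against the
#' subject with BLOSUM62, gap open 11 / extend 1, converted to bits with the
#' gapped Karlin-Altschul parameters of that scoring system, plus the
#' corresponding E-value `len(query) * len(subject) * 2^-bits`. This is the
#' scorer the simulator uses in place of blastp.
#'
#' @param queries character vector (or `AAStringSet`) of query sequences.
#' @param subject single subject sequence.
#' @return data frame with `raw`, `bits`, `evalue` (one row per query).
#' @export
align_bits <- function(queries, subject) {
  qs <- Biostrings::AAStringSet(queries)
  sub <- Biostrings::AAString(subject)
  raw <- Biostrings::pairwiseAlignment(
    qs, sub, type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  bits <- raw_to_bits(raw)
  data.frame(raw = raw, bits = bits,
             evalue = Biostrings::width(qs) * length(sub) * 2^(-bits))
}
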