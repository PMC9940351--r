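#' The 61 sense codons
#'
#' Sense codons of the standard genetic code, alphabetically ordered.
#' Stop codons (TAA, TAG, TGA) are excluded: dwelling occupancy is defined
#' over codons decoded in the ribosomal A-site.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc != "*"])
}

#' Stop codons of the standard genetic code
#' @return Character vector of length 3.
#' @export
stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc == "*"])
}

#' Read a tAI table
#'
#' Reads a two-column TSV (codon, tai) mapping each of the 61 sense codons to
#' a tRNA adaptation index value in (0, 1]. The tAI is a per-codon proxy for
#' decoding speed derived from tRNA gene copy numbers; higher means more
#' optimal.
#'
#' @param path Path to a TSV with columns \code{codon} and \code{tai}.
#' @return Named numeric vector over the 61 sense codons.
#' @export
read_tai <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "tai") %in% names(tab)))
    stop("tAI table must have columns 'codon' and 'tai'")
  tai <- stats::setNames(as.numeric(tab$tai), toupper(tab$codon))
  miss <- setdiff(sense_codons(), names(tai))
  if (length(miss) > 0)
    stop("tAI table missing sense codons: ", paste(miss, collapse = ", "))
  if (any(!is.finite(tai)) || any(tai <= 0))
    stop("tAI values must be positive and finite")
  tai[sense_codons()]
}

#' Synthetic tAI table
#'
#' A deterministic synthetic codon-optimality scale over the 61 sense codons,
#' with values in (0, 1]. This is NOT a measured tRNA adaptation index; it is
#' a stand-in optimality scale used by the simulator as ground truth and by
#' the examples. For real data supply a published tAI table via
#' \code{\link{read_tai}}. A copy is shipped as
#' \code{inst/extdata/tai_synthetic.tsv}.
#'
#' @param seed Integer seed fixing the table (default 101).
#' @return Named numeric vector over the 61 sense codons.
#' @export
synthetic_tai <- function(seed = 101L) {
  codons <- sense_codons()
  vals <- with_preserved_seed(seed, stats::runif(length(codons), 0.05, 1))
  stats::setNames(round(vals, 4), codons)
}
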