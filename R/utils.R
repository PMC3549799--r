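#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over `{A,C,G,T,N}`. Used for turning a
#' miRNA seed (read 5'->3' on the miRNA) into the site motif it pairs with
#' on the mRNA.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("AAGGCAC") # "GTGCCTT"
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Complement of single DNA bases
#' @noRd
comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

# stop() with a stage prefix so pipeline errors name their origin
stage_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
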