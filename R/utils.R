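# Internal helpers shared across modules.

#' Map gene identifiers to species
#'
#' Gene identifiers carry their species as a prefix, \code{"SPECIES|gene"},
#' unless an explicit \code{species_map} (named character vector,
#' gene id -> species) is supplied.  Merged multi-species files and
#' per-species files are thereby both supported.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param species_map optional named character vector overriding the prefix
#'   convention.
#' @param sep prefix separator, default \code{"|"}.
#' @return character vector of species labels, same length as
#'   \code{gene_ids}.
#' @export
species_of <- function(gene_ids, species_map = NULL, sep = "|") {
  if (!is.null(species_map)) {
    miss <- setdiff(gene_ids, names(species_map))
    if (length(miss) > 0L) {
      stop("species_map has no entry for: ", paste(utils::head(miss, 5L), collapse = ", "))
    }
    return(unname(species_map[gene_ids]))
  }
  has_sep <- grepl(sep, gene_ids, fixed = TRUE)
  if (!all(has_sep)) {
    stop("gene ids without a '", sep, "' species prefix and no species_map given: ",
         paste(utils::head(gene_ids[!has_sep], 5L), collapse = ", "))
  }
  vapply(strsplit(gene_ids, sep, fixed = TRUE), `[[`, character(1L), 1L)
}

# stop() with a consistent prefix for malformed input files
.fail_line <- function(path, line, msg) {
  stop(sprintf("%s (line %d): %s", path, line, msg), call. = FALSE)
}

# order an unordered gene pair lexicographically
.order_pair <- function(a, b) {
  swap <- b < a
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}
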