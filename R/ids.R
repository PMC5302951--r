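#' Canonicalize miRNA identifiers
#'
#' miRNA names arrive in several dialects: miRBase style (`hsa-miR-20b`,
#' `hsa-miR-196a-5p`), symbol style (`HSA-MIR20B`), and platform-specific
#' hybrids. These refer to the same molecules but do not intersect as plain
#' strings, which silently empties every set operation downstream. The
#' canonical form applied here is the weakest transformation that makes the
#' common dialects collide: trim surrounding whitespace, uppercase, and
#' remove all hyphens. The species prefix and any arm suffix (`5P`/`3P`)
#' are retained; digits are never altered.
#'
#' The function is deterministic and idempotent: applying it to an already
#' canonical identifier returns it unchanged.
#'
#' @param raw character vector of miRNA identifiers as read from a source.
#' @return character vector of canonical identifiers (no hyphens, no
#'   lowercase), same length as `raw`.
#' @examples
#' canonicalize_mirna_id("hsa-miR-20b")     # "HSAMIR20B"
#' canonicalize_mirna_id("HSA-MIR20B")      # "HSAMIR20B" (same molecule)
#' canonicalize_mirna_id("hsa-miR-196a-5p") # "HSAMIR196A5P"
#' @export
canonicalize_mirna_id <- function(raw) {
  if (!is.character(raw)) stop("`raw` must be a character vector", call. = FALSE)
  out <- toupper(gsub("-", "", trimws(raw), fixed = TRUE))
  if (length(out) == 0L || anyNA(out) || any(!nzchar(out))) {
    stop("invalid miRNA identifier: empty or missing after trimming",
         call. = FALSE)
  }
  out
}

#' Parse miRNA identifiers into raw, canonical and arm components
#'
#' @param raw character vector of miRNA identifiers.
#' @return a data.frame with columns `raw`, `canonical`, and `arm` (`"5P"`,
#'   `"3P"`, or `NA` when no arm suffix is present).
#' @examples
#' parse_mirna_id(c("hsa-miR-196a-5p", "hsa-miR-21"))
#' @export
parse_mirna_id <- function(raw) {
  canonical <- canonicalize_mirna_id(raw)
  arm <- ifelse(grepl("(5P|3P)$", canonical),
                substr(canonical, nchar(canonical) - 1L, nchar(canonical)),
                NA_character_)
  data.frame(raw = as.character(raw), canonical = canonical, arm = arm,
             stringsAsFactors = FALSE)
}

#' Render a canonical miRNA identifier in symbol dialect
#'
#' Reinserts a hyphen before the first `MIR` token so canonical identifiers
#' print the way curated symbol tables render them (e.g. `HSAMIR20B` ->
#' `HSA-MIR20B`). Purely cosmetic; set operations always use canonical ids.
#'
#' @param canonical character vector of canonical miRNA identifiers.
#' @return character vector of display symbols.
#' @examples
#' format_mirna_symbol("HSAMIR20B")
#' @export
format_mirna_symbol <- function(canonical) {
  sub("MIR", "-MIR", canonical, fixed = TRUE)
}
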