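# The 26 one-letter COG functional categories, grouped into the four
# conventional super-categories. Letter order follows the super-category
# grouping used throughout reporting.
COG_SUPER <- list(
  "information storage and processing" = c("J", "K", "L", "A", "B"),
  "cellular processes and signaling"   = c("D", "Y", "V", "T", "M", "N",
                                           "Z", "W", "U", "O", "X"),
  "metabolism"                         = c("C", "G", "E", "F", "H", "I",
                                           "P", "Q"),
  "poorly characterized"               = c("R", "S")
)

COG_LETTERS <- unname(unlist(COG_SUPER))

STOP_CODONS <- c("TAA", "TAG", "TGA")

BASES <- c("A", "C", "G", "T")

#' The 26 COG functional categories and their super-categories
#'
#' Returns the one-letter COG functional category alphabet used throughout
#' the package, with the conventional grouping into four super-categories
#' (information storage and processing: 5 letters; cellular processes and
#' signaling: 11; metabolism: 8; poorly characterized: 2).
#'
#' @return A tibble with columns `category` (letter, ordered by
#'   super-category) and `super_category`.
#' @examples
#' cog_categories()
#' @export
cog_categories <- function() {
  tibble(
    category = COG_LETTERS,
    super_category = rep(names(COG_SUPER), lengths(COG_SUPER))
  )
}
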