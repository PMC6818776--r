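#' Behaviour coding scheme
#'
#' A coding scheme names the main behaviour categories scored in each
#' observation interval and maps finer-grained coding subcategories onto
#' them. The default scheme, [mcam_scheme()], is the seven-category MCAM
#' (Middle Childhood Attachment Micro-observation) scheme used for
#' mother--child interaction: positive/negative mother and child behaviour
#' (`M+`, `M-`, `C+`, `C-`) plus three task-occupation categories
#' (`MAlone`, `CAlone`, `Together`).
#'
#' @param categories character vector of unique category identifiers, in
#'   display order.
#' @param subcategory_map named character vector: names are subcategory
#'   identifiers, values the parent category each one belongs to. May be
#'   empty for schemes coded directly at category level. Categories not
#'   appearing as a parent are taken to be coded directly (see
#'   [aggregate_subcategories()]).
#' @return An object of class `coding_scheme`.
#' @seealso [mcam_scheme()], [read_scheme()]
#' @examples
#' coding_scheme(c("A", "B"), c(a1 = "A", a2 = "A", b1 = "B"))
#' @export
coding_scheme <- function(categories, subcategory_map = character()) {
  categories <- as.character(categories)
  if (anyDuplicated(categories))
    stop("category identifiers must be unique")
  if (length(subcategory_map)) {
    subcategory_map <- vapply(subcategory_map, as.character, character(1))
    if (is.null(names(subcategory_map)) || any(!nzchar(names(subcategory_map))))
      stop("subcategory_map must be a named vector (subcategory -> category)")
    if (anyDuplicated(names(subcategory_map)))
      stop("each subcategory must map to exactly one category")
    unknown <- setdiff(unname(subcategory_map), categories)
    if (length(unknown))
      stop("subcategory_map refers to unknown categories: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(categories = categories, subcategory_map = subcategory_map),
            class = "coding_scheme")
}

#' @export
print.coding_scheme <- function(x, ...) {
  cat("Coding scheme:", length(x$categories), "categories,",
      length(x$subcategory_map), "mapped subcategories\n")
  cat("  categories:", paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

#' The default MCAM coding scheme
#'
#' Seven main categories — `M+`, `M-`, `C+`, `C-`, `MAlone`, `CAlone`,
#' `Together` — with the sixteen behaviour subcategories that are
#' aggregated into the four mother/child valence categories. The three
#' task-occupation categories are coded directly and have no
#' subcategories.
#'
#' @return A `coding_scheme` with 7 categories and 16 subcategories.
#' @export
mcam_scheme <- function() {
  coding_scheme(
    categories = c("M+", "M-", "C+", "C-", "MAlone", "CAlone", "Together"),
    subcategory_map = c(
      attention            = "M+",
      responsivity         = "M+",
      pos_affective_comm   = "M+",
      structuring_pos      = "M+",
      structuring_task     = "M+",
      structuring_neg      = "M-",
      covert_hostility     = "M-",
      overt_hostility      = "M-",
      noncontingent        = "M-",
      engagement           = "C+",
      positive_affect      = "C+",
      involving_pos        = "C+",
      involving_neg        = "C-",
      controlling          = "C-",
      avoidant             = "C-",
      resistant            = "C-"
    )
  )
}

#' Read a coding scheme from a two-column CSV
#'
#' The file must have a header and columns `subcategory,category`.
#' Category order follows first appearance. Directly coded categories
#' (no subcategories) are listed as self-mapping rows, as in the bundled
#' `mcam_scheme.csv`.
#'
#' @param path path to a CSV file.
#' @return A `coding_scheme`.
#' @export
read_scheme <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subcategory", "category") %in% names(df)))
    stop("scheme file needs columns 'subcategory' and 'category'")
  m <- stats::setNames(as.character(df$category), as.character(df$subcategory))
  coding_scheme(unique(as.character(df$category)), m)
}
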