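# ICD-9-CM code normalization and chapter lookup.

#' Truncate ICD-9-CM codes to their 3-digit base category
#'
#' Numeric ICD-9-CM codes carry up to five characters ("250.01"); the first
#' three digits identify the base disease category. Codes from the
#' supplementary classification chapters (V01-V91, E000-E999) do not describe
#' diseases and are excluded from path construction.
#'
#' @param code character vector of raw ICD-9-CM codes (whitespace tolerated,
#'   optional decimal part, optional leading "V"/"E" in either case).
#' @return character vector of the same length: the zero-padded 3-digit
#'   category for numeric codes, `NA` for excluded (V/E) codes. Codes that are
#'   neither numeric nor V/E-prefixed raise a warning with a count and are
#'   returned as `NA`; retrieve the count via attribute `"n_invalid"`.
#' @examples
#' truncate_icd9(c("250.01", "V70.0", "42"))
#' @export
truncate_icd9 <- function(code) {
  code <- trimws(as.character(code))
  out <- rep(NA_character_, length(code))
  if (!length(code)) {
    attr(out, "n_invalid") <- 0L
    return(out)
  }
  ve <- grepl("^[VEve]", code)
  base <- sub("\\..*$", "", code)
  numeric_ok <- !ve & grepl("^[0-9]{1,5}$", base)
  # 4-5 digit bare codes like "25001" keep their first three digits
  out[numeric_ok] <- sprintf("%03d", as.integer(substr(base[numeric_ok], 1L, 3L)))
  invalid <- !ve & !numeric_ok
  if (any(invalid)) {
    warning(sprintf("%d ICD-9 code(s) neither numeric nor V/E-prefixed; dropped", sum(invalid)))
  }
  attr(out, "n_invalid") <- sum(invalid)
  out
}

#' The 17 main ICD-9-CM chapters
#'
#' Canonical numeric ranges of the highest-level ICD-9-CM disease grouping.
#' The supplementary V/E chapters are deliberately absent: they are excluded
#' upstream. A copy ships as a TSV in `inst/extdata/icd9_chapters.tsv` for use
#' outside R; pass a modified table of the same shape to override.
#'
#' @return a `data.table` with integer columns `low`, `high` and character
#'   column `chapter`, rows ordered and non-overlapping, covering 001-999.
#' @export
icd9_chapters <- function() {
  data.table::data.table(
    low = c(1L, 140L, 240L, 280L, 290L, 320L, 390L, 460L, 520L, 580L,
            630L, 680L, 710L, 740L, 760L, 780L, 800L),
    high = c(139L, 239L, 279L, 289L, 319L, 389L, 459L, 519L, 579L, 629L,
             679L, 709L, 739L, 759L, 779L, 799L, 999L),
    chapter = c(
      "Infectious And Parasitic Diseases",
      "Neoplasms",
      "Endocrine, Nutritional And Metabolic Diseases, And Immunity Disorders",
      "Diseases Of The Blood And Blood-Forming Organs",
      "Mental Disorders",
      "Diseases Of The Nervous System And Sense Organs",
      "Diseases Of The Circulatory System",
      "Diseases Of The Respiratory System",
      "Diseases Of The Digestive System",
      "Diseases Of The Genitourinary System",
      "Complications Of Pregnancy, Childbirth, And The Puerperium",
      "Diseases Of The Skin And Subcutaneous Tissue",
      "Diseases Of The Musculoskeletal System And Connective Tissue",
      "Congenital Anomalies",
      "Certain Conditions Originating In The Perinatal Period",
      "Symptoms, Signs, And Ill-Defined Conditions",
      "Injury And Poisoning"
    )
  )
}

#' Map 3-digit ICD-9 codes to their chapter
#'
#' @param code character vector of 3-digit numeric codes ("001".."999").
#' @param chapter_map chapter range table, as from [icd9_chapters()].
#' @return character vector of chapter names.
#' @examples
#' chapter_of(c("250", "401"))
#' @export
chapter_of <- function(code, chapter_map = icd9_chapters()) {
  stopifnot(is.data.frame(chapter_map), all(c("low", "high", "chapter") %in% names(chapter_map)))
  code <- as.character(code)
  if (any(grepl("^[VEve]", code))) {
    stop("V/E supplementary codes have no disease chapter: ",
         paste(unique(code[grepl("^[VEve]", code)]), collapse = ", "))
  }
  num <- suppressWarnings(as.integer(code))
  if (anyNA(num)) {
    stop("non-numeric ICD-9 code(s): ", paste(unique(code[is.na(num)]), collapse = ", "))
  }
  idx <- findInterval(num, chapter_map$low)
  bad <- idx == 0L | num > chapter_map$high[pmax(idx, 1L)]
  if (any(bad)) {
    stop("ICD-9 code(s) outside all chapter ranges: ", paste(unique(code[bad]), collapse = ", "))
  }
  chapter_map$chapter[idx]
}
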