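# GTIN handling: check digits, normalization of raw receipt item numbers.

#' Compute the GTIN-13 mod-10 check digit
#'
#' For a 13-digit Global Trade Item Number the first twelve digits carry
#' alternating weights 1, 3, 1, 3, ... (left to right); the check digit is
#' the complement of the weighted sum modulo 10.
#'
#' @param payload12 Character vector of 12-digit strings (a GTIN-13 without
#'   its final check digit).
#' @return Integer vector of check digits in 0..9.
#' @examples
#' gtin_check_digit("570123456789")
#' @export
gtin_check_digit <- function(payload12) {
  stopifnot(is.character(payload12))
  bad <- !grepl("^[0-9]{12}$", payload12)
  if (any(bad)) {
    stop("gtin_check_digit() expects 12-digit strings; offending value: ",
         payload12[which(bad)[1]])
  }
  digits <- matrix(
    as.integer(unlist(strsplit(payload12, "", fixed = TRUE))),
    nrow = 12
  )
  weights <- rep(c(1L, 3L), 6L)
  (10L - colSums(digits * weights) %% 10L) %% 10L
}

#' Validate the check digit of 13-digit GTIN strings
#'
#' @param gtin13 Character vector of candidate 13-digit strings.
#' @return Logical vector; `FALSE` for anything that is not 13 digits or
#'   whose final digit disagrees with the mod-10 check digit.
#' @export
gtin_is_valid <- function(gtin13) {
  ok_shape <- grepl("^[0-9]{13}$", gtin13)
  out <- rep(FALSE, length(gtin13))
  if (any(ok_shape)) {
    payload <- substr(gtin13[ok_shape], 1L, 12L)
    check <- as.integer(substr(gtin13[ok_shape], 13L, 13L))
    out[ok_shape] <- gtin_check_digit(payload) == check
  }
  out
}

#' Normalize raw receipt item numbers
#'
#' Receipt item numbers are either GTIN barcodes or shorter
#' supplier-internal codes. This filter reproduces the enrichment
#' pipeline's front gate: non-digits are stripped, strings with fewer than
#' 3 or more than 14 digits are excluded outright, and digit counts 8, 12,
#' 13 and 14 are treated as GTIN candidates (8- and 12-digit codes are
#' left-padded with zeros to 13; a 14-digit code must start with a zero,
#' which is dropped). A candidate that fails the mod-10 check digit is kept
#' as a supplier-internal code rather than discarded, as are digit counts
#' 3-7 and 9-11; internal codes are eligible for name-based matching only.
#'
#' @param raw Character vector of raw item numbers as printed on receipts.
#' @return A tibble with one row per input: `item_number_raw`, `digits`
#'   (the stripped digit string), `n_digits`, `status` (one of `"gtin"`,
#'   `"internal"`, `"excluded"`), and `gtin` (normalized 13-digit string,
#'   `NA` unless `status == "gtin"`).
#' @examples
#' normalize_item_number(c("5701234567899", "12", "400638133393"))
#' @export
normalize_item_number <- function(raw) {
  stopifnot(is.character(raw))
  digits <- gsub("[^0-9]", "", raw)
  n <- nchar(digits)

  status <- rep("internal", length(raw))
  gtin <- rep(NA_character_, length(raw))

  status[n < 3L | n > 14L] <- "excluded"

  cand <- which(n %in% c(8L, 12L, 13L, 14L))
  if (length(cand)) {
    norm <- digits[cand]
    n_c <- n[cand]
    norm[n_c == 8L] <- paste0("00000", norm[n_c == 8L])
    norm[n_c == 12L] <- paste0("0", norm[n_c == 12L])
    is14 <- n_c == 14L
    lead0 <- is14 & startsWith(norm, "0")
    norm[lead0] <- substr(norm[lead0], 2L, 14L)
    # a 14-digit code not starting with 0 cannot be a GTIN-13
    eligible <- !is14 | lead0
    valid <- eligible & gtin_is_valid(norm)
    status[cand[valid]] <- "gtin"
    gtin[cand[valid]] <- norm[valid]
  }

  tibble::tibble(
    item_number_raw = raw,
    digits = digits,
    n_digits = n,
    status = status,
    gtin = gtin
  )
}
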