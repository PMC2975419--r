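# Canonical unordered protein pairs are the universal key of the package.
# A pair is stored as "smaller|larger" (lexicographic, C locale); the "|"
# separator is reserved and may not appear in protein identifiers.

PAIR_SEP <- "|"

#' Canonical key for an unordered protein pair
#'
#' Protein pairs are unordered throughout the package; the canonical form
#' places the lexicographically smaller identifier first and joins the two
#' with `"|"`. Self-pairs (a == b) are not representable by design and give
#' `NA`; callers are expected to drop them.
#'
#' @param a,b Character vectors of protein identifiers (recycled).
#' @return Character vector of canonical keys; `NA` for self-pairs.
#' @examples
#' pair_key(c("B", "A"), c("A", "B"))  # both "A|B"
#' @export
pair_key <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(character(0))
  bad <- grepl(PAIR_SEP, a, fixed = TRUE) | grepl(PAIR_SEP, b, fixed = TRUE)
  if (any(bad)) {
    stop("protein identifiers must not contain the reserved character '",
         PAIR_SEP, "'")
  }
  swap <- cmp_gt(a, b)
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  key <- paste(lo, hi, sep = PAIR_SEP)
  key[a == b] <- NA_character_
  key
}

# locale-independent a > b comparison
cmp_gt <- function(a, b) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  a > b
}

#' Split canonical pair keys back into their two identifiers
#'
#' @param keys Character vector of keys produced by [pair_key()].
#' @return A data.frame with columns `protein_a`, `protein_b`.
#' @export
pair_split <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, PAIR_SEP, fixed = TRUE)
  data.frame(protein_a = vapply(parts, `[`, "", 1L),
             protein_b = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' All unordered pairs among a set of identifiers
#'
#' @param ids Character vector of identifiers (deduplicated internally).
#' @return Character vector of canonical pair keys, one per unordered pair.
#' @export
all_pairs <- function(ids) {
  ids <- unique(as.character(ids))
  n <- length(ids)
  if (n < 2L) return(character(0))
  idx <- utils::combn(n, 2L)
  pair_key(ids[idx[1L, ]], ids[idx[2L, ]])
}

#' Canonicalize a pair table
#'
#' Canonicalizes pair order, drops self-pairs, and merges duplicate rows.
#' When a `score` column is present duplicates keep the maximum score;
#' otherwise the first occurrence is kept. Idempotent.
#'
#' @param df data.frame with columns `protein_a`, `protein_b` and optionally
#'   `score`.
#' @return data.frame with the same columns plus a `key` column, one row per
#'   canonical pair. The number of dropped self-pairs is reported via
#'   `message()`.
#' @export
canonicalize_pairs <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("protein_a", "protein_b") %in% names(df)))
  key <- pair_key(df$protein_a, df$protein_b)
  n_self <- sum(is.na(key))
  if (n_self > 0L) {
    message("dropped ", n_self, " self-pair(s)")
    df <- df[!is.na(key), , drop = FALSE]
    key <- key[!is.na(key)]
  }
  ab <- pair_split(key)
  df$protein_a <- ab$protein_a
  df$protein_b <- ab$protein_b
  df$key <- key
  if ("score" %in% names(df)) {
    # max-merge duplicates
    ord <- order(key, -xtfrm(df$score))
    df <- df[ord, , drop = FALSE]
  }
  df <- df[!duplicated(df$key), , drop = FALSE]
  rownames(df) <- NULL
  df
}
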