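# Shared helpers: rounding, keyword matching, seeded RNG scoping.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going up (away from zero),
#' the convention used when reporting percentage coverages and shares.
#' Base `round()` rounds half to even, which would turn 92.35 into 92.3.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(92.35, 1)  # 92.4
#' round_half_up(12 / 13 * 100, 1)  # 92.3
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Whole-word, case-insensitive keyword matching
#'
#' A label matches a keyword when the label equals the keyword
#' (case-insensitively) or contains it delimited by non-word characters or
#' string boundaries. So `"butyrate"` matches `"butyrate production"` but
#' not `"butyrogenesis"`, and `"Faecalibacterium"` matches
#' `"Faecalibacterium prausnitzii"`.
#'
#' @param labels Character vector of node labels.
#' @param keywords Character vector of keywords.
#' @return Logical vector: does each label match at least one keyword?
#' @export
matches_keyword <- function(labels, keywords) {
  keywords <- keywords[nzchar(keywords)]
  if (length(keywords) == 0 || length(labels) == 0) {
    return(rep(FALSE, length(labels)))
  }
  hit <- rep(FALSE, length(labels))
  for (kw in keywords) {
    # \Q...\E quotes the keyword literally; lookarounds enforce whole-word
    pat <- paste0("(?<![[:alnum:]_])\\Q", kw, "\\E(?![[:alnum:]_])")
    hit <- hit | grepl(pat, labels, ignore.case = TRUE, perl = TRUE)
  }
  hit
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr, .rng_kind = "Mersenne-Twister")
}

`%0%` <- function(x, y) if (length(x) == 0) y else x

# Stable hash of an R object, used to stamp reports with their configuration.
config_hash <- function(x) rlang::hash(x)

pkg_version <- function() as.character(utils::packageVersion("nutrikg"))
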