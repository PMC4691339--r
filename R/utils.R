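# Internal helpers shared across modules.

# Round half away from zero; base round() would give round(0.5) == 0.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Render a fraction as a whole-percent string
#'
#' All metrics in the package are fractions; reports render them as whole
#' percentages rounded half away from zero (0.3888... becomes `"39%"`).
#' Infinite overheads render as `"Inf%"`.
#'
#' @param x Fraction(s) to render.
#' @return Character vector of percent strings.
#' @examples
#' format_percent(7 / 18)  # "39%"
#' @export
format_percent <- function(x) {
  ifelse(is.finite(x),
         paste0(format(round_half_up(x * 100), trim = TRUE,
                       scientific = FALSE), "%"),
         paste0(x * 100, "%"))
}

# Numeric whole-percent value (39 from 0.3888...).
percent_value <- function(x) {
  ifelse(is.finite(x), round_half_up(x * 100), x)
}

# Derive an independent RNG sub-seed from a root seed and a component label,
# so adding a component never perturbs another component's draws.
derive_seed <- function(seed, label) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}
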