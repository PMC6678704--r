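# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
normalize_gene <- function(x) {
  toupper(trimws(as.character(x)))
}

# Quantiles throughout the package use the type-7 convention (linear
# interpolation between order statistics), R's default; the choice is
# configurable where it matters and recorded in run manifests.
#' @keywords internal
#' @noRd
quantile7 <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

# Deterministic, platform-independent rolling hash of a string to [0, 1).
# Polynomial hash base 31 modulo a Mersenne-like prime, carried in doubles
# (all intermediates < 2^53, so exact).
#' @keywords internal
#' @noRd
string_hash01 <- function(s) {
  mod <- 2147483647 # 2^31 - 1
  vapply(s, function(one) {
    codes <- utf8ToInt(one)
    h <- 7
    for (k in codes) {
      h <- (h * 31 + k) %% mod
    }
    # one extra mixing round to decorrelate short strings
    h <- (h * 2654435 + 101) %% mod
    h / mod
  }, numeric(1), USE.NAMES = FALSE)
}

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
is_binary01 <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x %in% c(0, 1))
}
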