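`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items.
#' Used to score mother-of-origin demultiplexing against planted truth.
#'
#' @param x,y label vectors of equal length (any atomic type).
#' @return A number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- b * cc / n2
  maxi <- (b + cc) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

# stop() with sprintf-style formatting, no call in message
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# deterministic seed derivation: keep child seeds within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
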