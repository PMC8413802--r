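#' @importFrom rlang .data .env
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# row-wise log-sum-exp of a matrix; returns vector of length nrow(x)
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

# enumerate all permutations of 1..k (k small; class counts rarely exceed 8)
all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (i in seq_len(k)) {
    for (p in sub) {
      rest <- seq_len(k)[-i]
      out[[idx]] <- c(i, rest[p])
      idx <- idx + 1L
    }
  }
  out
}

# derive a stream of sub-seeds from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  withr_seed <- function() {
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
  }
  withr_seed()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
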