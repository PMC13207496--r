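#' @keywords internal
"_PACKAGE"

# Modular arithmetic on doubles: operands < 2^31 so split multiplication to
# stay inside the 2^53 exact-integer range.
MOD31 <- 2147483647

mulmod <- function(a, b, m = MOD31) {
  a <- a %% m
  b <- b %% m
  hi <- floor(a / 65536)
  lo <- a - hi * 65536
  (((hi * b) %% m) * 65536 + lo * b) %% m
}

#' Derive a child seed from a master seed and a component path
#'
#' A stable multiplicative-mix hash over the master seed and any number of
#' string/integer path components (component name, client id, round index).
#' Adding new components to a pipeline never perturbs the streams of
#' existing ones, and the result always lies in `[1, 2^31 - 2]` so it is a
#' valid input to [set.seed()].
#'
#' @param master integer master seed.
#' @param ... path components (coerced to character).
#' @return integer scalar seed.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  h <- (abs(master) + 11) %% MOD31
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0("/", as.character(part)))) {
      h <- (mulmod(h, 1103515245) + ch + 12345) %% MOD31
    }
  }
  as.integer(h %% (MOD31 - 2) + 1)
}

# Largest-remainder integerization: nonnegative weights -> integers summing
# to `total`, proportional to the weights.
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), total >= 0)
  if (total == 0 || sum(weights) == 0) {
    return(integer(length(weights)))
  }
  ideal <- weights / sum(weights) * total
  base <- floor(ideal)
  left <- total - sum(base)
  if (left > 0) {
    take <- order(ideal - base, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# Configuration-error helper: consistent condition class so tests can match.
config_error <- function(field, msg) {
  stop(structure(
    class = c("fldpsim_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field '%s': %s", field, msg),
         call = sys.call(-1))
  ))
}

l2norm <- function(x) sqrt(sum(x^2))
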