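# Genotype call coding used throughout: integer matrix with
#   0 = HOM_REF, 1 = HET, 2 = HOM_ALT, NA = MISSING.

#' Genotype call codes
#'
#' Integer codes used in the genotype call matrix: `HOM_REF = 0L`,
#' `HET = 1L`, `HOM_ALT = 2L`; missing calls are `NA_integer_`.
#'
#' @format Named integer vector of length 3.
#' @export
CALL_CODES <- c(HOM_REF = 0L, HET = 1L, HOM_ALT = 2L)

#' ROH length classes
#'
#' The six ROH length classes, left-closed/right-open in Mb:
#' \[0,2) \[2,4) \[4,6) \[6,8) \[8,16) \[16,Inf).
#'
#' @format Character vector of the six class labels, in increasing length
#'   order.
#' @export
LENGTH_CLASSES <- c("LT2", "C2_4", "C4_6", "C6_8", "C8_16", "GT16")

#' Number of autosomes modelled (pig karyotype)
#' @format Integer scalar, 18.
#' @export
N_AUTOSOMES <- 18L

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rohcnn <- function(..., class = "rohcnn_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Derive reproducible per-stage seeds from one master seed
#'
#' A single pipeline seed fans out to one seed per named stage via a fixed
#' linear-congruential derivation, so each stage is independently
#' reproducible. All derived seeds are valid 32-bit R integers.
#'
#' @param seed Integer master seed.
#' @param stages Character vector of stage names.
#' @return Named integer vector of derived seeds.
#' @export
derive_seeds <- function(seed, stages) {
  stopifnot(length(seed) == 1, is.finite(seed))
  base <- as.double(seed) %% 2147483647
  out <- vapply(seq_along(stages), function(i) {
    as.integer((base * 48271 + i * 65537) %% 2147483647)
  }, integer(1))
  names(out) <- stages
  out
}

# Running (moving) sum of a 0/1 vector over windows of size w.
run_sum <- function(x, w) {
  n <- length(x)
  if (w > n) stop_rohcnn("window larger than vector")
  cs <- cumsum(x)
  cs[w:n] - c(0, cs[seq_len(n - w)])
}
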