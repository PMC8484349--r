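#' Clutch-size to fertility mapping
#'
#' Constructs the model linking the size of the clutch a female developed in
#' to her own lifetime fertility. In gregarious idiobiont egg parasitoids the
#' host egg is a fixed food supply, so per-offspring resources -- and hence
#' adult body size and fertility -- decline with clutch size. The default
#' mapping is
#' \deqn{\mathrm{fertility}(c) = \mathrm{round}(\,\mathrm{base} - \sqrt{c}\,)}
#' with \code{base = 20} offspring, rounded to the nearest integer after the
#' subtraction.
#'
#' @param base Fertility intercept: offspring count a female from an
#'   (hypothetical) zero-cost clutch would attain. Default 20.
#' @param decay Functional form of the decline; only \code{"sqrt"}
#'   (square root of clutch size) is currently implemented.
#' @param rounding Rounding rule applied to the continuous value;
#'   \code{"nearest"} rounds half away from zero.
#' @param max_clutch Largest clutch size on the model's support. Default 7,
#'   the species' observed maximum; larger values are permitted but flagged
#'   as extrapolation.
#'
#' @return An object of class \code{fertility_model}.
#' @seealso [fertility_of_clutch()], [enumerate_clutch_configs()]
#' @export
#' @examples
#' m <- fertility_model()
#' fertility_of_clutch(1:7, m)
fertility_model <- function(base = 20, decay = c("sqrt"),
                            rounding = c("nearest"), max_clutch = 7L) {
  decay <- match.arg(decay)
  rounding <- match.arg(rounding)
  stopifnot(is.numeric(base), length(base) == 1L, is.finite(base))
  base <- as.numeric(base)
  max_clutch <- as.integer(max_clutch)
  if (is.na(max_clutch) || max_clutch < 1L)
    stop("`max_clutch` must be an integer >= 1", call. = FALSE)
  if (max_clutch > 7L)
    message("max_clutch = ", max_clutch,
            " extrapolates beyond the observed support (1..7)")
  structure(
    list(base = base, decay = decay, rounding = rounding,
         max_clutch = max_clutch),
    class = "fertility_model"
  )
}

#' @export
print.fertility_model <- function(x, ...) {
  cat("Clutch-size -> fertility model\n")
  cat(sprintf("  fertility(c) = round(%g - sqrt(c)), c in 1..%d\n",
              x$base, x$max_clutch))
  invisible(x)
}

# round half away from zero (base R round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Per-female-offspring lifetime fertility for a given clutch size
#'
#' Evaluates the clutch-size to fertility mapping. Vectorised over
#' \code{size}.
#'
#' @param size Integer clutch size(s), each in \code{1..model$max_clutch}.
#' @param model A [fertility_model()]; default model if omitted.
#' @return Integer fertility (offspring count) for each clutch size.
#' @export
#' @examples
#' fertility_of_clutch(c(1, 4), fertility_model())  # 19, 18
fertility_of_clutch <- function(size, model = fertility_model()) {
  stopifnot(inherits(model, "fertility_model"))
  if (length(size) == 0L) return(integer(0))
  if (any(!is.finite(size)) || any(size != trunc(size)))
    stop("`size` must be whole numbers", call. = FALSE)
  if (any(size < 1 | size > model$max_clutch))
    stop("clutch size out of range: valid support is 1..",
         model$max_clutch, call. = FALSE)
  raw <- model$base - sqrt(size)
  as.integer(round_half_away(raw))
}

#' Enumerate all clutch configurations
#'
#' Every possible (clutch size, number of females) pair a female can lay
#' into one host egg: sizes \code{1..max_clutch}, each with \code{0..size}
#' females. For \code{max_clutch = 7} this yields the 35 possible
#' combinations available to the species.
#'
#' @param max_clutch Largest clutch size considered (default 7).
#' @return A data.frame with columns \code{size}, \code{females},
#'   \code{males}, one row per configuration, ordered by size then females.
#' @export
#' @examples
#' nrow(enumerate_clutch_configs(7))  # 35
enumerate_clutch_configs <- function(max_clutch = 7L) {
  max_clutch <- as.integer(max_clutch)
  if (is.na(max_clutch) || max_clutch < 1L)
    stop("`max_clutch` must be an integer >= 1", call. = FALSE)
  size <- rep.int(seq_len(max_clutch), seq_len(max_clutch) + 1L)
  females <- unlist(lapply(seq_len(max_clutch), function(s) 0:s),
                    use.names = FALSE)
  data.frame(size = size, females = females, males = size - females)
}
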