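#' Powder orientation schemes
#'
#' Build a weighted set of crystallite orientations (beta, gamma) representing
#' a non-oriented powder sample. Three schemes are provided:
#' `"golden-spiral"` (deterministic spiral, exactly `n` points),
#' `"zcw-like"` (Fibonacci-number scheme; uses the smallest Fibonacci number
#' >= `n` points), and `"grid"` (Gauss--Legendre nodes in cos(beta) crossed
#' with a uniform gamma grid; at least `n` points).
#'
#' @param n requested number of orientations (>= 1).
#' @param method orientation scheme.
#' @return a data frame of class `powder_scheme` with columns `beta` (rad,
#'   in \[0, pi\]), `gamma` (rad, in \[0, 2*pi)) and `weight` (sums to 1).
#' @examples
#' p <- make_powder_scheme(4096)
#' sum(p$weight)
#' @export
make_powder_scheme <- function(n, method = c("golden-spiral", "zcw-like", "grid")) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("configuration error: n must be a positive count", call. = FALSE)
  n <- as.integer(n)
  method <- tryCatch(match.arg(method),
                     error = function(e)
                       stop("configuration error: unknown powder method",
                            call. = FALSE))
  if (method == "golden-spiral") {
    i <- seq_len(n)
    cosb <- 1 - (2 * i - 1) / n
    golden_angle <- pi * (3 - sqrt(5))
    sch <- data.frame(beta = acos(cosb),
                      gamma = ((i - 1) * golden_angle) %% (2 * pi),
                      weight = rep(1 / n, n))
  } else if (method == "zcw-like") {
    fib <- c(1L, 1L)
    while (fib[length(fib)] < n)
      fib <- c(fib, fib[length(fib)] + fib[length(fib) - 1L])
    N <- fib[length(fib)]
    g <- if (length(fib) >= 3L) fib[length(fib) - 2L] else 1L
    j <- seq_len(N) - 1L
    sch <- data.frame(beta = acos(1 - 2 * (j + 0.5) / N),
                      gamma = 2 * pi * ((j * g) %% N) / N,
                      weight = rep(1 / N, N))
  } else { # grid
    n_gamma <- max(1L, as.integer(floor(sqrt(n))))
    n_beta <- max(1L, as.integer(ceiling(n / n_gamma)))
    gl <- pracma::gaussLegendre(n_beta, -1, 1)
    gam <- 2 * pi * (seq_len(n_gamma) - 0.5) / n_gamma
    sch <- data.frame(
      beta = rep(acos(gl$x), times = n_gamma),
      gamma = rep(gam, each = n_beta),
      weight = rep(gl$w / 2, times = n_gamma) / n_gamma)
  }
  sch$weight <- sch$weight / sum(sch$weight)
  class(sch) <- c("powder_scheme", "data.frame")
  sch
}

validate_powder <- function(powder) {
  if (is.null(powder) || !is.data.frame(powder) || nrow(powder) == 0L)
    stop("configuration error: powder scheme is empty", call. = FALSE)
  if (!all(c("beta", "gamma", "weight") %in% names(powder)))
    stop("configuration error: powder scheme needs beta, gamma, weight columns",
         call. = FALSE)
  if (abs(sum(powder$weight) - 1) > 1e-10)
    stop("configuration error: powder weights must sum to 1", call. = FALSE)
  invisible(powder)
}

#' @export
print.powder_scheme <- function(x, ...) {
  cat(sprintf("<powder_scheme: %d orientations, sum(weight) = %.12f>\n",
              nrow(x), sum(x$weight)))
  invisible(x)
}
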