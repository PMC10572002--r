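#' Yates-algorithm effects for a full 2^k factorial
#'
#' Classical Yates sweep: with the corner responses in standard order
#' (factor A fastest), k passes of pairwise sums and differences yield,
#' in one column, the grand total followed by the effect contrasts. The
#' overall mean is the first entry divided by 2^k; each effect is its
#' contrast divided by 2^(k-1). Half-effects (the saturated
#' regression-coefficient convention) are also reported.
#'
#' @param responses numeric vector of length 2^k, standard Yates order
#' @param factor_names names for the k factors (default A, B, C, ...)
#' @return an `effects_table`: data.frame with `term`, `effect`,
#'   `half_effect`, plus attribute `mean`
#' @export
yates_effects <- function(responses, factor_names = NULL) {
  n <- length(responses)
  k <- round(log2(n))
  if (n < 2 || 2 ^ k != n)
    stop("number of responses must be a power of two (got ", n, ")")
  factor_names <- factor_names %||% LETTERS[seq_len(k)]
  if (length(factor_names) != k) stop("need exactly ", k, " factor names")
  col <- responses
  for (pass in seq_len(k)) {
    half <- n / 2
    idx <- seq_len(half)
    col <- c(col[2 * idx] + col[2 * idx - 1],
             col[2 * idx] - col[2 * idx - 1])
  }
  # term label for position j: product of factors whose bit is set
  terms <- vapply(seq_len(n) - 1L, function(j) {
    on <- bitwAnd(j, 2 ^ (seq_len(k) - 1)) > 0
    if (!any(on)) "(mean)" else paste(factor_names[on], collapse = ":")
  }, character(1))
  out <- data.frame(term = terms[-1],
                    effect = col[-1] / 2 ^ (k - 1),
                    half_effect = col[-1] / 2 ^ k,
                    stringsAsFactors = FALSE)
  attr(out, "mean") <- col[1] / 2 ^ k
  class(out) <- c("effects_table", "data.frame")
  out
}

#' @export
print.effects_table <- function(x, ...) {
  cat(sprintf("<effects_table> mean = %.4g\n", attr(x, "mean")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Define a 2^k factorial design with a centre replicate
#'
#' @param factors named list; each element is `c(low, center, high)` (the
#'   levels may be numeric or character)
#' @return a `factorial_design`
#' @export
factorial_design <- function(factors) {
  if (!length(factors) || is.null(names(factors)))
    stop("factors must be a named list")
  bad <- names(factors)[vapply(factors, length, 0L) != 3L]
  if (length(bad))
    stop("each factor needs (low, center, high) levels: ",
         paste(bad, collapse = ", "))
  structure(list(factors = factors, k = length(factors)),
            class = "factorial_design")
}

#' Run a factorial design through a simulator
#'
#' Executes the 2^k corner runs in standard Yates order (first factor
#' fastest) plus the centre replicate, extracts one or more numeric
#' responses from each run, and returns the Yates effects per response
#' together with the centre-vs-corner-mean nonlinearity gap.
#'
#' @param design a [factorial_design()]
#' @param simulate_fun function taking a named list of factor levels and
#'   returning a run result
#' @param responses named list of functions, each mapping a run result
#'   to a numeric scalar
#' @return list: `runs` (level combinations with response columns),
#'   `center` (responses at the centre), `effects` (one
#'   [yates_effects()] table per response), `nonlinearity` (centre minus
#'   corner mean, per response)
#' @export
run_design <- function(design, simulate_fun, responses) {
  stopifnot(inherits(design, "factorial_design"))
  k <- design$k
  nm <- names(design$factors)
  corners <- expand.grid(rep(list(c(1L, 3L)), k), KEEP.OUT.ATTRS = FALSE)
  names(corners) <- nm
  resp_mat <- matrix(NA_real_, nrow = 2 ^ k, ncol = length(responses),
                     dimnames = list(NULL, names(responses)))
  run_levels <- vector("list", 2 ^ k)
  for (i in seq_len(2 ^ k)) {
    lv <- lapply(nm, function(f) design$factors[[f]][corners[i, f]])
    names(lv) <- nm
    run_levels[[i]] <- lv
    res <- tryCatch(simulate_fun(lv), error = function(e)
      stop("design point ", i, " (",
           paste(nm, unlist(lv), sep = "=", collapse = ", "),
           ") failed: ", conditionMessage(e), call. = FALSE))
    resp_mat[i, ] <- vapply(responses, function(f) f(res), numeric(1))
  }
  centre_lv <- lapply(design$factors, `[`, 2L)
  centre_res <- simulate_fun(centre_lv)
  centre <- vapply(responses, function(f) f(centre_res), numeric(1))
  effects <- lapply(names(responses), function(r)
    yates_effects(resp_mat[, r], nm))
  names(effects) <- names(responses)
  runs <- as.data.frame(t(vapply(run_levels, function(lv)
    vapply(lv, function(v) as.character(v), character(1)), character(k))),
    stringsAsFactors = FALSE)
  names(runs) <- nm
  runs <- cbind(runs, as.data.frame(resp_mat))
  list(runs = runs, center = centre, effects = effects,
       nonlinearity = centre - colMeans(resp_mat))
}
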