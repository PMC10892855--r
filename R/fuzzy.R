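# Generic Mamdani inference engine: Gaussian membership functions,
# min activation/implication, max aggregation, numeric center-of-area
# defuzzification on a uniform grid.

#' Gaussian membership function
#'
#' @param label Linguistic label, e.g. `"low"`.
#' @param center Location of the peak, in variable units.
#' @param sigma Spread (> 0), in variable units.
#' @return An object of class `gaussian_mf`.
#' @export
gaussian_mf <- function(label, center, sigma) {
  if (!is_scalar_number(sigma) || sigma <= 0) stop_config("gaussian_mf: sigma must be > 0")
  structure(list(label = as.character(label), center = as.numeric(center),
                 sigma = as.numeric(sigma)),
            class = "gaussian_mf")
}

#' Membership degree of a crisp value
#'
#' `exp(-(x - center)^2 / (2 sigma^2))`: 1 at the center, symmetric,
#' never exactly zero.
#'
#' @param x Crisp value(s).
#' @param mf A [gaussian_mf()].
#' @return Degree(s) in `[0, 1]`.
#' @export
membership <- function(x, mf) {
  stopifnot(inherits(mf, "gaussian_mf"))
  exp(-(x - mf$center)^2 / (2 * mf$sigma^2))
}

#' Linguistic fuzzy variable
#'
#' A named variable over a bounded range, carrying an ordered set of
#' Gaussian membership functions. When only `labels` are given, MF
#' centers are laid out evenly from `range[1]` to `range[2]` with
#' `sigma = spacing / 2`, giving about 0.6 crossover between
#' neighbours (standard practice); pass `mfs` to override.
#'
#' @param name Variable name.
#' @param range Two-element `c(min, max)` domain, in variable units.
#' @param labels Character vector of at least 2 labels (ignored if
#'   `mfs` given).
#' @param mfs Optional list of [gaussian_mf()], centers sorted ascending
#'   within `range`.
#' @return An object of class `fuzzy_variable`.
#' @examples
#' v <- fuzzy_variable("pain", c(0, 10), c("none", "low", "moderate", "severe"))
#' vapply(v$mfs, function(m) m$center, numeric(1))
#' @export
fuzzy_variable <- function(name, range, labels = NULL, mfs = NULL) {
  if (length(range) != 2L || range[2] <= range[1]) {
    stop_config("fuzzy_variable '", name, "': range must satisfy min < max")
  }
  if (is.null(mfs)) {
    if (length(labels) < 2L) {
      stop_config("fuzzy_variable '", name, "': need at least 2 labels")
    }
    centers <- seq(range[1], range[2], length.out = length(labels))
    spacing <- centers[2] - centers[1]
    mfs <- mapply(gaussian_mf, labels, centers, spacing / 2, SIMPLIFY = FALSE)
  }
  if (length(mfs) < 2L) stop_config("fuzzy_variable '", name, "': need >= 2 membership functions")
  centers <- vapply(mfs, function(m) m$center, numeric(1))
  if (is.unsorted(centers, strictly = TRUE)) {
    stop_config("fuzzy_variable '", name, "': MF centers must be strictly ascending")
  }
  if (any(centers < range[1]) || any(centers > range[2])) {
    stop_config("fuzzy_variable '", name, "': MF centers must lie within the range")
  }
  names(mfs) <- vapply(mfs, function(m) m$label, character(1))
  structure(list(name = as.character(name), range = as.numeric(range), mfs = mfs),
            class = "fuzzy_variable")
}

mf_labels <- function(variable) names(variable$mfs)

#' Fuzzify a crisp value
#'
#' Clips the value into the variable's range, then evaluates every
#' membership function.
#'
#' @param value Crisp scalar.
#' @param variable A [fuzzy_variable()].
#' @return Named numeric vector of degrees, one per label.
#' @export
fuzzify <- function(value, variable) {
  stopifnot(inherits(variable, "fuzzy_variable"))
  x <- clip(value, variable$range[1], variable$range[2])
  vapply(variable$mfs, function(m) membership(x, m), numeric(1))
}

#' Fuzzy rule
#'
#' An AND-connected antecedent (input variable -> label) with a single
#' consequent label on the output variable.
#'
#' @param antecedent Named character vector / list mapping input
#'   variable names to MF labels.
#' @param consequent Output MF label.
#' @return An object of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(antecedent, consequent) {
  antecedent <- unlist(antecedent)
  if (is.null(names(antecedent)) || any(names(antecedent) == "")) {
    stop_config("fuzzy_rule: antecedent must map variable names to labels")
  }
  structure(list(antecedent = antecedent, consequent = as.character(consequent)),
            class = "fuzzy_rule")
}

#' Assemble a Mamdani fuzzy inference system
#'
#' Validates that every rule references existing variables and labels.
#'
#' @param inputs List of input [fuzzy_variable()]s.
#' @param output Output [fuzzy_variable()].
#' @param rules Non-empty list of [fuzzy_rule()]s.
#' @param grid_points Number of uniform samples of the output range used
#'   for aggregation and center-of-area defuzzification (default 1001).
#' @return An object of class `fuzzy_system`.
#' @seealso [fuzzy_infer()], [build_block1()], [build_block2()]
#' @export
fuzzy_system <- function(inputs, output, rules, grid_points = 1001L) {
  stopifnot(all(vapply(inputs, inherits, logical(1), "fuzzy_variable")),
            inherits(output, "fuzzy_variable"))
  if (length(rules) == 0L) stop_config("fuzzy_system: rule base must be non-empty")
  if (!is_scalar_number(grid_points) || grid_points < 3) {
    stop_config("fuzzy_system: grid_points must be >= 3")
  }
  names(inputs) <- vapply(inputs, function(v) v$name, character(1))
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    stopifnot(inherits(r, "fuzzy_rule"))
    for (vn in names(r$antecedent)) {
      if (!vn %in% names(inputs)) {
        stop_config("fuzzy_system: rule ", i, " references unknown input variable '", vn, "'")
      }
      if (!r$antecedent[[vn]] %in% mf_labels(inputs[[vn]])) {
        stop_config("fuzzy_system: rule ", i, " references unknown label '",
                    r$antecedent[[vn]], "' of input '", vn, "'")
      }
    }
    if (!r$consequent %in% mf_labels(output)) {
      stop_config("fuzzy_system: rule ", i, " references unknown output label '",
                  r$consequent, "'")
    }
  }
  structure(list(inputs = inputs, output = output, rules = rules,
                 grid_points = as.integer(grid_points)),
            class = "fuzzy_system")
}

#' Run Mamdani inference and defuzzify
#'
#' Classical min/max Mamdani: each rule's activation is the minimum of
#' its antecedent membership degrees (inputs clipped into their variable
#' ranges first); the consequent MF is clipped at the activation
#' (min-implication); clipped consequents are aggregated by pointwise
#' maximum on a uniform grid over the output range; the crisp output is
#' the center of area of the aggregate,
#' `CoA = integral(f(x) x dx) / integral(f(x) dx)`, computed by
#' trapezoidal sums. An identically-zero aggregate returns the midpoint
#' of the output range with a warning (unreachable under the shipped
#' complete rule bases).
#'
#' @param system A [fuzzy_system()].
#' @param crisp_inputs Named numeric vector/list with one value per
#'   input variable.
#' @return Crisp output scalar, always within the output range.
#' @examples
#' v1 <- fuzzy_variable("x", c(0, 10), c("lo", "hi"))
#' out <- fuzzy_variable("y", c(0, 10), c("lo", "hi"))
#' sys <- fuzzy_system(list(v1), out, list(
#'   fuzzy_rule(c(x = "lo"), "lo"), fuzzy_rule(c(x = "hi"), "hi")))
#' fuzzy_infer(sys, c(x = 10))
#' @export
fuzzy_infer <- function(system, crisp_inputs) {
  stopifnot(inherits(system, "fuzzy_system"))
  crisp_inputs <- unlist(crisp_inputs)
  missing <- setdiff(names(system$inputs), names(crisp_inputs))
  if (length(missing)) {
    stop_input("fuzzy_infer: missing crisp value(s) for input(s): ",
               paste(missing, collapse = ", "))
  }
  degrees <- lapply(system$inputs, function(v) fuzzify(crisp_inputs[[v$name]], v))
  out <- system$output
  x <- seq(out$range[1], out$range[2], length.out = system$grid_points)
  agg <- numeric(length(x))
  for (r in system$rules) {
    act <- min(vapply(names(r$antecedent), function(vn) {
      degrees[[vn]][[r$antecedent[[vn]]]]
    }, numeric(1)))
    if (act <= 0) next
    agg <- pmax(agg, pmin(act, membership(x, out$mfs[[r$consequent]])))
  }
  area <- trapz_uniform(agg, x[2] - x[1])
  if (area <= 0) {
    warning("fuzzy_infer: zero aggregate; returning midpoint of output range")
    return(mean(out$range))
  }
  trapz_uniform(agg * x, x[2] - x[1]) / area
}

#' @export
print.fuzzy_system <- function(x, ...) {
  cat(sprintf("<fuzzy_system> %d input(s) -> '%s', %d rules, %d-point CoA grid\n",
              length(x$inputs), x$output$name, length(x$rules), x$grid_points))
  for (v in x$inputs) {
    cat(sprintf("  input  %-18s [%g, %g]  %d MFs: %s\n", v$name,
                v$range[1], v$range[2], length(v$mfs),
                paste(mf_labels(v), collapse = ", ")))
  }
  v <- x$output
  cat(sprintf("  output %-18s [%g, %g]  %d MFs: %s\n", v$name,
              v$range[1], v$range[2], length(v$mfs),
              paste(mf_labels(v), collapse = ", ")))
  invisible(x)
}

#' @export
summary.fuzzy_system <- function(object, ...) {
  print(object)
  cons <- table(vapply(object$rules, function(r) r$consequent, character(1)))
  cat("  rule consequents:", paste(sprintf("%s=%d", names(cons), cons), collapse = ", "), "\n")
  invisible(object)
}

#' Predict crisp outputs for a table of inputs
#'
#' @param object A [fuzzy_system()].
#' @param newdata Data frame with one column per input variable.
#' @param ... Unused.
#' @return Numeric vector of crisp outputs, one per row.
#' @export
predict.fuzzy_system <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  vapply(seq_len(nrow(newdata)), function(i) {
    fuzzy_infer(object, unlist(newdata[i, names(object$inputs), drop = FALSE]))
  }, numeric(1))
}

#' Plot the membership functions of a fuzzy variable
#'
#' @param x A [fuzzy_variable()].
#' @param n Grid resolution.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.fuzzy_variable <- function(x, n = 512, ...) {
  g <- seq(x$range[1], x$range[2], length.out = n)
  m <- vapply(x$mfs, function(mf) membership(g, mf), numeric(n))
  graphics::matplot(g, m, type = "l", lty = 1, xlab = x$name,
                    ylab = "membership", main = x$name, ...)
  graphics::legend("right", legend = mf_labels(x), lty = 1,
                   col = seq_along(x$mfs), cex = 0.8)
  invisible(x)
}
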