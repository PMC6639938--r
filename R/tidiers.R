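#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a discovery evaluation
#'
#' @param x An `alu_eval` object from [evaluate_discovery()].
#' @param ... Unused.
#' @return Per-insertion tibble with the classification `status`.
#' @method tidy alu_eval
#' @export
tidy.alu_eval <- function(x, ...) {
  as_tibble(x) |> select("chrom", "pos", "haplotype", "status")
}

#' Summarise a discovery evaluation
#'
#' One-row summary of an evaluation: overall sensitivity, sensitivity over
#' the detectable subset (insertions neither in N regions nor on repeated
#' flanks), the FN1/FN2 decomposition, and the false discovery count.
#'
#' @inheritParams tidy.alu_eval
#' @return One-row tibble.
#' @method glance alu_eval
#' @export
glance.alu_eval <- function(x, ...) {
  n <- nrow(x)
  det <- sum(x$status == "detected")
  fn1 <- sum(x$status == "FN1")
  fn2 <- sum(x$status == "FN2")
  other <- sum(x$status == "missed_other")
  detectable <- n - fn1 - fn2
  tibble(
    n = n, detected = det, fn1 = fn1, fn2 = fn2, missed_other = other,
    sensitivity = if (n > 0) det / n else NA_real_,
    sensitivity_detectable = if (detectable > 0) det / detectable
                             else NA_real_,
    fn1_rate = if (n > 0) fn1 / n else NA_real_,
    fn2_rate = if (n > 0) fn2 / n else NA_real_,
    false_discoveries = attr(x, "false_discoveries") %||% NA_integer_
  )
}

#' Tidy a calibrated caller model
#'
#' @param x A `caller_model`.
#' @param ... Unused.
#' @return Tibble of model parameters.
#' @method tidy caller_model
#' @export
tidy.caller_model <- function(x, ...) {
  tibble(
    term = c("lam", "eps"),
    estimate = c(x$lam, x$eps),
    description = c("expected per-allele k-mer coverage",
                    "absent-allele leak rate")
  )
}

#' @rdname tidy.caller_model
#' @method glance caller_model
#' @export
glance.caller_model <- function(x, ...) {
  tibble(lam = x$lam, eps = x$eps)
}

#' Summarise a set of genotype calls
#'
#' @param x An `alu_calls` tibble.
#' @param ... Unused.
#' @return One-row tibble of call-rate statistics.
#' @method glance alu_calls
#' @export
glance.alu_calls <- function(x, ...) {
  tibble(
    n = nrow(x),
    n_called = sum(x$genotype != "NC"),
    call_rate = if (nrow(x)) mean(x$genotype != "NC") else NA_real_,
    mean_depth = if (nrow(x)) mean(x$nA + x$nB) else NA_real_
  )
}
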