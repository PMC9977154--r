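#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy differential-expression results
#'
#' @param x An `oomics_de` object.
#' @param ... Unused.
#' @return A plain tibble of per-gene results.
#' @method tidy oomics_de
#' @export
tidy.oomics_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "oomics_de")
  out
}

#' @rdname tidy.oomics_de
#' @method glance oomics_de
#' @export
glance.oomics_de <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_up = if ("call" %in% names(x)) sum(x$call == "up") else NA_integer_,
    n_down = if ("call" %in% names(x)) sum(x$call == "down") else NA_integer_,
    n_sig = sum(x$padj < 0.05, na.rm = TRUE),
    median_dispersion = stats::median(x$dispersion))
}

#' Tidy moderated-t results
#'
#' @param x An `oomics_modt` object.
#' @param ... Unused.
#' @return A plain tibble of per-protein results.
#' @method tidy oomics_modt
#' @export
tidy.oomics_modt <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "oomics_modt")
  out
}

#' @rdname tidy.oomics_modt
#' @method glance oomics_modt
#' @export
glance.oomics_modt <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_up = if ("call" %in% names(x)) sum(x$call == "up") else NA_integer_,
    n_down = if ("call" %in% names(x)) sum(x$call == "down") else NA_integer_,
    prior_df = attr(x, "prior_df"),
    prior_var = attr(x, "prior_var"))
}

#' Tidy differential-methylation results
#'
#' @param x An `oomics_dmr_test` or `oomics_dmr` object.
#' @param ... Unused.
#' @return A plain tibble of per-tile results.
#' @method tidy oomics_dmr_test
#' @export
tidy.oomics_dmr_test <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), c("oomics_dmr", "oomics_dmr_test"))
  out
}

#' @rdname tidy.oomics_dmr_test
#' @method glance oomics_dmr_test
#' @export
glance.oomics_dmr_test <- function(x, ...) {
  tibble::tibble(
    n_tiles = nrow(x),
    n_tested = sum(!is.na(x$p)),
    n_dmr = if ("call" %in% names(x)) sum(x$call) else NA_integer_,
    n_hyper = if ("call" %in% names(x)) sum(x$call & x$direction == "hyper") else NA_integer_,
    n_hypo = if ("call" %in% names(x)) sum(x$call & x$direction == "hypo") else NA_integer_)
}
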