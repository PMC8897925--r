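# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a methylation-expression (or -accessibility) correlation
#'
#' @param x A `methylens_cor` object.
#' @param ... Unused.
#' @return One-row tibble: `r`, `p_value`, `n`, `scope`.
#' @export
tidy.methylens_cor <- function(x, ...) {
  tibble(r = x$r, p_value = x$p_value, n = x$n, scope = x$scope)
}

#' @rdname tidy.methylens_cor
#' @export
glance.methylens_cor <- function(x, ...) tidy(x)

#' Tidy a contingency-association result
#'
#' @param x A `methylens_assoc` object (quadrant association, hyper/hypo
#'   distribution comparison or triple-integration concordance).
#' @param ... Unused.
#' @return Long tibble of cell counts with the table's dimension names.
#' @export
tidy.methylens_assoc <- function(x, ...) {
  as_tibble(as.data.frame(x$table, responseName = "n"))
}

#' @rdname tidy.methylens_assoc
#' @export
glance.methylens_assoc <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         n = sum(x$table))
}

#' Tidy a random-placement null comparison
#'
#' @param x A `methylens_null` object.
#' @param ... Unused.
#' @return The per-category observed/expected comparison tibble.
#' @export
tidy.methylens_null <- function(x, ...) x$comparison

#' @rdname tidy.methylens_null
#' @export
glance.methylens_null <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         n_draws = x$n_draws)
}

#' @export
print.methylens_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3f, p = %.3g, n = %d (%s)\n",
              x$r, x$p_value, x$n, x$scope))
  invisible(x)
}

#' @export
print.methylens_assoc <- function(x, ...) {
  print(x$table)
  if (is.na(x$statistic)) {
    cat("Chi-square skipped (degenerate margin).\n")
  } else {
    cat(sprintf("Pearson chi-square = %.4g, df = %d, p = %.3g\n",
                x$statistic, x$df, x$p_value))
  }
  invisible(x)
}

#' @export
print.methylens_null <- function(x, ...) {
  print(x$comparison)
  cat(sprintf("Observed vs random placement: chi-square = %.4g, df = %d, p = %.3g (%d draws)\n",
              x$statistic, x$df, x$p_value, x$n_draws))
  invisible(x)
}
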