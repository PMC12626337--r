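#' Generalized Lotka-Volterra parameter set
#'
#' Bundles the per-capita growth-rate vector `r` (units 1/time) and the
#' interaction matrix `B` (units 1/(abundance x time)), where `B[i, j]` is the
#' effect of species `j` on the growth of species `i`. When abundances are
#' only observed as compositions, the diagonal (self-interaction) entries are
#' unidentifiable and must be pinned to zero; `self_interactions` records
#' whether the diagonal is free.
#'
#' @param r Numeric vector of growth rates, length `m`.
#' @param B Numeric `m x m` interaction matrix.
#' @param self_interactions Logical; whether diagonal entries are free. If
#'   `NULL` (default), inferred from the diagonal of `B`. If `FALSE`, the
#'   diagonal must be exactly zero.
#' @param labels Optional character vector of species names.
#' @return An object of class `glv_params`.
#' @examples
#' p <- glv_params(r = c(0.3, -0.1), B = matrix(c(0, 0.01, -0.02, 0), 2, 2))
#' @export
glv_params <- function(r, B, self_interactions = NULL, labels = NULL) {
  r <- as.numeric(r)
  B <- as.matrix(B)
  m <- length(r)
  if (!all(is.finite(r)) || !all(is.finite(B))) {
    stop("glv_params: all entries of 'r' and 'B' must be finite")
  }
  if (nrow(B) != m || ncol(B) != m) {
    stop("glv_params: 'B' must be a ", m, "x", m, " matrix to match 'r'")
  }
  if (is.null(self_interactions)) {
    self_interactions <- any(diag(B) != 0)
  }
  if (!self_interactions && any(diag(B) != 0)) {
    stop("glv_params: diagonal of 'B' must be exactly 0 when ",
         "'self_interactions' is FALSE")
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == m)
    names(r) <- labels
    dimnames(B) <- list(labels, labels)
  }
  structure(list(r = r, B = B, self_interactions = self_interactions,
                 labels = labels),
            class = "glv_params")
}

#' @export
print.glv_params <- function(x, ...) {
  m <- length(x$r)
  cat("gLV parameters:", m, "species",
      if (x$self_interactions) "(self-interactions free)" else
        "(self-interactions pinned to 0)", "\n")
  cat("r:", signif(x$r, 4), "\n")
  cat("B:\n")
  print(signif(x$B, 4))
  invisible(x)
}

#' Number of species in a parameter set
#' @param params A `glv_params` object.
#' @return Integer species count.
#' @export
n_species <- function(params) length(params$r)
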