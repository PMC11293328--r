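#' Spectra tibbles
#'
#' Throughout the package a set of absorbance spectra is a *wide tibble*: a
#' `sample_id` character column followed by one numeric column per wavenumber,
#' with column names equal to the wavenumber in cm^-1 (e.g. `"1652"`). A single
#' spectrum (such as the pure-water reference) is simply a one-row spectra
#' tibble. These helpers convert between the tibble and plain-matrix views.
#'
#' @param spectra A spectra tibble.
#' @return `spectra_grid()` returns the ascending numeric wavenumber axis;
#'   `spectra_matrix()` the samples-by-wavenumbers numeric matrix with
#'   `sample_id` rownames; `as_spectra()` rebuilds a spectra tibble from a
#'   matrix whose column names are wavenumbers.
#' @examples
#' s <- as_spectra(matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c(1000, 1002, 1004))))
#' spectra_grid(s)
#' spectra_matrix(s)
#' @export
spectra_grid <- function(spectra) {
  check_spectra(spectra)
  as.numeric(names(spectra)[-1])
}

#' @rdname spectra_grid
#' @export
spectra_matrix <- function(spectra) {
  check_spectra(spectra)
  m <- as.matrix(spectra[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- spectra$sample_id
  m
}

#' @rdname spectra_grid
#' @param m Numeric matrix, columns named by wavenumber.
#' @param sample_id Optional character vector of sample identifiers; defaults
#'   to the matrix rownames.
#' @export
as_spectra <- function(m, sample_id = rownames(m)) {
  if (is.null(colnames(m))) {
    abort("matrix columns must be named by wavenumber")
  }
  if (is.null(sample_id)) {
    sample_id <- paste0("S", seq_len(nrow(m)))
  }
  grid <- as.numeric(colnames(m))
  if (anyNA(grid)) abort("matrix column names must be numeric wavenumbers")
  if (is.unsorted(grid, strictly = TRUE)) {
    o <- order(grid)
    m <- m[, o, drop = FALSE]
    grid <- grid[o]
  }
  out <- as_tibble(m, .name_repair = "minimal")
  names(out) <- format_wavenumber(grid)
  bind_cols(tibble(sample_id = as.character(sample_id)), out)
}

format_wavenumber <- function(grid) {
  format(grid, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

check_spectra <- function(spectra, arg = deparse(substitute(spectra))) {
  if (!is.data.frame(spectra) || names(spectra)[1] != "sample_id") {
    abort(sprintf("`%s` must be a spectra tibble (first column `sample_id`)", arg))
  }
  grid <- suppressWarnings(as.numeric(names(spectra)[-1]))
  if (anyNA(grid)) {
    abort(sprintf("`%s` has non-numeric wavenumber column names", arg))
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    abort(sprintf("`%s` wavenumber columns must be strictly ascending", arg))
  }
  invisible(spectra)
}

# uniform grid spacing; errors if spacing varies beyond tolerance
grid_spacing <- function(grid) {
  d <- diff(grid)
  if (length(d) == 0) abort("grid needs at least two points")
  if (diff(range(d)) > 1e-8 * max(abs(d))) {
    abort("wavenumber grid must be uniformly spaced for finite differences")
  }
  d[1]
}
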