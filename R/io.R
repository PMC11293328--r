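#' Read and write spectra CSV files
#'
#' Interchange format for absorbance spectra: first column `sample_id`, the
#' remaining columns headed by the numeric wavenumber in cm^-1 and holding
#' absorbance in AU. A file with a descending wavenumber header is reordered
#' to the ascending convention with a warning; duplicate sample ids, ragged
#' rows and non-numeric cells are errors.
#'
#' @param path File path.
#' @return `read_spectra_csv()` returns a spectra tibble.
#' @export
read_spectra_csv <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(
      sample_id = readr::col_character(), .default = readr::col_double()
    ),
    progress = FALSE
  )
  if (names(df)[1] != "sample_id") abort("first column must be `sample_id`")
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf(
      "malformed spectra file: %d parsing problems (first at row %d)",
      nrow(prob), prob$row[1]
    ))
  }
  if (anyDuplicated(df$sample_id)) {
    abort("duplicate sample_id in spectra file")
  }
  grid <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(grid)) abort("non-numeric wavenumber column in spectra file")
  if (is.unsorted(grid, strictly = TRUE)) {
    warn("wavenumber header not ascending; columns reordered")
    df <- df[, c(1, 1 + order(grid))]
  }
  check_spectra(df)
  as_tibble(df)
}

#' @rdname read_spectra_csv
#' @param spectra Spectra tibble to write.
#' @export
write_spectra_csv <- function(spectra, path) {
  check_spectra(spectra)
  readr::write_csv(spectra, path)
  invisible(path)
}

#' Read a clinical-record CSV
#'
#' Typed parsing of the per-sample clinical table (anthropometrics, blood
#' pressures, medication flags, the 12-analyte panel). Empty cells become
#' `NA` and are mirrored in a logical `missing_mask` attribute-free companion:
#' downstream phenotype/risk-factor deciders treat `NA` as unknown.
#'
#' @param path File path.
#' @return A tibble, medication flags as logicals.
#' @export
read_clinical_csv <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      individual_id = readr::col_character(),
      visit = readr::col_integer(),
      sex = readr::col_character(),
      med_antihypertensive = readr::col_logical(),
      med_antidiabetic = readr::col_logical(),
      med_fibrates = readr::col_logical(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  if (anyDuplicated(df$sample_id)) abort("duplicate sample_id in clinical file")
  if (any(!df$visit %in% c(1L, 2L))) abort("`visit` must be 1 or 2")
  as_tibble(df)
}

#' Read a phenotype-label CSV
#'
#' Parses the five phenotype columns plus `unknown` and validates every
#' complete row against the feasibility constraints (no prediabetes together
#' with type 2 diabetes; `healthy` exactly when all conditions absent). An
#' infeasible row is a validation error naming the offending sample.
#'
#' @param path File path.
#' @return A labels tibble.
#' @export
read_labels_csv <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(
      sample_id = readr::col_character(), .default = readr::col_logical()
    ),
    progress = FALSE
  )
  labs <- phenotype_labels()
  miss <- setdiff(labs, names(df))
  if (length(miss)) abort(paste("label file lacks columns:", toString(miss)))
  m <- label_matrix(df, labs)
  complete <- stats::complete.cases(m)
  bad <- complete & ((m[, "prediabetes"] & m[, "t2d"]) |
    (m[, "healthy"] != !(m[, "dyslipidemia"] | m[, "hypertension"] |
      m[, "prediabetes"] | m[, "t2d"])))
  if (any(bad)) {
    abort(sprintf(
      "infeasible label row(s): %s",
      toString(head(df$sample_id[bad], 5))
    ))
  }
  if (!"unknown" %in% names(df)) df$unknown <- !complete
  as_tibble(df)
}

#' Write a synthetic cohort to disk
#'
#' Emits the full file set the pipeline consumes: one spectra CSV per sample
#' set, the water reference as a one-row spectra CSV, the clinical and label
#' tables, and a ground-truth JSON (per-sample water deficit, converter ids,
#' simulation seed). Reading the files back reproduces the in-memory values.
#'
#' @param cohort An `ir_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ir_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  ids1 <- cohort_set(cohort, 1)
  ids2 <- cohort_set(cohort, 2)
  sp <- cohort$spectra
  write_spectra_csv(sp[match(ids1, sp$sample_id), ], p("spectra_set1.csv"))
  if (length(ids2) > 0) {
    write_spectra_csv(sp[match(ids2, sp$sample_id), ], p("spectra_set2.csv"))
  }
  write_spectra_csv(cohort$water, p("water_reference.csv"))
  readr::write_csv(cohort$clinical, p("clinical.csv"))
  readr::write_csv(cohort$labels, p("labels.csv"))
  truth <- list(
    seed = cohort$config$seed,
    water_deficit = setNames(
      as.list(cohort$truth$deficit$deficit),
      cohort$truth$deficit$sample_id
    ),
    converters = cohort$truth$converters
  )
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  paths <- c(
    spectra_set1 = p("spectra_set1.csv"),
    spectra_set2 = if (length(ids2) > 0) p("spectra_set2.csv") else NA,
    water = p("water_reference.csv"), clinical = p("clinical.csv"),
    labels = p("labels.csv"), ground_truth = p("ground_truth.json")
  )
  invisible(paths[!is.na(paths)])
}

#' Serialize a fitted chain to JSON
#'
#' Stores the chain order, per-link weights and intercepts, regularization
#' and threshold, so a fit can be archived and reloaded exactly.
#'
#' @param model An `ir_chain`.
#' @param path Output path.
#' @export
write_chain_json <- function(model, path) {
  stopifnot(inherits(model, "ir_chain"))
  obj <- list(
    order = model$order, label_cols = model$label_cols,
    c_reg = model$c_reg, threshold = model$threshold,
    feature_names = model$feature_names,
    models = lapply(model$models, function(m) {
      list(
        coefficients = as.list(m$coefficients), intercept = m$intercept,
        lambda = m$lambda, c_reg = m$c_reg
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chain_json
#' @export
read_chain_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(obj$models, function(m) {
    structure(
      list(
        coefficients = unlist(m$coefficients), intercept = m$intercept,
        lambda = m$lambda, c_reg = m$c_reg,
        feature_names = names(unlist(m$coefficients))
      ),
      class = "ir_logit"
    )
  })
  structure(
    list(
      order = unlist(obj$order), models = models,
      label_cols = unlist(obj$label_cols), c_reg = obj$c_reg,
      threshold = obj$threshold, feature_names = unlist(obj$feature_names)
    ),
    class = "ir_chain"
  )
}

#' Minimal JCAMP-DX reader for a single IR spectrum
#'
#' Reads the `##XYDATA=(X++(Y..Y))` block of a JCAMP-DX file (the common
#' fixed-grid tabular layout used for IR exchange), applying `XFACTOR` /
#' `YFACTOR` scaling. Intended for interoperability with instrument exports;
#' the package's native interchange format remains the spectra CSV.
#'
#' @param path File path.
#' @param sample_id Identifier for the resulting one-row spectra tibble.
#' @return A one-row spectra tibble.
#' @export
read_jcamp <- function(path, sample_id = "jcamp") {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(name, default = NA_real_) {
    hit <- grep(paste0("^##", name, "="), lines, value = TRUE)
    if (length(hit) == 0) {
      return(default)
    }
    as.numeric(sub(paste0("^##", name, "="), "", hit[1]))
  }
  xf <- get_field("XFACTOR", 1)
  yf <- get_field("YFACTOR", 1)
  start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (length(start) == 0) abort("no ##XYDATA=(X++(Y..Y)) block found")
  end <- grep("^##END", lines)
  end <- min(end[end > start[1]], length(lines) + 1)
  block <- lines[(start[1] + 1):(end - 1)]
  xs <- c()
  ys <- c()
  for (ln in block) {
    vals <- as.numeric(strsplit(trimws(ln), "[ \t,]+")[[1]])
    if (length(vals) < 2 || anyNA(vals)) next
    x0 <- vals[1] * xf
    yv <- vals[-1] * yf
    dx <- get_field("DELTAX", NA)
    if (is.na(dx)) {
      npts <- get_field("NPOINTS")
      dx <- (get_field("LASTX") - get_field("FIRSTX")) * xf / (npts - 1)
    } else {
      dx <- dx * xf
    }
    xs <- c(xs, x0 + dx * (seq_along(yv) - 1))
    ys <- c(ys, yv)
  }
  o <- order(xs)
  m <- matrix(ys[o], nrow = 1, dimnames = list(sample_id, format_wavenumber(xs[o])))
  as_spectra(m)
}
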