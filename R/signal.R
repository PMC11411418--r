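# shared checks for delta tables
check_deltas <- function(d, arg = "deltas") {
  need <- c("element", "dR", "dG", "dB")
  if (!all(need %in% names(d))) {
    abort(paste0(arg, " must have columns element, dR, dG, dB"))
  }
  missing <- setdiff(element_ids(), d$element)
  if (length(missing) > 0) {
    abort(paste0(arg, " is missing elements: ", paste(missing, collapse = ", ")))
  }
  d[match(element_ids(), d$element), ]
}

# 12 x 3 delta table -> named 36-vector in canonical order
deltas_to_vector <- function(d) {
  d <- check_deltas(d)
  setNames(as.vector(t(as.matrix(d[, c("dR", "dG", "dB")]))), response_cols())
}

#' Corrected response vector for a volatile-compound assay
#'
#' The final signal of a VOC measurement removes the drift the device
#' shows in an empty container: per sensing element and channel,
#' `signal = delta(full container) - delta(empty container)`. The 12
#' corrected (R, G, B) triplets are assembled element-major into the
#' 36-feature response vector.
#'
#' Negative corrected values are retained; the difference equations permit
#' them and they carry pattern information.
#'
#' @param full,empty Delta tables (`element`, `dR`, `dG`, `dB`) from
#'   [compute_delta()] for the analyte-loaded and empty containers.
#' @param sample_id Optional sample identifier carried into the output.
#' @return A one-row tibble: `sample_id`, `mode` (`"voc"`), then the 36
#'   feature columns of [response_cols()].
#' @export
#' @examples
#' z <- tibble::tibble(element = element_ids(), dR = 0, dG = 0, dB = 0)
#' f <- dplyr::mutate(z, dR = 10)
#' e <- dplyr::mutate(z, dR = 2)
#' correct_voc(f, e)$S1_R
correct_voc <- function(full, empty, sample_id = NA_character_) {
  x <- deltas_to_vector(full) - deltas_to_vector(empty)
  dplyr::bind_cols(tibble(sample_id = sample_id, mode = "voc"),
                   as_tibble(as.list(x)))
}

#' Corrected response vector for a urine assay
#'
#' Urine headspace is mostly water vapor, so the urine signal subtracts
#' both the water-vapor response and the empty-container drift:
#' `signal = delta(urine) - delta(water) - delta(empty)` per element and
#' channel. Setting the water deltas to zero reduces this to the VOC
#' correction.
#'
#' @param urine,water,empty Delta tables for the urine sample, water
#'   vapor, and empty container runs.
#' @inheritParams correct_voc
#' @return A one-row tibble: `sample_id`, `mode` (`"urine"`), then the 36
#'   feature columns.
#' @export
correct_urine <- function(urine, water, empty, sample_id = NA_character_) {
  x <- deltas_to_vector(urine) - deltas_to_vector(water) -
    deltas_to_vector(empty)
  dplyr::bind_cols(tibble(sample_id = sample_id, mode = "urine"),
                   as_tibble(as.list(x)))
}

#' Euclidean-norm summary of a response vector
#'
#' Collapses the 36-feature corrected response to one scalar,
#' `sqrt(sum(x_i^2))`, the assay's "total result" used for condition
#' optimization, severity regression and reproducibility.
#'
#' @param x Numeric vector (any length; 36 for a full response vector).
#' @return Non-negative scalar.
#' @export
#' @examples
#' euclidean_norm(c(3, 4))
euclidean_norm <- function(x) {
  if (!is.numeric(x)) abort("euclidean_norm needs a numeric vector")
  if (any(!is.finite(x))) abort("euclidean_norm: non-finite component")
  sqrt(sum(x^2))
}

#' Per-sample Euclidean norms of a response matrix
#'
#' Applies [euclidean_norm()] row-wise to the 36 feature columns of a
#' response tibble; all metadata columns are preserved and a `norm`
#' column is appended.
#'
#' @param data A response tibble containing the [response_cols()]
#'   columns.
#' @param elements Optional subset of element ids (e.g. `c("S3", "S7")`)
#'   whose channels alone enter the norm; default all 12.
#' @return `data` with an added `norm` column.
#' @export
#' @examples
#' generate_voc_dataset(generator_config(seed = 1)) |>
#'   response_norms() |>
#'   dplyr::select(compound, replicate, norm)
response_norms <- function(data, elements = element_ids()) {
  m <- response_matrix_values(data)
  keep <- response_cols()[rep(element_ids(), each = 3) %in% elements]
  if (length(keep) == 0) abort("no elements selected")
  data$norm <- sqrt(rowSums(m[, keep, drop = FALSE]^2))
  as_tibble(data)
}

#' Read / write response matrices as CSV
#'
#' One row per sample; metadata columns first, then the 36 feature
#' columns `S1_R ... S12_B`.
#'
#' @param data Response tibble.
#' @param path CSV file path.
#' @return `read_responses()` returns a tibble; `write_responses()` the
#'   path, invisibly.
#' @export
write_responses <- function(data, path) {
  response_matrix_values(data)  # validate completeness before writing
  meta <- setdiff(names(data), response_cols())
  write.csv(data[, c(meta, response_cols())], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) abort(paste0("response file not found: ", path))
  out <- as_tibble(read.csv(path, check.names = FALSE))
  response_matrix_values(out)
  out
}
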