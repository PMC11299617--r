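# Plain-text readers and writers: curves as multi-column text (the common
# SAS .dat layout), model-selection results as JSON, sweep tallies as CSV.

RESULT_SCHEMA_VERSION <- "1.0"

#' Read a scattering curve from a text file
#'
#' Accepts whitespace- or comma-delimited text with `#` comment lines; the
#' first two columns are taken as q and y, extra columns (e.g. a sigma
#' column) are ignored.
#'
#' @param path File path.
#' @param T Pseudo-measurement time to attach to the curve.
#' @return A [sas_curve()].
#' @export
read_curve <- function(path, T = 1) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("no data rows in ", path)
  rows <- which(keep)
  parsed <- lapply(lines[keep], function(x) {
    strsplit(trimws(x), "[[:space:],]+")[[1L]]
  })
  ncols <- vapply(parsed, length, integer(1))
  if (any(ncols < 2L))
    stop(sprintf("malformed row at line %d of %s: need at least 2 columns",
                 rows[which(ncols < 2L)[1L]], path))
  q <- suppressWarnings(as.numeric(vapply(parsed, `[[`, character(1), 1L)))
  y <- suppressWarnings(as.numeric(vapply(parsed, `[[`, character(1), 2L)))
  bad <- which(is.na(q) | is.na(y))
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s: non-numeric value",
                 rows[bad[1L]], path))
  if (length(q) > 1L && any(diff(q) <= 0))
    stop(sprintf("non-monotone q at line %d of %s",
                 rows[which(diff(q) <= 0)[1L] + 1L], path))
  if (any(y < 0))
    stop(sprintf("negative intensity at line %d of %s",
                 rows[which(y < 0)[1L]], path))
  sas_curve(q, y, T = T)
}

#' Write a scattering curve as 3-column text
#'
#' Columns are q, y and `sqrt(y)` (the Poisson-scale sigma placeholder used
#' by common SAS .dat readers); a `#` header records N and T.
#'
#' @param curve A [sas_curve()].
#' @param path Output path.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "sas_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scattering curve: N = %d, T = %g", curve$N, curve$T), con)
  writeLines("# q[nm^-1]  counts  sigma", con)
  writeLines(sprintf("%.10g %.10g %.10g", curve$q, curve$y, sqrt(curve$y)), con)
  invisible(path)
}

#' Write a model-selection result as JSON
#'
#' The JSON object carries the schema version, the seed and sampler
#' configuration (so the run can be repeated exactly), and per-candidate
#' blocks with `logZ`, `F`, `P`, the MAP parameters and the reduced
#' chi-squared baseline.
#'
#' @param result A `model_selection` from [run_model_selection()].
#' @param path Output path.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "model_selection"))
  per_K <- lapply(seq_along(result$K), function(i) {
    m <- result$map[[i]]
    list(logZ = result$logZ[[i]], F = result$F[[i]], P = unname(result$P[i]),
         map = if (inherits(m, "flat_params")) list(B = m$B)
               else list(R = m$R, S = m$S, B = m$B),
         chi2_min = result$chi2$chi2_min[[i]],
         chi2_reduced = result$chi2$chi2_reduced[[i]])
  })
  names(per_K) <- paste0("K", result$K)
  obj <- list(schema_version = RESULT_SCHEMA_VERSION,
              seed = result$seed, config = result$config,
              selected_K = result$selected_K,
              chi2_selected_K = result$chi2$selected_K,
              models = per_K)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read back a model-selection result JSON
#' @param path File written by [write_result()].
#' @return The parsed list.
#' @export
read_result <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write / read a sweep tally as CSV
#'
#' @param tally The `tally` data frame of a `sweep_result` (or the output of
#'   [chi2_tally()]).
#' @param path File path.
#' @export
write_tally <- function(tally, path) {
  stopifnot(is.data.frame(tally))
  write.table(tally, path, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_tally
#' @export
read_tally <- function(path)
  read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
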