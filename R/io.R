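#' Read an orientation-tuning curve from CSV
#'
#' Expects columns `theta` (or `theta_rad`, always radians) and
#' `response`.  Angles in a `theta` column may be given in degrees
#' (`degrees = TRUE`); internally everything is radians.  Responses are
#' renormalized to maximum 1, with a warning when the input maximum
#' differs from 1 by more than 1e-6.
#'
#' @param path CSV file path.
#' @param degrees Interpret the `theta` column as degrees.
#' @return A [tuning_curve()].
#' @export
read_tuning_csv <- function(path, degrees = FALSE) {
  df <- utils::read.csv(path)
  if ("theta_rad" %in% names(df) && !"theta" %in% names(df)) {
    df$theta <- df$theta_rad
    degrees <- FALSE
  }
  if (!all(c("theta", "response") %in% names(df)))
    stop(sprintf("'%s' must have columns 'theta' and 'response'", path),
         call. = FALSE)
  df$theta <- suppressWarnings(as.numeric(df$theta))
  df$response <- suppressWarnings(as.numeric(df$response))
  bad <- which(!is.finite(df$theta) | !is.finite(df$response))
  if (length(bad))
    stop(sprintf("non-numeric or missing entries in '%s' at data line %d",
                 path, bad[1]), call. = FALSE)
  th <- if (degrees) df$theta * pi / 180 else df$theta
  mx <- max(df$response)
  if (mx <= 0) stop("all responses are zero", call. = FALSE)
  if (abs(mx - 1) > 1e-6)
    warning(sprintf("responses renormalized from maximum %.6g to 1", mx),
            call. = FALSE)
  tuning_curve(th, df$response / mx, meta = list(source = path))
}

#' Write a tuning curve to CSV (with JSON metadata sidecar)
#'
#' Columns `theta_rad`, `response` at full double precision; the model
#' metadata is written to `<path>.json`.
#'
#' @param curve A [tuning_curve()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tuning_csv <- function(curve, path) {
  stopifnot(inherits(curve, "tuning_curve"))
  df <- data.frame(theta_rad = curve$thetas, response = curve$values)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  write_sidecar(path, curve$meta)
  invisible(path)
}

#' Write resultant histograms to CSV
#'
#' Long format with columns `class`, `bin_lo`, `bin_hi`, `count`
#' (integer), in deterministic order.
#'
#' @param hists A single [rhistogram()] or a (possibly named) list of
#'   them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hists, path) {
  if (inherits(hists, "rhistogram")) hists <- list(hists)
  rows <- lapply(hists, function(h) {
    stopifnot(inherits(h, "rhistogram"))
    data.frame(class = h$label, bin_lo = utils::head(h$edges, -1),
               bin_hi = utils::tail(h$edges, -1), count = as.integer(h$counts))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read resultant histograms back from CSV
#'
#' Inverse of [write_histogram_csv()].
#'
#' @param path CSV path.
#' @return A named list of [rhistogram()] objects.
#' @export
read_histogram_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("class", "bin_lo", "bin_hi", "count")
  if (!all(need %in% names(df)))
    stop("histogram CSV must have columns class, bin_lo, bin_hi, count",
         call. = FALSE)
  out <- lapply(split(df, df$class), function(d) {
    d <- d[order(d$bin_lo), ]
    structure(list(edges = c(d$bin_lo, d$bin_hi[nrow(d)]),
                   counts = as.integer(d$count), label = d$class[1]),
              class = "rhistogram")
  })
  out[unique(df$class)]
}

#' Write a sampled kernel to CSV
#'
#' One row per `x2` value, one column per `x1` value; grid and model
#' parameters go to the JSON sidecar.
#'
#' @param kernel A [sample_spatial_rf()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kernel_csv <- function(kernel, path) {
  z <- t(kernel$z)  # rows indexed by x2
  df <- data.frame(x2 = kernel$x2, z)
  names(df) <- c("x2", sprintf("x1_%g", kernel$x1))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  sh <- kernel$rf$shape
  write_sidecar(path, list(sigma1 = sh$sigma1, sigma2 = sh$sigma2,
                           phi = sh$phi, m = kernel$rf$order_m,
                           step = kernel$step,
                           extent = max(kernel$x1)))
  invisible(path)
}

#' Write a cortical map to CSV
#'
#' Long format `x, y, orientation_rad, kappa, eccentricity`; the pinwheel
#' centers and parameters go to the JSON sidecar.
#'
#' @param map A [generate_pinwheel_map()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "cortical_map"))
  s <- map$sites
  df <- data.frame(x = s$x, y = s$y, orientation_rad = s$orientation,
                   kappa = s$kappa, eccentricity = s$eccentricity)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  write_sidecar(path, list(grid_size = map$grid_size,
                           centers = map$centers))
  invisible(path)
}

# JSON metadata sidecar: <path>.json with the full parameter set, so
# every artifact can be regenerated from its sidecar alone.
write_sidecar <- function(path, meta) {
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(NULL)
}
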