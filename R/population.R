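#' Specification of a simulated receptive-field population
#'
#' Describes a population of model neurons whose elongation ratio kappa is
#' distributed log-uniformly over `[1/kappa_max, kappa_max]`: the
#' log-parameterization `K = log(kappa)` is uniform on
#' `[-log(kappa_max), log(kappa_max)]`.  In `"grid"` sampling the K values
#' are equally spaced (fully deterministic); in `"random"` sampling they
#' are i.i.d. uniform, reproducible under `seed`.
#'
#' @param kappa_max Upper end of the ratio range; `> 1`.  Default 8.
#' @param n_per_class Number of simulated cells per class.  Default 10000.
#' @param orders Simple-cell derivative orders to include (subset of 1..4).
#' @param include_complex Include the complex-cell class.
#' @param sampling `"grid"` or `"random"`.
#' @param seed Integer seed for random sampling.
#' @param n_bins Number of equal-width resultant bins on `[0, 1]`.
#'   Default 10.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(kappa_max = 8, n_per_class = 10000L,
                            orders = 1:4, include_complex = TRUE,
                            sampling = c("grid", "random"), seed = NULL,
                            n_bins = 10L) {
  sampling <- match.arg(sampling)
  if (!is.finite(kappa_max) || kappa_max <= 1)
    stop("'kappa_max' must exceed 1", call. = FALSE)
  if (n_per_class < 1) stop("'n_per_class' must be at least 1", call. = FALSE)
  if (length(orders) && !all(orders %in% 1:4))
    stop("'orders' must be a subset of 1..4", call. = FALSE)
  if (n_bins < 1) stop("'n_bins' must be at least 1", call. = FALSE)
  structure(list(kappa_max = kappa_max, n_per_class = as.integer(n_per_class),
                 orders = as.integer(sort(unique(orders))),
                 include_complex = isTRUE(include_complex),
                 sampling = sampling, seed = seed, n_bins = as.integer(n_bins)),
            class = "population_spec")
}

#' Draw elongation ratios for a population
#'
#' @param spec A [population_spec()].
#' @param n Number of draws; defaults to `spec$n_per_class`.
#' @return Numeric vector of kappa values in `[1/kappa_max, kappa_max]`.
#' @examples
#' sample_kappa(population_spec(n_per_class = 3))  # 1/8, 1, 8
#' @export
sample_kappa <- function(spec, n = spec$n_per_class) {
  stopifnot(inherits(spec, "population_spec"))
  Kmax <- log(spec$kappa_max)
  if (spec$sampling == "grid") {
    if (n < 2) stop("grid sampling requires at least 2 values", call. = FALSE)
    return(exp(seq(-Kmax, Kmax, length.out = n)))
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  exp(stats::runif(n, -Kmax, Kmax))
}

#' Resultant histogram container
#'
#' Bins are equal-width on `[0, 1]`, right-open except the last, which is
#' closed at 1.
#'
#' @param moduli Vector of resultant moduli in `[0, 1]`.
#' @param n_bins Number of bins.
#' @param label Cell-class label.
#' @return An object of class `rhistogram` with fields `edges`
#'   (`n_bins + 1` boundaries), `counts`, and `label`.
#' @export
rhistogram <- function(moduli, n_bins = 10L, label = "") {
  if (any(moduli < 0 | moduli > 1))
    stop("resultant moduli must lie in [0, 1]", call. = FALSE)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- findInterval(moduli, edges, rightmost.closed = TRUE)
  structure(list(edges = edges,
                 counts = tabulate(idx, nbins = n_bins), label = label),
            class = "rhistogram")
}

#' @export
print.rhistogram <- function(x, ...) {
  cat(sprintf("rhistogram '%s': %d cells in %d bins on [0, 1]\n",
              x$label, sum(x$counts), length(x$counts)))
  print(stats::setNames(x$counts,
                        sprintf("[%.1f,%.1f)", utils::head(x$edges, -1),
                                utils::tail(x$edges, -1))))
  invisible(x)
}

#' Simulate resultant histograms over a population
#'
#' For each included cell class, draws kappa values according to the
#' population specification, evaluates the resultant modulus of the
#' class's model tuning curve at each kappa (closed forms for simple-cell
#' orders, quadrature for complex cells), and accumulates an equal-width
#' histogram of |R| on `[0, 1]`.
#'
#' @param spec A [population_spec()].
#' @return Named list of [rhistogram()] objects, one per class
#'   (`"simple1"` .. `"simple4"`, `"complex"`).
#' @export
simulate_histograms <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  kappas <- sample_kappa(spec)
  out <- list()
  for (m in spec$orders) {
    lab <- paste0("simple", m)
    out[[lab]] <- rhistogram(resultant_closed_form("simple", kappas, order = m),
                             spec$n_bins, lab)
  }
  if (spec$include_complex)
    out[["complex"]] <- rhistogram(resultant_closed_form("complex", kappas),
                                   spec$n_bins, "complex")
  out
}

#' Combine simple-cell histograms across derivative orders
#'
#' Sums the per-order histograms of simple cells up to `max_order` with
#' equal weight (the same number of neurons per order), as when modelling
#' a recorded population that mixes derivative orders.
#'
#' @param hists Named list of histograms as returned by
#'   [simulate_histograms()], or a [population_spec()] (in which case the
#'   histograms are simulated first).
#' @param max_order Combine orders `1..max_order` (2 or 4).
#' @return An [rhistogram()] labelled `"simple_upto<max_order>"`.
#' @export
combine_orders <- function(hists, max_order = 4L) {
  if (inherits(hists, "population_spec")) hists <- simulate_histograms(hists)
  if (!max_order %in% c(2L, 4L))
    stop("'max_order' must be 2 or 4", call. = FALSE)
  labs <- paste0("simple", seq_len(max_order))
  if (!all(labs %in% names(hists)))
    stop("histograms for orders 1..", max_order, " are required", call. = FALSE)
  parts <- hists[labs]
  edges <- parts[[1]]$edges
  ns <- vapply(parts, function(h) sum(h$counts), numeric(1))
  if (length(unique(ns)) != 1L)
    stop("combining requires equal cell counts per order", call. = FALSE)
  for (h in parts)
    if (!isTRUE(all.equal(h$edges, edges)))
      stop("histograms have incompatible bin edges", call. = FALSE)
  counts <- Reduce(`+`, lapply(parts, `[[`, "counts"))
  structure(list(edges = edges, counts = counts,
                 label = paste0("simple_upto", max_order)),
            class = "rhistogram")
}
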