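# Boost parameterization and Maclaurin-series energetic reweighting of
# boosted (accelerated-sampling) ensembles.

#' Boost parameters from a conventional-run dihedral-energy average
#'
#' The threshold energy and acceleration factor of the dihedral boost are
#' set from the conventional simulation:
#' `E = V_dihedral_mean + 3.5 * N_residues` and
#' `alpha = (3.5 / 5) * N_residues`, both in kcal mol^-1.  Exact arithmetic;
#' no tolerance involved.
#'
#' @param V_dihedral_mean average dihedral energy of the conventional run
#'   (kcal mol^-1)
#' @param N_residues number of protein residues
#' @return list with `E`, `alpha`, and the inputs
#' @export
amd_parameters <- function(V_dihedral_mean, N_residues) {
  if (N_residues < 0) stop("amd_parameters: N_residues must be >= 0")
  list(E = V_dihedral_mean + 3.5 * N_residues,
       alpha = (3.5 / 5) * N_residues,
       V_dihedral_mean = V_dihedral_mean,
       N_residues = N_residues)
}

#' Assemble a reweighting input
#'
#' @param coordinates per-sample PC values: a numeric vector (1D) or a
#'   2-column matrix (2D)
#' @param deltaV per-sample boost energies (kcal mol^-1, all >= 0)
#' @param temperature_K temperature (K); sets beta = 1/(kB T)
#' @param bin_size histogram bin width in PC units (default 5)
#' @param order_K Maclaurin truncation order (default 10)
#' @return a `reweight_input`
#' @export
reweight_input <- function(coordinates, deltaV, temperature_K = 310,
                           bin_size = 5, order_K = 10L) {
  if (is.null(dim(coordinates))) coordinates <- cbind(coordinates)
  coordinates <- as.matrix(coordinates)
  stopifnot(ncol(coordinates) %in% 1:2,
            nrow(coordinates) == length(deltaV),
            bin_size > 0, temperature_K > 0)
  if (order_K < 0) stop("reweight_input: Maclaurin order K must be >= 0")
  if (any(deltaV < 0)) stop("reweight_input: deltaV must be >= 0")
  structure(list(coordinates = coordinates, deltaV = as.numeric(deltaV),
                 beta = beta_from_temperature(temperature_K),
                 temperature_K = temperature_K,
                 bin_size = bin_size, order_K = as.integer(order_K)),
            class = "reweight_input")
}

#' Maclaurin-series approximation of the per-bin exponential boost average
#'
#' `sum_{k=0}^{K} beta^k <deltaV^k> / k!`, the truncated series for
#' `<exp(beta deltaV)>`.  Monotone non-decreasing in K for deltaV >= 0.
#'
#' @param deltaV boost energies of the samples in one bin
#' @param beta inverse temperature (mol kcal^-1)
#' @param order_K truncation order
#' @return scalar factor >= 1
#' @export
maclaurin_factor <- function(deltaV, beta, order_K) {
  acc <- 1
  term <- rep(1, length(deltaV))
  for (k in seq_len(order_K)) {
    term <- term * (beta * deltaV) / k
    acc <- acc + mean(term)
  }
  acc
}

#' Reweight a boosted ensemble into a free-energy profile or surface
#'
#' Bins the PC samples (bins anchored at 0), estimates the per-bin
#' reweighting factor `<exp(beta deltaV)>` by its Maclaurin series truncated
#' at order K, multiplies the biased bin probabilities by the factors, and
#' converts to a potential of mean force `-(1/beta) ln p*`, shifted so the
#' minimum is 0.  Bins with fewer than `low_confidence_n` samples are
#' flagged in the result (`low_confidence`); unobserved bins are `NA`.
#'
#' @param input a [reweight_input()]
#' @param min_points minimum total sample count (default 100)
#' @param low_confidence_n per-bin count below which a bin is flagged
#' @return an `fes` with extra fields `counts`, `factor`, `low_confidence`,
#'   `order_K`
#' @export
reweight_pmf <- function(input, min_points = 100L, low_confidence_n = 10L) {
  stopifnot(inherits(input, "reweight_input"))
  X <- input$coordinates
  n <- nrow(X)
  if (n < min_points) stop("reweight_pmf: need at least ", min_points, " samples")
  bs <- input$bin_size
  beta <- input$beta
  i1 <- floor(X[, 1] / bs)
  two_d <- ncol(X) == 2L
  if (two_d) {
    i2 <- floor(X[, 2] / bs)
    r1 <- seq(min(i1), max(i1)); r2 <- seq(min(i2), max(i2))
    key <- (i1 - min(i1)) * length(r2) + (i2 - min(i2)) + 1L
    nkey <- length(r1) * length(r2)
  } else {
    r1 <- seq(min(i1), max(i1))
    key <- i1 - min(i1) + 1L
    nkey <- length(r1)
  }
  counts <- tabulate(key, nbins = nkey)
  if (sum(counts > 0) < 2L) {
    stop("reweight_pmf: all samples fall in one bin (no landscape)")
  }
  # per-bin truncated exponential average, accumulated term by term
  factor <- rep(1, nkey)
  term <- rep(1, n)
  for (k in seq_len(input$order_K)) {
    term <- term * (beta * input$deltaV) / k
    sums <- rep(0, nkey)
    agg <- rowsum(term, key)
    sums[as.integer(rownames(agg))] <- agg[, 1]
    factor <- factor + ifelse(counts > 0, sums / pmax(counts, 1L), 0)
  }
  p_star <- (counts / n) * factor
  pmf <- ifelse(counts > 0, -(1 / beta) * log(p_star / max(p_star)), NA_real_)
  pmf <- pmf - min(pmf, na.rm = TRUE)
  centers <- function(ix) (ix + 0.5) * bs
  if (two_d) {
    shape <- function(v) matrix(v, length(r1), length(r2), byrow = TRUE)
    out <- list(axis1 = centers(r1), axis2 = centers(r2),
                pmf = shape(pmf), counts = shape(counts),
                factor = shape(factor),
                low_confidence = shape(counts < low_confidence_n & counts > 0),
                temperature_K = input$temperature_K, bin_size = bs,
                order_K = input$order_K)
  } else {
    out <- list(axis1 = centers(r1), axis2 = NULL, pmf = pmf, counts = counts,
                factor = factor,
                low_confidence = counts < low_confidence_n & counts > 0,
                temperature_K = input$temperature_K, bin_size = bs,
                order_K = input$order_K)
  }
  class(out) <- "fes"
  out
}

#' Pool several reweighting inputs into one
#'
#' Samples are concatenated; all runs must share the same temperature, bin
#' size, truncation order, and dimensionality, and their projections must
#' already be expressed in a shared PC basis (project all runs onto one
#' reference run's components with [project_onto()] before pooling).
#'
#' @param inputs list of [reweight_input()] objects
#' @return a single `reweight_input`
#' @export
combine_runs <- function(inputs) {
  inputs <- inputs[vapply(inputs, function(x) nrow(x$coordinates) > 0, logical(1))]
  if (!length(inputs)) stop("combine_runs: no non-empty inputs")
  ref <- inputs[[1]]
  for (x in inputs[-1]) {
    if (!isTRUE(all.equal(x$beta, ref$beta)) || x$bin_size != ref$bin_size ||
        x$order_K != ref$order_K || ncol(x$coordinates) != ncol(ref$coordinates)) {
      stop("combine_runs: inputs disagree on beta, bin_size, order_K, or dimensionality")
    }
  }
  reweight_input(do.call(rbind, lapply(inputs, `[[`, "coordinates")),
                 unlist(lapply(inputs, `[[`, "deltaV")),
                 temperature_K = ref$temperature_K,
                 bin_size = ref$bin_size, order_K = ref$order_K)
}
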