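#' Predicted occurrence frequency under the Sloan neutral community model
#'
#' Under neutral assembly of local communities of size `N` by drift and
#' immigration (probability `m` per death-birth replacement) from a source
#' metacommunity where a taxon has relative abundance `p`, the taxon's local
#' relative abundance follows a beta distribution with shape parameters
#' `N*m*p` and `N*m*(1-p)`. The probability of detecting the taxon in a host
#' at detection limit `d` reads is therefore
#' `1 - I(d/N; N*m*p, N*m*(1-p))`, with `I` the regularised incomplete beta
#' function.
#'
#' @param p metacommunity relative abundance(s), in (0, 1); vectorised
#' @param N local community size (reads per host after rarefaction)
#' @param m immigration probability per replacement, in (0, 1]
#' @param d detection limit in reads (default 1); must satisfy `0 < d < N`
#' @return predicted detection frequency in `[0, 1]`, same length as `p`;
#'   non-decreasing in `p` for fixed `(N, m, d)`
#' @examples
#' predicted_occurrence(0.5, N = 20, m = 0.1, d = 2)
#' @export
predicted_occurrence <- function(p, N, m, d = 1) {
  stopifnot(is.numeric(p), is.numeric(N), is.numeric(m), is.numeric(d),
            length(N) == 1L, length(m) == 1L, length(d) == 1L)
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly between 0 and 1")
  if (N <= 0) stop("N must be positive")
  if (m <= 0 || m > 1) stop("m must lie in (0, 1]")
  if (d <= 0 || d >= N) stop("d must satisfy 0 < d < N")
  stats::pbeta(d / N, N * m * p, N * m * (1 - p), lower.tail = FALSE)
}

#' Wilson score confidence band around a predicted frequency
#'
#' The binomial Wilson score interval evaluated algebraically at (possibly
#' non-integer) successes `x = freq_pred * n_hosts` and `n_hosts` trials;
#' the standard choice for the 95% band drawn around the fitted neutral
#' occurrence curve.
#'
#' @param freq_pred predicted frequency (vectorised), in `[0, 1]`
#' @param n_hosts number of host samples (trials)
#' @param alpha two-sided significance level (default 0.05)
#' @return list with numeric vectors `lower` and `upper`,
#'   `0 <= lower <= upper <= 1`; the interval always contains `freq_pred`
#' @export
confidence_band <- function(freq_pred, n_hosts, alpha = 0.05) {
  stopifnot(all(freq_pred >= 0 & freq_pred <= 1), n_hosts >= 1,
            alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  n <- n_hosts
  x <- freq_pred * n
  centre <- (x + z^2 / 2) / (n + z^2)
  half <- z * sqrt(x * (n - x) / n + z^2 / 4) / (n + z^2)
  list(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Fit the Sloan neutral community model to an OTU table
#'
#' Estimates the immigration parameter `m` by bounded one-dimensional least
#' squares on the occurrence-frequency curve: for each OTU the observed
#' detection frequency across hosts (`freq_obs`, counts `>= d`) is compared
#' with [predicted_occurrence()] at the OTU's mean relative abundance `p`,
#' and `m` minimises the sum of squared residuals over `(1e-6, 1]`. Fit
#' quality is the generalised R-squared `1 - SSR/SST` (may be negative;
#' never clamped). Each fitted OTU receives a 95% Wilson band
#' ([confidence_band()]) and a partition label via [classify_partitions()].
#'
#' The table should be rarefied first so that sample depths are equal;
#' `N` is taken as the mean sample total.
#'
#' @param table an [otu_table], typically rarefied
#' @param samples optional character vector restricting the fit to a sample
#'   subset (e.g. one population); at least 5 samples
#' @param d detection limit in reads (default 1)
#' @param m_start starting value for the optimiser (default 0.1)
#' @param alpha significance level of the partition band (default 0.05)
#' @return an object of class `neutral_fit`: list with `m`, `N`, `Nm`, `d`,
#'   `r_squared`, `ssr`, `n_hosts`, `n_otus_fit`, `alpha`, and `per_otu`, a
#'   data.frame with columns `otu_id`, `p`, `freq_obs`, `freq_pred`,
#'   `ci_lower`, `ci_upper`, `partition`
#' @export
fit_neutral <- function(table, samples = NULL, d = 1, m_start = 0.1,
                        alpha = 0.05) {
  stopifnot(inherits(table, "otu_table"))
  if (!is.null(samples)) table <- table[samples, ]
  if (n_samples(table) < 5L)
    stop("need at least 5 samples to fit the neutral model, got ",
         n_samples(table))
  totals <- sample_totals(table)
  if (max(totals) > 1.05 * min(totals))
    warning("sample depths differ by more than 5%; rarefy before fitting")
  N <- mean(totals)
  n_hosts <- n_samples(table)

  p <- colMeans(relative_abundance(table))
  freq_obs <- colMeans(table$counts >= d)
  keep <- freq_obs > 0 & p > 0 & p < 1
  if (sum(keep) < 10L)
    stop("need at least 10 detected OTUs to fit the neutral model, got ",
         sum(keep))
  p <- p[keep]
  freq_obs <- freq_obs[keep]
  ids <- otu_ids(table)[keep]

  fit <- fit_neutral_curve(p, freq_obs, N = N, d = d, m_start = m_start)

  freq_pred <- predicted_occurrence(p, N, fit$m, d)
  band <- confidence_band(freq_pred, n_hosts, alpha)
  per_otu <- data.frame(otu_id = ids, p = unname(p),
                        freq_obs = unname(freq_obs),
                        freq_pred = unname(freq_pred),
                        ci_lower = unname(band$lower),
                        ci_upper = unname(band$upper),
                        partition = NA_character_,
                        stringsAsFactors = FALSE)
  out <- structure(list(m = fit$m, N = N, Nm = N * fit$m, d = d,
                        m_start = m_start, r_squared = fit$r_squared,
                        ssr = fit$ssr, sst = fit$sst, n_hosts = n_hosts,
                        n_otus_fit = length(ids), alpha = alpha,
                        per_otu = per_otu),
                   class = "neutral_fit")
  classify_partitions(out)
}

#' Least-squares estimate of m from occurrence-frequency data
#'
#' The numerical core of [fit_neutral()], usable directly on per-OTU
#' `(p, freq_obs)` pairs (e.g. model-generated data): minimises
#' `sum((freq_obs - predicted_occurrence(p, N, m, d))^2)` over
#' `m` in `(1e-6, 1]` by golden-section/parabolic search refined from
#' `m_start` with a quasi-Newton polish; the better of the two iterates is
#' kept (objective tolerance below 1e-8).
#'
#' @param p vector of mean relative abundances in (0, 1)
#' @param freq_obs observed detection frequencies in (0, 1], same length
#' @param N community size (reads per host)
#' @param d detection limit in reads
#' @param m_start starting value in (0, 1]
#' @return list with `m`, `ssr`, `sst` and `r_squared` (`NA` and a warning
#'   when all `freq_obs` are equal, which leaves `SST = 0`)
#' @export
fit_neutral_curve <- function(p, freq_obs, N, d = 1, m_start = 0.1) {
  stopifnot(length(p) == length(freq_obs), length(p) >= 2L,
            all(p > 0 & p < 1), all(freq_obs >= 0 & freq_obs <= 1),
            m_start > 0, m_start <= 1)
  ssr_fun <- function(m) sum((freq_obs - predicted_occurrence(p, N, m, d))^2)
  opt1 <- stats::optimize(ssr_fun, interval = c(1e-6, 1), tol = 1e-10)
  opt2 <- stats::nlminb(start = m_start, objective = ssr_fun,
                        lower = 1e-6, upper = 1,
                        control = list(abs.tol = 1e-12, rel.tol = 1e-10))
  if (opt2$convergence != 0 && opt2$objective < opt1$objective)
    warning("optimizer reported non-convergence at m = ", opt2$par)
  m_hat <- if (opt2$objective < opt1$objective) opt2$par else opt1$minimum
  ssr <- ssr_fun(m_hat)
  sst <- sum((freq_obs - mean(freq_obs))^2)
  r2 <- if (sst == 0) {
    warning("all observed frequencies are equal; r_squared undefined")
    NA_real_
  } else 1 - ssr / sst
  list(m = m_hat, ssr = ssr, sst = sst, r_squared = r2)
}

#' Partition OTUs against the neutral confidence band
#'
#' Labels each fitted OTU `above` when its observed occurrence frequency
#' exceeds the upper 95% bound at its abundance, `below` when it falls under
#' the lower bound, and `within` otherwise. Ties (frequency exactly on a
#' bound) classify as `within` — conservative toward neutrality. OTUs above
#' the band are candidates for host selection, OTUs below for host
#' elimination.
#'
#' Because the observed frequency moves on the grid of multiples of
#' `1/n_hosts` while the band is continuous, the comparison applies a
#' half-count continuity correction: an OTU leaves the within class only
#' when its observed host count exceeds the bound by more than half a host.
#' Without this, the Wilson bound — which shrinks toward 1/2 — sits a hair
#' inside 0 and 1, and every saturated OTU (detected in all hosts with
#' predicted occupancy also ~1) would be spuriously labelled `above`, and
#' every rare undetected OTU `below`.
#'
#' @param fit a `neutral_fit` from [fit_neutral()]
#' @return the fit with `per_otu$partition` filled in and a `partition_summary`
#'   element: named fractions `above`, `within`, `below` (summing to 1)
#' @export
classify_partitions <- function(fit) {
  stopifnot(inherits(fit, "neutral_fit"))
  po <- fit$per_otu
  cc <- 1 / (2 * fit$n_hosts)
  part <- ifelse(po$freq_obs > po$ci_upper + cc, "above",
                 ifelse(po$freq_obs < po$ci_lower - cc, "below", "within"))
  fit$per_otu$partition <- part
  fit$partition_summary <- c(above = mean(part == "above"),
                             within = mean(part == "within"),
                             below = mean(part == "below"))
  fit
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  m = %.5f  (Nm = %.1f, N = %.1f, d = %g)\n",
              x$m, x$Nm, x$N, x$d))
  cat(sprintf("  generalized R-squared = %.4f over %d OTUs, %d hosts\n",
              x$r_squared, x$n_otus_fit, x$n_hosts))
  if (!is.null(x$partition_summary))
    cat(sprintf("  partitions: above %.1f%% | within %.1f%% | below %.1f%%\n",
                100 * x$partition_summary[["above"]],
                100 * x$partition_summary[["within"]],
                100 * x$partition_summary[["below"]]))
  invisible(x)
}

#' Fitted occurrence curve on an abundance grid
#'
#' Convenience table for plotting the fit: a log-spaced grid of abundances
#' with the model prediction and its confidence band.
#'
#' @param fit a `neutral_fit`
#' @param n grid size (default 200)
#' @return data.frame with columns `p`, `freq_pred`, `ci_lower`, `ci_upper`
#' @export
neutral_curve <- function(fit, n = 200) {
  stopifnot(inherits(fit, "neutral_fit"))
  p <- exp(seq(log(min(fit$per_otu$p)), log(max(fit$per_otu$p)),
               length.out = n))
  freq_pred <- predicted_occurrence(p, fit$N, fit$m, fit$d)
  band <- confidence_band(freq_pred, fit$n_hosts, fit$alpha)
  data.frame(p = p, freq_pred = freq_pred,
             ci_lower = band$lower, ci_upper = band$upper)
}

#' Cross-population partition summary
#'
#' Tallies, for every OTU appearing in any population's fit, the number of
#' populations in which it is classified above, below or within the neutral
#' band, and in how many it is absent (not part of that population's fit,
#' e.g. never detected there). Also reports the histogram of OTUs by
#' above-count and the number of OTUs that are exclusively within (never
#' above or below in any population where present).
#'
#' @param fits named list of `neutral_fit` objects, one per population
#'   (at least 2)
#' @return list with `per_otu` (data.frame `otu_id`, `n_above`, `n_below`,
#'   `n_within`, `n_absent`), `above_histogram` (named integer vector:
#'   number of OTUs above in exactly 0, 1, ... populations) and
#'   `n_exclusively_within`
#' @export
cross_population_summary <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1L), "neutral_fit")))
  if (is.null(names(fits)))
    names(fits) <- paste0("population_", seq_along(fits))
  all_ids <- sort(unique(unlist(lapply(fits,
                                       function(f) f$per_otu$otu_id))))
  n_pop <- length(fits)
  tally <- matrix(0L, nrow = length(all_ids), ncol = 3L,
                  dimnames = list(all_ids, c("above", "below", "within")))
  present <- matrix(FALSE, nrow = length(all_ids), ncol = n_pop,
                    dimnames = list(all_ids, names(fits)))
  for (k in seq_along(fits)) {
    po <- fits[[k]]$per_otu
    present[po$otu_id, k] <- TRUE
    for (lab in c("above", "below", "within")) {
      ids <- po$otu_id[po$partition == lab]
      tally[ids, lab] <- tally[ids, lab] + 1L
    }
  }
  per_otu <- data.frame(otu_id = all_ids,
                        n_above = tally[, "above"],
                        n_below = tally[, "below"],
                        n_within = tally[, "within"],
                        n_absent = as.integer(n_pop - rowSums(present)),
                        row.names = NULL, stringsAsFactors = FALSE)
  hist <- vapply(0:n_pop, function(k) sum(per_otu$n_above == k), integer(1L))
  names(hist) <- as.character(0:n_pop)
  excl_within <- sum(per_otu$n_above == 0L & per_otu$n_below == 0L &
                     per_otu$n_within > 0L)
  list(per_otu = per_otu, above_histogram = hist,
       n_exclusively_within = excl_within)
}

#' Write a neutral fit to disk
#'
#' Emits the per-OTU table as TSV (`otu_id`, `p`, `freq_obs`, `freq_pred`,
#' `ci_lower`, `ci_upper`, `partition`) and, optionally, a JSON summary of
#' the fitted parameters.
#'
#' @param fit a `neutral_fit`
#' @param path destination TSV path
#' @param json_path optional destination for the JSON parameter summary
#' @return `path`, invisibly
#' @export
write_neutral_fit <- function(fit, path, json_path = NULL) {
  stopifnot(inherits(fit, "neutral_fit"))
  utils::write.table(fit$per_otu, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    summ <- list(m = fit$m, Nm = fit$Nm, N = fit$N, d = fit$d,
                 r_squared = fit$r_squared, n_hosts = fit$n_hosts,
                 n_otus_fit = fit$n_otus_fit,
                 partition_fractions = as.list(fit$partition_summary))
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
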