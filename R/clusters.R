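# Seizure clusters: inter-seizure-interval histogram, lead-time rules,
# lead-seizure-aligned biomarker profiles.

#' Inter-seizure-interval histogram
#'
#' Histogram of consecutive onset differences with 1-h bins, half-open
#' `[k, k+1)` hours.
#'
#' @param catalog Seizure catalog (`onset_h`, >= 2 seizures).
#' @return List of class `isi_histogram`: `counts`, `breaks_h`,
#'   `intervals_h`.
#' @export
isi_histogram <- function(catalog) {
  if (nrow(catalog) < 2) stop("need at least 2 seizures for ISI histogram")
  isi <- diff(sort(catalog$onset_h))
  nb <- ceiling(max(isi)) + 1
  counts <- tabulate(floor(isi) + 1L, nbins = nb)
  structure(list(counts = counts, breaks_h = 0:nb, intervals_h = isi),
            class = "isi_histogram")
}

#' Does the catalog contain seizure clusters?
#'
#' TRUE iff at least five inter-seizure intervals shorter than one day
#' exist; patients below that are not considered to have clusters.
#'
#' @param catalog Seizure catalog.
#' @return Logical.
#' @export
classify_clustering <- function(catalog) {
  if (nrow(catalog) < 2) return(FALSE)
  sum(diff(sort(catalog$onset_h)) < 24) >= 5
}

#' Lead time from the ISI histogram shape
#'
#' After 3-bin moving-average smoothing: an exponential-decay-shaped
#' histogram (first bin maximal, no later peak) gives a lead time of 1 day;
#' a multi-peak histogram gives the time of the first trough between the
#' first two peaks. Ambiguous shapes (a single isolated peak, or too few
#' counts) fall back to 1 day with a warning.
#'
#' @param histogram An `isi_histogram`.
#' @param smooth_bins Smoothing window in bins (default 3).
#' @return Lead time in days, with attribute `shape` in
#'   `c("decay", "multipeak", "ambiguous")`.
#' @export
lead_time <- function(histogram, smooth_bins = 3) {
  h <- histogram$counts
  n <- length(h)
  s <- as.numeric(stats::filter(h, rep(1 / smooth_bins, smooth_bins),
                                sides = 2))
  s[is.na(s)] <- h[is.na(s)]
  # local maxima of the smoothed histogram; small noise bumps (< 25% of the
  # modal bin) do not count as peaks
  ispeak <- s >= 0.25 * max(s) & s > 0 &
    s >= c(-Inf, s[-n]) & s > c(s[-1], -Inf)
  peaks <- which(ispeak)
  # a later peak only counts as a separate mode if a genuine trough
  # separates it from the first peak (sampling noise on an exponential
  # decay produces shallow local maxima that must not trigger the
  # multipeak rule)
  if (length(peaks) >= 2) {
    a <- peaks[1]
    for (b in peaks[-1]) {
      trough <- a + which.min(s[a:b]) - 1L
      if (s[trough] < 0.6 * min(s[a], s[b]))
        return(structure((trough - 0.5) / 24, shape = "multipeak"))
    }
  }
  first_is_max <- length(s) > 0 && which.max(s) == 1L
  if (first_is_max || (length(peaks) >= 1 && peaks[1] <= 3L)) {
    return(structure(1, shape = "decay"))
  }
  warning("ambiguous ISI histogram shape; defaulting lead time to 1 day")
  structure(1, shape = "ambiguous")
}

#' Lead/follower partition of a seizure catalog
#'
#' A lead seizure has no prior seizure within `lead_time_d` days of its
#' onset; every other seizure is a follower of the most recent lead.
#'
#' @param catalog Seizure catalog.
#' @param lead_time_d Lead time in days.
#' @return Logical vector: TRUE for lead seizures (exhaustive, exclusive
#'   partition with its complement).
#' @export
lead_seizures <- function(catalog, lead_time_d) {
  onsets <- sort(catalog$onset_h)
  lead <- logical(length(onsets))
  if (length(onsets) == 0) return(lead)
  lead[1] <- TRUE
  for (i in seq_along(onsets)[-1])
    lead[i] <- (onsets[i] - onsets[i - 1]) >= lead_time_d * 24
  lead
}

#' Lead-seizure-aligned biomarker profiles
#'
#' Extracts ACFW and variance on the given channel over `[0, span_d]` days
#' after each lead seizure, averages across lead seizures (mean +/- SE,
#' missing samples ignored), and computes the follower density: a 2-h
#' moving sum of follow-on (non-lead) onsets relative to the lead time 0.
#'
#' @param features A `feature_series`.
#' @param catalog Seizure catalog.
#' @param lead_time_d Lead time in days.
#' @param channel Channel index (use the highest-SI channel).
#' @param span_d Profile span in days (default 4).
#' @return List of class `cluster_analysis`: `isi`, `has_clusters`,
#'   `lead_time_d`, `lead_mask`, `rel_time_h`, `mean_acfw`, `se_acfw`,
#'   `mean_var`, `se_var`, `follower_density`, `n_lead`.
#' @export
aligned_profiles <- function(features, catalog, lead_time_d, channel = 1,
                             span_d = 4) {
  lead <- lead_seizures(catalog, lead_time_d)
  if (!any(lead)) stop("zero lead seizures")
  onsets <- sort(catalog$onset_h)
  cad_h <- features$cadence_min / 60
  n_prof <- floor(span_d * 24 / cad_h)
  rel_h <- (seq_len(n_prof) - 1) * cad_h
  A <- V <- matrix(NA_real_, n_prof, sum(lead))
  leads <- onsets[lead]
  for (i in seq_along(leads)) {
    j0 <- findInterval(leads[i], features$times_h)
    idx <- j0 + seq_len(n_prof) - 1L
    ok <- idx <= length(features$times_h)
    A[ok, i] <- features$acfw[idx[ok], channel]
    V[ok, i] <- features$variance[idx[ok], channel]
  }
  msd <- function(M) {
    m <- rowMeans(M, na.rm = TRUE)
    nn <- rowSums(!is.na(M))
    se <- apply(M, 1, stats::sd, na.rm = TRUE) / sqrt(pmax(nn, 1))
    list(mean = m, se = se)
  }
  a <- msd(A); v <- msd(V)
  followers <- onsets[!lead]
  rel_follow <- unlist(lapply(leads, function(t0) {
    d <- followers - t0
    d[d > 0 & d <= span_d * 24]
  }))
  dens <- vapply(rel_h, function(t0)
    sum(rel_follow >= t0 - 1 & rel_follow < t0 + 1), numeric(1))
  structure(list(isi = if (nrow(catalog) >= 2) isi_histogram(catalog) else NULL,
                 has_clusters = classify_clustering(catalog),
                 lead_time_d = lead_time_d, lead_mask = lead,
                 rel_time_h = rel_h,
                 mean_acfw = a$mean, se_acfw = a$se,
                 mean_var = v$mean, se_var = v$se,
                 follower_density = dens, n_lead = sum(lead)),
            class = "cluster_analysis")
}

#' Full cluster analysis of a recording
#'
#' Applies the ISI rules (clustering classification, lead-time selection)
#' and computes aligned profiles on the requested channel.
#'
#' @param features A `feature_series`.
#' @param catalog Seizure catalog.
#' @param channel Channel (best-SI channel recommended).
#' @param span_d Profile span (days).
#' @return A `cluster_analysis`, or a list with `has_clusters = FALSE` when
#'   the clustering rule fails.
#' @export
cluster_analysis <- function(features, catalog, channel = 1, span_d = 4) {
  if (!classify_clustering(catalog))
    return(structure(list(has_clusters = FALSE,
                          isi = if (nrow(catalog) >= 2) isi_histogram(catalog) else NULL),
                     class = "cluster_analysis"))
  hist <- isi_histogram(catalog)
  lt <- lead_time(hist)
  out <- aligned_profiles(features, catalog, as.numeric(lt), channel, span_d)
  out$lead_time_shape <- attr(lt, "shape")
  out
}
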