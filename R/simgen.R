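# Synthetic centroided HCD spectra with ground truth.
#
# The generator emulates the product-ion region of an intact-protein HCD
# spectrum: several co-eluting b/y-ion envelopes at charge states 1-15+,
# whose isotopic peaks collide and merge whenever they fall within the
# stated ppm tolerance (creating true overlapping isotopic peaks),
# multiplicative log-normal abundance noise, uniform m/z jitter and
# uniform-random chemical-noise peaks. Collisions arise from the ions'
# honest theoretical envelopes -- m/z values are never edited to force an
# overlap.

#' Simulate a centroid spectrum from known ions
#'
#' @param pf A `proteoform` supplying the fragment compositions.
#' @param ion_labels Character vector of product-ion labels (see
#'   [ion_label()]), e.g. `c("y10-1+", "y20-2+", "y72-7+")`.
#' @param abundances Base-peak absolute abundance per ion (> 0, recycled).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal abundance noise (0 = noiseless).
#' @param ppm_jitter Half-width of the uniform m/z jitter in ppm.
#' @param n_noise_peaks Number of uniform-random chemical-noise peaks.
#' @param seed Integer seed; the same seed reproduces the spectrum exactly.
#' @param ipaco Envelope truncation cutoff in percent.
#' @param merge_ppm Peaks from different ions closer than this tolerance
#'   are merged into one observed peak by abundance summation.
#' @param scan_id Identifier given to the spectrum.
#' @return A list with `spectrum` (a `centroid_spectrum`) and `truth`: a
#'   list with `peaks` (data.frame: `ion`, `theo_peak`, `theo_mz`,
#'   `true_abundance`, `exp_index` into the spectrum), `overlaps`
#'   (data.frame of merged peaks claimed by >= 2 ions: `exp_index`,
#'   `n_ions`, `ions`), and the generation parameters.
#' @export
simulate_spectrum <- function(pf, ion_labels, abundances,
                              noise_cv = 0.05, ppm_jitter = 5,
                              n_noise_peaks = 0, seed = 1L,
                              ipaco = 20, merge_ppm = 15,
                              scan_id = "synthetic") {
  stopifnot(length(ion_labels) >= 1, all(abundances > 0), noise_cv >= 0)
  abundances <- rep_len(abundances, length(ion_labels))
  old_seed <- .save_seed()
  on.exit(.restore_seed(old_seed))
  set.seed(seed)
  peaks <- do.call(rbind, lapply(seq_along(ion_labels), function(i) {
    spec <- parse_ion_label(ion_labels[i])
    comp <- fragment_composition(pf, spec$series, spec$index, spec$nl)
    env <- aggregate_envelope(comp, charge = spec$charge, ipaco = ipaco)
    data.frame(ion = ion_labels[i], theo_peak = seq_along(env$mz),
               theo_mz = env$mz,
               true_abundance = abundances[i] * env$rel / 100,
               stringsAsFactors = FALSE)
  }))
  peaks <- peaks[order(peaks$theo_mz), , drop = FALSE]
  # greedy clustering: a peak joins the open cluster if it is within
  # merge_ppm of the cluster's running abundance-weighted centroid
  cluster <- integer(nrow(peaks))
  cid <- 0L
  centroid <- -Inf; weight <- 0
  for (i in seq_len(nrow(peaks))) {
    if (cid == 0L ||
        abs(ipmd(centroid, peaks$theo_mz[i])) > merge_ppm) {
      cid <- cid + 1L
      centroid <- peaks$theo_mz[i]
      weight <- peaks$true_abundance[i]
    } else {
      w <- peaks$true_abundance[i]
      centroid <- (centroid * weight + peaks$theo_mz[i] * w) / (weight + w)
      weight <- weight + w
    }
    cluster[i] <- cid
  }
  fcluster <- factor(cluster, levels = seq_len(cid))
  obs_ab <- as.numeric(tapply(peaks$true_abundance, fcluster, sum))
  obs_mz <- as.numeric(tapply(peaks$true_abundance * peaks$theo_mz,
                              fcluster, sum)) / obs_ab
  # noise
  if (noise_cv > 0) {
    s <- sqrt(log(1 + noise_cv^2))
    obs_ab <- obs_ab * stats::rlnorm(length(obs_ab),
                                     meanlog = -s^2 / 2, sdlog = s)
  }
  if (ppm_jitter > 0)
    obs_mz <- obs_mz * (1 + stats::runif(length(obs_mz),
                                         -ppm_jitter, ppm_jitter) * 1e-6)
  mz_all <- obs_mz; ab_all <- obs_ab
  if (n_noise_peaks > 0) {
    lo <- min(obs_mz) - 2; hi <- max(obs_mz) + 2
    mz_all <- c(mz_all, stats::runif(n_noise_peaks, lo, hi))
    ab_all <- c(ab_all, stats::runif(n_noise_peaks, 0,
                                     0.05 * max(obs_ab)))
  }
  keep <- ab_all > 0
  mz_all <- mz_all[keep]; ab_all <- ab_all[keep]
  spec <- centroid_spectrum(mz_all, ab_all, scan_id = scan_id)
  # map clusters to final spectrum indices
  cl_idx <- match(obs_mz, spec$mz)
  peaks$exp_index <- cl_idx[cluster]
  ov <- tapply(peaks$ion, fcluster, function(x) unique(x))
  multi <- which(lengths(ov) >= 2)
  overlaps <- data.frame(
    exp_index = cl_idx[multi],
    n_ions = lengths(ov)[multi],
    ions = vapply(ov[multi], paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  rownames(overlaps) <- NULL
  list(spectrum = spec,
       truth = list(peaks = peaks, overlaps = overlaps,
                    noise_cv = noise_cv, ppm_jitter = ppm_jitter,
                    n_noise_peaks = n_noise_peaks, seed = seed,
                    ipaco = ipaco, merge_ppm = merge_ppm))
}

#' Write simulation ground truth as TSV
#'
#' @param truth The `truth` component of [simulate_spectrum()]'s result.
#' @param path Output TSV (per-peak table; overlap groups are flagged via
#'   `exp_index` multiplicity).
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  df <- truth$peaks
  df$theo_mz <- sprintf("%.6f", df$theo_mz)
  df$true_abundance <- sprintf("%.6f", df$true_abundance)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
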