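# Isotopic m/z and envelope fingerprinting: aligning theoretical envelopes
# to experimental centroid peaks under IPACO/IPMD/IPAD tolerances.

#' Search tolerance parameters
#'
#' The three tolerances of envelope fingerprinting: IPACO (isotopic peak
#' abundance cutoff, percent), IPMD (isotopic peak m/z deviation, ppm) and
#' IPAD (isotopic peak abundance deviation, percentage points). The engine's
#' defaults are 40/15/100 for precursors and 20/15/50 for products.
#'
#' @param ipaco Abundance cutoff in percent, `[0, 100)`.
#' @param ipmd m/z tolerance in ppm, > 0.
#' @param ipad Abundance-deviation tolerance in percentage points, >= 0.
#' @param scope `"product"` or `"precursor"` (informational).
#' @return An object of class `search_params`.
#' @export
search_params <- function(ipaco = 20, ipmd = 15, ipad = 50,
                          scope = c("product", "precursor")) {
  scope <- match.arg(scope)
  if (ipaco < 0 || ipaco >= 100) stop("ipaco must be in [0, 100)")
  if (ipmd <= 0) stop("ipmd must be > 0")
  if (ipad < 0) stop("ipad must be >= 0")
  structure(list(ipaco = ipaco, ipmd = ipmd, ipad = ipad, scope = scope),
            class = "search_params")
}

#' Create a centroid spectrum
#'
#' @param mz Numeric vector of peak m/z values (need not be pre-sorted).
#' @param abundance Absolute abundances, same length, all > 0.
#' @param precursor_mz,precursor_charge Optional precursor metadata.
#' @param scan_id Spectrum identifier.
#' @param rt Retention time (seconds), optional.
#' @return An object of class `centroid_spectrum` with peaks sorted by m/z.
#' @export
centroid_spectrum <- function(mz, abundance, precursor_mz = NA_real_,
                              precursor_charge = NA_integer_,
                              scan_id = "", rt = NA_real_) {
  if (length(mz) != length(abundance))
    stop("mz and abundance lengths differ")
  if (any(abundance <= 0)) stop("abundances must be positive")
  o <- order(mz)
  mz <- mz[o]; abundance <- abundance[o]
  if (any(diff(mz) <= 0)) stop("duplicate m/z values in spectrum")
  structure(list(mz = mz, abundance = abundance,
                 precursor_mz = precursor_mz,
                 precursor_charge = precursor_charge,
                 scan_id = scan_id, rt = rt),
            class = "centroid_spectrum")
}

#' @export
print.centroid_spectrum <- function(x, ...) {
  cat(sprintf("<centroid_spectrum> %s: %d peaks, m/z %.4f-%.4f\n",
              x$scan_id, length(x$mz),
              if (length(x$mz)) min(x$mz) else NA,
              if (length(x$mz)) max(x$mz) else NA))
  invisible(x)
}

#' Isotopic peak m/z deviation (ppm, signed)
#'
#' `1e6 * (exp_mz - theo_mz) / theo_mz`. Reports round it to the nearest
#' integer; tolerance checks always use the unrounded value.
#'
#' @param theo_mz Theoretical m/z (> 0).
#' @param exp_mz Experimental m/z.
#' @return Signed deviation in ppm (vectorized).
#' @export
ipmd <- function(theo_mz, exp_mz) {
  1e6 * (exp_mz - theo_mz) / theo_mz
}

#' Isotopic peak abundance deviation (percentage points, signed)
#'
#' `exp_rel - theo_rel`, both on the percent scale. A percentage-point
#' difference, not a ratio.
#'
#' @param theo_rel Theoretical relative abundance (percent).
#' @param exp_rel Experimental relative abundance (percent).
#' @return Signed deviation in percentage points (vectorized).
#' @export
ipad <- function(theo_rel, exp_rel) {
  exp_rel - theo_rel
}

# nearest spectrum peak to `target` within ppm tolerance; ties -> smaller
# |dm/z|, then lower m/z. Returns index or NA.
.nearest_peak <- function(spec_mz, target, ppm_tol) {
  n <- length(spec_mz)
  if (n == 0) return(NA_integer_)
  i <- findInterval(target, spec_mz)
  cand <- unique(pmax(1L, pmin(n, c(i, i + 1L))))
  d <- abs(spec_mz[cand] - target)
  best <- cand[order(d, spec_mz[cand])][1]
  if (abs(ipmd(target, spec_mz[best])) <= ppm_tol) best else NA_integer_
}

#' Fish one ion from a spectrum
#'
#' An ion is fished only if its theoretically highest (100%) isotopic peak
#' is observed within the IPMD tolerance. Every theoretical peak is then
#' linked to its nearest experimental peak within tolerance (ties: smaller
#' m/z difference, then lower m/z), a reference peak is selected (see
#' [select_reference()]), and per-peak experimental relative abundances and
#' IPADs are computed against it.
#'
#' @param ion A one-row `ion_db` slice or a list with at least `label` and
#'   `envelope` (an IPACO-truncated `theo_envelope`).
#' @param spec A `centroid_spectrum`.
#' @param params A [search_params()] object.
#' @param oip_peaks Experimental-peak indices known to be overlapping
#'   (excluded from reference choice); normally filled in by
#'   [resolve_spectrum()] after OIP detection.
#' @return An object of class `envelope_match`, or NULL if the base peak
#'   is not observed (or the spectrum is empty).
#' @export
fish_ion <- function(ion, spec, params, oip_peaks = integer(0)) {
  if (is.data.frame(ion)) {
    stopifnot(nrow(ion) == 1)
    ion <- list(label = ion$label, series = ion$series, index = ion$index,
                nl = ion$nl, charge = ion$charge,
                envelope = ion$envelope[[1]])
  }
  env <- ion$envelope
  if (length(spec$mz) == 0) return(NULL)
  links <- vapply(env$mz, .nearest_peak, integer(1),
                  spec_mz = spec$mz, ppm_tol = params$ipmd)
  if (is.na(links[env$base_index])) return(NULL)
  m <- structure(list(
    label = ion$label,
    series = if (!is.null(ion$series)) ion$series else NA_character_,
    index = if (!is.null(ion$index)) ion$index else NA_integer_,
    nl = if (!is.null(ion$nl)) ion$nl else "none",
    charge = env$charge,
    theo_mz = env$mz,
    theo_rel = env$rel,
    base_index = env$base_index,
    exp_idx = links,
    exp_mz = ifelse(is.na(links), NA_real_, spec$mz[links]),
    exp_abund = ifelse(is.na(links), NA_real_, spec$abundance[links]),
    ipmd = ifelse(is.na(links), NA_real_,
                  ipmd(env$mz, spec$mz[links])),
    exp_rel = rep(NA_real_, length(links)),
    ipad = rep(NA_real_, length(links)),
    reference_index = NA_integer_,
    reference_degenerate = FALSE,
    verdict = NA_character_
  ), class = "envelope_match")
  m$reference_index <- select_reference(m, oip_peaks)
  m <- .update_relatives(m)
  m
}

#' Select the reference isotopic peak of a match
#'
#' The reference peak normalizes the ion's absolute experimental abundances
#' to the theoretical relative scale (its IPAD is 0 by construction). Among
#' linked theoretical peaks whose experimental peak is not overlapping, the
#' one with the highest theoretical relative abundance is chosen (ties:
#' lower m/z). If every linked peak is overlapping, the linked peak with
#' the smallest |IPAD| under a provisional base-peak normalization is used
#' and the match is flagged `reference_degenerate`.
#'
#' @param match An `envelope_match`.
#' @param oip_peaks Experimental-peak indices that are overlapping.
#' @return The chosen theoretical-peak index (side effect free; the caller
#'   stores it). Sets no fields itself.
#' @export
select_reference <- function(match, oip_peaks = integer(0)) {
  linked <- which(!is.na(match$exp_idx))
  if (length(linked) == 0) stop("match has no linked peaks")
  clean <- linked[!(match$exp_idx[linked] %in% oip_peaks)]
  if (length(clean) > 0) {
    return(clean[order(-match$theo_rel[clean], match$theo_mz[clean])][1])
  }
  # degenerate: every linked peak is shared; normalize provisionally at the
  # base peak and pick the linked peak with smallest |IPAD|
  base <- match$base_index
  rel <- match$exp_abund[linked] * match$theo_rel[base] /
    match$exp_abund[base]
  dev <- abs(rel - match$theo_rel[linked])
  linked[order(dev, match$theo_mz[linked])][1]
}

# recompute exp_rel / ipad from the current reference and abundances
.update_relatives <- function(match) {
  r <- match$reference_index
  ea_r <- match$exp_abund[r]
  ta_r <- match$theo_rel[r]
  match$exp_rel <- match$exp_abund * ta_r / ea_r
  match$ipad <- ipad(match$theo_rel, match$exp_rel)
  match
}

#' Classify a match as matching or non-matching
#'
#' An ion has an ideal isotopic envelope -- and is a matching product ion
#' (MP) -- iff every above-IPACO theoretical peak is linked to an observed
#' experimental peak, all |IPMD| are within the m/z tolerance, and all
#' |IPAD| within the abundance tolerance. Anything else is non-matching.
#'
#' @param match An `envelope_match`.
#' @param params A [search_params()] object.
#' @return `"matching"` or `"non-matching"`.
#' @export
classify_match <- function(match, params) {
  if (any(is.na(match$exp_idx))) return("non-matching")
  if (any(abs(match$ipmd) > params$ipmd)) return("non-matching")
  if (any(abs(match$ipad) > params$ipad)) return("non-matching")
  "matching"
}

#' Fish every ion of a database from one spectrum
#'
#' @param db An `ion_db`.
#' @param spec A `centroid_spectrum`.
#' @param params A [search_params()] object.
#' @param oip_peaks See [fish_ion()].
#' @return A named list of `envelope_match` objects (one per fished ion),
#'   with verdicts assigned.
#' @export
fish_spectrum <- function(db, spec, params, oip_peaks = integer(0)) {
  matches <- list()
  for (i in seq_len(nrow(db))) {
    m <- fish_ion(db[i, , drop = FALSE], spec, params, oip_peaks)
    if (!is.null(m)) {
      m$verdict <- classify_match(m, params)
      matches[[m$label]] <- m
    }
  }
  matches
}

#' Find overlapping isotopic peaks among fished ions
#'
#' An OIP is an experimental peak linked by theoretical peaks of two or
#' more distinct ions. Each OIP yields one group carrying, per claimant,
#' the theoretical relative abundance of the shared peak and the claimant's
#' current reference data.
#'
#' @param matches A list of `envelope_match` objects from one spectrum.
#' @param spec The `centroid_spectrum` the matches came from.
#' @return A list of `oip_group` objects: each has `exp_idx`, `exp_mz`,
#'   `ea_oip` (observed abundance) and a data.frame `claimants` with
#'   columns `label`, `theo_peak`, `ta_i`, `ea_r`, `ta_r`, `degenerate`.
#' @export
find_oips <- function(matches, spec) {
  if (length(matches) == 0) return(list())
  claims <- do.call(rbind, lapply(matches, function(m) {
    linked <- which(!is.na(m$exp_idx))
    data.frame(label = m$label, theo_peak = linked,
               exp_idx = m$exp_idx[linked], stringsAsFactors = FALSE)
  }))
  counts <- tapply(claims$label, claims$exp_idx,
                   function(x) length(unique(x)))
  shared <- as.integer(names(counts)[counts >= 2])
  lapply(shared, function(pi) {
    cl <- claims[claims$exp_idx == pi, , drop = FALSE]
    claimants <- do.call(rbind, lapply(seq_len(nrow(cl)), function(k) {
      m <- matches[[cl$label[k]]]
      r <- m$reference_index
      data.frame(label = cl$label[k], theo_peak = cl$theo_peak[k],
                 ta_i = m$theo_rel[cl$theo_peak[k]],
                 ea_r = m$exp_abund[r], ta_r = m$theo_rel[r],
                 degenerate = m$reference_degenerate,
                 stringsAsFactors = FALSE)
    }))
    rownames(claimants) <- NULL
    structure(list(exp_idx = pi, exp_mz = spec$mz[pi],
                   ea_oip = spec$abundance[pi], claimants = claimants),
              class = "oip_group")
  })
}

#' Tabular match report
#'
#' One row per theoretical peak per fished ion, in the documented column
#' order: `ion`, `theo_mz`, `theo_rel`, `exp_mz`, `exp_abund`, `exp_rel`,
#' `ipmd`, `ipad`, `is_oip`, `verdict`. IPMD/IPAD are rounded to the
#' nearest integer, relative abundances to 2 decimals and absolute
#' abundances to 6 (display convention; tolerance checks elsewhere use
#' unrounded values).
#'
#' @param matches A list of `envelope_match` objects.
#' @param oip_peaks Experimental-peak indices that are OIPs (e.g. from
#'   [find_oips()] groups).
#' @return A data.frame.
#' @export
match_report <- function(matches, oip_peaks = integer(0)) {
  if (length(matches) == 0)
    return(data.frame(ion = character(0), theo_mz = numeric(0),
                      theo_rel = numeric(0), exp_mz = numeric(0),
                      exp_abund = numeric(0), exp_rel = numeric(0),
                      ipmd = integer(0), ipad = integer(0),
                      is_oip = logical(0), verdict = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(matches, function(m) {
    data.frame(ion = m$label,
               theo_mz = round(m$theo_mz, 6),
               theo_rel = round(m$theo_rel, 2),
               exp_mz = round(m$exp_mz, 6),
               exp_abund = round(m$exp_abund, 6),
               exp_rel = round(m$exp_rel, 2),
               ipmd = as.integer(round(m$ipmd)),
               ipad = as.integer(round(m$ipad)),
               is_oip = !is.na(m$exp_idx) & m$exp_idx %in% oip_peaks,
               verdict = m$verdict,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
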